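#' Export a social network to GraphML or an edge-list CSV
#'
#' GraphML files carry node attributes (`sex`, `life_stage`, `centrality`,
#' `community`, when supplied) and the edge attribute `weight`; weights are
#' written with full double precision so a re-import reproduces them
#' exactly. The edge-list CSV has columns `source,target,weight`, one row
#' per nonzero dyad (upper triangle).
#'
#' @param network a [social_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param partition optional [fast_greedy_partition()] result (or a tibble
#'   with `id`, `community`).
#' @param scores optional [eigenvector_centrality()] tibble.
#' @param roster optional roster tibble supplying `sex` and `life_stage`
#'   per node id.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edgelist"),
                           partition = NULL, scores = NULL, roster = NULL) {
  stopifnot(inherits(network, "social_network"))
  format <- match.arg(format)
  ids <- network$ids
  w <- network$weights

  node_attr <- tibble::tibble(id = ids)
  if (!is.null(roster)) {
    node_attr <- dplyr::left_join(
      node_attr,
      dplyr::select(roster, "id", "sex", "life_stage"),
      by = "id"
    )
  }
  if (!is.null(scores)) {
    node_attr <- dplyr::left_join(node_attr, scores, by = "id")
  }
  if (!is.null(partition)) {
    pt <- if (inherits(partition, "community_partition")) {
      partition$partition
    } else {
      partition
    }
    node_attr <- dplyr::left_join(node_attr, pt, by = "id")
  }

  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = ids[ut[, 1]],
    target = ids[ut[, 2]],
    weight = w[ut]
  )

  if (format == "edgelist") {
    readr::write_csv(edges, path, progress = FALSE)
    return(invisible(path))
  }

  num <- function(v) sprintf("%.17g", v)
  esc <- function(v) {
    v <- gsub("&", "&amp;", v, fixed = TRUE)
    v <- gsub("<", "&lt;", v, fixed = TRUE)
    gsub(">", "&gt;", v, fixed = TRUE)
  }
  keys <- c(
    '  <key id="d_weight" for="edge" attr.name="weight" attr.type="double"/>'
  )
  attr_cols <- setdiff(names(node_attr), "id")
  for (col in attr_cols) {
    type <- if (is.numeric(node_attr[[col]])) "double" else "string"
    keys <- c(keys, sprintf(
      '  <key id="d_%s" for="node" attr.name="%s" attr.type="%s"/>',
      col, col, type
    ))
  }
  nodes_xml <- purrr::map_chr(seq_along(ids), function(i) {
    data <- purrr::map_chr(attr_cols, function(col) {
      v <- node_attr[[col]][i]
      if (is.na(v)) {
        return("")
      }
      val <- if (is.numeric(v)) num(v) else esc(as.character(v))
      sprintf('      <data key="d_%s">%s</data>', col, val)
    })
    data <- data[data != ""]
    paste(
      c(
        sprintf('    <node id="%s">', esc(ids[i])), data,
        "    </node>"
      ),
      collapse = "\n"
    )
  })
  edges_xml <- purrr::map_chr(seq_len(nrow(edges)), function(i) {
    paste(
      c(
        sprintf(
          '    <edge source="%s" target="%s">',
          esc(edges$source[i]), esc(edges$target[i])
        ),
        sprintf('      <data key="d_weight">%s</data>', num(edges$weight[i])),
        "    </edge>"
      ),
      collapse = "\n"
    )
  })
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keys,
    '  <graph edgedefault="undirected">',
    nodes_xml,
    edges_xml,
    "  </graph>",
    "</graphml>"
  )
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Re-import a GraphML file written by [export_network()]
#'
#' @param path GraphML path.
#' @param weight_kind weight label to record on the returned network.
#' @return a [social_network()] with node attributes (if present) in
#'   attribute `node_attributes`.
#' @export
read_graphml <- function(path, weight_kind = "count") {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  ids <- xml2::xml_attr(node_els, "id")
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  for (e in edge_els) {
    s <- xml2::xml_attr(e, "source")
    t <- xml2::xml_attr(e, "target")
    wt <- as.numeric(xml2::xml_text(
      xml2::xml_find_first(e, './/g:data[@key="d_weight"]', ns)
    ))
    w[s, t] <- wt
    w[t, s] <- wt
  }
  attrs <- purrr::map_dfr(node_els, function(nd) {
    data <- xml2::xml_find_all(nd, ".//g:data", ns)
    vals <- stats::setNames(
      as.list(xml2::xml_text(data)),
      sub("^d_", "", xml2::xml_attr(data, "key"))
    )
    tibble::as_tibble(c(list(id = xml2::xml_attr(nd, "id")), vals))
  })
  net <- social_network(w, weight_kind = weight_kind)
  attr(net, "node_attributes") <- attrs
  net
}
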