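#' Per-individual and dyadic sighting counts from an observation log
#'
#' The unit of association is the recording: two individuals are associated
#' when they appear in the same camera-trap recording. `n_i` counts the
#' recordings containing node `i`; `x_ij` counts the recordings containing
#' both `i` and `j`. A `collapse_map` can merge raw ids onto a single node
#' (e.g. all pups onto one `"Pups"` node); a recording containing several
#' merged ids counts once for the merged node. Unidentified occupants do
#' not contribute to any node but do not invalidate the recording for its
#' identified occupants.
#'
#' @param log an [observation_log()] with at least one event.
#' @param node_ids character vector of node ids to tally; defaults to all
#'   roster ids after applying `collapse_map`.
#' @param collapse_map named character vector mapping raw ids to node ids
#'   (e.g. `c(P1 = "Pups", P2 = "Pups")`); unmapped ids keep their own name.
#' @return an object of class `sighting_summary`: a list with `ids`, `n`
#'   (named integer vector) and `x` (symmetric matrix of joint counts with
#'   `x[i, i] = n_i`).
#' @export
cooccurrence_counts <- function(log, node_ids = NULL, collapse_map = NULL) {
  stopifnot(inherits(log, "observation_log"))
  if (nrow(log$events) == 0) {
    stop("cannot tally co-occurrences from an empty log", call. = FALSE)
  }
  map_id <- function(ids) {
    ids <- setdiff(ids, UNIDENTIFIED)
    if (!is.null(collapse_map)) {
      hit <- ids %in% names(collapse_map)
      ids[hit] <- collapse_map[ids[hit]]
    }
    unique(ids)
  }
  if (is.null(node_ids)) {
    node_ids <- unique(map_id(log$roster$id))
  }
  occupants <- log$events |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(
      who = list(unique(unlist(.data$present))),
      .groups = "drop"
    )
  k <- length(node_ids)
  x <- matrix(0L, k, k, dimnames = list(node_ids, node_ids))
  for (who in occupants$who) {
    nodes <- intersect(map_id(who), node_ids)
    if (length(nodes) == 0) next
    x[nodes, nodes] <- x[nodes, nodes] + 1L
  }
  structure(
    list(ids = node_ids, n = stats::setNames(diag(x), node_ids), x = x),
    class = "sighting_summary"
  )
}

#' @export
print.sighting_summary <- function(x, ...) {
  cat(
    "<sighting_summary> ", length(x$ids), " nodes, ",
    sum(x$x[upper.tri(x$x)] > 0), " associated dyads\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a weighted association network
#'
#' Edge weights are either raw joint-sighting counts
#' (`weight_kind = "count"`, the default: sociogram edges weighted by the
#' number of recorded associations) or the simple-ratio association index
#' `SRI_ij = x_ij / (n_i + n_j - x_ij)`, the fraction of sightings of
#' either member of the dyad in which both were together.
#'
#' @param summary a [cooccurrence_counts()] summary.
#' @param weight_kind `"count"` or `"sri"`.
#' @return an object of class `social_network`: a list with `ids`,
#'   `weights` (symmetric non-negative matrix, zero diagonal) and
#'   `weight_kind`.
#' @export
association_matrix <- function(summary, weight_kind = c("count", "sri")) {
  stopifnot(inherits(summary, "sighting_summary"))
  weight_kind <- match.arg(weight_kind)
  x <- summary$x
  n <- summary$n
  if (weight_kind == "count") {
    w <- x
  } else {
    denom <- outer(n, n, "+") - x
    w <- ifelse(denom > 0, x / ifelse(denom > 0, denom, 1), 0)
  }
  diag(w) <- 0
  social_network(w, weight_kind = weight_kind)
}

#' Low-level social-network constructor
#'
#' @param weights symmetric non-negative matrix with id dimnames and zero
#'   diagonal.
#' @param weight_kind label recording how the weights were derived.
#' @return a `social_network`.
#' @export
social_network <- function(weights, weight_kind = "count") {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <- paste0("N", seq_len(nrow(weights)))
  }
  if (!isTRUE(all.equal(weights, t(weights)))) {
    stop("association weights must be symmetric", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (any(diag(weights) != 0)) {
    stop("weight matrix must have a zero diagonal", call. = FALSE)
  }
  structure(
    list(
      ids = rownames(weights),
      weights = weights,
      weight_kind = weight_kind
    ),
    class = "social_network"
  )
}

#' @export
print.social_network <- function(x, ...) {
  cat(
    "<social_network> ", length(x$ids), " nodes, ",
    sum(x$weights[upper.tri(x$weights)] > 0), " edges (",
    x$weight_kind, " weights)\n",
    sep = ""
  )
  invisible(x)
}

#' Connected components of a network on its nonzero weights
#' @keywords internal
network_components <- function(weights) {
  n <- nrow(weights)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nxt <- which(colSums(weights[frontier, , drop = FALSE] > 0) > 0)
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

#' Eigenvector centrality of a weighted association network
#'
#' Scores are proportional to the leading eigenvector of the symmetric
#' weight matrix, computed by power iteration started from the uniform
#' vector; each iterate is scaled to maximum 1 and iteration stops when two
#' successive iterates differ by less than `tol` in max-norm. The iteration
#' runs on the diagonally shifted matrix `A + sI` (s = the largest weighted
#' degree), which has the same eigenvectors as `A` but a strictly dominant
#' leading eigenvalue, so bipartite-like networks cannot oscillate. The
#' returned scores are scaled so the most central node has score exactly 1.
#' High scores mean many and/or strong connections, directly or through
#' well-connected partners.
#'
#' @param network a [social_network()].
#' @param tol convergence tolerance (max-norm), default `1e-12`.
#' @param max_iter iteration cap.
#' @param largest_component if `TRUE`, a disconnected network is restricted
#'   to its largest connected component (ties broken by first node) instead
#'   of raising an error.
#' @return a tibble of class `centrality_scores` with columns `id` and
#'   `centrality`.
#' @export
eigenvector_centrality <- function(network, tol = 1e-12, max_iter = 1e5,
                                   largest_component = FALSE) {
  stopifnot(inherits(network, "social_network"))
  w <- network$weights
  if (all(w == 0)) {
    stop("all association weights are zero; centrality undefined",
      call. = FALSE
    )
  }
  comp <- network_components(w)
  if (max(comp) > 1) {
    if (!largest_component) {
      stop(
        "network is disconnected (", max(comp), " components); ",
        "set largest_component = TRUE to analyse the largest one",
        call. = FALSE
      )
    }
    keep <- comp == which.max(tabulate(comp))
    w <- w[keep, keep, drop = FALSE]
  }
  m <- w + diag(max(rowSums(w)), nrow(w))
  v <- rep(1, nrow(w))
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(m %*% v)
    v_new <- v_new / max(v_new)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  out <- tibble::tibble(id = rownames(w), centrality = v / max(v))
  class(out) <- c("centrality_scores", class(out))
  out
}

#' Weighted modularity of a node partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]` with `A` the
#' symmetric weight matrix, `k_i` the weighted degree and `2m` the total
#' weight. `Q` compares the within-community weight fraction with its
#' expectation under a degree-preserving random network; values above about
#' 0.3 are conventionally read as strong community structure.
#'
#' @param network a [social_network()].
#' @param partition named vector (or factor) of community labels covering
#'   every node id.
#' @return modularity `Q`, a single number.
#' @export
modularity_q <- function(network, partition) {
  stopifnot(inherits(network, "social_network"))
  a <- network$weights
  if (all(a == 0)) {
    stop("all weights are zero; modularity undefined", call. = FALSE)
  }
  if (is.null(names(partition))) {
    if (length(partition) != length(network$ids)) {
      stop("partition must be named or match the node order", call. = FALSE)
    }
    names(partition) <- network$ids
  }
  if (!all(network$ids %in% names(partition))) {
    stop("partition must cover every node", call. = FALSE)
  }
  cc <- as.character(partition[network$ids])
  two_m <- sum(a)
  k <- rowSums(a)
  same <- outer(cc, cc, "==")
  sum((a - outer(k, k) / two_m) * same) / two_m
}
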