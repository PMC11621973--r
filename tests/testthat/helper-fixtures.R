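# Fixture builders and independent oracles shared across the suite.

make_roster <- function(ids, life_stage = "adult", sex = "unknown",
                        entry = "2023-01-01", exit = NA) {
  tibble::tibble(
    id = ids,
    sex = rep_len(sex, length(ids)),
    life_stage = rep_len(life_stage, length(ids)),
    entry_date = as.Date(rep_len(entry, length(ids))),
    exit_date = as.Date(rep_len(exit, length(ids)))
  )
}

make_event <- function(recording_id, timestamp, behaviour, actor,
                       recipient = NA_character_, present = NULL,
                       camera_id = "C1") {
  if (is.null(present)) {
    present <- setdiff(c(actor, recipient), c(NA_character_, "UNIDENTIFIED"))
  }
  tibble::tibble(
    recording_id = recording_id,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    camera_id = camera_id,
    behaviour = behaviour,
    actor = actor,
    recipient = recipient,
    present = list(present)
  )
}

make_log <- function(roster, ...) {
  events <- dplyr::bind_rows(...)
  observation_log(roster, if (nrow(events) > 0) events else NULL)
}

named_square <- function(values, ids) {
  matrix(values, length(ids), length(ids),
    byrow = TRUE, dimnames = list(ids, ids)
  )
}

# weight matrix from an edge list: rows (i, j, w)
edge_weights <- function(ids, edges) {
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- e[[3]]
    w[e[[2]], e[[1]]] <- e[[3]]
  }
  w
}

unit_triangles_bridged <- function(bridge = 1) {
  ids <- letters[1:6]
  edges <- list(
    list("a", "b", 1), list("b", "c", 1), list("a", "c", 1),
    list("d", "e", 1), list("e", "f", 1), list("d", "f", 1)
  )
  if (bridge > 0) edges <- c(edges, list(list("c", "d", bridge)))
  social_network(edge_weights(ids, edges))
}

# random symmetric weighted graph; resamples until connected
random_connected_network <- function(n, p_edge = 0.5) {
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on_edge <- stats::runif(sum(ut)) < p_edge
    vals <- ifelse(on_edge, stats::runif(sum(ut), 0.1, 3), 0)
    w[ut] <- vals
    w <- w + t(w)
    dimnames(w) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
    comp <- packsocial:::network_components(w)
    if (max(comp) == 1 && any(w > 0)) {
      return(social_network(w))
    }
  }
}

# --- independent oracles -------------------------------------------------

# modularity by an explicit double loop over node pairs
oracle_modularity <- function(w, membership) {
  two_m <- sum(w)
  k <- unname(rowSums(w))
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + w[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}

# leading eigenvector via a full symmetric eigendecomposition
oracle_centrality <- function(w) {
  dec <- eigen(w, symmetric = TRUE)
  v <- dec$vectors[, which.max(dec$values)]
  v <- v * sign(v[which.max(abs(v))])
  v / max(v)
}

# all set partitions of seq_len(n) as restricted-growth strings
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, next_label) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(assign, lab), max(next_label, lab + 1))
    }
  }
  recurse(integer(0), 1)
  out
}

# exhaustive modularity maximum using the oracle Q
oracle_best_partition <- function(w) {
  parts <- all_set_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_modularity(w, p), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# canonical form of a partition for set-of-sets comparison
partition_groups <- function(ids, membership) {
  unname(sort(vapply(
    split(ids, membership),
    function(g) paste(sort(g), collapse = ","), character(1)
  )))
}
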