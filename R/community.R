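#' Fast-greedy community detection (hierarchical modularity agglomeration)
#'
#' Starts from singleton communities and repeatedly merges the pair of
#' currently *connected* communities giving the largest modularity gain
#' `dQ = 2 (e_ij - a_i a_j)`, where `e_ij` is the fraction of total edge
#' weight between communities `i` and `j` and `a_i` the fraction of edge
#' ends attached to `i`. Ties are broken by the lexicographically smallest
#' pair of community labels (a community is labelled by its smallest member
#' id), so runs are bit-reproducible. The returned partition is the state
#' of maximum modularity along the full merge trace, which includes the
#' initial all-singleton state.
#'
#' @param network a connected [social_network()] with at least 2 nodes.
#' @param threshold modularity above which the partition is flagged as
#'   strong community structure (conventional value 0.3).
#' @return an object of class `community_partition`: a list with
#'   \describe{
#'     \item{partition}{tibble `id`, `community` (community = smallest
#'       member id) at the modularity maximum}
#'     \item{merges}{tibble of the N-1 merges: `step`, `a`, `b` (labels of
#'       the merged communities) and `q` after the merge; step 0 is the
#'       singleton state}
#'     \item{q_max}{maximum modularity along the trace}
#'     \item{n_communities}{number of communities at the maximum}
#'     \item{strong_structure}{`q_max > threshold`}
#'   }
#' @export
fast_greedy_partition <- function(network, threshold = 0.3) {
  stopifnot(inherits(network, "social_network"))
  w <- network$weights
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (all(w == 0)) stop("all weights are zero", call. = FALSE)
  if (max(network_components(w)) > 1) {
    stop("network is disconnected; analyse components separately",
      call. = FALSE
    )
  }
  ids <- rownames(w)
  two_m <- sum(w)
  # e[i, j]: fraction of edge weight between current communities i and j
  e <- w / two_m
  a <- rowSums(e)
  members <- stats::setNames(as.list(ids), ids) # community label -> member ids
  label_of <- stats::setNames(ids, ids) # node -> community label
  q <- sum(diag(e)) - sum(a^2)

  trace_q <- q
  merge_a <- character(0)
  merge_b <- character(0)
  assignments <- list(label_of)

  for (step in seq_len(n - 1)) {
    labs <- rownames(e)
    k <- length(labs)
    dq <- 2 * (e - outer(a, a))
    connected <- e > 0
    diag(connected) <- FALSE
    dq[!connected] <- -Inf
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    best <- max(dq)
    if (!is.finite(best)) break # should not happen on a connected network
    cand <- which(dq == best, arr.ind = TRUE)
    # lexicographic tie-break on the sorted label pair
    pair_key <- apply(cand, 1, function(rc) {
      p <- sort(c(labs[rc[1]], labs[rc[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]
    j <- pick[2]
    la <- labs[i]
    lb <- labs[j]
    new_label <- min(la, lb)

    # merge community j into i
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    e[i, i] <- e[i, i] # off-diagonal mass between i and j now on diagonal
    e <- e[-j, -j, drop = FALSE]
    a <- rowSums(e) # recompute; cheap at these sizes
    rownames(e)[rownames(e) == la] <- new_label
    colnames(e) <- rownames(e)
    names(a) <- rownames(e)

    merged_members <- c(members[[la]], members[[lb]])
    members[[la]] <- NULL
    members[[lb]] <- NULL
    members[[new_label]] <- merged_members
    label_of[merged_members] <- new_label

    q <- q + best
    trace_q <- c(trace_q, q)
    merge_a <- c(merge_a, la)
    merge_b <- c(merge_b, lb)
    assignments[[length(assignments) + 1]] <- label_of
  }

  best_state <- which.max(trace_q)
  best_assign <- assignments[[best_state]]
  partition <- tibble::tibble(
    id = ids,
    community = unname(best_assign[ids])
  )
  merges <- tibble::tibble(
    step = seq_along(trace_q) - 1L,
    a = c(NA_character_, merge_a),
    b = c(NA_character_, merge_b),
    q = trace_q
  )
  structure(
    list(
      partition = partition,
      merges = merges,
      q_max = trace_q[best_state],
      n_communities = length(unique(partition$community)),
      strong_structure = trace_q[best_state] > threshold,
      threshold = threshold
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(
    "<community_partition> ", x$n_communities, " communities, Q = ",
    format(x$q_max, digits = 6),
    if (x$strong_structure) " (strong structure)" else " (weak structure)",
    "\n",
    sep = ""
  )
  invisible(x)
}
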