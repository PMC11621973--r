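#' Tidy a kappa result into a one-row tibble
#'
#' @param x a [cohens_kappa()] result.
#' @param ... unused.
#' @return a tibble with `kappa`, `p_o`, `p_e`, `n`, `n_labels`.
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, p_o = x$p_o, p_e = x$p_e,
    n = x$n, n_labels = length(x$labels)
  )
}

#' @rdname tidy.kappa_result
#' @export
glance.kappa_result <- function(x, ...) tidy.kappa_result(x)

#' Tidy a community partition into a node-level tibble
#'
#' @param x a [fast_greedy_partition()] result.
#' @param ... unused.
#' @return the node -> community tibble.
#' @export
tidy.community_partition <- function(x, ...) x$partition

#' One-row summary of a community partition
#'
#' @param x a [fast_greedy_partition()] result.
#' @param ... unused.
#' @return a tibble with `q_max`, `n_communities`, `strong_structure`.
#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(
    q_max = x$q_max,
    n_communities = x$n_communities,
    strong_structure = x$strong_structure
  )
}

#' Generic tidiers
#'
#' `tidy()` returns an observation- or node-level tibble; `glance()` a
#' one-row model-level summary, following the broom convention.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.davids_score_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.davids_score_table <- function(x, ...) {
  tibble::tibble(
    n_individuals = attr(x, "n_individuals"),
    sum_ds = sum(x$ds),
    sum_norm_ds = sum(x$norm_ds),
    total_interactions = sum(x$total_wins)
  )
}

#' @export
tidy.social_network <- function(x, ...) {
  ut <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble::tibble(
    from = x$ids[ut[, 1]],
    to = x$ids[ut[, 2]],
    weight = x$weights[ut]
  ) |>
    dplyr::filter(.data$weight > 0)
}

#' @export
glance.social_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  tibble::tibble(
    n_nodes = length(x$ids),
    n_edges = sum(w > 0),
    total_weight = sum(w),
    weight_kind = x$weight_kind
  )
}
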