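#' Build a dominance matrix from coded agonistic and scent-marking events
#'
#' Three behaviours contribute "wins", each worth exactly one point:
#' \itemize{
#'   \item aggression: the aggressor gains a win over the recipient;
#'   \item submission: the recipient of the submissive display gains a win
#'     over the displayer;
#'   \item scent marking: the marker gains a win over every other adult that
#'     was a group member on the day of the event (tenure-based roster), the
#'     literal reading of "towards the rest of the group". Set
#'     `scent_mark = "single"` for the alternative of one aggregate win,
#'     split evenly across the other members so each mark still contributes
#'     one point in total.
#' }
#' Events involving an `UNIDENTIFIED` actor or recipient cannot be
#' attributed and are skipped; their number is kept in the `n_skipped`
#' attribute.
#'
#' @param log an [observation_log()].
#' @param adults character vector of ids to include (at least 2); defaults
#'   to all roster adults.
#' @param scent_mark `"fan_out"` (default: one win against each other
#'   member present in the group that day) or `"single"` (one point split
#'   across them).
#' @return an object of class `dominance_matrix`: a square non-negative
#'   matrix `wins` with `wins[i, j]` the number of wins of `i` over `j`,
#'   zero diagonal, and attribute `n_skipped`.
#' @export
build_dominance_matrix <- function(log, adults = NULL,
                                   scent_mark = c("fan_out", "single")) {
  stopifnot(inherits(log, "observation_log"))
  scent_mark <- match.arg(scent_mark)
  if (is.null(adults)) {
    adults <- log$roster$id[log$roster$life_stage == "adult"]
  }
  if (length(adults) < 2) {
    stop("need at least 2 individuals to build a dominance matrix",
      call. = FALSE
    )
  }
  if (!all(adults %in% log$roster$id)) {
    stop("adults must be a subset of the roster", call. = FALSE)
  }
  wins <- matrix(0, length(adults), length(adults),
    dimnames = list(adults, adults)
  )
  n_skipped <- 0L
  ev <- log$events[log$events$behaviour %in%
    c("aggression", "submission", "scent marking"), ]
  roster <- log$roster
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$actor == UNIDENTIFIED ||
      (!is.na(e$recipient) && e$recipient == UNIDENTIFIED)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (e$behaviour == "aggression") {
      if (e$actor %in% adults && e$recipient %in% adults) {
        wins[e$actor, e$recipient] <- wins[e$actor, e$recipient] + 1
      }
    } else if (e$behaviour == "submission") {
      if (e$actor %in% adults && e$recipient %in% adults) {
        wins[e$recipient, e$actor] <- wins[e$recipient, e$actor] + 1
      }
    } else { # scent marking
      if (!(e$actor %in% adults)) next
      day <- as.Date(e$timestamp, tz = "UTC")
      members <- roster$id[
        roster$entry_date <= day &
          (is.na(roster$exit_date) | roster$exit_date >= day)
      ]
      others <- setdiff(intersect(members, adults), e$actor)
      if (length(others) == 0) next
      pt <- if (scent_mark == "fan_out") 1 else 1 / length(others)
      wins[e$actor, others] <- wins[e$actor, others] + pt
    }
  }
  structure(wins,
    class = c("dominance_matrix", "matrix"),
    n_skipped = n_skipped
  )
}

#' Coerce a labelled square win-count matrix to a dominance matrix
#'
#' @param wins square numeric matrix with identical dimnames, zero
#'   diagonal, non-negative entries.
#' @return a `dominance_matrix`.
#' @export
as_dominance_matrix <- function(wins) {
  wins <- as.matrix(wins)
  if (nrow(wins) != ncol(wins) ||
    is.null(rownames(wins)) || !identical(rownames(wins), colnames(wins))) {
    stop("wins must be square with identical row and column ids",
      call. = FALSE
    )
  }
  if (any(wins < 0)) stop("win counts must be non-negative", call. = FALSE)
  if (any(diag(wins) != 0)) stop("diagonal must be zero", call. = FALSE)
  structure(wins,
    class = c("dominance_matrix", "matrix"),
    n_skipped = attr(wins, "n_skipped") %||% 0L
  )
}

#' Dyadic win proportions from a dominance matrix
#'
#' `P[i, j] = s_ij / (s_ij + s_ji)` for dyads that interacted and 0 for
#' dyads never observed interacting (the plain proportion convention, the
#' default). `method = "dij"` applies the correction
#' `Dij = P_ij - (P_ij - 0.5) / (n_ij + 1)`, which shrinks proportions from
#' sparsely observed dyads towards one half.
#'
#' @param matrix a `dominance_matrix` (or coercible matrix).
#' @param method `"proportion"` (default) or `"dij"`.
#' @return a square numeric matrix of dyadic proportions with zero diagonal.
#' @export
dyadic_proportions <- function(matrix, method = c("proportion", "dij")) {
  method <- match.arg(method)
  if (!inherits(matrix, "dominance_matrix")) {
    matrix <- as_dominance_matrix(matrix)
  }
  s <- unclass(matrix)
  n_ij <- s + t(s)
  p <- ifelse(n_ij > 0, s / ifelse(n_ij > 0, n_ij, 1), 0)
  if (method == "dij") {
    p <- ifelse(n_ij > 0, p - (p - 0.5) / (n_ij + 1), 0)
  }
  diag(p) <- 0
  p
}

#' David's scores and normalised David's scores
#'
#' For each individual, from the dyadic proportion matrix `P`:
#' `w = sum_j P_ij` (win proportions), `w2 = sum_j w_j P_ij`
#' (opponent-weighted wins), `l = sum_j P_ji`, `l2 = sum_j l_j P_ji`,
#' `DS = w + w2 - l - l2`, and
#' `NormDS = (DS + N(N-1)/2) / N`, which maps DS onto `[0, N-1]`. Higher
#' NormDS means higher relative rank in the hierarchy.
#'
#' @param matrix a `dominance_matrix`.
#' @param method proportion convention passed to [dyadic_proportions()].
#' @return a tibble of class `davids_score_table` with columns `id`, `w`,
#'   `w2`, `l`, `l2`, `ds`, `norm_ds`, `total_wins`, `total_losses`, in the
#'   id order of the input matrix; attribute `n_individuals`.
#' @export
#' @examples
#' m <- matrix(c(0, 3, 0, 0), 2, 2,
#'   byrow = TRUE,
#'   dimnames = list(c("A", "B"), c("A", "B"))
#' )
#' davids_scores(as_dominance_matrix(m)) # NormDS 1 and 0
davids_scores <- function(matrix, method = c("proportion", "dij")) {
  method <- match.arg(method)
  if (!inherits(matrix, "dominance_matrix")) {
    matrix <- as_dominance_matrix(matrix)
  }
  n <- nrow(matrix)
  if (n < 2) stop("David's scores need at least 2 individuals", call. = FALSE)
  p <- dyadic_proportions(matrix, method = method)
  w <- rowSums(p)
  l <- colSums(p)
  w2 <- as.numeric(p %*% w)
  l2 <- as.numeric(t(p) %*% l)
  ds <- w + w2 - l - l2
  norm_ds <- (ds + n * (n - 1) / 2) / n
  s <- unclass(matrix)
  out <- tibble::tibble(
    id = rownames(matrix),
    w = unname(w), w2 = w2, l = unname(l), l2 = l2,
    ds = unname(ds), norm_ds = unname(norm_ds),
    total_wins = unname(rowSums(s)), total_losses = unname(colSums(s))
  )
  attr(out, "n_individuals") <- n
  class(out) <- c("davids_score_table", class(out))
  out
}

#' Rank a hierarchy by normalised David's score
#'
#' Orders individuals by NormDS (descending). Printed score tables can tie;
#' ties are broken deterministically by (1) more total raw wins, (2) fewer
#' total raw losses, (3) lexicographic id, and the criterion that decided
#' each individual's position relative to the next is recorded in
#' `tie_break`.
#'
#' @param table a [davids_scores()] table.
#' @return the table sorted by rank with added columns `rank` and
#'   `tie_break`.
#' @export
rank_hierarchy <- function(table) {
  stopifnot(inherits(table, "davids_score_table"))
  ord <- order(-table$norm_ds, -table$total_wins, table$total_losses,
    table$id)
  out <- table[ord, ]
  n <- nrow(out)
  tie_break <- rep("norm_ds", n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (out$norm_ds[i] != out$norm_ds[i + 1]) next
      if (out$total_wins[i] != out$total_wins[i + 1]) {
        tie_break[i] <- "wins"
      } else if (out$total_losses[i] != out$total_losses[i + 1]) {
        tie_break[i] <- "losses"
      } else {
        tie_break[i] <- "id"
      }
    }
  }
  out$rank <- seq_len(n)
  out$tie_break <- tie_break
  attr(out, "n_individuals") <- attr(table, "n_individuals")
  class(out) <- class(table)
  out
}

#' Read / write a dominance matrix as a labelled square CSV
#'
#' @param path CSV path (first column `id`, remaining columns the same ids).
#' @return [read_dominance_csv()] returns a `dominance_matrix`.
#' @export
read_dominance_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  as_dominance_matrix(m)
}

#' @rdname read_dominance_csv
#' @param matrix a `dominance_matrix`.
#' @export
write_dominance_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "dominance_matrix"))
  df <- tibble::as_tibble(unclass(matrix), rownames = "id")
  readr::write_csv(df, path, progress = FALSE)
  invisible(matrix)
}
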