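#' Build a confusion table from two rounds of identity labels
#'
#' Intra-observer reliability is assessed by re-identifying animals in a
#' random sample of recordings and cross-tabulating the first-round label
#' against the second-round label. The table is square over the union of
#' labels seen in either round.
#'
#' @param x either a square numeric matrix with identical dimnames on both
#'   axes, or a data frame with columns `round1` and `round2` of labels
#'   (one row per identification).
#' @return an object of class `confusion_table`: a square integer matrix
#'   (round-1 label in rows, round-2 label in columns).
#' @export
#' @examples
#' confusion_table(matrix(c(50, 5, 5, 40), 2, 2,
#'   dimnames = list(c("A", "B"), c("A", "B"))
#' ))
confusion_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("round1", "round2") %in% names(x)))
    labels <- sort(unique(c(as.character(x$round1), as.character(x$round2))))
    m <- table(
      factor(x$round1, levels = labels),
      factor(x$round2, levels = labels)
    )
    m <- matrix(as.numeric(m), length(labels), length(labels),
      dimnames = list(labels, labels)
    )
  } else if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) {
      stop("confusion table must be square", call. = FALSE)
    }
    if (is.null(rownames(x)) || is.null(colnames(x)) ||
      !identical(rownames(x), colnames(x))) {
      stop("confusion table needs identical row and column labels",
        call. = FALSE
      )
    }
    m <- x
  } else {
    stop("x must be a square labelled matrix or a round1/round2 data frame",
      call. = FALSE
    )
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("confusion table entries must be non-negative integers",
      call. = FALSE
    )
  }
  if (sum(m) < 1) {
    stop("confusion table must contain at least one identification",
      call. = FALSE
    )
  }
  structure(m, class = c("confusion_table", "matrix"))
}

#' Read / write a confusion table as a labelled square CSV matrix
#'
#' The first column holds the round-1 labels; the header row holds the
#' round-2 labels.
#'
#' @param path CSV path.
#' @return [read_confusion_csv()] returns a `confusion_table`;
#'   [write_confusion_csv()] returns its input invisibly.
#' @export
read_confusion_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      label = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  confusion_table(m)
}

#' @rdname read_confusion_csv
#' @param table a `confusion_table`.
#' @export
write_confusion_csv <- function(table, path) {
  stopifnot(inherits(table, "confusion_table"))
  df <- tibble::as_tibble(unclass(table), rownames = "label")
  readr::write_csv(df, path, progress = FALSE)
  invisible(table)
}

#' Cohen's kappa for two labelling rounds
#'
#' Chance-corrected agreement between a first and a second identification
#' round by the same observer: `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement proportion (diagonal mass) and `p_e` the
#' agreement expected from the marginal label frequencies. The unweighted
#' form is used; any number of identity labels is supported.
#'
#' @param table a [confusion_table()] (or coercible matrix/data frame).
#' @return an object of class `kappa_result`: a list with `kappa`, `p_o`,
#'   `p_e`, `n` and `labels`.
#' @export
#' @examples
#' m <- matrix(c(50, 5, 5, 40), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' cohens_kappa(m)$kappa # 0.79797...
cohens_kappa <- function(table) {
  if (!inherits(table, "confusion_table")) table <- confusion_table(table)
  n <- sum(table)
  p_o <- sum(diag(table)) / n
  p_e <- sum(rowSums(table) * colSums(table)) / n^2
  if (isTRUE(all.equal(p_e, 1))) {
    stop("kappa undefined: all mass in one label (p_e = 1)", call. = FALSE)
  }
  structure(
    list(
      kappa = (p_o - p_e) / (1 - p_e),
      p_o = p_o, p_e = p_e, n = n,
      labels = rownames(table)
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa = %.4f  (p_o = %.4f, p_e = %.4f, n = %d, %d labels)\n",
    x$kappa, x$p_o, x$p_e, x$n, length(x$labels)
  ))
  invisible(x)
}

#' Per-bin detection counts from an observation log
#'
#' Bins the time axis into contiguous windows of `bin_width` days, from the
#' day of the first event to the day of the last, and counts in each bin the
#' number of distinct recordings whose first event falls in that bin. This
#' is the series whose autocorrelation is used to check temporal
#' independence of camera-trap recordings. Recordings with only
#' `UNIDENTIFIED` occupants still count: detection totals do not require
#' identification.
#'
#' @param log an [observation_log()] with at least one event.
#' @param bin_width bin width in days (default 1).
#' @return a tibble with columns `bin_start` (Date) and `n_recordings`.
#' @export
detection_series <- function(log, bin_width = 1) {
  stopifnot(inherits(log, "observation_log"))
  if (nrow(log$events) == 0) {
    stop("cannot build a detection series from an empty log", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  starts <- log$events |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(start = min(.data$timestamp), .groups = "drop")
  day0 <- as.Date(min(starts$start), tz = "UTC")
  day <- as.numeric(as.Date(starts$start, tz = "UTC") - day0)
  bin <- floor(day / bin_width)
  n_bins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = n_bins)
  tibble::tibble(
    bin_start = day0 + (seq_len(n_bins) - 1L) * bin_width,
    n_recordings = counts
  )
}

#' Sample autocorrelation of a detection-count series
#'
#' The lag-k sample autocorrelation
#' `r_k = sum_{t=1}^{n-k} (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`
#' for k = 1..`max_lag`. Values near zero at all lags indicate temporal
#' independence of the recordings. The default lag range is
#' `min(30, floor(n/4))`, the usual short-series guidance.
#'
#' @param x numeric series (e.g. the `n_recordings` column of
#'   [detection_series()]).
#' @param max_lag largest lag to compute.
#' @return an object of class `acf_result`: a tibble with columns `lag`
#'   and `r`, with the series length in attribute `n`.
#' @export
#' @examples
#' autocorrelation(rep(c(1, -1), 5), max_lag = 1) # r_1 = -0.9
autocorrelation <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(30L, floor(n / 4))
  if (max_lag < 1) stop("max_lag must be at least 1", call. = FALSE)
  if (n < max_lag + 2) {
    stop("series too short for max_lag = ", max_lag, call. = FALSE)
  }
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    stop("series has zero variance; autocorrelation undefined", call. = FALSE)
  }
  r <- vapply(seq_len(max_lag), function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / denom
  }, numeric(1))
  out <- tibble::tibble(lag = seq_len(max_lag), r = r)
  attr(out, "n") <- n
  class(out) <- c("acf_result", class(out))
  out
}
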