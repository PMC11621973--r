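#' Behavioural ethogram used to code camera-trap recordings
#'
#' The 13 behaviour categories recognised when coding 30-second camera-trap
#' recordings of a canid social group, together with whether each behaviour
#' is directed at a recipient. Only `aggression` and `submission` are
#' directed; every other behaviour is recorded without a recipient.
#'
#' @format A tibble with 13 rows and 2 columns:
#' \describe{
#'   \item{behaviour}{canonical lower-case behaviour label}
#'   \item{directed}{logical; does the behaviour have a recipient?}
#' }
#' @export
#' @examples
#' ethogram()
ethogram <- function() {
  tibble::tibble(
    behaviour = c(
      "solitary travel", "social travel",
      "solitary resting", "social resting",
      "solitary foraging/feeding", "social foraging/feeding",
      "solitary vocalisation", "social vocalisation",
      "scent marking", "scanning environment",
      "affiliation", "aggression", "submission"
    ),
    directed = c(rep(FALSE, 11), TRUE, TRUE)
  )
}

#' Normalise a behaviour label to its canonical ethogram form
#'
#' Labels are matched case-insensitively after collapsing runs of
#' whitespace, so `" Scent   Marking "` resolves to `"scent marking"`.
#'
#' @param x character vector of behaviour labels.
#' @return character vector of canonical labels.
#' @keywords internal
normalise_behaviour <- function(x) {
  y <- tolower(trimws(gsub("\\s+", " ", x)))
  eth <- ethogram()
  bad <- !(y %in% eth$behaviour) & !is.na(y)
  if (any(bad)) {
    stop(
      "unknown behaviour label(s): ",
      paste(unique(x[bad]), collapse = ", "),
      " (must be one of the 13 ethogram behaviours, see ethogram())",
      call. = FALSE
    )
  }
  y
}

#' Is a behaviour directed (has a recipient)?
#'
#' @param behaviour character vector of canonical behaviour labels.
#' @return logical vector.
#' @keywords internal
is_directed_behaviour <- function(behaviour) {
  eth <- ethogram()
  eth$directed[match(behaviour, eth$behaviour)]
}

#' Sentinel actor label for animals that could not be identified
#' @keywords internal
UNIDENTIFIED <- "UNIDENTIFIED"
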