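#' Construct a validated observation log
#'
#' An observation log couples a group roster (who was in the group, and
#' when) with an ordered stream of coded behavioural events extracted from
#' camera-trap recordings. Events are sorted by timestamp, with ties broken
#' by recording id. Validation enforces the ethogram contract: directed
#' behaviours (aggression, submission) carry a recipient, undirected ones
#' do not; identified actors appear in the `present` set of their
#' recording; and every identified id is on the roster.
#'
#' @param roster a data frame with columns `id`, `sex`
#'   (`"female"`/`"male"`/`"unknown"`), `life_stage` (`"adult"`/`"juvenile"`),
#'   `entry_date` (Date) and `exit_date` (Date or `NA`).
#' @param events a data frame with columns `recording_id`, `timestamp`
#'   (POSIXct, UTC), `camera_id`, `behaviour`, `actor` (an id or
#'   `"UNIDENTIFIED"`), `recipient` (id or `NA`) and `present` (a
#'   list-column of character vectors of co-detected ids).
#' @return an object of class `observation_log`: a list with tibbles
#'   `roster` and `events`.
#' @export
#' @examples
#' roster <- tibble::tibble(
#'   id = c("AA", "BB"), sex = c("female", "male"),
#'   life_stage = "adult",
#'   entry_date = as.Date("2023-01-01"), exit_date = as.Date(NA)
#' )
#' events <- tibble::tibble(
#'   recording_id = "R1",
#'   timestamp = as.POSIXct("2023-02-01 10:00:00", tz = "UTC"),
#'   camera_id = "C1", behaviour = "aggression",
#'   actor = "AA", recipient = "BB", present = list(c("AA", "BB"))
#' )
#' observation_log(roster, events)
observation_log <- function(roster, events = NULL) {
  roster <- tibble::as_tibble(roster)
  req <- c("id", "sex", "life_stage", "entry_date", "exit_date")
  missing_cols <- setdiff(req, names(roster))
  if (length(missing_cols) > 0) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  roster$entry_date <- as.Date(roster$entry_date)
  roster$exit_date <- as.Date(roster$exit_date)
  if (any(is.na(roster$id) | roster$id == "")) {
    stop("roster ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(roster$id)) {
    stop("roster ids must be unique", call. = FALSE)
  }
  if (UNIDENTIFIED %in% roster$id) {
    stop("'UNIDENTIFIED' is a reserved sentinel and cannot be a roster id",
      call. = FALSE
    )
  }
  if (!all(roster$sex %in% c("female", "male", "unknown"))) {
    stop("roster sex must be one of female/male/unknown", call. = FALSE)
  }
  if (!all(roster$life_stage %in% c("adult", "juvenile"))) {
    stop("roster life_stage must be adult or juvenile", call. = FALSE)
  }
  bad_tenure <- !is.na(roster$exit_date) & roster$exit_date < roster$entry_date
  if (any(bad_tenure)) {
    stop(
      "exit_date earlier than entry_date for: ",
      paste(roster$id[bad_tenure], collapse = ", "),
      call. = FALSE
    )
  }

  if (is.null(events) || nrow(tibble::as_tibble(events)) == 0) {
    events <- tibble::tibble(
      recording_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      camera_id = character(),
      behaviour = character(),
      actor = character(),
      recipient = character(),
      present = list()
    )
  } else {
    events <- tibble::as_tibble(events)
    reqe <- c(
      "recording_id", "timestamp", "camera_id", "behaviour",
      "actor", "recipient", "present"
    )
    missing_cols <- setdiff(reqe, names(events))
    if (length(missing_cols) > 0) {
      stop("events is missing column(s): ",
        paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    events$timestamp <- as.POSIXct(events$timestamp, tz = "UTC")
    events$behaviour <- normalise_behaviour(events$behaviour)
    events$recipient <- as.character(events$recipient)
    if (!is.list(events$present)) {
      stop("events$present must be a list-column of character vectors",
        call. = FALSE
      )
    }
    events$present <- purrr::map(events$present, function(p) {
      sort(unique(as.character(p)))
    })

    directed <- is_directed_behaviour(events$behaviour)
    has_recipient <- !is.na(events$recipient)
    bad <- which(directed != has_recipient)
    if (length(bad) > 0) {
      stop(
        "event row ", bad[1], " (recording ", events$recording_id[bad[1]],
        "): directed behaviours require a recipient and undirected ones",
        " forbid it",
        call. = FALSE
      )
    }
    self <- which(has_recipient & events$recipient == events$actor)
    if (length(self) > 0) {
      stop("event row ", self[1], ": recipient must differ from actor",
        call. = FALSE
      )
    }
    ids_used <- setdiff(
      unique(c(
        events$actor, events$recipient[has_recipient],
        unlist(events$present)
      )),
      c(UNIDENTIFIED, NA_character_)
    )
    unknown <- setdiff(ids_used, roster$id)
    if (length(unknown) > 0) {
      stop("event references id(s) not on the roster: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    identified <- events$actor != UNIDENTIFIED
    in_present <- purrr::map2_lgl(
      events$actor, events$present,
      function(a, p) a %in% p
    )
    bad <- which(identified & !in_present)
    if (length(bad) > 0) {
      stop("event row ", bad[1], ": identified actor must be in `present`",
        call. = FALSE
      )
    }
    events <- dplyr::arrange(events, .data$timestamp, .data$recording_id)
  }

  structure(list(roster = roster, events = events),
    class = "observation_log"
  )
}

#' @export
print.observation_log <- function(x, ...) {
  n_rec <- length(unique(x$events$recording_id))
  cat(
    "<observation_log> ", nrow(x$roster), " individuals (",
    sum(x$roster$life_stage == "adult"), " adults), ",
    nrow(x$events), " events in ", n_rec, " recordings\n",
    sep = ""
  )
  if (nrow(x$events) > 0) {
    cat(
      "  ", format(min(x$events$timestamp), "%Y-%m-%d"), " to ",
      format(max(x$events$timestamp), "%Y-%m-%d"), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Read an observation log from roster and event CSV files
#'
#' Both files are UTF-8 comma-separated with a header row. The roster has
#' columns `id,sex,life_stage,entry_date,exit_date` (ISO dates, empty
#' `exit_date` for current members). The event file has columns
#' `recording_id,timestamp,camera_id,behaviour,actor,recipient,present`,
#' where `timestamp` is ISO 8601 and `present` is a semicolon-joined list
#' of co-detected ids. Rows with an `UNIDENTIFIED` actor are retained;
#' downstream stages decide whether to use them.
#'
#' @param roster_path,events_path paths to the two CSV files.
#' @return an [observation_log()].
#' @export
read_event_log <- function(roster_path, events_path) {
  if (!file.exists(roster_path)) {
    stop("roster file not found: ", roster_path, call. = FALSE)
  }
  if (!file.exists(events_path)) {
    stop("events file not found: ", events_path, call. = FALSE)
  }
  roster <- readr::read_csv(
    roster_path,
    col_types = readr::cols(
      id = readr::col_character(),
      sex = readr::col_character(),
      life_stage = readr::col_character(),
      entry_date = readr::col_date(),
      exit_date = readr::col_date()
    ),
    progress = FALSE
  )
  events_raw <- readr::read_csv(
    events_path,
    col_types = readr::cols(
      recording_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      camera_id = readr::col_character(),
      behaviour = readr::col_character(),
      actor = readr::col_character(),
      recipient = readr::col_character(),
      present = readr::col_character()
    ),
    progress = FALSE
  )
  events <- NULL
  if (nrow(events_raw) > 0) {
    events <- events_raw
    events$present <- purrr::map(
      events_raw$present,
      function(p) {
        if (is.na(p) || p == "") character() else strsplit(p, ";", fixed = TRUE)[[1]]
      }
    )
  }
  observation_log(roster, events)
}

#' Write an observation log to roster and event CSV files
#'
#' Inverse of [read_event_log()]: `read_event_log()` applied to the files
#' written here reproduces the log field-for-field.
#'
#' @param log an [observation_log()].
#' @param roster_path,events_path output paths.
#' @return the input `log`, invisibly.
#' @export
write_event_log <- function(log, roster_path, events_path) {
  stopifnot(inherits(log, "observation_log"))
  readr::write_csv(log$roster, roster_path, progress = FALSE)
  ev <- log$events
  flat <- tibble::tibble(
    recording_id = ev$recording_id,
    timestamp = format(ev$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    camera_id = ev$camera_id,
    behaviour = ev$behaviour,
    actor = ev$actor,
    recipient = ev$recipient,
    present = purrr::map_chr(ev$present, paste, collapse = ";")
  )
  readr::write_csv(flat, events_path, na = "", progress = FALSE)
  invisible(log)
}

#' Restrict an observation log to a date window and set of life stages
#'
#' Keeps exactly the events whose timestamp falls within
#' `[start_date, end_date]` (whole days, inclusive) and whose identified
#' actor -- and recipient, for directed behaviours -- belongs to one of
#' the requested life stages. Events by `UNIDENTIFIED` actors pass the
#' life-stage check (their stage is unknown) but are still date-filtered.
#' The roster is filtered to individuals of the requested stages whose
#' tenure overlaps the window, and `present` sets are intersected with the
#' retained ids.
#'
#' @param log an [observation_log()].
#' @param start_date,end_date the window, coerced with [as.Date()].
#' @param life_stages character subset of `c("adult", "juvenile")`.
#' @return a restricted [observation_log()].
#' @export
restrict_log <- function(log, start_date, end_date,
                         life_stages = c("adult", "juvenile")) {
  stopifnot(inherits(log, "observation_log"))
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) {
    stop("start_date must not be after end_date", call. = FALSE)
  }
  life_stages <- match.arg(life_stages, several.ok = TRUE)

  r <- log$roster
  tenure_overlaps <- r$entry_date <= end_date &
    (is.na(r$exit_date) | r$exit_date >= start_date)
  roster <- r[r$life_stage %in% life_stages & tenure_overlaps, ]
  keep_ids <- roster$id

  ev <- log$events
  if (nrow(ev) > 0) {
    day <- as.Date(ev$timestamp, tz = "UTC")
    in_window <- day >= start_date & day <= end_date
    actor_ok <- ev$actor == UNIDENTIFIED | ev$actor %in% keep_ids
    recipient_ok <- is.na(ev$recipient) | ev$recipient %in% keep_ids
    ev <- ev[in_window & actor_ok & recipient_ok, ]
    ev$present <- purrr::map(ev$present, intersect, y = keep_ids)
    # an actor dropped from `present` by the intersection would violate the
    # log invariant; such events are by construction excluded already
  }
  observation_log(roster, ev)
}
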