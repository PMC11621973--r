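#' Configuration for the synthetic camera-trap event generator
#'
#' Defines a group with a latent linear dominance hierarchy, planted
#' association clusters, a composition timeline (a dispersal event and a
#' pup cohort) and an identification-noise level. The defaults emulate a
#' small territorial canid group watched by camera traps for four months:
#' seven adults of which a dominant pair clearly outranks five homogeneous
#' subordinates, about five recordings per day, three subordinates
#' dispersing mid-study and a cohort of six pups appearing afterwards.
#'
#' @param n_adults number of adults at study start.
#' @param ids adult ids; default `"J01"..` codes.
#' @param sexes adult sexes; default: dominant pair female/male, others
#'   unknown.
#' @param latent_strengths numeric latent dominance strength per adult
#'   (higher = more dominant). Default: a clear dominant pair over
#'   homogeneous subordinates.
#' @param beta steepness of the win model: individual `i` beats `j` with
#'   probability `plogis(beta * (s_i - s_j))`.
#' @param lambda expected number of agonistic events per dyad per day
#'   (Poisson).
#' @param scent_mark_rates expected scent marks per adult per day; default
#'   0.3 for the dominant pair, 0.05 for subordinates.
#' @param cluster_assignment integer cluster label per adult; default: the
#'   dominant pair in cluster 1, subordinates in cluster 2.
#' @param p_in,p_out probability that an individual joins a recording
#'   anchored by a member of the same / another cluster.
#' @param dominant_pair_coupling extra co-detection probability added
#'   between the two strongest adults (emulates a bonded pair being
#'   recorded together unusually often).
#' @param recordings_per_day number of association recordings drawn per day.
#' @param n_days study length in days.
#' @param start_date calendar date of day 1.
#' @param dispersal list `(ids, day)`: these adults leave the group after
#'   `day` (no events or detections afterwards); default: the three
#'   weakest adults at mid-study.
#' @param pup_cohort list `(count, day)`: this many pups (juveniles) join
#'   the group from `day` on.
#' @param submission_frac fraction of agonistic events emitted as a
#'   submissive display by the loser instead of aggression by the winner;
#'   both encodings contribute the same dominance-matrix win.
#' @param misid_accuracy probability `q` that a re-identification is
#'   correct, used by [simulate_reidentification()].
#' @param seed integer seed from which all randomness flows.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_adults = 7,
                         ids = sprintf("J%02d", seq_len(n_adults)),
                         sexes = c(
                           "female", "male",
                           rep("unknown", max(0, n_adults - 2))
                         ),
                         latent_strengths = c(
                           2.5, 2.3,
                           rep(0.6, max(0, n_adults - 2))
                         ),
                         beta = 1.5,
                         lambda = 0.1,
                         scent_mark_rates = c(
                           0.3, 0.3,
                           rep(0.05, max(0, n_adults - 2))
                         ),
                         cluster_assignment = c(
                           1, 1,
                           rep(2, max(0, n_adults - 2))
                         ),
                         p_in = 0.5,
                         p_out = 0.2,
                         dominant_pair_coupling = 0.2,
                         recordings_per_day = 5,
                         n_days = 120,
                         start_date = as.Date("2023-01-01"),
                         dispersal = list(
                           ids = ids[order(latent_strengths)][
                             seq_len(min(3, n_adults - 2))
                           ],
                           day = floor(n_days / 2)
                         ),
                         pup_cohort = list(
                           count = 6,
                           day = floor(n_days * 0.625)
                         ),
                         submission_frac = 0.3,
                         misid_accuracy = 0.9,
                         seed = 1L) {
  stopifnot(
    n_adults >= 2,
    length(ids) == n_adults, !anyDuplicated(ids),
    length(sexes) == n_adults,
    length(latent_strengths) == n_adults,
    length(scent_mark_rates) == n_adults,
    length(cluster_assignment) == n_adults,
    beta > 0, lambda >= 0, all(scent_mark_rates >= 0),
    recordings_per_day >= 0, n_days >= 1
  )
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("p_in and p_out must be probabilities in [0, 1]", call. = FALSE)
  }
  if (misid_accuracy <= 0 || misid_accuracy > 1) {
    stop("misid_accuracy must be in (0, 1]", call. = FALSE)
  }
  if (submission_frac < 0 || submission_frac > 1) {
    stop("submission_frac must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(dispersal)) {
    stopifnot(all(dispersal$ids %in% ids))
    if (dispersal$day < 1 || dispersal$day > n_days) {
      stop("dispersal day must be within [1, n_days]", call. = FALSE)
    }
  }
  if (!is.null(pup_cohort) && pup_cohort$count > 0) {
    if (pup_cohort$day < 1 || pup_cohort$day > n_days) {
      stop("pup day must be within [1, n_days]", call. = FALSE)
    }
  }
  cfg <- list(
    n_adults = n_adults, ids = ids, sexes = sexes,
    latent_strengths = stats::setNames(latent_strengths, ids),
    beta = beta, lambda = lambda,
    scent_mark_rates = stats::setNames(scent_mark_rates, ids),
    cluster_assignment = stats::setNames(cluster_assignment, ids),
    p_in = p_in, p_out = p_out,
    dominant_pair_coupling = dominant_pair_coupling,
    recordings_per_day = recordings_per_day,
    n_days = n_days, start_date = as.Date(start_date),
    dispersal = dispersal, pup_cohort = pup_cohort,
    submission_frac = submission_frac,
    misid_accuracy = misid_accuracy,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Run an expression with a locally seeded Mersenne-Twister stream
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Simulate a camera-trap event log with known ground truth
#'
#' For every day and every adult dyad present, a Poisson(`lambda`) number of
#' agonistic events is drawn; the stronger animal wins each with probability
#' `plogis(beta * (s_i - s_j))`. A won interaction is emitted either as
#' aggression winner -> loser or, with probability `submission_frac`, as a
#' submissive display loser -> winner; both encodings yield the same
#' dominance-matrix win. Scent marks are drawn per adult per day at
#' `scent_mark_rates`. Association recordings are populated by an anchor
#' individual plus each other present individual joining with probability
#' `p_in` (same cluster) or `p_out` (different cluster); pups join the
#' dominant (natal) cluster. Dispersed individuals emit nothing after the
#' dispersal day; pups appear as juveniles from the pup day. Identical
#' seeds give identical logs.
#'
#' @param config a [synth_config()].
#' @return a list with elements `log` (an [observation_log()]) and `truth`
#'   (latent strengths, strength order, cluster labels, dyadic win and
#'   co-detection probabilities).
#' @export
simulate_event_log <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, simulate_event_log_impl(config))
}

simulate_event_log_impl <- function(config) {
  ids <- config$ids
  s <- config$latent_strengths
  start <- config$start_date

  disp_ids <- if (is.null(config$dispersal)) character() else config$dispersal$ids
  disp_day <- if (is.null(config$dispersal)) Inf else config$dispersal$day
  pup_n <- if (is.null(config$pup_cohort)) 0L else config$pup_cohort$count
  pup_day <- if (is.null(config$pup_cohort)) Inf else config$pup_cohort$day
  pup_ids <- if (pup_n > 0) sprintf("P%02d", seq_len(pup_n)) else character()

  roster <- tibble::tibble(
    id = c(ids, pup_ids),
    sex = c(config$sexes, rep("unknown", pup_n)),
    life_stage = c(rep("adult", length(ids)), rep("juvenile", pup_n)),
    entry_date = c(
      rep(start, length(ids)),
      rep(start + pup_day - 1, pup_n)
    ),
    exit_date = as.Date(ifelse(c(ids, pup_ids) %in% disp_ids,
      as.character(start + disp_day - 1), NA
    ))
  )

  cluster <- c(
    config$cluster_assignment,
    stats::setNames(
      rep(config$cluster_assignment[order(-s)][1], pup_n), pup_ids
    )
  )
  top2 <- ids[order(-s)][1:2]

  # accumulate columns as flat vectors; one recording per event
  acc <- new.env()
  acc$n <- 0L
  acc$day <- integer()
  acc$offset <- numeric()
  acc$behaviour <- character()
  acc$actor <- character()
  acc$recipient <- character()
  acc$present <- list()
  add_event <- function(day, behaviour, actor, recipient, present) {
    acc$n <- acc$n + 1L
    acc$day[acc$n] <- day
    acc$offset[acc$n] <- stats::runif(1, 0, 86399)
    acc$behaviour[acc$n] <- behaviour
    acc$actor[acc$n] <- actor
    acc$recipient[acc$n] <- recipient
    acc$present[[acc$n]] <- present
  }

  for (day in seq_len(config$n_days)) {
    adults_here <- ids[!(ids %in% disp_ids) | day <= disp_day]
    pups_here <- if (day >= pup_day) pup_ids else character()
    all_here <- c(adults_here, pups_here)

    # agonistic events per adult dyad
    if (length(adults_here) >= 2 && config$lambda > 0) {
      dyads <- utils::combn(adults_here, 2)
      for (d in seq_len(ncol(dyads))) {
        i <- dyads[1, d]
        j <- dyads[2, d]
        n_ev <- stats::rpois(1, config$lambda)
        if (n_ev == 0) next
        p_i_wins <- stats::plogis(config$beta * (s[i] - s[j]))
        for (k in seq_len(n_ev)) {
          winner <- if (stats::runif(1) < p_i_wins) i else j
          loser <- setdiff(c(i, j), winner)
          if (stats::runif(1) < config$submission_frac) {
            add_event(day, "submission", loser, winner, c(i, j))
          } else {
            add_event(day, "aggression", winner, loser, c(i, j))
          }
        }
      }
    }

    # scent marks
    for (i in adults_here) {
      n_sm <- stats::rpois(1, config$scent_mark_rates[i])
      for (k in seq_len(n_sm)) {
        add_event(day, "scent marking", i, NA_character_, i)
      }
    }

    # association recordings
    for (r in seq_len(config$recordings_per_day)) {
      anchor <- sample(all_here, 1)
      others <- setdiff(all_here, anchor)
      p_join <- ifelse(cluster[others] == cluster[anchor],
        config$p_in, config$p_out
      )
      pairwise_top2 <- (anchor %in% top2) & (others %in% top2)
      p_join <- pmin(1, p_join + pairwise_top2 * config$dominant_pair_coupling)
      joined <- others[stats::runif(length(others)) < p_join]
      occupants <- c(anchor, joined)
      behaviour <- if (length(occupants) > 1) "social resting" else "solitary resting"
      add_event(day, behaviour, anchor, NA_character_, occupants)
    }
  }

  events <- NULL
  if (acc$n > 0) {
    events <- tibble::tibble(
      recording_id = sprintf("R%06d", seq_len(acc$n)),
      timestamp = as.POSIXct(start, tz = "UTC") +
        (acc$day - 1) * 86400 + acc$offset,
      camera_id = sprintf("C%d", 1 + (seq_len(acc$n) %% 4)),
      behaviour = acc$behaviour,
      actor = acc$actor,
      recipient = acc$recipient,
      present = acc$present
    )
  }
  log <- observation_log(roster, events)

  win_prob <- outer(s, s, function(a, b) stats::plogis(config$beta * (a - b)))
  diag(win_prob) <- 0
  codetect <- outer(
    config$cluster_assignment, config$cluster_assignment,
    function(a, b) ifelse(a == b, config$p_in, config$p_out)
  )
  diag(codetect) <- 0
  dimnames(win_prob) <- dimnames(codetect) <- list(ids, ids)

  truth <- list(
    strengths = s,
    strength_order = ids[order(-s)],
    cluster_labels = cluster,
    win_prob = win_prob,
    codetect_prob = codetect,
    pup_ids = pup_ids,
    dispersed_ids = disp_ids,
    dispersal_day = disp_day,
    pup_day = pup_day
  )
  list(log = log, truth = truth)
}

#' Simulate a re-identification round and tally the confusion table
#'
#' Emulates the intra-observer reliability protocol: a random sample of
#' identifications (occupant appearances across recordings) is re-labelled.
#' Each sampled identification keeps its true label with probability `q`
#' and is otherwise assigned uniformly to one of the other roster ids.
#'
#' @param log an [observation_log()].
#' @param q identification accuracy in (0, 1].
#' @param seed integer seed.
#' @param n_ident number of identifications to re-label (default 120, or
#'   the whole pool if smaller).
#' @return a [confusion_table()] (round-1 truth in rows, round-2 re-labels
#'   in columns).
#' @export
simulate_reidentification <- function(log, q, seed = 1L, n_ident = 120) {
  stopifnot(inherits(log, "observation_log"))
  if (q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
  roster_ids <- log$roster$id
  if (length(roster_ids) < 2) {
    stop("need at least 2 roster ids to mislabel", call. = FALSE)
  }
  pool <- unlist(purrr::map(
    split(log$events$present, log$events$recording_id),
    function(p) setdiff(unique(unlist(p)), UNIDENTIFIED)
  ))
  if (length(pool) == 0) {
    stop("log contains no identified occupants", call. = FALSE)
  }
  with_local_seed(seed, {
    take <- sample(pool, min(n_ident, length(pool)))
    relabel <- vapply(take, function(id) {
      if (stats::runif(1) < q) {
        id
      } else {
        sample(setdiff(roster_ids, id), 1)
      }
    }, character(1))
    confusion_table(tibble::tibble(
      round1 = factor(take, levels = roster_ids),
      round2 = factor(relabel, levels = roster_ids)
    ))
  })
}

#' Generate a sighting summary with planted association clusters
#'
#' Draws `n_days * recordings_per_day` recordings among the adults only
#' (no timeline): each recording has a uniformly chosen anchor, and every
#' other adult joins with probability `p_in` (same planted cluster) or
#' `p_out` (different cluster). Requires at least two clusters and
#' `p_in > p_out`, otherwise the planted structure is undefined.
#'
#' @param config a [synth_config()].
#' @return a list with `summary` (a [cooccurrence_counts()]-style
#'   `sighting_summary`) and `truth` (cluster labels and probabilities).
#' @export
planted_association_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$cluster_assignment
  if (length(unique(cl)) < 2) {
    stop("planted structure needs at least two clusters", call. = FALSE)
  }
  if (config$p_in <= config$p_out) {
    stop("planted structure requires p_in > p_out", call. = FALSE)
  }
  ids <- config$ids
  k <- length(ids)
  n_rec <- config$n_days * config$recordings_per_day
  with_local_seed(config$seed, {
    x <- matrix(0L, k, k, dimnames = list(ids, ids))
    for (r in seq_len(n_rec)) {
      anchor <- sample(ids, 1)
      others <- setdiff(ids, anchor)
      p_join <- ifelse(cl[others] == cl[anchor], config$p_in, config$p_out)
      occupants <- c(anchor, others[stats::runif(k - 1) < p_join])
      x[occupants, occupants] <- x[occupants, occupants] + 1L
    }
    summary <- structure(
      list(ids = ids, n = stats::setNames(diag(x), ids), x = x),
      class = "sighting_summary"
    )
    list(
      summary = summary,
      truth = list(
        cluster_labels = cl,
        p_in = config$p_in, p_out = config$p_out
      )
    )
  })
}
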