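#' Configuration for an end-to-end analysis run
#'
#' Bundles the file paths, period definitions and method switches that
#' [run_pipeline()] needs to reproduce the full analysis shape: reliability
#' diagnostics, an adult dominance hierarchy over the whole study, and one
#' association network (centrality + communities) per named period, with
#' an optional collapsed node for the pup cohort.
#'
#' @param roster_path,events_path input CSVs (see [read_event_log()]).
#' @param periods named list of two-element date vectors, e.g.
#'   `list(before = c("2023-01-01", "2023-04-30"), after = ...)`.
#' @param dominance_life_stages life stages entering the dominance matrix
#'   (default adults only).
#' @param collapse_map named character vector merging raw ids into single
#'   network nodes (e.g. every pup id onto `"Pups"`).
#' @param weight_kind `"count"` or `"sri"` association weights.
#' @param acf_bin_width detection-series bin width in days.
#' @param acf_max_lag largest autocorrelation lag (default
#'   `min(30, floor(n/4))`).
#' @param modularity_threshold modularity above which community structure
#'   is flagged strong (default 0.3).
#' @param confusion_path optional labelled square CSV of re-identification
#'   counts; when given, Cohen's kappa is reported.
#' @param out_dir directory for exported tables and graphs.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(roster_path, events_path, periods,
                            dominance_life_stages = "adult",
                            collapse_map = NULL,
                            weight_kind = c("count", "sri"),
                            acf_bin_width = 1,
                            acf_max_lag = NULL,
                            modularity_threshold = 0.3,
                            confusion_path = NULL,
                            out_dir = tempfile("packsocial_run_")) {
  weight_kind <- match.arg(weight_kind)
  if (length(periods) == 0 || is.null(names(periods)) ||
    any(names(periods) == "")) {
    stop("periods must be a non-empty named list of date ranges",
      call. = FALSE
    )
  }
  periods <- purrr::map(periods, function(p) {
    p <- as.Date(p)
    if (length(p) != 2 || p[1] > p[2]) {
      stop("each period must be c(start, end) with start <= end",
        call. = FALSE
      )
    }
    p
  })
  if (!is.null(collapse_map)) {
    overlap <- intersect(unname(collapse_map), names(collapse_map))
    if (length(overlap) > 0) {
      stop("collapse targets must be distinct from the ids they replace: ",
        paste(overlap, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      roster_path = roster_path, events_path = events_path,
      periods = periods,
      dominance_life_stages = dominance_life_stages,
      collapse_map = collapse_map,
      weight_kind = weight_kind,
      acf_bin_width = acf_bin_width,
      acf_max_lag = acf_max_lag,
      modularity_threshold = modularity_threshold,
      confusion_path = confusion_path,
      out_dir = out_dir
    ),
    class = "analysis_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically: (1) reliability diagnostics -- Cohen's
#' kappa if a confusion table is supplied, and the autocorrelation of
#' per-bin recording counts; (2) the dominance stage on the full-period log
#' restricted to the configured life stages -- dominance matrix, David's
#' scores, hierarchy ranks; (3) per period: co-occurrence counts (with the
#' collapse map applied), the association network, eigenvector centrality
#' and fast-greedy communities. All tables are written to `out_dir` as CSV,
#' each network as GraphML plus an edge list, and a machine-readable
#' `summary.json`; a plain-text `run.log` records every default and the
#' skipped-event tally. If any stage fails, its name is reported and
#' partial outputs are removed.
#'
#' @param config an [analysis_config()].
#' @return a list of class `report_bundle` with elements `hierarchy`,
#'   `networks` (per period: network, centrality, partition, modularity,
#'   n_recordings, n_events), `kappa`, `acf`, `skipped_events`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$out_dir
  created <- character(0)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  emit <- function(name) {
    p <- file.path(out_dir, name)
    created <<- c(created, p)
    p
  }
  stage <- "read"
  result <- tryCatch(
    {
      note("packsocial pipeline run")
      note("weight_kind = ", config$weight_kind)
      note("modularity_threshold = ", config$modularity_threshold)
      note("acf_bin_width = ", config$acf_bin_width, " day(s)")
      log <- read_event_log(config$roster_path, config$events_path)
      note(
        "events: ", nrow(log$events), ", individuals: ", nrow(log$roster)
      )

      stage <- "reliability"
      kappa <- NULL
      if (!is.null(config$confusion_path)) {
        kappa <- cohens_kappa(read_confusion_csv(config$confusion_path))
        note(sprintf("kappa = %.4f (n = %d)", kappa$kappa, kappa$n))
      }
      series <- detection_series(log, bin_width = config$acf_bin_width)
      acf_res <- autocorrelation(series$n_recordings,
        max_lag = config$acf_max_lag
      )
      note(sprintf(
        "acf over %d lags in [%.4f, %.4f]",
        nrow(acf_res), min(acf_res$r), max(acf_res$r)
      ))

      stage <- "dominance"
      full_range <- range(as.Date(log$events$timestamp, tz = "UTC"))
      adult_log <- restrict_log(
        log, full_range[1], full_range[2],
        life_stages = config$dominance_life_stages
      )
      dmat <- build_dominance_matrix(adult_log)
      skipped <- attr(dmat, "n_skipped")
      note("dominance events skipped (unidentified): ", skipped)
      hierarchy <- rank_hierarchy(davids_scores(dmat))
      write_dominance_csv(dmat, emit("dominance_matrix.csv"))
      hier_out <- dplyr::left_join(
        hierarchy,
        dplyr::select(log$roster, "id", "sex", "life_stage"),
        by = "id"
      )
      readr::write_csv(
        dplyr::select(
          hier_out, "id", "life_stage", "sex", "rank", "norm_ds",
          "ds", "w", "w2", "l", "l2", "tie_break"
        ),
        emit("hierarchy.csv"),
        progress = FALSE
      )

      stage <- "networks"
      networks <- list()
      for (period in names(config$periods)) {
        rng <- config$periods[[period]]
        plog <- restrict_log(log, rng[1], rng[2])
        if (nrow(plog$events) == 0) {
          stop("period '", period, "' contains no events", call. = FALSE)
        }
        summ <- cooccurrence_counts(plog, collapse_map = config$collapse_map)
        # drop nodes never sighted in this period
        seen <- names(summ$n[summ$n > 0])
        summ$x <- summ$x[seen, seen, drop = FALSE]
        summ$n <- summ$n[seen]
        summ$ids <- seen
        net <- association_matrix(summ, weight_kind = config$weight_kind)
        cent <- eigenvector_centrality(net)
        part <- fast_greedy_partition(net,
          threshold = config$modularity_threshold
        )
        n_rec <- length(unique(plog$events$recording_id))
        networks[[period]] <- list(
          network = net, centrality = cent, partition = part,
          modularity = part$q_max,
          strong_structure = part$strong_structure,
          n_recordings = n_rec,
          n_events = nrow(plog$events)
        )
        note(sprintf(
          "period %s: %d recordings, %d events, Q = %.6g (%s structure)",
          period, n_rec, nrow(plog$events), part$q_max,
          if (part$strong_structure) "strong" else "weak"
        ))
        cent_tab <- dplyr::bind_rows(
          tibble::tibble(
            individual = cent$id,
            eigenvector_centrality = format(cent$centrality, digits = 15)
          ),
          tibble::tibble(
            individual = "Modularity",
            eigenvector_centrality = format(part$q_max, digits = 15)
          )
        )
        readr::write_csv(cent_tab,
          emit(sprintf("centrality_%s.csv", period)),
          progress = FALSE
        )
        readr::write_csv(part$partition,
          emit(sprintf("partition_%s.csv", period)),
          progress = FALSE
        )
        export_network(net, emit(sprintf("network_%s.graphml", period)),
          format = "graphml", partition = part, scores = cent,
          roster = log$roster
        )
        export_network(net, emit(sprintf("edges_%s.csv", period)),
          format = "edgelist"
        )
      }

      stage <- "summary"
      summary <- list(
        skipped_events = skipped,
        kappa = if (is.null(kappa)) NULL else kappa[c("kappa", "p_o", "p_e", "n")],
        acf = list(
          min_r = min(acf_res$r), max_r = max(acf_res$r),
          max_lag = nrow(acf_res)
        ),
        hierarchy = stats::setNames(hierarchy$norm_ds, hierarchy$id),
        periods = purrr::map(networks, function(nw) {
          list(
            n_recordings = nw$n_recordings,
            n_events = nw$n_events,
            modularity = nw$modularity,
            strong_structure = nw$strong_structure,
            centrality = stats::setNames(
              nw$centrality$centrality, nw$centrality$id
            ),
            communities = stats::setNames(
              nw$partition$partition$community, nw$partition$partition$id
            )
          )
        })
      )
      jsonlite::write_json(summary, emit("summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
      )
      writeLines(log_lines, emit("run.log"))

      structure(
        list(
          hierarchy = hierarchy,
          networks = networks,
          kappa = kappa,
          acf = acf_res,
          skipped_events = skipped,
          paths = created,
          out_dir = out_dir
        ),
        class = "report_bundle"
      )
    },
    error = function(e) {
      unlink(created)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  result
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  hierarchy of", nrow(x$hierarchy), "individuals; top:",
    x$hierarchy$id[1], sprintf("(NormDS %.3f)\n", x$hierarchy$norm_ds[1]))
  for (p in names(x$networks)) {
    nw <- x$networks[[p]]
    cat(sprintf(
      "  period %-8s %d nodes, Q = %.6g, %d communities\n",
      p, length(nw$network$ids), nw$modularity,
      nw$partition$n_communities
    ))
  }
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}
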