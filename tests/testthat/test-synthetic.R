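test_that("identical seeds give identical logs; config validation catches bad rates", {
  cfg <- synth_config(n_days = 15, seed = 123)
  a <- simulate_event_log(cfg)
  b <- simulate_event_log(cfg)
  expect_identical(a$log$events, b$log$events)
  expect_identical(a$log$roster, b$log$roster)

  # different seed, different draw
  c_ <- simulate_event_log(synth_config(n_days = 15, seed = 124))
  expect_false(identical(a$log$events, c_$log$events))

  expect_error(synth_config(p_in = 1.4), "p_in")
  expect_error(synth_config(misid_accuracy = 0), "misid_accuracy")
  expect_error(
    synth_config(dispersal = list(ids = "J01", day = 999)),
    "dispersal day"
  )
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulate_event_log(synth_config(n_days = 5, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("dispersed individuals emit nothing after the dispersal day", {
  cfg <- synth_config(
    n_days = 40,
    dispersal = list(ids = c("J06", "J07"), day = 20),
    pup_cohort = NULL, seed = 4
  )
  sim <- simulate_event_log(cfg)
  ev <- sim$log$events
  after <- ev[as.Date(ev$timestamp, tz = "UTC") > cfg$start_date + 19, ]
  touched <- unique(c(
    after$actor, after$recipient[!is.na(after$recipient)],
    unlist(after$present)
  ))
  expect_false(any(c("J06", "J07") %in% touched))
  expect_equal(
    sim$log$roster$exit_date[sim$log$roster$id == "J06"],
    cfg$start_date + 19
  )
})

test_that("pups appear as juveniles only from the pup day onwards", {
  cfg <- synth_config(
    n_days = 30, dispersal = NULL,
    pup_cohort = list(count = 4, day = 21), seed = 6
  )
  sim <- simulate_event_log(cfg)
  pups <- sim$truth$pup_ids
  expect_length(pups, 4)
  expect_true(all(
    sim$log$roster$life_stage[sim$log$roster$id %in% pups] == "juvenile"
  ))
  ev <- sim$log$events
  pup_days <- as.Date(ev$timestamp[purrr::map_lgl(
    ev$present, function(p) any(pups %in% p)
  )], tz = "UTC")
  expect_true(all(pup_days >= cfg$start_date + 20))
})

test_that("both agonistic encodings land the win on the same matrix cell", {
  base <- list(
    n_adults = 2, ids = c("HI", "LO"), sexes = c("female", "male"),
    latent_strengths = c(3, 0), scent_mark_rates = c(0, 0),
    cluster_assignment = c(1, 2), lambda = 0.5, n_days = 60,
    recordings_per_day = 0, dispersal = NULL, pup_cohort = NULL, seed = 10
  )
  all_aggr <- do.call(synth_config, c(base, submission_frac = 0))
  all_subm <- do.call(synth_config, c(base, submission_frac = 1))
  m_a <- build_dominance_matrix(simulate_event_log(all_aggr)$log)
  m_s <- build_dominance_matrix(simulate_event_log(all_subm)$log)
  # same seed, same winners; only the behavioural encoding differs
  expect_equal(unclass(m_a)[, ], unclass(m_s)[, ])
  expect_gt(sum(m_a), 10)
})

test_that("with steep strengths the strongest adult beats the weakest almost always", {
  cfg <- synth_config(
    latent_strengths = seq(6, 0, length.out = 7),
    beta = 1.5, lambda = 0.6, n_days = 100, recordings_per_day = 0,
    scent_mark_rates = rep(0, 7), dispersal = NULL, pup_cohort = NULL,
    seed = 12
  )
  sim <- simulate_event_log(cfg)
  m <- build_dominance_matrix(sim$log)
  top <- sim$truth$strength_order[1]
  bottom <- sim$truth$strength_order[7]
  n_top <- m[top, bottom]
  n_all <- m[top, bottom] + m[bottom, top]
  expect_gt(n_all, 20)
  expect_gte(n_top / n_all, 0.95) # sigma(1.5 * 6) = 0.99988
})

test_that("re-identification at q = 1 is diagonal with kappa 1", {
  sim <- simulate_event_log(synth_config(n_days = 10, seed = 2))
  ct <- simulate_reidentification(sim$log, q = 1, seed = 3)
  expect_true(all(ct[upper.tri(ct)] == 0) && all(ct[lower.tri(ct)] == 0))
  expect_equal(cohens_kappa(ct)$kappa, 1)
  expect_error(simulate_reidentification(sim$log, q = 0), "q must be")
})

test_that("at chance-level accuracy kappa concentrates near zero", {
  # all individuals always together -> equally frequent identifications;
  # q = 1/k then makes round-2 labels independent of round-1 labels
  sim <- simulate_event_log(synth_config(
    n_days = 20, p_in = 1, p_out = 1, lambda = 0,
    scent_mark_rates = rep(0, 7),
    dispersal = NULL, pup_cohort = NULL, seed = 14
  ))
  k <- length(sim$log$roster$id)
  kappas <- vapply(1:40, function(s) {
    cohens_kappa(simulate_reidentification(sim$log, q = 1 / k, seed = s))$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas)), 0.05)
})

test_that("kappa under the noise model tracks the closed-form prediction", {
  # two equally frequent ids: p_o = q + (1-q) * 0 on the diagonal only via
  # correct labels, p_e from margins; at q = 0.9 the expected kappa is
  # (0.9 - p_e)/(1 - p_e) with p_e -> 0.5 for symmetric margins
  cfg <- synth_config(
    n_adults = 2, ids = c("AA", "BB"), sexes = c("female", "male"),
    latent_strengths = c(1, 0), scent_mark_rates = c(0, 0),
    cluster_assignment = 1:2, lambda = 0, p_in = 1, p_out = 1,
    recordings_per_day = 10, n_days = 60,
    dispersal = NULL, pup_cohort = NULL, seed = 15
  )
  sim <- simulate_event_log(cfg)
  kappas <- vapply(1:60, function(s) {
    cohens_kappa(
      simulate_reidentification(sim$log, q = 0.9, seed = s, n_ident = 120)
    )$kappa
  }, numeric(1))
  expect_equal(mean(kappas), (0.9 - 0.5) / 0.5, tolerance = 0.05)
})

test_that("planted association networks honour their probabilities", {
  cfg <- synth_config(
    n_adults = 6, ids = paste0("N", 1:6), sexes = rep("unknown", 6),
    latent_strengths = rep(1, 6), scent_mark_rates = rep(0, 6),
    cluster_assignment = rep(1:2, each = 3),
    p_in = 1, p_out = 0, recordings_per_day = 10, n_days = 5,
    dispersal = NULL, pup_cohort = NULL, seed = 16
  )
  pl <- planted_association_network(cfg)
  x <- pl$summary$x
  between <- x[1:3, 4:6]
  expect_true(all(between == 0))
  within <- x[1:3, 1:3][upper.tri(x[1:3, 1:3])]
  expect_true(all(within > 0))

  expect_error(
    planted_association_network(
      synth_config(p_in = 0.3, p_out = 0.3)
    ),
    "p_in > p_out"
  )
  expect_error(
    planted_association_network(
      synth_config(cluster_assignment = rep(1, 7), p_in = .8, p_out = .1)
    ),
    "two clusters"
  )
})

test_that("a seeded planted 2-cluster network is recovered by fast-greedy", {
  cfg <- synth_config(
    n_adults = 8, ids = paste0("N", 1:8), sexes = rep("unknown", 8),
    latent_strengths = rep(1, 8), scent_mark_rates = rep(0, 8),
    cluster_assignment = rep(1:2, each = 4),
    p_in = 0.8, p_out = 0.1, recordings_per_day = 10, n_days = 20,
    dispersal = NULL, pup_cohort = NULL, seed = 17
  )
  pl <- planted_association_network(cfg)
  fg <- fast_greedy_partition(association_matrix(pl$summary))
  expect_equal(
    partition_groups(fg$partition$id, fg$partition$community),
    partition_groups(names(pl$truth$cluster_labels), pl$truth$cluster_labels)
  )
})
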