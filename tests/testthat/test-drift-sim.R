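test_that("lineage counts start at the founding number and never increase", {
  cfg <- sim_config(n_demes = 4L, deme_size = 50L, init_lineages = 30L,
                    generations = 80L, replicates = 20L, seed = 3,
                    init = "balanced")  # exact founding count at generation 0
  sim <- simulate_lineage_sorting(cfg, keep_replicates = TRUE)
  expect_equal(sim$trajectory$mean_system[1], 30)
  expect_true(all(apply(sim$system_counts, 2, function(s) all(diff(s) <= 0))))
  expect_true(all(sim$system_counts >= 1))
  expect_true(all(sim$trajectory$mean_per_deme <= sim$trajectory$mean_system))
  expect_true(all(sim$trajectory$lo95 <= sim$trajectory$mean_system &
                    sim$trajectory$mean_system <= sim$trajectory$hi95))
})

test_that("trajectories are reproducible from seed and config", {
  cfg <- sim_config(n_demes = 3L, deme_size = 20L, init_lineages = 10L,
                    generations = 30L, replicates = 5L, seed = 77)
  s1 <- simulate_lineage_sorting(cfg, keep_replicates = TRUE)
  s2 <- simulate_lineage_sorting(cfg, keep_replicates = TRUE)
  expect_identical(s1$system_counts, s2$system_counts)
})

test_that("small populations match the exact Markov-chain oracle", {
  # N = 2, K = 2: P(both offspring share a parent lineage) = 1/2, so the
  # expected distinct count after one generation is 1.5
  cfg <- sim_config(n_demes = 1L, deme_size = 2L, migration_rate = 0,
                    init_lineages = 2L, generations = 1L,
                    replicates = 4000L, seed = 9, init = "balanced")
  sim <- simulate_lineage_sorting(cfg)
  expect_equal(sim$trajectory$mean_system[2], 1.5, tolerance = 0.03)

  # N = 4, K = 3 over three generations against full state-space iteration
  init <- c(2L, 1L, 1L)
  expected <- vapply(1:3, function(t) wf_expected_distinct(init, t),
                     numeric(1))
  reps <- 3000L
  set.seed(31)
  observed <- rowMeans(vapply(seq_len(reps), function(r) {
    counts <- init
    out <- numeric(3)
    for (g in 1:3) {
      counts <- as.integer(rmultinom(1, 4, counts / 4))
      out[g] <- sum(counts > 0)
    }
    out
  }, numeric(3)))
  expect_equal(observed, expected, tolerance = 0.05)
})

test_that("heterozygosity decays as (1 - 1/N)^t in a single deme", {
  N <- 50L; K <- 50L; t <- 20L; reps <- 400L
  set.seed(13)
  h <- vapply(seq_len(reps), function(r) {
    counts <- gynoclone:::drift_label_counts(K, N, t)
    1 - sum((counts / N)^2)
  }, numeric(1))
  # E[H_0] = (1 - 1/K)(1 - 1/N) under iid uniform initialization
  expected <- (1 - 1 / K) * (1 - 1 / N) * (1 - 1 / N)^t
  expect_equal(mean(h), expected, tolerance = 3 * sd(h) / sqrt(reps) /
                 expected)
})

test_that("per-deme crossing reports the first generation at a threshold", {
  cfg <- sim_config(n_demes = 4L, deme_size = 50L, init_lineages = 30L,
                    generations = 50L, replicates = 10L, seed = 5)
  sim <- simulate_lineage_sorting(cfg)
  expect_equal(per_deme_crossing(sim, 30), 0)
  expect_true(is.na(per_deme_crossing(sim, 0.5)))  # a lineage always survives
  expect_error(per_deme_crossing(sim, 0), "positive")
  g <- per_deme_crossing(sim, 15)
  expect_true(sim$trajectory$mean_per_deme[g + 1] <= 15)
  if (g > 0) expect_true(all(sim$trajectory$mean_per_deme[seq_len(g)] > 15))
})

test_that("rarefaction matches the hypergeometric expectation", {
  # tiny exact case: counts (2, 2), n = 2 -> 5/3 distinct on average
  set.seed(17)
  r <- rarefy(c(2, 2), 2, reps = 8000L)
  expect_equal(r$mean, 5 / 3, tolerance = 0.02)

  # full-census sample always sees every lineage
  expect_equal(rarefy(c(3, 1, 7), 11, reps = 5L)$mean, 3)
  expect_error(rarefy(c(3, 1), 5, 10L), "exceeds population size")

  # arbitrary count vector within 3 standard errors of the closed form
  counts <- c(330, rpois(49, 13) + 1)
  r2 <- rarefy(counts, 24, reps = 400L)
  expect_lt(abs(r2$mean - rarefaction_expect(counts, 24)),
            3 * r2$sd / sqrt(400) + 1e-9)
})

test_that("effective-lineage estimation walks the candidate curve", {
  cfg <- rarefaction_config(seed = 19)
  est <- estimate_effective_lineages(15, cfg)
  expect_equal(est$curve$k, c(15L, 30L, 40L, 50L))
  expect_true(all(diff(est$curve$mean) > 0))  # more lineages, more observed
  # every candidate mean agrees with the closed form for its own population
  for (i in seq_len(4)) {
    set.seed(cfg$seed + i)
    pop <- gynoclone:::build_anchored_population(est$curve$k[i], cfg)
    se <- est$curve$sd[i] / sqrt(cfg$samplings)
    expect_lt(abs(est$curve$mean[i] -
                    rarefaction_expect(pop, cfg$sample_size)), 3 * se)
  }
  expect_equal(estimate_effective_lineages(1, cfg)$adequate_k, 15L)
  expect_error(estimate_effective_lineages(30, cfg), "exceeds the sample")
})

test_that("diversity-to-time calibration brackets the observed count", {
  traj <- tibble::tibble(generation = 0:100,
                         mean_system = seq(100, 0, length.out = 101),
                         lo95 = 0, hi95 = 0,
                         mean_per_deme = seq(100, 0, length.out = 101))
  cal <- calibrate_time(c(40, 60), traj)
  expect_equal(cal$generation_interval, c(40, 60))
  expect_equal(calibrate_time(100, traj)$generation_interval[1], 0)
  cal_y <- calibrate_time(c(40, 60), traj, years_per_generation = 25)
  expect_equal(cal_y$years_bp, c(1000, 1500))
  expect_error(calibrate_time(150, traj), "exceeds the initial")

  # trajectory still above the band at the end: open-ended interval
  short <- traj[1:31, ]
  expect_true(is.na(calibrate_time(c(5, 10), short)$generation_interval[2]))
})
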