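test_that("scenario validation rejects bad stochastic matrices", {
  bad <- default_psg_transitions()
  bad[1, 1] <- 0.5                                # row no longer sums to 1
  expect_error(sim_scenario(transitions = bad), "row-stochastic")
  expect_error(sim_scenario(n_epochs = 0), "n_epochs")
  ml <- matrix(1, 3, 3, dimnames = list(stage_alphabets$DEV3,
                                        stage_alphabets$DEV3))
  expect_error(sim_scenario(mislabel = ml), "row-stochastic")
})

test_that("the PSG chain is deterministic given the seed", {
  s <- sim_scenario(n_epochs = 500, seed = 123)
  expect_identical(simulate_psg(s), simulate_psg(s))
  s2 <- sim_scenario(n_epochs = 500, seed = 124)
  expect_false(identical(simulate_psg(s)$stages, simulate_psg(s2)$stages))
  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_psg(s)); after <- runif(1)
  expect_identical(before, after)
})

test_that("an identity transition matrix yields a constant night", {
  P <- diag(5); dimnames(P) <- dimnames(default_psg_transitions())
  s <- sim_scenario(n_epochs = 100, transitions = P,
                    init = c(Wake = 0, N1 = 0, N2 = 1, N3 = 0, REM = 0))
  expect_equal(unique(simulate_psg(s)$stages), "N2")
})

test_that("empirical stage frequencies match the stationary distribution", {
  # ergodic chain, long run; oracle: left eigenvector of the transition matrix
  P <- default_psg_transitions()
  s <- sim_scenario(n_epochs = 50000, seed = 8)
  h <- simulate_psg(s)
  e <- eigen(t(P))
  stat <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stat <- stat / sum(stat)
  freq <- as.numeric(table(factor(h$stages, stage_alphabets$PSG5))) / 50000
  # 3 sigma with an effective-sample correction for chain autocorrelation
  expect_true(all(abs(freq - stat) < 3 * sqrt(stat * (1 - stat) / 50000) * 6))
})

test_that("a zero-error device equals the categorized PSG end to end", {
  s <- sim_scenario(n_epochs = 960, seed = 10)
  night <- simulate_pair(s)
  expect_identical(night$device$stages, categorize_psg(night$psg, "II")$stages)
  expect_false(any(night$truth$mislabeled))
  expect_equal(lmi_sequence(night$pair)$rates$correct, 100)
})

test_that("a +1 epoch lag turns every transition into two one-sided ones", {
  # hand-traceable toy night with 3 transitions
  s <- sim_scenario(n_epochs = 8, lag_epochs = 1L, seed = 2)
  psg5 <- psg5_hyp(c("Wake", "Wake", "N1", "N1", "N3", "N3", "Wake", "Wake"))
  dev <- simulate_device(psg5, s)$hypnogram
  expect_identical(dev$stages, c("Wake", "Wake", "Wake", "Light", "Light",
                                 "Deep", "Deep", "Wake"))
  r <- lmi_sequence(aligned_pair(categorize_psg(psg5, "II"), dev))
  expect_equal(length(r$transition_set), 6)        # 3 transitions doubled
  expect_true(all(r$lmi_values == 0))
  expect_equal(r$rates$correct, 0)
})

test_that("the mislabel channel hits the planted rate", {
  s <- sim_scenario(n_epochs = 960, seed = 14, mislabel = 0.2)
  truth <- simulate_pair(s)$truth
  expect_lt(abs(mean(truth$mislabeled) - 0.2), 3 * sqrt(0.2 * 0.8 / 960))

  # a full confusion-matrix error model is honoured too
  dev_st <- stage_alphabets$DEV3
  M <- matrix(c(0.9, 0.1, 0,
                0,   1,   0,
                0,   0.5, 0.5), 3, byrow = TRUE,
              dimnames = list(dev_st, dev_st))
  s2 <- sim_scenario(n_epochs = 2000, seed = 15, mislabel = M)
  tr <- simulate_pair(s2)$truth
  deep_rows <- tr[tr$true_stage == "Deep", ]
  frac_light <- mean(deep_rows$device_stage == "Light")
  expect_lt(abs(frac_light - 0.5),
            3 * sqrt(0.25 / nrow(deep_rows)))
  expect_true(all(tr$device_stage[tr$true_stage == "Light"] == "Light"))
})

test_that("dropout epochs hold the previous reported stage", {
  s <- sim_scenario(n_epochs = 2000, seed = 16, missing_prob = 0.3)
  night <- simulate_pair(s)
  tr <- night$truth
  expect_gt(sum(tr$missing), 0)
  miss <- which(tr$missing)
  expect_identical(tr$device_stage[miss], tr$device_stage[miss - 1])
})

test_that("cohorts are written reproducibly with derived per-night seeds", {
  s <- sim_scenario(n_epochs = 120, seed = 77, mislabel = 0.1)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  m1 <- simulate_cohort(5, s, d1)
  m2 <- simulate_cohort(5, s, d2)
  expect_equal(nrow(m1), 5)
  expect_setequal(list.files(d1), c(sprintf("psg_%03d.csv", 1:5),
                                    sprintf("device_%03d.csv", 1:5),
                                    "manifest.csv"))
  for (f in setdiff(list.files(d1), "manifest.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # nights differ from each other
  expect_false(identical(readLines(file.path(d1, "psg_001.csv")),
                         readLines(file.path(d1, "psg_002.csv"))))
})

test_that("cohort-level accuracy recovers the planted mislabel rate", {
  s <- sim_scenario(n_epochs = 480, seed = 21, mislabel = 0.15)
  accs <- vapply(1:10, function(k) {
    sk <- s; sk$seed <- s$seed + k
    confusion(simulate_pair(sk)$pair)$accuracy / 100
  }, numeric(1))
  n_tot <- 10 * 480
  expect_lt(abs(mean(accs) - 0.85), 3 * sqrt(0.15 * 0.85 / n_tot))
})

test_that("YAML scenarios round-trip through read_scenario", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_epochs: 240", "seed: 5", "mislabel: 0.25",
               "dev_type: 'I'", "start_time: '23:15:00'"), f)
  sc <- read_scenario(f)
  expect_s3_class(sc, "sim_scenario")
  expect_equal(sc$n_epochs, 240)
  expect_equal(sc$dev_type$alphabet, "DEV4")
  expect_equal(sc$mislabel, 0.25)
  # the bundled default scenario parses
  sc2 <- read_scenario(system.file("extdata", "default_scenario.yaml",
                                   package = "hypnomatch"))
  expect_equal(sc2$n_epochs, 960)
})
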