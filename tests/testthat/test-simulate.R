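small_config <- function(rng_seed = 99, ...) {
  cohort_config(n_donors = 2, cells_per_group = 5, n_events = 2000,
                n_training_senescent = 10, rng_seed = rng_seed, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(bgal_prob_E = 1.2), "probabilities")
  expect_error(cohort_config(debris_fraction = 1), "probabilities")
  expect_error(cohort_config(n_donors = 0), "counts")
  expect_error(cohort_config(true_abundances_E = c(NADH_free = -1,
    NADH_bound = 1, FAD = 1, lipopigment = 1)), "non-negative")
  expect_error(cohort_config(spectra_noise_sd = -0.1), "dispersions")
})

test_that("spectrum generation obeys the forward model in its limit cases", {
  expect_error(simulate_spectrum(truth_lib, c(-1, 0, 0, 0)), "non-negative")
  expect_error(simulate_spectrum(truth_lib, c(1, 1)), "4 abundances")
  z <- simulate_spectrum(truth_lib, c(0, 0, 0, 0), 0, zero_background())
  expect_true(all(z$intensity == 0))
  fad <- simulate_spectrum(truth_lib, c(0, 0, 1, 0), 0)
  expect_equal(fad$intensity, truth_mat[, "FAD"], tolerance = 1e-12)
})

test_that("mean of noisy replicates converges to the noiseless mixture", {
  a <- c(0.5, 1.0, 1.5, 2.0)
  clean <- as.numeric(truth_mat %*% a)
  set.seed(91)
  reps <- replicate(100, simulate_spectrum(truth_lib, a, 0.01)$intensity)
  se <- 0.01 * max(clean) / sqrt(100)
  expect_true(all(abs(rowMeans(reps) - clean) < 3 * se + 1e-12))
})

test_that("same seed gives byte-identical cohorts", {
  s1 <- simulate_cohort(small_config())
  s2 <- simulate_cohort(small_config())
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- simulate_cohort(small_config(rng_seed = 100))
  expect_false(identical(serialize(s1$bundle, NULL),
                         serialize(s3$bundle, NULL)))
})

test_that("cohorts carry the structure the pipeline needs, plus truth", {
  sim <- simulate_cohort(small_config())
  expect_length(sim$bundle$donors, 2)
  d <- sim$bundle$donors$D1
  expect_length(d$spectra_E, 5)
  expect_length(d$backgrounds_E, 5)  # five background measurements per group
  expect_length(d$backgrounds_S, 5)
  expect_s3_class(d$flow_E, "flow_sample")
  expect_s3_class(d$growth, "growth_curve")
  tr <- sim$truth$donors$D1
  expect_equal(dim(tr$abundances_E), c(5, 4))
  expect_gt(tr$lipopigment_fold, 0)
  expect_equal(sim$truth$configured_folds$lipopigment, 2)
  expect_equal(sim$truth$configured_folds$fsc, 1.3, tolerance = 1e-12)
})

test_that("noiseless generated spectra invert to the true abundances", {
  cfg <- small_config(spectra_noise_sd = 0, background_level = 0)
  sim <- simulate_cohort(cfg)
  d <- sim$bundle$donors$D1
  for (i in 1:3) {
    fit <- unmix(preprocess(d$spectra_E[[i]], d$backgrounds_E, smooth = FALSE),
                 truth_lib)
    a_true <- sim$truth$donors$D1$abundances_E[i, ]
    expect_lt(max(abs(coef(fit) - a_true)) / max(a_true), 1e-8)
  }
})

test_that("equal staining probabilities give fold differences near one", {
  set.seed(92)
  sims <- lapply(1:6, function(i)
    simulate_cohort(cohort_config(n_donors = 1, cells_per_group = 5,
                                  n_events = 1000, n_training_senescent = 10,
                                  bgal_prob_E = 0.3, bgal_prob_S = 0.3,
                                  bgal_logit_sd = 0, rng_seed = 1000 + i)))
  folds <- vapply(sims, function(s) {
    b <- s$bundle$donors$D1$bgal
    (b$positive[b$passage == "S"] / b$total[b$passage == "S"]) /
      (b$positive[b$passage == "E"] / b$total[b$passage == "E"])
  }, 0)
  # each fold inside a wide binomial CI around 1 (p = 0.3, n = 300 per well)
  ci <- qbinom(c(0.001, 0.999), 300, 0.3) / (300 * 0.3)
  expect_true(all(folds > ci[1]^2 & folds < ci[2]^2))
  expect_lt(abs(mean(folds) - 1), 0.15)
})

test_that("a cohort written to disk reproduces the per-file dialects", {
  sim <- simulate_cohort(small_config())
  dir <- withr::local_tempdir()
  write_cohort(sim$bundle, dir, truth = sim$truth)
  sp <- read_spectrum_csv(file.path(dir, "D1", "cell_E_01.csv"))
  expect_identical(sp$intensity, sim$bundle$donors$D1$spectra_E[[1]]$intensity)
  fl <- read_flow_csv(file.path(dir, "D1", "flow_S.csv"))
  expect_identical(fl$events$FSC, sim$bundle$donors$D1$flow_S$events$FSC)
  gc <- read_growth_csv(file.path(dir, "D2", "growth.csv"))
  expect_equal(as.data.frame(gc), as.data.frame(sim$bundle$donors$D2$growth))
  bg <- read_bgal_csv(file.path(dir, "D2", "bgal.csv"))
  expect_equal(bg$positive, sim$bundle$donors$D2$bgal$positive)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "config.json")))
})
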