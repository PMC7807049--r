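test_that("fit_component recovers an exact Gaussian reference", {
  ref <- spectrum(WL, exp(-(WL - 525)^2 / (2 * 30^2)), role = "reference")
  comp <- fit_component(list(ref), list(zero_background()), "FAD",
                        max_gaussians = 1)
  expect_lt(abs(comp$gaussians$center_nm - 525), 0.5)
  expect_lt(abs(comp$gaussians$width_nm - 30) / 30, 0.02)
})

test_that("fit_component is invariant to uniform intensity scaling", {
  shape <- exp(-(WL - 460)^2 / (2 * 55^2))
  c1 <- fit_component(list(spectrum(WL, shape, role = "reference")),
                      list(zero_background()), "NADH_free")
  c10 <- fit_component(list(spectrum(WL, 10 * shape, role = "reference")),
                       list(zero_background()), "NADH_free")
  expect_equal(predict(c1, WL), predict(c10, WL), tolerance = 1e-8)
})

test_that("fitted centers are stable across noisy replicate pairs", {
  shape <- exp(-(WL - 525)^2 / (2 * 40^2))
  set.seed(31)
  centers <- replicate(5, {
    refs <- lapply(1:2, function(i)
      spectrum(WL, shape + rnorm(length(WL), 0, 0.01), role = "reference"))
    comp <- fit_component(refs, list(zero_background()), "FAD",
                          max_gaussians = 1)
    comp$gaussians$center_nm[1]
  })
  expect_true(all(abs(centers - 525) < 1))
})

test_that("fit_component errors on absent signal and disjoint grids", {
  flat <- spectrum(WL, rep(0.2, length(WL)), role = "reference")
  bg <- spectrum(WL, rep(0.2, length(WL)), role = "background")
  expect_error(fit_component(list(flat), list(bg), "x"), "no signal")
  other <- spectrum(seq(900, 1000), rep(1, 101), role = "reference")
  expect_error(fit_component(list(other), list(zero_background()), "x"),
               "overlap|extrapolate")
})

test_that("lipopigment residual learning recovers the injected shape", {
  lib3 <- spectral_library(unname(truth_lib$components[1:3]))
  truth_shape <- truth_mat[, "lipopigment"]

  # senescent cells: lipopigment mean doubled relative to early (0.5 -> 1.0),
  # heterogeneous cell-to-cell, no measurement noise
  set.seed(77)
  ab <- draw_training_abundances(50)
  sen <- lapply(seq_len(nrow(ab)), function(i)
    simulate_spectrum(truth_lib, ab[i, ], 0, NULL, WL))
  learned <- learn_residual_component(sen, list(zero_background()), lib3)
  expect_gte(cosine_sim(predict(learned, WL), truth_shape), 0.99)

  # with 1% noise and 100 spectra
  set.seed(78)
  abn <- draw_training_abundances(100)
  senn <- lapply(seq_len(nrow(abn)), function(i)
    simulate_spectrum(truth_lib, abn[i, ], 0.01, NULL, WL))
  learned_n <- learn_residual_component(senn, list(zero_background()), lib3)
  expect_gte(cosine_sim(predict(learned_n, WL), truth_shape), 0.95)
})

test_that("absence of a fourth component is reported, not invented", {
  lib3 <- spectral_library(unname(truth_lib$components[1:3]))
  set.seed(79)
  sen0 <- lapply(1:8, function(i)
    simulate_spectrum(truth_lib, c(runif(1, 0.8, 1.4), runif(1, 0.6, 1.2),
                                   runif(1, 0.4, 1), 0), 0, NULL, WL))
  expect_error(learn_residual_component(sen0, list(zero_background()), lib3),
               "no residual component detectable")
  expect_error(learn_residual_component(sen0[1:3], list(zero_background()),
                                        lib3), "at least 5")
})

test_that("adding the learned component reduces the unmixing residual", {
  lib3 <- spectral_library(unname(truth_lib$components[1:3]))
  set.seed(80)
  ab <- draw_training_abundances(20)
  sen <- lapply(seq_len(nrow(ab)), function(i)
    simulate_spectrum(truth_lib, ab[i, ], 0.01, NULL, WL))
  learned <- learn_residual_component(sen, list(zero_background()), lib3)
  lib4 <- add_component(lib3, learned)
  res3 <- mean(vapply(sen, function(s)
    unmix(preprocess(s, list(zero_background())), lib3)$residual_l2, 0))
  res4 <- mean(vapply(sen, function(s)
    unmix(preprocess(s, list(zero_background())), lib4)$residual_l2, 0))
  expect_lt(res4, res3)
})
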