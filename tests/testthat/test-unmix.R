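test_that("preprocess subtracts background, crops, and clips", {
  bg <- spectrum(WL, rep(0.3, length(WL)), role = "background")
  cell <- spectrum(WL, rep(0.3, length(WL)))
  out <- preprocess(cell, list(bg))
  expect_true(all(out$intensity == 0))  # self-subtraction
  expect_true(isTRUE(out$meta$preprocessed))

  wide <- spectrum(seq(350, 900), rep(1, 551))
  bg_w <- spectrum(seq(350, 900), rep(0, 551), role = "background")
  cropped <- preprocess(wide, list(bg_w))
  expect_gte(min(cropped$wavelength_nm), 400)
  expect_lte(max(cropped$wavelength_nm), 850)

  # over-subtraction cannot leave negative intensities
  hot_bg <- spectrum(WL, rep(2, length(WL)), role = "background")
  corr <- preprocess(spectrum(WL, rep(1, length(WL))), list(hot_bg))
  expect_true(all(corr$intensity >= 0))

  expect_error(preprocess(cell, list()), "background")
  narrow <- spectrum(seq(500, 600), rep(1, 101))
  expect_error(preprocess(narrow, list(bg)), "cover")
})

test_that("unmixing identities: single component, zero spectrum, scaling", {
  y <- 2 * truth_mat[, "FAD"]
  fit <- unmix(spectrum(WL, y), truth_lib)
  expect_equal(unname(coef(fit)), c(0, 0, 2, 0), tolerance = 1e-10)
  expect_lt(fit$residual_l2, 1e-10)

  z <- unmix(spectrum(WL, rep(0, length(WL))), truth_lib)
  expect_equal(unname(coef(z)), rep(0, 4))
  expect_equal(z$total_autofluorescence, 0)

  # linearity in the noiseless case
  a <- c(0.5, 1.0, 1.5, 2.0)
  mix <- as.numeric(truth_mat %*% a)
  f1 <- unmix(spectrum(WL, mix), truth_lib)
  f3 <- unmix(spectrum(WL, 3 * mix), truth_lib)
  expect_equal(3 * coef(f1), coef(f3), tolerance = 1e-9)
})

test_that("noiseless mixtures are recovered to numerical precision", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(4, 0, 3)
    fit <- unmix(spectrum(WL, as.numeric(truth_mat %*% a)), truth_lib)
    expect_lt(max(abs(coef(fit) - a)) / max(a), 1e-8)
    expect_lt(fit$residual_l2, 1e-8 * sqrt(sum((truth_mat %*% a)^2)))
  }
})

test_that("NNLS agrees with independent constrained minimizers", {
  # 2-component toy vs brute-force nested grid search
  A2 <- truth_mat[, c("FAD", "lipopigment")]
  set.seed(22)
  for (i in 1:5) {
    b <- as.numeric(A2 %*% runif(2, 0.2, 3)) + rnorm(length(WL), 0, 0.02)
    mine <- senospec:::nnls_solve(A2, b)$x
    grid <- oracle_nnls_grid(A2, b)
    expect_equal(mine, grid, tolerance = 1e-4)
  }
  # 4-component toys vs pracma's Lawson-Hanson implementation
  skip_if_not_installed("pracma")
  set.seed(23)
  for (i in 1:10) {
    a <- runif(4, 0, 2) * rbinom(4, 1, 0.8)  # include boundary solutions
    b <- as.numeric(truth_mat %*% a) + rnorm(length(WL), 0, 0.05)
    mine <- senospec:::nnls_solve(truth_mat, b)$x
    ref <- pracma::lsqnonneg(truth_mat, b)$x
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("noisy recovery is unbiased within Monte-Carlo tolerance", {
  a <- c(0.5, 1.0, 1.5, 2.0)
  mix <- as.numeric(truth_mat %*% a)
  set.seed(24)
  est <- replicate(100, {
    y <- mix + rnorm(length(WL), 0, 0.01 * max(mix))
    coef(unmix(spectrum(WL, pmax(y, 0)), truth_lib))
  })
  expect_true(all(est >= 0))  # noise never yields negative coefficients
  rel_rmse <- sqrt(rowMeans((est - a)^2)) / a
  expect_true(all(rel_rmse < 0.05))
})

test_that("component order does not matter", {
  a <- c(0.5, 1.0, 1.5, 2.0)
  y <- spectrum(WL, as.numeric(truth_mat %*% a))
  perm <- c(3, 1, 4, 2)
  lib_perm <- spectral_library(unname(truth_lib$components)[perm])
  f1 <- unmix(y, truth_lib)
  f2 <- unmix(y, lib_perm)
  expect_equal(coef(f1)[names(coef(f2))], coef(f2), tolerance = 1e-9)
  expect_equal(f1$integrated_intensity[names(coef(f2))],
               f2$integrated_intensity, tolerance = 1e-9)
})

test_that("unmixing result bookkeeping is coherent", {
  set.seed(25)
  a <- c(0.8, 0.5, 1.2, 1.5)
  y <- as.numeric(truth_mat %*% a) + rnorm(length(WL), 0, 0.02)
  fit <- unmix(spectrum(WL, pmax(y, 0)), truth_lib)
  expect_true(all(coef(fit) >= 0))
  expect_true(all(fit$integrated_intensity >= 0))
  expect_lte(fit$r_squared, 1)
  # component integrals cannot exceed the corrected-spectrum integral by
  # more than the residual allows (Cauchy-Schwarz bound on the grid)
  allowance <- fit$residual_l2 * sqrt(length(WL))
  expect_lte(sum(fit$integrated_intensity),
             fit$total_autofluorescence + allowance)
  expect_error(unmix(spectrum(c(500, 501, 502), c(1, 1, 1)), truth_lib),
               "underdetermined")
})

test_that("summarize_cells computes sample statistics and handles n = 1", {
  mk <- function(v) {
    y <- v * truth_mat[, "lipopigment"]
    unmix(spectrum(WL, y), truth_lib)
  }
  fits <- lapply(c(1, 2, 3), mk)
  s <- summarize_cells(fits, "coefficient", component = "lipopigment")
  expect_equal(s$mean, 2, tolerance = 1e-8)
  expect_equal(s$sd, 1, tolerance = 1e-6)
  expect_equal(s$n, 3)
  one <- summarize_cells(fits[2], "total_af")
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1)
  none <- summarize_cells(fits, "integral", component = "FAD")
  expect_equal(none$mean, 0, tolerance = 1e-9)
  expect_error(summarize_cells(list(), "total_af"), "no unmixing results")
})
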