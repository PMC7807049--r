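test_that("population doubling follows the log2 expansion law", {
  expect_equal(population_doubling(1e5, 1e6), log2(10), tolerance = 1e-12)
  expect_equal(population_doubling(5e4, 5e4), 0)
  expect_equal(population_doubling(5e4, 1e5), 1)
  expect_error(population_doubling(0, 10), "positive")
  expect_error(population_doubling(10, -1), "positive")
})

test_that("growth curves accumulate cPD exactly", {
  gc <- growth_curve(data.frame(passage = 1:4, seeded = rep(1e5, 4),
                                harvested = c(8e5, 4e5, 3e5, 1.5e5),
                                days = c(7, 7, 7, 14)))
  expect_equal(gc$cpd, cumsum(gc$pd))
  expect_true(all(diff(gc$cpd) >= 0))  # all PDs positive here
  expect_equal(gc$pd_rate, gc$pd / gc$days)
})

test_that("early passage is the cPD closest to six, ties to the earlier", {
  mk <- function(cpds, days = 7) {
    pd <- diff(c(0, cpds))
    growth_curve(data.frame(passage = seq_along(cpds), seeded = 1e5,
                            harvested = 1e5 * 2^pd, days = days))
  }
  cls <- suppressWarnings(classify_passages(mk(c(2.1, 4.0, 6.13, 8.0))))
  expect_equal(cls$early, 3)
  expect_equal(cls$early_cpd, 6.13, tolerance = 1e-9)
  # exact tie |5-6| = |7-6| breaks to the earlier passage
  tie <- suppressWarnings(classify_passages(mk(c(5, 7))))
  expect_equal(tie$early, 1)
})

test_that("senescence rules trigger on the documented doubling rates", {
  curve <- growth_curve(data.frame(
    passage = 1:4, seeded = 1e5,
    harvested = 1e5 * 2^c(3.0, 2.0, 0.9, 0.4), days = 7))
  # 0.9 PD in 7 days: fails the 7-day rule but not the 14-day rule
  expect_equal(classify_passages(curve)$senescent, 3)
  expect_equal(classify_passages(curve,
                                 senescent_rule = "no_doubling_14d")$senescent,
               4)  # 0.4 PD / 7 d < 1/14 PD per day
  # no growth arrest at all -> S undefined with a warning
  healthy <- growth_curve(data.frame(passage = 1:3, seeded = 1e5,
                                     harvested = 1e6, days = 7))
  expect_warning(cls <- classify_passages(healthy), "S undefined")
  expect_true(is.na(cls$senescent))
})

test_that("classification ignores passages recorded after senescence", {
  base <- data.frame(passage = 1:5, seeded = 1e5,
                     harvested = 1e5 * 2^c(3.5, 2.8, 1.4, 0.8, 0.5), days = 7)
  with_extra <- rbind(base, data.frame(passage = 6:7, seeded = 1e5,
                                       harvested = 1e5 * 2^0.3, days = 7))
  c1 <- classify_passages(growth_curve(base))
  c2 <- classify_passages(growth_curve(with_extra))
  expect_equal(c1$early, c2$early)
  expect_equal(c1$senescent, c2$senescent)
})

test_that("beta-gal percentage arithmetic, bounds and undercount warning", {
  expect_equal(as.numeric(bgal_percentage(50, 200)), 25)
  expect_silent(p0 <- bgal_percentage(0, 250))
  expect_equal(as.numeric(p0), 0)
  expect_warning(p <- bgal_percentage(10, 150), "undercounted")
  expect_equal(as.numeric(p), 100 * 10 / 150, tolerance = 1e-9)
  expect_true(attr(p, "undercounted"))
  expect_error(bgal_percentage(201, 200), "\\[0, total\\]")
  expect_error(bgal_percentage(1, 0), ">= 1")
  # always a percentage
  set.seed(51)
  for (i in 1:20) {
    tot <- sample(200:400, 1)
    pos <- sample(0:tot, 1)
    v <- as.numeric(suppressWarnings(bgal_percentage(pos, tot)))
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("growth and beta-gal CSV dialects round-trip", {
  gc <- growth_curve(data.frame(passage = 1:3, seeded = c(1e5, 1e5, 12e4),
                                harvested = c(9e5, 6e5, 2e5), days = c(7, 7, 10)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(gc, f)
  expect_equal(as.data.frame(read_growth_csv(f)), as.data.frame(gc))
  bg <- data.frame(well = c("w1", "w2"), positive = c(30L, 180L),
                   total = c(300L, 300L))
  write_bgal_csv(bg, f)
  expect_equal(read_bgal_csv(f), bg)
})
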