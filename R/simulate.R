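#' Configuration for a synthetic hMSC senescence cohort
#'
#' Bundles every knob of the synthetic study: how many donors, how many
#' cells are measured spectroscopically per passage group, the spectral
#' ground-truth abundances for early (E) and senescent (S) cells, the
#' lognormal flow-channel populations, the beta-gal staining probabilities,
#' the growth-curve kinetics and the RNG seed. The defaults encode the study
#' conditions the downstream tests exercise: six donors; ten cell spectra
#' per passage group; a two-fold senescent increase in lipopigment abundance
#' (and a 1.4-fold increase in the metabolic fluorophores); a 1.3-fold shift
#' in forward-scatter median; beta-gal positivity rising from 10% to 60%;
#' and a growth curve whose doubling rate decays geometrically until the
#' senescence rule trips.
#'
#' @param n_donors number of donors.
#' @param cells_per_group cell spectra per donor per passage group.
#' @param wavelengths common wavelength grid (nm) for all generated spectra.
#' @param spectra_noise_sd additive Gaussian noise sd, as a fraction of each
#'   spectrum's peak (noiseless) intensity.
#' @param background_level amplitude (a.u.) of the smooth imaging-solution
#'   background curve.
#' @param true_abundances_E,true_abundances_S named non-negative mean
#'   abundance vectors, one entry per library component.
#' @param abundance_cv per-cell lognormal coefficient of variation of the
#'   true abundances.
#' @param donor_cv lognormal coefficient of variation of the per-donor
#'   brightness factor (applied to E and S alike, so configured S/E folds
#'   are preserved).
#' @param flow_params_E,flow_params_S per-channel lognormal parameters:
#'   `list(FSC = c(median, sigma), FL1 = c(median, sigma))`.
#' @param n_events flow events per sample.
#' @param debris_fraction expected fraction of low-FSC debris events in
#'   `[0, 1)`.
#' @param debris_params lognormal parameters of the debris subpopulation.
#' @param bgal_prob_E,bgal_prob_S per-cell probability of staining beta-gal
#'   positive.
#' @param cells_counted_bgal cells counted per stained well (>= 200 keeps
#'   the counting rule satisfied).
#' @param bgal_logit_sd donor-to-donor sd of the staining probabilities on
#'   the logit scale.
#' @param growth list with `initial_seed` (cells seeded per passage),
#'   `initial_pd_rate` (population doublings per day at passage 1), `decay`
#'   (geometric per-passage decay of that rate), `days_per_passage` and
#'   `n_passages`.
#' @param donor_flow_cv lognormal CV of the per-donor flow-channel median
#'   factor (applied to E and S alike). Kept modest so the configured
#'   group shifts dominate donor effects.
#' @param n_training_senescent number of senescent-cell spectra in the
#'   shared library-training set.
#' @param training_lipo_cv per-cell CV of lipopigment abundance in the
#'   training senescent cells; set well above `abundance_cv` because
#'   lipofuscin accumulation is highly heterogeneous, and that variation is
#'   what makes the residual component identifiable.
#' @param rng_seed integer seed; the whole cohort is reproducible from it.
#' @return A validated `"cohort_config"` list.
#' @export
cohort_config <- function(
    n_donors = 6L,
    cells_per_group = 10L,
    wavelengths = seq(400, 850),
    spectra_noise_sd = 0.01,
    background_level = 0.05,
    true_abundances_E = c(NADH_free = 1.0, NADH_bound = 0.8, FAD = 0.6,
                          lipopigment = 0.5),
    true_abundances_S = c(NADH_free = 1.4, NADH_bound = 1.12, FAD = 0.84,
                          lipopigment = 1.0),
    abundance_cv = 0.15,
    donor_cv = 0.15,
    flow_params_E = list(FSC = c(median = 5e4, sigma = 0.25),
                         FL1 = c(median = 1000, sigma = 0.35)),
    flow_params_S = list(FSC = c(median = 6.5e4, sigma = 0.25),
                         FL1 = c(median = 3000, sigma = 0.35)),
    n_events = 1e5,
    debris_fraction = 0.05,
    debris_params = list(FSC = c(median = 5e3, sigma = 0.5),
                         FL1 = c(median = 300, sigma = 0.5)),
    bgal_prob_E = 0.10,
    bgal_prob_S = 0.60,
    cells_counted_bgal = 300L,
    bgal_logit_sd = 0.25,
    growth = list(initial_seed = 1e5, initial_pd_rate = 0.45, decay = 0.82,
                  days_per_passage = 7, n_passages = 12),
    donor_flow_cv = 0.05,
    n_training_senescent = 50L,
    training_lipo_cv = 0.5,
    rng_seed = 1L) {
  probs <- c(bgal_prob_E, bgal_prob_S, debris_fraction)
  if (any(probs < 0) || any(probs > 1) || debris_fraction >= 1)
    stop("probabilities must lie in [0,1] (debris_fraction in [0,1))")
  counts <- c(n_donors, cells_per_group, n_events, cells_counted_bgal)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (any(true_abundances_E < 0) || any(true_abundances_S < 0))
    stop("abundances must be non-negative")
  if (!identical(names(true_abundances_E), names(true_abundances_S)))
    stop("E and S abundance vectors must name the same components")
  if (spectra_noise_sd < 0 || abundance_cv < 0 || donor_cv < 0)
    stop("dispersions must be non-negative")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# lognormal parameterised by its mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one cell emission spectrum (the forward unmixing model)
#'
#' Intensities are the non-negative mixture of the library's unit-peak
#' component shapes, plus an optional background spectrum, plus additive
#' Gaussian noise scaled to the peak of the noiseless signal.
#'
#' @param library a [spectral_library] (the ground truth).
#' @param abundances non-negative vector, one coefficient per component.
#' @param noise_sd noise sd as a fraction of the peak noiseless intensity.
#' @param background optional background [spectrum] on a covering grid.
#' @param wavelengths grid to generate on (default 400-850 nm at 1 nm).
#' @param ... metadata passed to [spectrum()].
#' @return A [spectrum] with role `"cell"`.
#' @export
simulate_spectrum <- function(library, abundances, noise_sd = 0,
                              background = NULL,
                              wavelengths = seq(400, 850), ...) {
  stopifnot(inherits(library, "spectral_library"))
  k <- length(library$components)
  if (length(abundances) != k)
    stop(sprintf("need %d abundances, got %d", k, length(abundances)))
  if (any(abundances < 0)) stop("abundances must be non-negative")
  y <- as.numeric(library_matrix(library, wavelengths) %*% abundances)
  if (!is.null(background))
    y <- y + resample_spectrum(background, wavelengths)$intensity
  peak <- max(y)
  if (noise_sd > 0 && peak > 0)
    y <- y + stats::rnorm(length(y), 0, noise_sd * peak)
  spectrum(wavelengths, y, role = "cell", ...)
}

# smooth low-amplitude imaging-solution background plus measurement noise
simulate_background <- function(wavelengths, level, noise_sd = 0, ...) {
  y <- level * (0.7 + 0.6 * exp(-((wavelengths - 480) / 120)^2))
  if (noise_sd > 0 && level > 0)
    y <- y + stats::rnorm(length(y), 0, noise_sd * level)
  spectrum(wavelengths, y, role = "background", ...)
}

#' Simulate a flow-cytometry sample
#'
#' Events are drawn lognormally per channel (scatter and fluorescence
#' intensities are right-skewed and positive); a low-FSC debris
#' subpopulation is mixed in with binomial count at `debris_fraction`.
#' Per-event truth labels (`"cell"` / `"debris"`) are retained.
#'
#' @param n_events number of events (>= 1).
#' @param params `list(FSC = c(median, sigma), FL1 = c(median, sigma))` for
#'   the cell population (`sigma` is the lognormal sdlog; 0 collapses the
#'   population onto its median).
#' @param debris_fraction expected debris fraction in `[0, 1)`.
#' @param debris_params lognormal parameters of the debris subpopulation.
#' @param ... metadata passed to [flow_sample()].
#' @return A [flow_sample] with a `label` column.
#' @export
simulate_flow_sample <- function(n_events, params, debris_fraction = 0,
                                 debris_params = list(
                                   FSC = c(median = 5e3, sigma = 0.5),
                                   FL1 = c(median = 300, sigma = 0.5)),
                                 ...) {
  stopifnot(n_events >= 1)
  n_debris <- if (debris_fraction > 0)
    stats::rbinom(1L, n_events, debris_fraction) else 0L
  n_cell <- n_events - n_debris
  draw <- function(p, n) {
    if (p[["sigma"]] == 0) return(rep(p[["median"]], n))  # exact zero-variance limit
    stats::rlnorm(n, log(p[["median"]]), p[["sigma"]])
  }
  fsc <- c(draw(params$FSC, n_cell), draw(debris_params$FSC, n_debris))
  fl1 <- c(draw(params$FL1, n_cell), draw(debris_params$FL1, n_debris))
  flow_sample(fsc, fl1,
              label = rep(c("cell", "debris"), c(n_cell, n_debris)), ...)
}

#' Simulate a whole senescence-study cohort with recorded ground truth
#'
#' Generates, for each donor: E and S cell-spectra sets with five background
#' spectra per group, E and S flow samples, binomial beta-gal counts and a
#' multi-passage growth record; plus one shared library-training set
#' (reference-solution spectra for the three solution-trainable fluorophores
#' and senescent-cell spectra for lipopigment residual learning). Everything
#' is reproducible from `config$rng_seed`, and a truth record of the
#' realized per-donor abundances, fold differences and staining
#' probabilities is returned alongside the data so parameter-recovery tests
#' can compare pipeline output against what was actually simulated.
#'
#' @param config a [cohort_config()].
#' @param library the ground-truth [spectral_library]; default
#'   [default_library()]. Its component names must match the configured
#'   abundance vectors.
#' @return A list with `bundle` (class `"senospec_cohort"`: `$donors`,
#'   `$training`, `$config`) and `truth` (class `"cohort_truth"`).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            library = default_library()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!identical(names(library$components), names(config$true_abundances_E)))
    stop("library component names do not match the configured abundances")
  set.seed(config$rng_seed)
  wl <- config$wavelengths
  k <- length(library$components)
  comp_names <- names(library$components)

  make_group <- function(means, donor, passage) {
    ab <- vapply(seq_len(k), function(j)
      rlnorm_mean_cv(config$cells_per_group, means[j], config$abundance_cv),
      numeric(config$cells_per_group))
    ab <- matrix(ab, nrow = config$cells_per_group,
                 dimnames = list(NULL, comp_names))
    bg_true <- simulate_background(wl, config$background_level)
    spectra <- lapply(seq_len(config$cells_per_group), function(i)
      simulate_spectrum(library, ab[i, ], config$spectra_noise_sd, bg_true,
                        wavelengths = wl, donor = donor, passage = passage,
                        sample_id = sprintf("%s_%s_cell%02d", donor, passage, i)))
    backgrounds <- lapply(seq_len(5L), function(i)
      simulate_background(wl, config$background_level,
                          config$spectra_noise_sd, donor = donor))
    list(abundances = ab, spectra = spectra, backgrounds = backgrounds)
  }

  donors <- list()
  truth_donors <- list()
  for (d in seq_len(config$n_donors)) {
    id <- sprintf("D%d", d)
    dfac <- rlnorm_mean_cv(1L, 1, config$donor_cv)
    grpE <- make_group(config$true_abundances_E * dfac, id, "E")
    grpS <- make_group(config$true_abundances_S * dfac, id, "S")

    ffac <- rlnorm_mean_cv(1L, 1, config$donor_flow_cv)
    jitter_flow <- function(p) {
      p$FSC[["median"]] <- p$FSC[["median"]] * ffac
      p$FL1[["median"]] <- p$FL1[["median"]] * ffac
      p
    }
    fpE <- jitter_flow(config$flow_params_E)
    fpS <- jitter_flow(config$flow_params_S)
    flowE <- simulate_flow_sample(config$n_events, fpE,
                                  config$debris_fraction, config$debris_params,
                                  donor = id, passage = "E")
    flowS <- simulate_flow_sample(config$n_events, fpS,
                                  config$debris_fraction, config$debris_params,
                                  donor = id, passage = "S")

    jit <- function(p) stats::plogis(stats::qlogis(p) +
                                       stats::rnorm(1L, 0, config$bgal_logit_sd))
    pE <- jit(config$bgal_prob_E); pS <- jit(config$bgal_prob_S)
    bgal <- data.frame(
      well = paste0(id, c("_E", "_S")),
      passage = c("E", "S"),
      positive = c(stats::rbinom(1L, config$cells_counted_bgal, pE),
                   stats::rbinom(1L, config$cells_counted_bgal, pS)),
      total = rep(config$cells_counted_bgal, 2L))

    growth <- simulate_growth(config$growth)

    donors[[id]] <- list(
      spectra_E = grpE$spectra, spectra_S = grpS$spectra,
      backgrounds_E = grpE$backgrounds, backgrounds_S = grpS$backgrounds,
      flow_E = flowE, flow_S = flowS, bgal = bgal, growth = growth)
    truth_donors[[id]] <- list(
      abundances_E = grpE$abundances, abundances_S = grpS$abundances,
      mean_abundances_E = colMeans(grpE$abundances),
      mean_abundances_S = colMeans(grpS$abundances),
      lipopigment_fold = mean(grpS$abundances[, "lipopigment"]) /
        mean(grpE$abundances[, "lipopigment"]),
      fsc_fold = fpS$FSC[["median"]] / fpE$FSC[["median"]],
      fl1_fold = fpS$FL1[["median"]] / fpE$FL1[["median"]],
      bgal_prob_E = pE, bgal_prob_S = pS, bgal_fold = pS / pE)
  }

  # shared library-training material: reference solutions for the first
  # three fluorophores, backgrounds, and senescent cells rich in lipopigment
  train_bg_true <- simulate_background(wl, config$background_level)
  ref_names <- setdiff(comp_names, "lipopigment")
  references <- lapply(ref_names, function(nm) {
    a <- numeric(k); names(a) <- comp_names; a[nm] <- 1
    lapply(seq_len(3L), function(i)
      simulate_spectrum(library, a, config$spectra_noise_sd / 2, train_bg_true,
                        wavelengths = wl, sample_id = paste0("ref_", nm, "_", i)))
  })
  names(references) <- ref_names
  train_backgrounds <- lapply(seq_len(5L), function(i)
    simulate_background(wl, config$background_level, config$spectra_noise_sd))
  # lipofuscin accumulation is highly heterogeneous cell to cell, which is
  # also what makes the residual component identifiable during training
  senescent_training <- lapply(seq_len(config$n_training_senescent), function(i) {
    a <- vapply(seq_len(k), function(j)
      rlnorm_mean_cv(1L, config$true_abundances_S[j],
                     if (comp_names[j] == "lipopigment")
                       config$training_lipo_cv else config$abundance_cv), 0)
    simulate_spectrum(library, a, config$spectra_noise_sd, train_bg_true,
                      wavelengths = wl, passage = "S",
                      sample_id = sprintf("training_sen_%02d", i))
  })

  bundle <- structure(list(
    donors = donors,
    training = list(references = references,
                    backgrounds = train_backgrounds,
                    senescent = senescent_training),
    config = config), class = "senospec_cohort")
  truth <- structure(list(donors = truth_donors,
                          configured_folds = list(
                            lipopigment = unname(
                              config$true_abundances_S[["lipopigment"]] /
                                config$true_abundances_E[["lipopigment"]]),
                            fsc = config$flow_params_S$FSC[["median"]] /
                              config$flow_params_E$FSC[["median"]],
                            bgal = config$bgal_prob_S / config$bgal_prob_E),
                          rng_seed = config$rng_seed),
                     class = "cohort_truth")
  list(bundle = bundle, truth = truth)
}

# geometric decay of the per-day doubling rate across passages, with a
# small multiplicative harvest-count error
simulate_growth <- function(g) {
  rate0 <- g$initial_pd_rate * rlnorm_mean_cv(1L, 1, 0.08)
  passages <- seq_len(g$n_passages)
  rate <- rate0 * g$decay^(passages - 1)
  pd_true <- rate * g$days_per_passage
  harvested <- pmax(round(g$initial_seed * 2^pd_true *
                            rlnorm_mean_cv(g$n_passages, 1, 0.02)), 1)
  growth_curve(data.frame(passage = passages,
                          seeded = rep(g$initial_seed, g$n_passages),
                          harvested = harvested,
                          days = rep(g$days_per_passage, g$n_passages)))
}

#' @export
print.senospec_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d donors, %d spectra/group, %g flow events/sample>\n",
              length(x$donors), x$config$cells_per_group, x$config$n_events))
  invisible(x)
}

#' Write a cohort bundle to disk in the package's text dialects
#'
#' Spectra as per-measurement CSVs, flow samples and beta-gal counts and
#' growth records as CSVs, the configuration and (optionally) the truth
#' record as JSON.
#'
#' @param bundle a `"senospec_cohort"`.
#' @param dir output directory (created if needed).
#' @param truth optional `"cohort_truth"` to write alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir, truth = NULL) {
  stopifnot(inherits(bundle, "senospec_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(bundle$donors)) {
    dd <- file.path(dir, id)
    dir.create(dd, showWarnings = FALSE)
    don <- bundle$donors[[id]]
    for (grp in c("E", "S")) {
      sp <- don[[paste0("spectra_", grp)]]
      for (i in seq_along(sp))
        write_spectrum_csv(sp[[i]],
                           file.path(dd, sprintf("cell_%s_%02d.csv", grp, i)))
      bgs <- don[[paste0("backgrounds_", grp)]]
      for (i in seq_along(bgs))
        write_spectrum_csv(bgs[[i]],
                           file.path(dd, sprintf("background_%s_%02d.csv", grp, i)))
      write_flow_csv(don[[paste0("flow_", grp)]],
                     file.path(dd, sprintf("flow_%s.csv", grp)))
    }
    write_bgal_csv(don$bgal, file.path(dd, "bgal.csv"))
    write_growth_csv(don$growth, file.path(dd, "growth.csv"))
  }
  cfg <- bundle$config
  cfg$wavelengths <- range(cfg$wavelengths)  # keep the file small
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
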