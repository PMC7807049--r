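# shared fixtures and independent oracles, built in code at test time

WL <- seq(400, 850)

zero_background <- function(wl = WL) {
  spectrum(wl, rep(0, length(wl)), role = "background")
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# truth library and its component matrix on the standard grid
truth_lib <- default_library()
truth_mat <- vapply(truth_lib$components, function(c) predict(c, WL),
                    numeric(length(WL)))

# draw per-cell senescent-like training abundances (heterogeneous lipopigment)
draw_training_abundances <- function(n, lipo_mean = 1, lipo_cv = 0.5) {
  t(vapply(seq_len(n), function(i) c(
    NADH_free = rlnorm(1, log(1.4), 0.15),
    NADH_bound = rlnorm(1, log(1.12), 0.15),
    FAD = rlnorm(1, log(0.84), 0.15),
    lipopigment = rlnorm(1, log(lipo_mean), lipo_cv)
  ), numeric(4)))
}

# independent Spearman oracle: full enumeration with a recursive permutation
# generator and stats::cor on mid-ranks (different code path from the package)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y); n <- length(x)
  r_obs <- stats::cor(rx, ry)
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rs <- vapply(permute(seq_len(n)), function(p) stats::cor(rx, ry[p]), 0)
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

# brute-force non-negative least squares by nested grid refinement
# (only usable for 2 components; independent of the active-set solver)
oracle_nnls_grid <- function(A, b, hi = 5, levels = 8, pts = 41) {
  lo <- c(0, 0); hi <- c(hi, hi)
  best <- NULL
  for (l in seq_len(levels)) {
    g1 <- seq(lo[1], hi[1], length.out = pts)
    g2 <- seq(lo[2], hi[2], length.out = pts)
    obj <- outer(g1, g2, Vectorize(function(a1, a2)
      sum((b - A %*% c(a1, a2))^2)))
    ij <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    best <- c(g1[ij[1]], g2[ij[2]])
    step1 <- g1[2] - g1[1]; step2 <- g2[2] - g2[1]
    lo <- pmax(c(best[1] - step1, best[2] - step2), 0)
    hi <- c(best[1] + step1, best[2] + step2)
  }
  best
}
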