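test_that("ncm_predict matches the quadrature oracle and the beta reflection identity", {
  # frozen from numerical integration of the Beta(5,5) density over (0.01, 1)
  expect_equal(ncm_predict(0.5, Nm = 10, d = 0.01), 0.999999987815,
               tolerance = 1e-9)

  # reflection: 1 - I_d(a, b) = I_{1-d}(b, a)
  for (p in c(0.01, 0.3, 0.7)) {
    for (d in c(0.001, 0.1)) {
      a <- 200 * p; b <- 200 * (1 - p)
      expect_equal(ncm_predict(p, 200, d),
                   pbeta(1 - d, b, a), tolerance = 1e-12)
    }
  }

  # abundant taxon far above the detection limit is near-certain to occur
  expect_gt(ncm_predict(0.1, Nm = 1e4, d = 1e-4), 0.999)

  expect_error(ncm_predict(0, 10, 0.01), "strictly in")
  expect_error(ncm_predict(0.5, 10, 1.2), "detection limit")
})

test_that("ncm_predict is strictly increasing in p and Nm", {
  # grids chosen below the double-precision saturation of the beta tail
  p_grid <- 10^seq(-4, -2, length.out = 40)
  f <- ncm_predict(p_grid, Nm = 500, d = 1e-3)
  expect_true(all(f < 1) && all(diff(f) > 0))

  nm_grid <- 10^seq(0.5, 2.5, length.out = 40)
  f2 <- vapply(nm_grid, function(nm) ncm_predict(0.01, nm, d = 1e-3),
               numeric(1))
  expect_true(all(f2 < 1) && all(diff(f2) > 0))
})

test_that("fit_ncm recovers Nm exactly on noiseless self-consistent input", {
  set.seed(5)
  N <- 5000
  p <- sort(10^runif(80, -4, -1), decreasing = TRUE)
  p <- p / sum(p) * 0.9               # keep p in (0,1), realistic total
  freq <- ncm_predict(p, Nm = 500, d = 1 / N)
  # exercise the estimator core on exact (p, freq) pairs
  est <- phycoassembly:::fit_nm_value(p, freq, d = 1 / N, nm_max = 10 * N)
  expect_equal(est, 500, tolerance = 1e-3)
  pred <- ncm_predict(p, est, 1 / N)
  r2 <- 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)
  expect_gt(r2, 1 - 1e-6)
})

test_that("R-squared collapses when occurrence is shuffled against abundance", {
  set.seed(11)
  ds <- generate_neutral_dataset(n_taxa = 200, shape = 1, N = 2000, m = 0.1,
                                 n_samples = 30, seed = 11)
  x <- ds$abundance
  fit <- fit_ncm(x)
  expect_gt(fit$r_squared, 0.5)       # the real relationship is strong

  rel <- x / rowSums(x)
  p <- colMeans(rel); fo <- colMeans(x > 0)
  keep <- fo > 0 & p > 0 & p < 1
  fo_shuf <- sample(fo[keep])         # break the abundance-occurrence link
  est <- phycoassembly:::fit_nm_value(p[keep], fo_shuf, 1 / 2000, 2e4)
  pred <- ncm_predict(p[keep], est, 1 / 2000)
  r2 <- 1 - sum((fo_shuf - pred)^2) / sum((fo_shuf - mean(fo_shuf))^2)
  expect_lt(r2, 0.1)
})

test_that("fit_ncm recovers the generator's exact stationary scale", {
  # the Moran scheme's stationary count law is beta-binomial with scale
  # m(N-1)/(1-m); the Sloan continuous fit lands near that scale (with a
  # known upward detection-discretisation offset), far from pathological
  N <- 2000; m <- 0.1
  ds <- generate_neutral_dataset(n_taxa = 300, shape = 1, N = N, m = m,
                                 n_samples = 40, seed = 21)
  fit <- fit_ncm(ds$abundance)
  scale_exact <- m * (N - 1) / (1 - m)
  expect_gt(fit$Nm, 0.8 * scale_exact)
  expect_lt(fit$Nm, 1.6 * scale_exact)
  expect_equal(fit$Nm, fit$m * fit$N, tolerance = 1e-9)
  expect_equal(fit$N, 2000)           # rows sum to N exactly
  expect_equal(fit$d, 1 / 2000)
})

test_that("fitted Nm is monotone in the generator's immigration rate", {
  fits <- vapply(c(0.02, 0.1, 0.5), function(m) {
    ds <- generate_neutral_dataset(n_taxa = 200, shape = 1, N = 1000, m = m,
                                   n_samples = 30, seed = 31)
    fit_ncm(ds$abundance)$Nm
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("R-squared is invariant to taxon order and to duplicating samples", {
  ds <- generate_neutral_dataset(n_taxa = 150, shape = 1, N = 1000, m = 0.2,
                                 n_samples = 25, seed = 41)
  x <- ds$abundance
  f0 <- fit_ncm(x)
  set.seed(1)
  f1 <- fit_ncm(x[, sample(ncol(x))])
  expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-9)
  expect_equal(f1$Nm, f0$Nm, tolerance = 1e-6)

  xdup <- rbind(x, x)
  rownames(xdup) <- paste0("s", seq_len(nrow(xdup)))
  f2 <- fit_ncm(xdup)
  expect_equal(f2$r_squared, f0$r_squared, tolerance = 1e-9)
})

test_that("fit_ncm enforces its input contract", {
  x <- matrix(0, 3, 12, dimnames = list(paste0("s", 1:3), paste0("t", 1:12)))
  expect_error(fit_ncm(x), "all-zero")

  rel <- matrix(1 / 12, 3, 12,
                dimnames = list(paste0("s", 1:3), paste0("t", 1:12)))
  expect_error(fit_ncm(rel), "relative abundances")

  small <- random_table(5, 4, 1)
  expect_error(fit_ncm(small), "at least 10 taxa")
})

test_that("bootstrap CI degenerates on noiseless input and rejects n_boot = 0", {
  set.seed(6)
  N <- 5000
  p <- 10^runif(60, -3.5, -1)
  freq <- ncm_predict(p, Nm = 800, d = 1 / N)
  # embed the noiseless pairs in an ncm_fit to bootstrap the refitter
  fit <- structure(list(m = 800 / N, Nm = 800, N = N, d = 1 / N,
                        r_squared = 1, n_samples = 50, n_taxa = length(p),
                        per_taxon = data.frame(p = p, freq_obs = freq,
                                               freq_pred = freq),
                        ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L),
                   class = "ncm_fit")
  bf <- bootstrap_ncm(fit, n_boot = 200, seed = 9)
  expect_lt(bf$ci_high - bf$ci_low, 0.01 * 800)
  expect_true(bf$ci_low <= 800 && 800 <= bf$ci_high)
  expect_error(bootstrap_ncm(fit, n_boot = 0), "at least 1")
})

test_that("envelope classification separates clear departures and partitions taxa", {
  ds <- generate_neutral_dataset(n_taxa = 150, shape = 1, N = 1000, m = 0.2,
                                 n_samples = 25, seed = 51)
  fit <- fit_ncm(ds$abundance)
  cls <- classify_partitions(fit)
  expect_equal(nrow(cls), fit$n_taxa)
  expect_true(all(cls$class %in% c("above", "within", "below")))

  # exact agreement with the prediction is always 'within'
  f2 <- fit
  f2$per_taxon$freq_obs <- f2$per_taxon$freq_pred
  expect_true(all(classify_partitions(f2)$class == "within"))

  # freq_obs = 1 against freq_pred = 0.2 with n = 50 lies far above the
  # envelope; prop.test without continuity correction is an independent
  # Wilson-interval oracle for the envelope bounds
  f3 <- fit
  f3$n_samples <- 50
  f3$per_taxon$freq_pred[1] <- 0.2
  f3$per_taxon$freq_obs[1] <- 1
  cls3 <- classify_partitions(f3)
  expect_equal(cls3$class[1], "above")
  oracle <- prop.test(10, 50, correct = FALSE)$conf.int
  expect_equal(cls3$envelope_low[1], oracle[1], tolerance = 1e-9)
  expect_equal(cls3$envelope_high[1], oracle[2], tolerance = 1e-9)
})

test_that("ncm_fit methods print, summarise, predict and expose coefficients", {
  ds <- generate_neutral_dataset(n_taxa = 150, shape = 1, N = 1000, m = 0.2,
                                 n_samples = 25, seed = 61)
  fit <- bootstrap_ncm(fit_ncm(ds$abundance), n_boot = 50, seed = 1)
  expect_output(print(fit), "Nm")
  expect_output(print(summary(fit)), "envelope")
  expect_named(coef(fit), c("Nm", "m", "N", "d"))
  expect_equal(unname(predict(fit, newdata = 0.05)),
               ncm_predict(0.05, fit$Nm, fit$d))
  expect_equal(fitted(fit) + residuals(fit),
               setNames(fit$per_taxon$freq_obs, rownames(fit$per_taxon)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
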