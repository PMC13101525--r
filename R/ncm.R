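#' Predicted occurrence frequency under the Sloan neutral model
#'
#' Under neutral assembly from a metacommunity, the local relative
#' abundance of a taxon with metacommunity abundance p is approximately
#' Beta(Nm p, Nm (1 - p)) distributed, so the probability of detecting it
#' above the detection limit d is
#' \deqn{\hat f(p) = 1 - I_d(Nm\,p,\; Nm\,(1-p))}
#' where \eqn{I} is the regularized incomplete beta function. Nm, the
#' product of community size N and immigration rate m, is the model's
#' single dispersal parameter.
#'
#' @param p metacommunity relative abundance(s), strictly in (0, 1).
#' @param Nm dispersal parameter, > 0.
#' @param d detection limit (relative abundance), in (0, 1).
#' @return predicted occurrence frequency in [0, 1], vectorised over `p`.
#' @export
#' @examples
#' ncm_predict(c(0.001, 0.01, 0.1), Nm = 1000, d = 1e-4)
ncm_predict <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (Nm <= 0) stop("Nm must be positive")
  if (d <= 0 || d >= 1) stop("detection limit d must lie in (0, 1)")
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

## sum of squared errors of the neutral prediction at log(Nm)
ncm_sse <- function(log_nm, p, freq_obs, d) {
  pred <- ncm_predict(p, exp(log_nm), d)
  sum((freq_obs - pred)^2)
}

## bounded scalar least squares over log(Nm) with a 3-start split of the
## search interval; log scaling keeps the optimum away from the bounds
fit_nm_value <- function(p, freq_obs, d, nm_max) {
  lo <- log(1e-3)
  hi <- log(nm_max)
  cuts <- seq(lo, hi, length.out = 4)
  best <- NULL
  for (k in 1:3) {
    opt <- stats::optimize(ncm_sse, c(cuts[k], cuts[k + 1]),
                           p = p, freq_obs = freq_obs, d = d,
                           tol = .Machine$double.eps^0.5)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  exp(best$minimum)
}

#' Fit the Sloan neutral community model to an abundance table
#'
#' Estimates the dispersal parameter Nm by bounded nonlinear least squares
#' of predicted against observed occurrence frequencies over taxa:
#' for each taxon, p is its mean relative abundance across samples and the
#' observed frequency is the fraction of samples in which it is detected
#' (count > 0). Fit quality is the coefficient of determination
#' \eqn{R^2 = 1 - SS_{resid}/SS_{total}} on the observed frequencies
#' (can be negative when the neutral relationship is absent). Taxa never
#' detected are excluded. N defaults to the mean per-sample total count
#' and the detection limit d to 1/N; both are recorded in the fit.
#'
#' @param x abundance matrix (samples x taxa). Counts unless `N` is given
#'   explicitly; a table whose rows sum to (near) 1 without an `N`
#'   override is rejected, because N would be meaningless.
#' @param N community size; default mean per-sample total count.
#' @param d detection limit; default 1/N.
#' @return an object of class `ncm_fit` with components `m`, `Nm`, `N`,
#'   `d`, `r_squared`, `n_samples`, `n_taxa` and `per_taxon` (data.frame
#'   `p`, `freq_obs`, `freq_pred`). Methods: print, summary, coef,
#'   predict, fitted, residuals, plot.
#' @seealso [ncm_predict()], [bootstrap_ncm()], [classify_partitions()]
#' @export
fit_ncm <- function(x, N = NULL, d = NULL) {
  validate_abundance(x)
  if (all(x == 0)) stop("all-zero abundance table")
  depths <- rowSums(x)
  if (is.null(N)) {
    if (all(abs(depths - 1) < 1e-6))
      stop("table looks like relative abundances; supply counts or an ",
           "explicit N override")
    N <- mean(depths)
  }
  if (N <= 0) stop("N must be positive")
  if (is.null(d)) d <- 1 / N
  rel <- relative_abundance(x)
  p <- colMeans(rel)
  freq_obs <- colMeans(x > 0)
  keep <- freq_obs > 0 & p > 0 & p < 1
  p <- p[keep]; freq_obs <- freq_obs[keep]
  if (length(p) < 10)
    stop("need at least 10 taxa detected in at least one sample")
  nm <- fit_nm_value(p, freq_obs, d, nm_max = 10 * N)
  pred <- ncm_predict(p, nm, d)
  ss_res <- sum((freq_obs - pred)^2)
  ss_tot <- sum((freq_obs - mean(freq_obs))^2)
  structure(list(m = nm / N, Nm = nm, N = N, d = d,
                 r_squared = 1 - ss_res / ss_tot,
                 n_samples = nrow(x), n_taxa = length(p),
                 per_taxon = data.frame(p = p, freq_obs = freq_obs,
                                        freq_pred = pred,
                                        row.names = names(p)),
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.4g  (N = %.4g, m = %.4g, detection limit d = %.3g)\n",
              x$Nm, x$N, x$m, x$d))
  cat(sprintf("  R^2 = %.3f over %d taxa, %d samples\n",
              x$r_squared, x$n_taxa, x$n_samples))
  if (x$n_boot > 0)
    cat(sprintf("  bootstrap 95%% CI for Nm: [%.4g, %.4g]  (%d replicates)\n",
                x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' @export
summary.ncm_fit <- function(object, alpha = 0.05, ...) {
  cls <- classify_partitions(object, alpha = alpha)
  out <- list(fit = object, class_counts = table(cls$class), alpha = alpha)
  class(out) <- "summary.ncm_fit"
  out
}

#' @export
print.summary.ncm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  taxa vs the %.0f%% neutral envelope:\n", 100 * (1 - x$alpha)))
  for (cl in c("above", "within", "below"))
    cat(sprintf("    %-6s %d\n", cl,
                if (cl %in% names(x$class_counts)) x$class_counts[[cl]] else 0L))
  invisible(x)
}

#' @export
coef.ncm_fit <- function(object, ...) {
  c(Nm = object$Nm, m = object$m, N = object$N, d = object$d)
}

#' @export
#' @param newdata optional vector of metacommunity relative abundances; if
#'   omitted, the fitted taxa's p values are used.
#' @rdname fit_ncm
predict.ncm_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$per_taxon$p else newdata
  ncm_predict(p, object$Nm, object$d)
}

#' @export
fitted.ncm_fit <- function(object, ...) {
  stats::setNames(object$per_taxon$freq_pred, rownames(object$per_taxon))
}

#' @export
residuals.ncm_fit <- function(object, ...) {
  stats::setNames(object$per_taxon$freq_obs - object$per_taxon$freq_pred,
                  rownames(object$per_taxon))
}

#' @export
#' @param alpha envelope level for the plotted prediction band.
#' @rdname fit_ncm
plot.ncm_fit <- function(x, alpha = 0.05, ...) {
  pt <- x$per_taxon
  cls <- classify_partitions(x, alpha = alpha)
  ord <- order(pt$p)
  cols <- c(above = "#d95f02", within = "#7570b3", below = "#1b9e77")
  plot(log10(pt$p), pt$freq_obs, pch = 16, col = cols[cls$class],
       xlab = "log10 mean relative abundance",
       ylab = "occurrence frequency",
       main = sprintf("Neutral model fit: Nm = %.0f, R^2 = %.2f",
                      x$Nm, x$r_squared), ...)
  lines(log10(pt$p[ord]), pt$freq_pred[ord], lwd = 2)
  lines(log10(pt$p[ord]), cls$envelope_low[ord], lty = 2)
  lines(log10(pt$p[ord]), cls$envelope_high[ord], lty = 2)
  legend("bottomright", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Bootstrap confidence interval for Nm
#'
#' Resamples taxa (the fit's observation units) with replacement, refits
#' Nm in each replicate and returns the percentile 95% interval — the
#' standard 1,000-replicate bootstrap for Sloan-model dispersal estimates.
#'
#' @param fit an `ncm_fit`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return the fit, with `ci_low`, `ci_high`, `n_boot` filled in and the
#'   replicate estimates attached as `boot_nm`.
#' @export
bootstrap_ncm <- function(fit, n_boot = 1000, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ncm_fit"))
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  pt <- fit$per_taxon
  k <- nrow(pt)
  est <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(k, k, replace = TRUE)
    tryCatch(fit_nm_value(pt$p[idx], pt$freq_obs[idx], fit$d, 10 * fit$N),
             error = function(e) NA_real_)
  }, numeric(1))
  fail <- mean(is.na(est))
  if (fail > 0.2)
    stop(sprintf("%.0f%% of bootstrap refits failed to converge", 100 * fail))
  qs <- stats::quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  fit$ci_low <- qs[1]
  fit$ci_high <- qs[2]
  fit$n_boot <- as.integer(n_boot)
  fit$boot_nm <- est
  fit
}

## Wilson score interval for a binomial proportion
wilson_interval <- function(phat, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Classify taxa against the neutral prediction envelope
#'
#' Builds a Wilson binomial interval at level 1 - alpha around each
#' taxon's predicted frequency (with n = number of samples) and classes
#' the taxon `above`, `within` or `below` by where its observed frequency
#' falls — the standard companion output of a Sloan-model fit, separating
#' taxa that are over-represented (e.g. host-selected) or
#' under-represented (e.g. dispersal-limited) relative to neutrality.
#'
#' @param fit an `ncm_fit`.
#' @param alpha envelope significance level (default 0.05).
#' @return data.frame with columns `p`, `freq_obs`, `freq_pred`,
#'   `envelope_low`, `envelope_high`, `class`.
#' @export
classify_partitions <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "ncm_fit"))
  pt <- fit$per_taxon
  env <- wilson_interval(pt$freq_pred, fit$n_samples, alpha)
  cls <- ifelse(pt$freq_obs > env[, "high"], "above",
                ifelse(pt$freq_obs < env[, "low"], "below", "within"))
  data.frame(pt, envelope_low = env[, "low"], envelope_high = env[, "high"],
             class = cls, stringsAsFactors = FALSE)
}
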