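#' Fit the exponential decay of the correct-pilus distribution
#'
#' @description
#' For every terminating model, \eqn{\ln P(C,n)} becomes linear in \eqn{n}
#' with asymptotic slope \eqn{\ln \max(p_{EE}, p_{AA})}.  This fit is how
#' tail probabilities \eqn{P^\ast} at lengths far beyond what direct
#' sampling can reach are estimated from simulation: fit the decay on the
#' observable part of the distribution, then extrapolate in log space
#' ([extrapolate_p_star()]).
#'
#' Two kinds of input are accepted:
#'
#' * an [empirical_pmf()] table -- weighted least squares of
#'   \eqn{\ln \hat P(C,n)} over bins with `correct_count >= min_count` and
#'   `n >= n_lo`, with inverse-variance weights (the delta-method variance
#'   of a log proportion is \eqn{\approx 1/\mathrm{count}});
#' * a [pilus_pmf()] table (exact probabilities) -- ordinary least squares
#'   over `n_range`, by default `c(20, 60)`, a window past the
#'   pre-asymptotic composition regime where the decay is log-linear to
#'   high accuracy.
#'
#' @param x An `pilus_empirical_pmf` or `pilus_pmf` object.
#' @param min_count Minimum correct count for an empirical bin to qualify
#'   (default 10).
#' @param n_lo Smallest length admitted to an empirical fit (default 10,
#'   excluding the strongly curved onset region just above length 6).
#' @param n_range Length-2 window for exact-pmf fits; default `c(20, 60)`.
#' @return An object of class `pilus_decay_fit`: `slope` and `intercept`
#'   (natural-log scale, per subunit), `fit_range`, `n_points`,
#'   `residual_sd`, `vcov` (2x2 covariance of intercept and slope).
#' @examples
#' m <- transition_model(builtin_rate_table("in_vitro"))
#' fit_decay(pilus_pmf(m, 100))$slope   # ~ log(45.8 / 83.9)
#' @export
fit_decay <- function(x, min_count = 10, n_lo = 10, n_range = NULL) {
  if (inherits(x, "pilus_empirical_pmf")) {
    keep <- x$correct_count >= min_count & x$n >= n_lo
    if (!is.null(n_range))
      keep <- keep & x$n >= n_range[1] & x$n <= n_range[2]
    if (sum(keep) < 2L)
      stop("insufficient support for fit: fewer than 2 bins with count >= ",
           min_count, call. = FALSE)
    n <- x$n[keep]
    y <- log(x$p_cn[keep])
    w <- x$correct_count[keep]
  } else if (inherits(x, "pilus_pmf")) {
    if (is.null(n_range)) n_range <- c(20, 60)
    keep <- x$n >= n_range[1] & x$n <= n_range[2] & is.finite(x$log_p_cn)
    if (sum(keep) < 2L)
      stop("insufficient support for fit: fewer than 2 finite P(C,n) ",
           "values in the window", call. = FALSE)
    n <- x$n[keep]
    y <- x$log_p_cn[keep]
    w <- rep(1, length(n))
  } else {
    stop("x must be an empirical_pmf() or pilus_pmf() table", call. = FALSE)
  }
  fit <- stats::lm(y ~ n, weights = w)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 fit_range = range(n), n_points = length(n),
                 residual_sd = sqrt(max(0, mean(stats::residuals(fit)^2))),
                 # exactly log-linear inputs are legitimate; silence the
                 # "essentially perfect fit" note their zero variance triggers
                 vcov = suppressWarnings(stats::vcov(fit))),
            class = "pilus_decay_fit")
}

#' @export
print.pilus_decay_fit <- function(x, ...) {
  cat(sprintf(
    "exponential decay fit of ln P(C,n): slope %.5f / subunit,\n", x$slope))
  cat(sprintf("  intercept %.4f, window [%d, %d], %d points, resid sd %.3g\n",
              x$intercept, x$fit_range[1], x$fit_range[2], x$n_points,
              x$residual_sd))
  invisible(x)
}

#' Extrapolate a decay fit to a tail probability P*
#'
#' Given the fitted log-linear decay \eqn{\ln P(C,n) = a + b\,n} with
#' \eqn{b < 0}, the tail sum is the geometric series
#' \deqn{P^\ast = \sum_{n \ge n_{min}} e^{a + b n}
#'             = \frac{e^{a + b\,n_{min}}}{1 - e^{b}},}
#' evaluated and reported in log10.  A standard-error band is propagated
#' from the fit covariance; over extrapolations of hundreds of subunits the
#' slope term dominates, which is why far extrapolations are meaningful
#' only to order of magnitude.
#'
#' @param fit A [fit_decay()] result with negative slope.
#' @param n_min Minimum length (inclusive).
#' @return A `pilus_p_star` object with `method = "fit_extrapolation"` and
#'   `log10_se` from the fit covariance.
#' @examples
#' m <- transition_model(builtin_rate_table("in_vitro"))
#' extrapolate_p_star(fit_decay(pilus_pmf(m, 100)), 100)
#' @export
extrapolate_p_star <- function(fit, n_min) {
  stopifnot(inherits(fit, "pilus_decay_fit"))
  if (!is.finite(fit$slope) || fit$slope >= 0)
    stop("non-decaying fit cannot be extrapolated", call. = FALSE)
  b <- fit$slope
  ln_p <- fit$intercept + b * n_min - log1p(-exp(b))
  # gradient of ln P* wrt (a, b)
  g <- c(1, n_min + exp(b) / (1 - exp(b)))
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  .p_star_result(ln_p / log(10), n_min, "fit_extrapolation",
                 log10_se = se / log(10))
}

#' Write a decay-fit report as TSV
#'
#' One header block row with the fit parameters, followed by one row per
#' requested `n_min` with the extrapolated `log10_p_star` and `log10_se`.
#'
#' @param fit A [fit_decay()] result.
#' @param n_min Integer vector of extrapolation lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, n_min, path) {
  stopifnot(inherits(fit, "pilus_decay_fit"))
  ps <- lapply(n_min, function(nm) extrapolate_p_star(fit, nm))
  out <- data.frame(slope = fit$slope, intercept = fit$intercept,
                    n_lo = fit$fit_range[1], n_hi = fit$fit_range[2],
                    n_points = fit$n_points, residual_sd = fit$residual_sd,
                    n_min = as.integer(n_min),
                    log10_p_star = vapply(ps, `[[`, 0, "log10_p_star"),
                    log10_se = vapply(ps, `[[`, 0, "log10_se"))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
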