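#' Exact log-space length distribution P(n)
#'
#' \eqn{P(n)} is the probability that a finished pilus is exactly \eqn{n}
#' subunits long, counting every subunit including the terminal PapH --
#' equivalently, the probability of finding PapH at position \eqn{n}.  It is
#' computed by propagating the acceptor-state occupancy vector of the
#' embedded chain position by position, with per-step renormalization so
#' that probabilities far below double-precision range (down past
#' \eqn{10^{-300}} and beyond) remain exactly representable in log space.
#'
#' For models with stall states the distribution is defective:
#' \eqn{\sum_n P(n) < 1}, the missing mass being pili that stalled without
#' ever appending PapH.
#'
#' @param model A [transition_model()].
#' @param n_max Largest length to tabulate (>= 2).
#' @return Named numeric vector `log_p_n` over `n = 2..n_max`, natural-log
#'   probabilities.
#' @seealso [correct_pmf()], [pilus_pmf()]
#' @export
length_pmf <- function(model, n_max) {
  stopifnot(inherits(model, "pilus_transition_model"), n_max >= 2)
  n_max <- as.integer(n_max)
  acc <- .acceptors()
  Q <- .survival_matrix(model)
  pH <- model$p[, "H"]
  v <- stats::setNames(c(1, 0, 0, 0, 0), acc)   # position 1: PapG
  logscale <- 0
  out <- rep(-Inf, n_max - 1L)
  for (n in 2:n_max) {
    ph <- sum(v * pH)
    out[n - 1L] <- if (ph > 0) logscale + log(ph) else -Inf
    v <- as.vector(v %*% Q)
    s <- sum(v)
    if (s <= 0) break      # all mass absorbed or stalled
    logscale <- logscale + log(s)
    v <- v / s
  }
  stats::setNames(out, 2:n_max)
}

# log of c0 = p(G->F) p(F->E) p(E->K) p(K->A) p(A->H), the fixed part of
# every correct sequence, plus the two self-transition probabilities.
.correct_params <- function(model) {
  p <- model$p
  list(
    log_c0 = log(p["G", "F"]) + log(p["F", "E"]) + log(p["E", "K"]) +
             log(p["K", "A"]) + log(p["A", "H"]),
    p_EE = p["E", "E"], p_AA = p["A", "A"])
}

# log sum_{i+j=m, i,j>=1} p_EE^(i-1) p_AA^(j-1)
#   = log[(p_AA^(m-1) - p_EE^(m-1)) / (p_AA - p_EE)]   (distinct)
#   = log[(m-1) rho^(m-2)]                              (p_EE = p_AA = rho)
# Vectorized over m >= 2; handles zero probabilities through the same
# closed forms (0^0 = 1 for the m = 2 composition).
.log_composition_sum <- function(m, p_EE, p_AA) {
  if (abs(p_EE - p_AA) < 1e-14) {
    rho <- p_AA
    lr <- if (rho > 0) log(rho) else -Inf
    out <- log(m - 1) + (m - 2) * lr
    out[m == 2] <- 0                      # single composition i = j = 1
    return(out)
  }
  hi <- max(p_EE, p_AA); lo <- min(p_EE, p_AA)
  lhi <- log(hi)
  if (lo == 0) return((m - 2) * lhi)      # only the lo-exponent-0 term chain
  llo <- log(lo)
  # (hi^(m-1) - lo^(m-1)) / (hi - lo), all in logs
  (m - 1) * lhi + .log1mexp((m - 1) * (llo - lhi)) -
    (lhi + .log1mexp(llo - lhi))
}

#' Exact log-space correct-and-length distribution P(C, n)
#'
#' \eqn{P(C,n)} is the probability that a finished pilus is exactly \eqn{n}
#' subunits long *and* has the naturally occurring subunit order
#' \eqn{G\,F\,E^i\,K\,A^j\,H} with \eqn{i,j \ge 1}.  Summing the transition
#' probabilities over the \eqn{m-1} compositions \eqn{i+j=m} of the
#' variable-length segment (\eqn{m = n-4}) gives the closed form
#' \deqn{P(C,n) = c_0 \sum_{i+j=n-4} p_{EE}^{\,i-1} p_{AA}^{\,j-1}, \qquad
#'   c_0 = p_{GF}\,p_{FE}\,p_{EK}\,p_{KA}\,p_{AH},}
#' evaluated stably in log space (geometric-difference form, or
#' \eqn{(n-5)\rho^{n-6}} when \eqn{p_{EE}=p_{AA}=\rho}).  No correct pilus
#' is shorter than 6 subunits, so \eqn{P(C,n)=0} for \eqn{n<6}.
#'
#' @inheritParams length_pmf
#' @param n_max Largest length to tabulate (>= 6).
#' @return Named numeric vector `log_p_cn` over `n = 2..n_max`.
#' @export
correct_pmf <- function(model, n_max) {
  stopifnot(inherits(model, "pilus_transition_model"), n_max >= 6)
  n_max <- as.integer(n_max)
  cp <- .correct_params(model)
  n <- 2:n_max
  out <- rep(-Inf, length(n))
  idx <- n >= 6
  if (cp$log_c0 > -Inf)
    out[idx] <- cp$log_c0 + .log_composition_sum(n[idx] - 4, cp$p_EE, cp$p_AA)
  stats::setNames(out, n)
}

#' Tabulate P(n) and P(C, n) together
#'
#' @inheritParams length_pmf
#' @return A `data.frame` of class `pilus_pmf` with columns `n`, `log_p_n`,
#'   `log_p_cn` (natural logs).
#' @examples
#' m <- transition_model(builtin_rate_table("equal"))
#' head(pilus_pmf(m, 20))
#' @export
pilus_pmf <- function(model, n_max = 1000L) {
  stopifnot(n_max >= 6)
  structure(data.frame(n = 2:n_max,
                       log_p_n = unname(length_pmf(model, n_max)),
                       log_p_cn = unname(correct_pmf(model, n_max))),
            class = c("pilus_pmf", "data.frame"))
}

#' Write a distribution table as TSV
#'
#' Columns: `n`, `P_n`, `P_Cn`, `log10_P_n`, `log10_P_Cn`.  Probabilities
#' below double-precision range print as 0 in the linear columns; the
#' `log10` columns are always exact.
#'
#' @param pmf A [pilus_pmf()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pilus_pmf"))
  out <- data.frame(n = pmf$n,
                    P_n = exp(pmf$log_p_n),
                    P_Cn = exp(pmf$log_p_cn),
                    log10_P_n = pmf$log_p_n / log(10),
                    log10_P_Cn = pmf$log_p_cn / log(10))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.p_star_result <- function(log10_p_star, n_min, method, log10_se = NA_real_) {
  structure(list(log10_p_star = log10_p_star, n_min = as.integer(n_min),
                 method = method, log10_se = log10_se),
            class = "pilus_p_star")
}

#' @export
print.pilus_p_star <- function(x, ...) {
  cat(sprintf("P* (correct sequence, length >= %d): log10 = %.4f", x$n_min,
              x$log10_p_star))
  if (is.finite(x$log10_se)) cat(sprintf(" (se %.3f)", x$log10_se))
  cat(sprintf("  [%s]\n", x$method))
  invisible(x)
}

#' Closed-form tail probability P* of a long, correctly ordered pilus
#'
#' @description
#' \eqn{P^\ast = \sum_{n \ge n_{min}} P(C,n)}: the probability that a pilus
#' has the correct subunit order and is at least \eqn{n_{min}} subunits
#' long.  The geometric structure of [correct_pmf()] gives the exact tail
#' \deqn{P^\ast = \frac{c_0}{p_{AA}-p_{EE}}\left[
#'    \frac{p_{AA}^{M-1}}{1-p_{AA}} - \frac{p_{EE}^{M-1}}{1-p_{EE}}\right],
#'    \quad M = \max(2, n_{min}-4),}
#' (with the usual limit when \eqn{p_{EE}=p_{AA}}), evaluated in log space,
#' so values down to \eqn{10^{-700}} and below carry no truncation error
#' beyond floating precision of the logarithm.
#'
#' @param model A [transition_model()].
#' @param n_min Minimum length (>= 2); lengths are counted including the
#'   terminal PapH and the threshold is inclusive (`n >= n_min`).
#' @return A `pilus_p_star` object: `log10_p_star`, `n_min`,
#'   `method = "closed_form"`.
#' @examples
#' m <- transition_model(builtin_rate_table("hypothetical_R"))
#' p_star_closed_form(m, 100)    # ~0.17
#' @export
p_star_closed_form <- function(model, n_min) {
  stopifnot(inherits(model, "pilus_transition_model"), n_min >= 2)
  cp <- .correct_params(model)
  if (cp$p_AA >= 1 || cp$p_EE >= 1)
    stop("non-terminating chain: p[A][A] or p[E][E] is 1, PapH is never ",
         "reached", call. = FALSE)
  M <- max(2, as.integer(n_min) - 4L)
  if (cp$log_c0 == -Inf)
    return(.p_star_result(-Inf, n_min, "closed_form"))
  if (abs(cp$p_EE - cp$p_AA) < 1e-14) {
    rho <- cp$p_AA
    # sum_{m>=M} (m-1) rho^(m-2) = rho^(T-1) (T(1-rho)+rho) / (1-rho)^2,
    # T = M-1
    Tt <- M - 1
    lr <- if (rho > 0) log(rho) else -Inf
    ltail <- if (rho == 0) {
      if (M <= 2) 0 else -Inf
    } else {
      (Tt - 1) * lr + log(Tt * (1 - rho) + rho) - 2 * log1p(-rho)
    }
  } else {
    hi <- max(cp$p_EE, cp$p_AA); lo <- min(cp$p_EE, cp$p_AA)
    lhi <- log(hi)
    lx <- (M - 1) * lhi - log1p(-hi)
    if (lo == 0) {
      ltail <- lx - lhi                         # sum_{m>=M} hi^(m-2)
    } else {
      llo <- log(lo)
      ly <- (M - 1) * llo - log1p(-lo)
      ltail <- lx + .log1mexp(ly - lx) - (lhi + .log1mexp(llo - lhi))
    }
  }
  .p_star_result((cp$log_c0 + ltail) / log(10), n_min, "closed_form")
}
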