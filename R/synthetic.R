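#' Generate a synthetic rate table with cognate-fast structure
#'
#' @description
#' Builds a rate table in which every cognate acceptor<-donor pair --
#' G<-F, F<-E, E<-E, E<-K, K<-A, A<-A, the pairs adjacent in the natural
#' pilus order -- reacts at `k_fast` and every other permitted pair at
#' `k_fast / ratio`; the PapG donor column and PapH acceptor row stay zero.
#' Termination (A<-H) is deliberately slow: a fast terminator would cap
#' every pilus within a few subunits.  `ratio = 1000, k_fast = 1000`
#' reproduces the hypothetical reference scheme exactly; `ratio = 1,
#' k_fast = 1` degenerates to the equal-rates table.
#'
#' Optional multiplicative lognormal noise (mean-preserving, coefficient of
#' variation `noise_cv`) perturbs every permitted entry independently --
#' rates are positive and span orders of magnitude, so lognormal
#' perturbation respects validation by construction.
#'
#' @param ratio `k_fast / k_slow` (>= 1).
#' @param k_fast Fast rate, \eqn{10^{-3}\,h^{-1}} (> 0).
#' @param noise_cv Coefficient of variation of the lognormal noise
#'   (default 0 = deterministic).
#' @param seed Optional seed used when `noise_cv > 0`.
#' @param slow_EE If `TRUE`, the E<-E cell is slow instead of fast (the
#'   variant in which PapE self-association is not privileged).
#' @param name Label for the table.
#' @return A [rate_table()].
#' @examples
#' identical(unclass(make_rate_table(1000, 1000)),
#'           unclass(builtin_rate_table("hypothetical_R")))
#' @export
make_rate_table <- function(ratio, k_fast = 1000, noise_cv = 0, seed = NULL,
                            slow_EE = FALSE,
                            name = sprintf("synthetic_ratio_%g", ratio)) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio >= 1,
            is.numeric(k_fast), length(k_fast) == 1L, k_fast > 0,
            is.numeric(noise_cv), length(noise_cv) == 1L, noise_cv >= 0)
  subs <- pilus_subunits()
  k <- matrix(k_fast / ratio, 6, 6, dimnames = list(subs, subs))
  cg <- .cognate_pairs()
  if (slow_EE) cg <- cg[!(cg[, "acceptor"] == "E" & cg[, "donor"] == "E"), ,
                        drop = FALSE]
  k[cg] <- k_fast
  k[, "G"] <- 0
  k["H", ] <- 0
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    permitted <- k > 0
    noise <- stats::rlnorm(sum(permitted), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
    k[permitted] <- k[permitted] * noise
  }
  rate_table(k, name = name)
}

#' Write a simulated pilus ensemble to a TSV fixture
#'
#' Convenience wrapper around [simulate_ensemble()] +
#' [write_ensemble_tsv()] so downstream stages (empirical distributions,
#' decay fitting) can be exercised from a plain-text file without any
#' external data.  Deterministic per seed.
#'
#' @param table A [rate_table()].
#' @param n_pili,seed,length_cap Simulation controls.
#' @param path Output TSV path.
#' @param conc Concentration profile (default uniform).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' make_ensemble_fixture(builtin_rate_table("in_vitro"), 500, seed = 7,
#'                       path = f)
#' ens <- read_ensemble_tsv(f)
#' @export
make_ensemble_fixture <- function(table, n_pili, seed, path,
                                  length_cap = 1e5,
                                  conc = uniform_profile()) {
  model <- transition_model(table, conc)
  ens <- simulate_ensemble(model, n_pili, seed = seed,
                           length_cap = length_cap, keep_sequences = TRUE)
  write_ensemble_tsv(ens, path)
}
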