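.table1_model <- function(case) {
  switch(case,
    equal = transition_model(builtin_rate_table("equal")),
    in_vitro = transition_model(builtin_rate_table("in_vitro")),
    R = transition_model(builtin_rate_table("hypothetical_R")),
    C = transition_model(builtin_rate_table("in_vitro"),
                         scaled_profile(uniform_profile(), "A", 200)),
    stop("unknown case '", case, "'; valid cases: equal, in_vitro, R, C",
         call. = FALSE))
}

.p_star_by_method <- function(model, n_min, method, n_pili, seed,
                              length_cap, fit_n_max = 200L) {
  switch(method,
    closed_form = p_star_closed_form(model, n_min),
    monte_carlo = p_star_monte_carlo(model, n_min, n_pili = n_pili,
                                     seed = seed, length_cap = length_cap),
    fit_extrapolation =
      extrapolate_p_star(fit_decay(pilus_pmf(model, fit_n_max)), n_min),
    stop("unknown method '", method, "'", call. = FALSE))
}

#' Reproduce the P* summary over the four reference scenarios
#'
#' @description
#' Evaluates \eqn{P^\ast} for each scenario and minimum length:
#'
#' * `equal` — equal rates, equal concentrations (fully random growth);
#' * `in_vitro` — measured in vitro DSE rates, equal concentrations;
#' * `R` — hypothetical cognate-fast scheme ([builtin_rate_table()]
#'   `"hypothetical_R"`), equal concentrations;
#' * `C` — in vitro rates with the PapA concentration 200-fold higher than
#'   every other subunit.
#'
#' The default method is the exact closed form; `"monte_carlo"` and
#' `"fit_extrapolation"` mirror the simulate-then-fit route and agree with
#' it within sampling / extrapolation error where they overlap.
#'
#' @param n_min Integer vector of minimum lengths (default
#'   `c(100, 1000)`).
#' @param cases Subset of `c("equal", "in_vitro", "R", "C")`.
#' @param method `"closed_form"`, `"monte_carlo"`, or
#'   `"fit_extrapolation"`.
#' @param n_pili,seed,length_cap Monte Carlo controls.
#' @return A `data.frame` with columns `case`, `n_min`, `log10_p_star`,
#'   `p_star`, `method`.
#' @examples
#' run_table1(cases = "R")
#' @export
run_table1 <- function(n_min = c(100L, 1000L),
                       cases = c("equal", "in_vitro", "R", "C"),
                       method = c("closed_form", "monte_carlo",
                                  "fit_extrapolation"),
                       n_pili = 1e5, seed = 1, length_cap = 1e5) {
  method <- match.arg(method)
  stopifnot(all(n_min >= 2))
  grid <- expand.grid(case = cases, n_min = as.integer(n_min),
                      stringsAsFactors = FALSE)
  res <- mapply(function(case, nm) {
    ps <- .p_star_by_method(.table1_model(case), nm, method, n_pili, seed,
                            length_cap)
    ps$log10_p_star
  }, grid$case, grid$n_min)
  data.frame(case = grid$case, n_min = grid$n_min, log10_p_star = res,
             p_star = 10^res, method = method, row.names = NULL)
}

#' Sweep the relative concentration of one subunit
#'
#' Re-evaluates \eqn{P^\ast} while multiplying the concentration weight of
#' one subunit by each factor in turn -- e.g. the PapA fold-change sweep
#' from 2 to 200, where factor 1 reproduces the plain in vitro case and
#' factor 200 reproduces case C.
#'
#' @param factors Positive fold-changes to apply.
#' @param subunit Subunit whose weight is scaled (default `"A"`).
#' @param table Rate table (default the in vitro rates).
#' @param base Base concentration profile (default uniform).
#' @param n_min Minimum length for \eqn{P^\ast}.
#' @param method,n_pili,seed,length_cap As in [run_table1()].
#' @return `data.frame` with columns `factor`, `log10_p_star`, `p_star`.
#' @examples
#' sweep_concentration(c(2, 20, 200), n_min = 100)
#' @export
sweep_concentration <- function(factors, subunit = "A",
                                table = builtin_rate_table("in_vitro"),
                                base = uniform_profile(), n_min = 100L,
                                method = "closed_form", n_pili = 1e5,
                                seed = 1, length_cap = 1e5) {
  stopifnot(all(factors > 0))
  res <- vapply(factors, function(f) {
    m <- transition_model(table, scaled_profile(base, subunit, f))
    .p_star_by_method(m, n_min, method, n_pili, seed,
                      length_cap)$log10_p_star
  }, 0)
  data.frame(factor = factors, log10_p_star = res, p_star = 10^res)
}

#' P* for the combined concentration variant
#'
#' The "modestly skewed" concentration condition: PapA at least
#' `a_factor` (default 6) times more abundant than PapE/PapF/PapK and PapH
#' `1/h_factor` (default 10) times less abundant, with in vitro rates.
#'
#' @param a_factor Fold-increase of the PapA weight.
#' @param h_factor Fold-change of the PapH weight (default 0.1).
#' @param table Rate table.
#' @param n_min Minimum length.
#' @return A `pilus_p_star` (closed form).
#' @export
combined_concentration_case <- function(a_factor = 6, h_factor = 0.1,
                                        table = builtin_rate_table("in_vitro"),
                                        n_min = 100L) {
  prof <- scaled_profile(scaled_profile(uniform_profile(), "A", a_factor),
                         "H", h_factor)
  p_star_closed_form(transition_model(table, prof), n_min)
}

#' Sweep the cognate / non-cognate rate ratio
#'
#' Builds the hypothetical cognate-fast rate pattern with
#' \eqn{k_{slow} = k_{fast}/\mathrm{ratio}} for each ratio and evaluates
#' \eqn{P^\ast}.  Ratio 1000 reproduces scenario R; ratio 1 degenerates to
#' the equal-rates table.  `slow_EE = TRUE` evaluates the variant in which
#' the PapE--PapE self-association is slow as well.
#'
#' @param ratios Ratios `k_fast / k_slow` (>= 1).
#' @param n_min Minimum length.
#' @param k_fast Fast rate in \eqn{10^{-3} h^{-1}}.
#' @param slow_EE Make the E<-E cell slow.
#' @param method,n_pili,seed,length_cap As in [run_table1()].
#' @return `data.frame` with columns `ratio`, `log10_p_star`, `p_star`.
#' @examples
#' sweep_rate_ratio(c(100, 1000), n_min = 100)
#' @export
sweep_rate_ratio <- function(ratios, n_min = 100L, k_fast = 1000,
                             slow_EE = FALSE, method = "closed_form",
                             n_pili = 1e5, seed = 1, length_cap = 1e5) {
  stopifnot(all(ratios >= 1))
  res <- vapply(ratios, function(r) {
    m <- transition_model(make_rate_table(ratio = r, k_fast = k_fast,
                                          slow_EE = slow_EE))
    .p_star_by_method(m, n_min, method, n_pili, seed,
                      length_cap)$log10_p_star
  }, 0)
  data.frame(ratio = ratios, log10_p_star = res, p_star = 10^res)
}
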