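fake_pmf <- function(n, log_p_cn, log_p_n = log_p_cn) {
  structure(data.frame(n = n, log_p_n = log_p_n, log_p_cn = log_p_cn),
            class = c("pilus_pmf", "data.frame"))
}

test_that("an exactly geometric input is fitted exactly", {
  pm <- fake_pmf(2:80, (2:80) * log(0.5))
  fit <- fit_decay(pm, n_range = c(10, 60))
  expect_equal(fit$slope, log(0.5), tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_lt(fit$residual_sd, 1e-10)

  # geometric tail: sum_{n>=10} 0.5^n = 2^-9
  ps <- extrapolate_p_star(fit, 10)
  expect_equal(10^ps$log10_p_star, 2^-9, tolerance = 1e-9)
  expect_identical(ps$method, "fit_extrapolation")
})

test_that("the in vitro decay slope is ln(k_AA / sum k_A) to within 1%", {
  m <- model_in_vitro()
  fit <- fit_decay(pilus_pmf(m, 100))     # default asymptotic window 20-60
  target <- log(45.8 / 83.9)
  expect_lt(abs(fit$slope - target) / abs(target), 0.01)
  expect_lt(fit$slope, 0)

  # extrapolation of the analytic fit reproduces the closed form
  ps <- extrapolate_p_star(fit, 100)
  expect_equal(ps$log10_p_star, p_star_closed_form(m, 100)$log10_p_star,
               tolerance = 0.01)
})

test_that("extrapolation is monotone in n_min and consistent with summation", {
  fit <- fit_decay(pilus_pmf(model_in_vitro(), 100))
  v <- vapply(c(30, 100, 300, 1000),
              function(nm) extrapolate_p_star(fit, nm)$log10_p_star, 0)
  expect_true(all(diff(v) < 0))
  # inside the fitted range, the tail equals direct summation of the line
  direct <- sum(exp(fit$intercept + fit$slope * (30:5000)))
  expect_equal(10^extrapolate_p_star(fit, 30)$log10_p_star, direct,
               tolerance = 1e-8)
})

test_that("slope recovery from simulated ensembles is unbiased", {
  # a table whose E self-rate is zero makes P(C,n) exactly geometric from
  # n = 6 on, so the empirical fit has no curvature bias to hide
  k <- unclass(builtin_rate_table("in_vitro"))[, ]
  k[3, 3] <- 0
  m <- transition_model(rate_table(k, name = "in_vitro_noEE"))
  truth <- log(m$p["A", "A"])
  slopes <- ses <- numeric(8)
  for (r in seq_along(slopes)) {
    e <- simulate_ensemble(m, 3e4, seed = 100 + r)
    fit <- fit_decay(empirical_pmf(e))
    slopes[r] <- fit$slope
    ses[r] <- sqrt(fit$vcov[2, 2])
  }
  expect_true(all(abs(slopes - truth) < 4 * ses))
  expect_lt(abs(mean(slopes) - truth), 3 * stats::sd(slopes) / sqrt(8))
})

test_that("degenerate fits are rejected with clear errors", {
  e <- simulate_ensemble(model_in_vitro(), 50, seed = 1)
  expect_error(fit_decay(empirical_pmf(e), min_count = 100),
               "insufficient support")
  rising <- fake_pmf(10:40, (10:40) * 0.1)
  fit <- fit_decay(rising, n_range = c(10, 40))
  expect_error(extrapolate_p_star(fit, 100), "non-decaying")
})

test_that("fit reports serialize as TSV", {
  fit <- fit_decay(pilus_pmf(model_in_vitro(), 100))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fit_tsv(fit, c(100, 1000), f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 2L)
  expect_equal(back$slope[1], fit$slope, tolerance = 1e-9)
  expect_equal(back$log10_p_star[1],
               extrapolate_p_star(fit, 100)$log10_p_star, tolerance = 1e-6)
})
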