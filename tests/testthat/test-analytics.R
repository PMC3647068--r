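test_that("equal-rates length distribution is the geometric closed form", {
  m <- model_equal()
  lp <- length_pmf(m, 60)
  n <- 2:60
  expect_equal(unname(lp), (n - 2) * log(4 / 5) + log(1 / 5),
               tolerance = 1e-12)
})

test_that("analytic P(n) and P(C,n) match brute-force path enumeration", {
  for (m in list(model_equal(), model_in_vitro(), model_R())) {
    ref <- enum_pmf(m, 9)
    lp <- length_pmf(m, 9)
    lc <- correct_pmf(m, 9)
    expect_equal(unname(lp), unname(log(ref$p_n)), tolerance = 1e-12)
    ok <- ref$p_cn > 0
    expect_equal(unname(lc[ok]), unname(log(ref$p_cn[ok])),
                 tolerance = 1e-12)
    expect_true(all(lc[!ok] == -Inf))
  }
})

test_that("length probabilities sum to one and dominate P(C,n)", {
  m_iv <- model_in_vitro()
  expect_equal(sum(exp(length_pmf(m_iv, 500))), 1, tolerance = 1e-10)
  for (m in list(model_equal(), model_in_vitro(), model_R())) {
    pm <- pilus_pmf(m, 200)
    expect_true(all(pm$log_p_cn <= pm$log_p_n + 1e-12))
    expect_true(sum(exp(pm$log_p_n)) <= 1 + 1e-12)
  }
})

test_that("no correct pilus is shorter than six subunits", {
  for (m in list(model_equal(), model_R())) {
    lc <- correct_pmf(m, 10)
    expect_true(all(lc[as.character(2:5)] == -Inf))
  }
  expect_equal(exp(correct_pmf(model_equal(), 8)[["6"]]), (1 / 5)^5)
  expect_equal(exp(correct_pmf(model_equal(), 8)[["8"]]), 3 * (1 / 5)^7)
})

test_that("closed-form P* equals direct summation of P(C,n)", {
  for (m in list(model_equal(), model_in_vitro(), model_R())) {
    lc <- correct_pmf(m, 20000)
    for (nm in c(6L, 20L, 100L)) {
      direct <- sum(exp(lc[as.numeric(names(lc)) >= nm]))
      expect_equal(10^p_star_closed_form(m, nm)$log10_p_star, direct,
                   tolerance = 1e-9)
    }
  }
  expect_equal(10^p_star_closed_form(model_equal(), 6)$log10_p_star, 5e-4,
               tolerance = 1e-12)
})

test_that("P* is nonincreasing in the minimum length", {
  for (m in list(model_equal(), model_in_vitro(), model_R())) {
    v <- vapply(c(2, 6, 10, 50, 100, 500, 1000),
                function(nm) p_star_closed_form(m, nm)$log10_p_star, 0)
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("the asymptotic decay slope is log max(p_EE, p_AA)", {
  for (m in list(model_equal(), model_in_vitro(), model_R())) {
    lc <- correct_pmf(m, 201)
    slope <- lc[["201"]] - lc[["200"]]
    expect_equal(slope, log(max(m$p["E", "E"], m$p["A", "A"])),
                 tolerance = 0.01)
  }
})

test_that("a chain that can never reach PapH is rejected", {
  k <- matrix(0, 6, 6)
  k[1, 2] <- 1; k[2, 3] <- 1; k[3, 4] <- 1; k[4, 5] <- 1
  k[5, 5] <- 1          # PapA only ever accepts PapA: no terminator
  m <- suppressWarnings(transition_model(rate_table(k)))
  expect_error(p_star_closed_form(m, 10), "non-terminating")
})

test_that("distribution TSV export carries exact log10 columns", {
  m <- model_R()
  pm <- pilus_pmf(m, 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pmf_tsv(pm, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(back), c("n", "P_n", "P_Cn", "log10_P_n", "log10_P_Cn"))
  expect_equal(back$log10_P_Cn[back$n == 50],
               correct_pmf(m, 50)[["50"]] / log(10), tolerance = 1e-6)
})
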