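test_that("sequence correctness classifier implements G F E+ K A+ H", {
  expect_true(classify_correct("GFEKAH"))
  expect_true(classify_correct("GFEEEKAAAAH"))
  expect_true(classify_correct(c("G", "F", "E", "K", "A", "A", "H")))
  expect_false(classify_correct("GFKAH"))       # no PapE
  expect_false(classify_correct("GFEKH"))       # no PapA
  expect_false(classify_correct("GFEKAHH"))     # anything after H
  expect_false(classify_correct("FGEKAH"))      # wrong start
  expect_false(classify_correct("GFEKAHA"))
  expect_error(classify_correct("GFXKAH"), "alphabet")
  expect_error(classify_correct(character(0)), "empty")
})

test_that("single-pilus growth respects structural invariants", {
  m <- model_in_vitro()
  set.seed(101)
  for (i in 1:200) {
    rec <- grow_pilus(m, length_cap = 50)
    expect_identical(rec$sequence[1], "G")
    expect_identical(rec$length, length(rec$sequence))
    expect_identical(length(rec$waiting_times), rec$length - 1L)
    expect_gte(rec$assembly_time, 0)
    if (rec$terminated == "absorbed_H") {
      expect_identical(sum(rec$sequence == "H"), 1L)
      expect_identical(rec$sequence[rec$length], "H")
    } else {
      expect_identical(rec$terminated, "truncated_at_cap")
      expect_identical(rec$length, 50L)
      expect_false("H" %in% rec$sequence)
    }
    if (rec$correct) expect_true(classify_correct(rec$sequence))
  }
})

test_that("a chain with forced cognate transitions grows G, F, E, ...", {
  # all non-cognate rates zero: the embedded chain is deterministic until
  # the E self-loop / branch
  k <- matrix(0, 6, 6)
  k[1, 2] <- 7; k[2, 3] <- 7; k[3, 4] <- 7; k[4, 5] <- 7; k[5, 6] <- 7
  m <- transition_model(rate_table(k))
  set.seed(1)
  rec <- grow_pilus(m)
  expect_identical(rec$sequence, c("G", "F", "E", "K", "A", "H"))
  expect_identical(rec$terminated, "absorbed_H")
})

test_that("ensembles are bit-identical for identical seeds", {
  m <- model_R()
  e1 <- simulate_ensemble(m, 2000, seed = 77)
  e2 <- simulate_ensemble(m, 2000, seed = 77)
  expect_identical(e1$length, e2$length)
  expect_identical(e1$assembly_time, e2$assembly_time)
  expect_identical(e1$correct, e2$correct)
  e3 <- simulate_ensemble(m, 2000, seed = 78)
  expect_false(identical(e1$length, e3$length))
})

test_that("empty ensembles are empty summaries, not errors", {
  e <- simulate_ensemble(model_equal(), 0, seed = 1)
  expect_identical(e$n_pili, 0L)
  expect_identical(length(e$length), 0L)
})

test_that("the length cap truncates and truncation vanishes as it grows", {
  m <- model_equal()
  e3 <- simulate_ensemble(m, 2000, seed = 5, length_cap = 3)
  expect_true(all(e3$length <= 3))
  expect_false(any(e3$correct))   # no correct pilus fits in 3 subunits
  frac3 <- mean(e3$terminated == "truncated_at_cap")
  e30 <- simulate_ensemble(m, 2000, seed = 5, length_cap = 30)
  frac30 <- mean(e30$terminated == "truncated_at_cap")
  expect_gt(frac3, frac30)
  expect_lt(frac30, 0.005)
})

test_that("ensemble frequencies agree with the analytic distribution", {
  m <- model_equal()
  n_pili <- 5e4
  e <- simulate_ensemble(m, n_pili, seed = 20)
  p2 <- 1 / 5
  se <- sqrt(p2 * (1 - p2) / n_pili)
  expect_lt(abs(mean(e$length == 2) - p2), 4 * se)

  # every bin with analytic expectation >= 5, both P(n) and P(C,n)
  ep <- empirical_pmf(e)
  pm <- pilus_pmf(m, max(e$length))
  for (col in c("p_n", "p_cn")) {
    p_true <- exp(if (col == "p_n") pm$log_p_n else pm$log_p_cn)
    keep <- p_true * n_pili >= 5
    obs <- ep[[col]][match(pm$n[keep], ep$n)]
    se_bin <- sqrt(p_true[keep] * (1 - p_true[keep]) / n_pili)
    expect_lt(max(abs(obs - p_true[keep]) / se_bin),
              max_z_threshold(sum(keep)))
  }
})

test_that("simulated P* for the cognate-fast scheme matches closed form", {
  m <- model_R()
  n_pili <- 2e4
  e <- simulate_ensemble(m, n_pili, seed = 31)
  p_true <- 10^p_star_closed_form(m, 100)$log10_p_star
  se <- sqrt(p_true * (1 - p_true) / n_pili)
  expect_lt(abs(mean(e$correct & e$length >= 100) - p_true), 4 * se)

  ps <- p_star_monte_carlo(m, 100, n_pili = n_pili, seed = 31)
  expect_equal(10^ps$log10_p_star, mean(e$correct & e$length >= 100),
               tolerance = 1e-12)
})

test_that("simulated waiting times in the PapA acceptor state average 11.92 h", {
  m <- model_in_vitro()
  set.seed(55)
  waits <- numeric(0)
  for (i in 1:3000) {
    rec <- grow_pilus(m, length_cap = 200)
    in_A <- rec$sequence[seq_len(rec$length - 1L)] == "A"
    waits <- c(waits, rec$waiting_times[in_A])
  }
  expect_gt(length(waits), 500)
  mu <- 1 / 0.0839
  se <- stats::sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - mu), 3 * se)
})

test_that("empirical distributions carry Wilson intervals", {
  m <- model_equal()
  e <- simulate_ensemble(m, 1000, seed = 4)
  ep <- empirical_pmf(e)
  for (i in c(1, 5, 10)) {
    ref <- wilson_oracle(ep$count[i], 1000)
    expect_equal(ep$p_n_lower[i], ref[1], tolerance = 1e-12)
    expect_equal(ep$p_n_upper[i], ref[2], tolerance = 1e-12)
  }
  # frozen reference values for 200/1000 and 0/1000
  expect_equal(wilson_oracle(200, 1000), c(0.17638, 0.22592),
               tolerance = 1e-4)
  zero <- ep[ep$correct_count == 0, ][1, ]
  expect_identical(zero$p_cn, 0)
  expect_equal(zero$p_cn_upper, wilson_oracle(0, 1000)[2], tolerance = 1e-12)
  expect_equal(wilson_oracle(0, 1000)[2], 0.003827, tolerance = 1e-3)
  expect_equal(wilson_oracle(1000, 1000)[2], 1)
})

test_that("ensemble TSV and FASTA exports round-trip", {
  m <- model_in_vitro()
  e <- simulate_ensemble(m, 300, seed = 8, keep_sequences = TRUE)
  expect_true(all(substr(e$sequence, 1, 1) == "G"))
  expect_identical(nchar(e$sequence), e$length)
  expect_identical(unname(vapply(e$sequence, classify_correct, TRUE)),
                   e$correct)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble_tsv(e, f)
  back <- read_ensemble_tsv(f)
  expect_identical(back$length, e$length)
  expect_identical(back$correct, e$correct)
  expect_identical(back$sequence, e$sequence)
  expect_equal(back$assembly_time, e$assembly_time, tolerance = 1e-6)

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_ensemble_fasta(e, fa)
  lines <- readLines(fa)
  expect_identical(length(lines), 600L)
  expect_true(grepl("^>pilus_1 correct=[01] time_h=", lines[1]))
  expect_identical(lines[2], e$sequence[1])

  e_bare <- simulate_ensemble(m, 10, seed = 8)
  expect_error(write_ensemble_tsv(e_bare, f), "keep_sequences")
})

test_that("mean time to reach a length threshold is recorded", {
  m <- model_equal()
  e <- simulate_ensemble(m, 5000, seed = 13, time_thresholds = c(4, 6))
  expect_named(e$mean_time_reaching, c("4", "6"))
  # waiting rate is 5e-3/h in every state: reaching n subunits takes
  # (n-1)/5e-3 hours on average, independent of the path taken
  expect_equal(unname(e$mean_time_reaching[["4"]]), 3 / 5e-3,
               tolerance = 0.05)
  expect_gt(e$mean_time_reaching[["6"]], e$mean_time_reaching[["4"]])
})
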