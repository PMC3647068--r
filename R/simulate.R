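#' Classify a subunit sequence as correctly ordered
#'
#' A pilus sequence is "correct" when it reads
#' \eqn{G\,F\,E^i\,K\,A^j\,H} with \eqn{i, j \ge 1}: the adhesin tip
#' (PapG), the PapF adaptor, at least one flexible PapE, the PapK adaptor,
#' at least one rod subunit PapA, and the PapH terminator -- nothing
#' before, between, or after.
#'
#' @param sequence Either a character vector of one-letter subunit symbols
#'   or a single collapsed string such as `"GFEEKAAH"`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' classify_correct("GFEKAH")        # TRUE, minimal correct pilus
#' classify_correct(c("G","F","K","A","H"))   # FALSE, no PapE
#' @export
classify_correct <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) == 0L)
    stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(sequence), pilus_subunits())
  if (length(bad) > 0L)
    stop("symbol(s) outside the subunit alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  grepl("^GFE+KA+H$", paste(sequence, collapse = ""))
}

# Correctness tracked incrementally as a tiny DFA over appended donors.
# States: 1 "G" seen, 2 "GF", 3 in E run, 4 K seen, 5 in A run, 0 dead.
# Absorption by H from state 5 completes a correct pilus.
.dfa_step <- function(dfa, donor_idx) {
  # donor_idx: 1..6 over G,F,E,K,A,H
  new <- integer(length(dfa))
  new[dfa == 1L & donor_idx == 2L] <- 2L
  new[dfa == 2L & donor_idx == 3L] <- 3L
  new[dfa == 3L & donor_idx == 3L] <- 3L
  new[dfa == 3L & donor_idx == 4L] <- 4L
  new[dfa == 4L & donor_idx == 5L] <- 5L
  new[dfa == 5L & donor_idx == 5L] <- 5L
  new
}

#' Simulate the growth of a single pilus
#'
#' Kinetic Monte Carlo in the embedded-chain formulation: starting from
#' PapG, each step draws an exponential waiting time with the acceptor
#' state's total exit rate and, independently, the next donor with the
#' embedded-chain probabilities.  Growth stops when PapH attaches
#' (absorbed), when a stall state is reached, or at `length_cap`
#' (truncated).  Uses the current R random number stream.
#'
#' @param model A [transition_model()].
#' @param length_cap Maximum number of subunits (>= 2); default `1e5`.
#' @return A list of class `pilus_record`: `sequence` (character vector
#'   starting with `"G"`), `length`, `correct`, `assembly_time` (hours),
#'   `waiting_times` (one per elongation step), `terminated` (one of
#'   `"absorbed_H"`, `"stalled"`, `"truncated_at_cap"`).
#' @examples
#' m <- transition_model(builtin_rate_table("hypothetical_R"))
#' set.seed(1)
#' grow_pilus(m, length_cap = 50)
#' @export
grow_pilus <- function(model, length_cap = 1e5) {
  stopifnot(inherits(model, "pilus_transition_model"), length_cap >= 2)
  cap <- as.integer(length_cap)
  subs <- pilus_subunits()
  seq_out <- character(cap)
  waits <- numeric(cap - 1L)
  seq_out[1L] <- "G"
  state <- 1L
  len <- 1L
  terminated <- "truncated_at_cap"
  while (len < cap) {
    if (model$stalled[state]) { terminated <- "stalled"; break }
    waits[len] <- stats::rexp(1L, rate = model$exit_rate[state])
    donor <- sample.int(6L, 1L, prob = model$p[state, ])
    len <- len + 1L
    seq_out[len] <- subs[donor]
    if (donor == 6L) { terminated <- "absorbed_H"; break }
    state <- donor
  }
  seq_out <- seq_out[1:len]
  waits <- waits[seq_len(len - 1L)]
  structure(list(
    sequence = seq_out,
    length = len,
    correct = terminated == "absorbed_H" && classify_correct(seq_out),
    assembly_time = sum(waits),
    waiting_times = waits,
    terminated = terminated
  ), class = "pilus_record")
}

#' @export
print.pilus_record <- function(x, ...) {
  cat(sprintf("pilus: %d subunits, %s, correct=%s, %.3g h\n", x$length,
              x$terminated, x$correct, x$assembly_time))
  s <- paste(x$sequence, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' Simulate an ensemble of pili
#'
#' Vectorized kinetic Monte Carlo over `n_pili` independent pili from one
#' seeded random stream (all pili advance one position per sweep, grouped
#' by acceptor state, in a fixed order), so identical
#' `(seed, model, n_pili, length_cap)` give bit-identical results.
#' Correctness is tracked incrementally; full sequences are stored only on
#' request to keep million-pilus ensembles cheap.
#'
#' @param model A [transition_model()].
#' @param n_pili Number of pili (>= 0; 0 gives an empty summary).
#' @param seed Integer seed.
#' @param length_cap Maximum subunits per pilus; truncated pili are counted
#'   as incorrect and reported separately.
#' @param keep_sequences Store each pilus sequence (needed for
#'   [write_ensemble_tsv()]).
#' @param time_thresholds Integer lengths L at which to record the mean
#'   elapsed assembly time among pili reaching >= L subunits.
#' @return An object of class `pilus_ensemble`: vectors `length`,
#'   `correct`, `assembly_time`, `terminated` (one entry per pilus),
#'   `count_by_length` / `correct_count_by_length` tables,
#'   `mean_time_reaching`, `n_pili`, `seed`, `length_cap`, `model_name`,
#'   and `sequence` when requested.
#' @examples
#' m <- transition_model(builtin_rate_table("equal"))
#' e <- simulate_ensemble(m, 1000, seed = 42)
#' e$count_by_length[1:5]
#' @export
simulate_ensemble <- function(model, n_pili, seed, length_cap = 1e5,
                              keep_sequences = FALSE,
                              time_thresholds = integer(0)) {
  stopifnot(inherits(model, "pilus_transition_model"), n_pili >= 0)
  n <- as.integer(n_pili)
  cap <- as.integer(length_cap)
  stopifnot(cap >= 2L)
  thr <- sort(unique(as.integer(time_thresholds)))
  subs <- pilus_subunits()

  empty <- function() {
    structure(list(length = integer(0), correct = logical(0),
                   assembly_time = numeric(0), terminated = character(0),
                   count_by_length = table(integer(0)),
                   correct_count_by_length = table(integer(0)),
                   mean_time_reaching =
                     stats::setNames(rep(NaN, length(thr)), thr),
                   n_pili = 0L, seed = as.integer(seed), length_cap = cap,
                   model_name = model$table_name),
              class = "pilus_ensemble")
  }
  if (n == 0L) return(empty())

  set.seed(as.integer(seed))
  state <- rep(1L, n)              # acceptor index (1..5), start at PapG
  dfa <- rep(1L, n)
  len <- rep(1L, n)
  tim <- numeric(n)
  correct <- logical(n)
  terminated <- character(n)
  active <- rep(TRUE, n)
  # sequences are reconstructed at the end from a chronological event log
  # (per pilus the log entries are already in position order)
  log_id <- if (keep_sequences) vector("list", 64L) else NULL
  log_sym <- if (keep_sequences) vector("list", 64L) else NULL
  n_log <- 0L
  time_at <- if (length(thr) > 0L)
    matrix(NA_real_, n, length(thr), dimnames = list(NULL, thr)) else NULL

  # sweep over positions; only active pili are touched, so total work is
  # proportional to the number of subunit events, not n_pili * max length
  act_idx <- seq_len(n)
  while (length(act_idx) > 0L) {
    st <- state[act_idx]
    for (s in 1:5) {
      idx <- act_idx[st == s]
      if (length(idx) == 0L) next
      if (model$stalled[s]) {
        terminated[idx] <- "stalled"
        active[idx] <- FALSE
        next
      }
      tim[idx] <- tim[idx] + stats::rexp(length(idx),
                                         rate = model$exit_rate[s])
      donor <- sample.int(6L, length(idx), replace = TRUE,
                          prob = model$p[s, ])
      len[idx] <- len[idx] + 1L
      if (keep_sequences) {
        n_log <- n_log + 1L
        if (n_log > length(log_id)) {
          length(log_id) <- 2L * length(log_id)
          length(log_sym) <- 2L * length(log_sym)
        }
        log_id[[n_log]] <- idx
        log_sym[[n_log]] <- donor
      }
      if (!is.null(time_at)) {
        for (j in seq_along(thr)) {
          hit <- idx[len[idx] == thr[j]]
          if (length(hit) > 0L) time_at[hit, j] <- tim[hit]
        }
      }
      absorbed <- donor == 6L
      if (any(absorbed)) {
        ai <- idx[absorbed]
        terminated[ai] <- "absorbed_H"
        correct[ai] <- dfa[ai] == 5L
        active[ai] <- FALSE
      }
      cont <- !absorbed
      if (any(cont)) {
        ci <- idx[cont]
        dfa[ci] <- .dfa_step(dfa[ci], donor[cont])
        state[ci] <- donor[cont]
      }
    }
    capped <- active[act_idx] & len[act_idx] >= cap
    if (any(capped)) {
      ci <- act_idx[capped]
      terminated[ci] <- "truncated_at_cap"
      active[ci] <- FALSE
    }
    act_idx <- act_idx[active[act_idx]]
  }

  cbl <- table(len)
  ccl <- table(len[correct])
  mtr <- if (length(thr) > 0L)
    stats::setNames(colMeans(time_at, na.rm = TRUE), thr)
  else stats::setNames(numeric(0), character(0))

  out <- structure(list(length = len, correct = correct, assembly_time = tim,
                        terminated = terminated, count_by_length = cbl,
                        correct_count_by_length = ccl,
                        mean_time_reaching = mtr, n_pili = n,
                        seed = as.integer(seed), length_cap = cap,
                        model_name = model$table_name),
                   class = "pilus_ensemble")
  if (keep_sequences) {
    ids <- unlist(log_id[seq_len(n_log)], use.names = FALSE)
    syms <- subs[unlist(log_sym[seq_len(n_log)], use.names = FALSE)]
    by_pilus <- split(syms, factor(ids, levels = seq_len(n)))
    out$sequence <- vapply(by_pilus, function(d)
      paste(c("G", d), collapse = ""), "")
    names(out$sequence) <- NULL
  }
  out
}

#' @export
print.pilus_ensemble <- function(x, ...) {
  cat(sprintf("pilus ensemble: %d pili (model '%s', seed %d)\n", x$n_pili,
              x$model_name, x$seed))
  if (x$n_pili > 0L)
    cat(sprintf("  correct: %d (%.3g%%); mean length %.2f; truncated: %d\n",
                sum(x$correct), 100 * mean(x$correct), mean(x$length),
                sum(x$terminated == "truncated_at_cap")))
  invisible(x)
}

# Wilson score interval for a binomial proportion.
.wilson <- function(count, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- count / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, center - hw), upper = pmin(1, center + hw))
}

#' Empirical length / correctness distribution with Wilson intervals
#'
#' Point estimates `count / n_pili` per length bin with Wilson 95% (by
#' default) confidence intervals, for both the plain length distribution
#' and the correct-and-length distribution.  Bins with zero counts carry a
#' zero point estimate and a positive Wilson upper bound.
#'
#' @param ensemble A [simulate_ensemble()] result (or an ensemble read back
#'   by [read_ensemble_tsv()]).
#' @param conf Confidence level.
#' @return A `data.frame` of class `pilus_empirical_pmf` with columns `n`,
#'   `count`, `p_n`, `p_n_lower`, `p_n_upper`, `correct_count`, `p_cn`,
#'   `p_cn_lower`, `p_cn_upper`, and attribute `n_pili`.
#' @export
empirical_pmf <- function(ensemble, conf = 0.95) {
  stopifnot(inherits(ensemble, "pilus_ensemble"), ensemble$n_pili >= 1L)
  n_tot <- ensemble$n_pili
  ns <- seq(2L, max(ensemble$length))
  count <- tabulate(factor(ensemble$length, levels = ns), nbins = length(ns))
  ccount <- tabulate(factor(ensemble$length[ensemble$correct], levels = ns),
                     nbins = length(ns))
  ci <- .wilson(count, n_tot, conf)
  cci <- .wilson(ccount, n_tot, conf)
  out <- data.frame(n = ns, count = count, p_n = count / n_tot,
                    p_n_lower = ci[, "lower"], p_n_upper = ci[, "upper"],
                    correct_count = ccount, p_cn = ccount / n_tot,
                    p_cn_lower = cci[, "lower"], p_cn_upper = cci[, "upper"])
  attr(out, "n_pili") <- n_tot
  class(out) <- c("pilus_empirical_pmf", "data.frame")
  out
}

#' Monte Carlo estimate of P*
#'
#' Fraction of simulated pili that are correctly ordered and at least
#' `n_min` subunits long, with a binomial standard error.  Useful as a
#' stochastic cross-check of [p_star_closed_form()] where the probability
#' is large enough to sample.
#'
#' @param model A [transition_model()].
#' @param n_min Minimum length (inclusive).
#' @param n_pili,seed,length_cap Passed to [simulate_ensemble()].
#' @return A `pilus_p_star` object with `method = "monte_carlo"` and an
#'   extra `n_hits` field.
#' @export
p_star_monte_carlo <- function(model, n_min, n_pili = 1e5, seed = 1,
                               length_cap = 1e5) {
  ens <- simulate_ensemble(model, n_pili, seed, length_cap)
  hits <- sum(ens$correct & ens$length >= n_min)
  p <- hits / ens$n_pili
  se <- sqrt(p * (1 - p) / ens$n_pili)
  out <- .p_star_result(log10(p), n_min, "monte_carlo",
                        log10_se = if (p > 0) se / (p * log(10)) else NA_real_)
  out$n_hits <- hits
  out$n_pili <- ens$n_pili
  out
}

#' Write / read an ensemble as TSV, or export FASTA-like sequences
#'
#' The TSV has one row per pilus with columns `pilus_id`, `sequence`
#' (collapsed one-letter string), `length`, `correct` (0/1),
#' `assembly_time_h`, `terminated`.  The FASTA-like export writes
#' `>pilus_<id> correct=<0/1> time_h=<t>` headers over the same alphabet.
#' Reading a TSV reconstitutes a `pilus_ensemble` suitable for
#' [empirical_pmf()] and [fit_decay()].
#'
#' @param ensemble A [simulate_ensemble()] result with
#'   `keep_sequences = TRUE`.
#' @param path File path.
#' @return The path, invisibly (writers); a `pilus_ensemble` (reader).
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pilus_ensemble"))
  if (is.null(ensemble$sequence))
    stop("ensemble was simulated without keep_sequences = TRUE", call. = FALSE)
  df <- data.frame(pilus_id = seq_len(ensemble$n_pili),
                   sequence = ensemble$sequence, length = ensemble$length,
                   correct = as.integer(ensemble$correct),
                   assembly_time_h = ensemble$assembly_time,
                   terminated = ensemble$terminated)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "integer",
                                         "integer", "numeric", "character"))
  structure(list(length = df$length, correct = df$correct == 1L,
                 assembly_time = df$assembly_time_h,
                 terminated = df$terminated, sequence = df$sequence,
                 count_by_length = table(df$length),
                 correct_count_by_length = table(df$length[df$correct == 1L]),
                 mean_time_reaching = stats::setNames(numeric(0), character(0)),
                 n_pili = nrow(df), seed = NA_integer_, length_cap = NA_integer_,
                 model_name = sub("\\.tsv$", "", basename(path))),
            class = "pilus_ensemble")
}

#' @rdname write_ensemble_tsv
#' @export
write_ensemble_fasta <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pilus_ensemble"))
  if (is.null(ensemble$sequence))
    stop("ensemble was simulated without keep_sequences = TRUE", call. = FALSE)
  lines <- character(2L * ensemble$n_pili)
  lines[c(TRUE, FALSE)] <- sprintf(">pilus_%d correct=%d time_h=%.6g",
                                   seq_len(ensemble$n_pili),
                                   as.integer(ensemble$correct),
                                   ensemble$assembly_time)
  lines[c(FALSE, TRUE)] <- ensemble$sequence
  writeLines(lines, path)
  invisible(path)
}
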