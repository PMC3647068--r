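# Independent oracles, kept deliberately naive and separate from the
# package's computational paths.

# Brute-force enumeration of every donor sequence of the growth chain up
# to length n_max: walks all non-terminated partial paths, accumulating
# path probabilities in plain arithmetic and classifying finished
# sequences with a regular expression.
enum_pmf <- function(model, n_max) {
  subs <- pilus_subunits()
  p <- model$p
  p_n <- stats::setNames(numeric(n_max - 1L), 2:n_max)
  p_cn <- p_n
  frontier_seq <- "G"
  frontier_state <- 1L
  frontier_prob <- 1
  for (n in 2:n_max) {
    p_abs <- frontier_prob * p[cbind(frontier_state, 6L)]
    done <- paste0(frontier_seq, "H")
    p_n[as.character(n)] <- sum(p_abs)
    p_cn[as.character(n)] <- sum(p_abs[grepl("^GFE+KA+H$", done)])
    if (n == n_max) break
    new_seq <- character(0); new_state <- integer(0); new_prob <- numeric(0)
    for (d in 2:5) {
      pr <- frontier_prob * p[cbind(frontier_state, d)]
      keep <- pr > 0
      if (!any(keep)) next
      new_seq <- c(new_seq, paste0(frontier_seq[keep], subs[d]))
      new_state <- c(new_state, rep(d, sum(keep)))
      new_prob <- c(new_prob, pr[keep])
    }
    frontier_seq <- new_seq; frontier_state <- new_state
    frontier_prob <- new_prob
  }
  list(p_n = p_n, p_cn = p_cn)
}

# Exact conditional mean assembly time for pili reaching >= L subunits,
# by forward-backward occupancy over the embedded chain: positions
# 2..L-1 constrained to be non-H, one exponential wait per position
# 1..L-1 with the state's total exit rate.
exact_reach_time <- function(model, L) {
  Q <- model$p[, c("G", "F", "E", "K", "A")]
  lam <- model$exit_rate
  f <- matrix(0, L - 1L, 5L); f[1L, ] <- c(1, 0, 0, 0, 0)
  if (L >= 3L) for (k in 2:(L - 1L)) f[k, ] <- f[k - 1L, ] %*% Q
  h <- matrix(0, L - 1L, 5L); h[L - 1L, ] <- 1
  if (L >= 3L) for (k in (L - 2L):1L) h[k, ] <- as.vector(Q %*% h[k + 1L, ])
  Z <- sum(f[1L, ] * h[1L, ])
  tot <- 0
  for (k in 1:(L - 1L)) tot <- tot + sum(f[k, ] * h[k, ] / lam) / Z
  tot
}

# Wilson score interval, written out directly.
wilson_oracle <- function(count, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- count / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# Family-wise bound on the largest |z| when comparing many binomial bins
# against analytic probabilities: 4 SE for a handful of bins, Bonferroni
# at family level 1e-3 when thousands of bins are compared at once.
max_z_threshold <- function(nbins) {
  max(4, stats::qnorm(1 - 0.001 / (2 * nbins)))
}

model_equal <- function() transition_model(builtin_rate_table("equal"))
model_in_vitro <- function() transition_model(builtin_rate_table("in_vitro"))
model_R <- function() transition_model(builtin_rate_table("hypothetical_R"))
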