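#' Embedded-chain transition model of pilus growth
#'
#' @description
#' Pilus elongation is modeled as a set of competing first-order DSE events:
#' with the growing pilus ending in chaperone-capped acceptor \eqn{A}, donor
#' \eqn{D} attaches in a short interval \eqn{dt} with probability
#' \eqn{[D]\,k_{AD}\,dt}.  The identity of the next subunit and the waiting
#' time until it attaches are therefore independent, and growth is an
#' absorbing Markov chain over acceptor states with
#'
#' \deqn{p_{A\to D} = \frac{[D]\,k_{AD}}{\sum_{D'} [D']\,k_{AD'}}, \qquad
#'       \lambda_A = \sum_{D'} [D']\,k_{AD'},}
#'
#' where \eqn{\lambda_A} is the total exit rate of state \eqn{A} (in
#' \eqn{h^{-1}}; table entries are converted from \eqn{10^{-3}\,h^{-1}}
#' here).  Appending PapH absorbs the chain (PapH never accepts).  The chain
#' starts with PapG already assembled at position 1.
#'
#' An acceptor whose effective rates (`weight * rate`) are all zero is a
#' *stall state*: growth arriving there terminates without PapH.  Stall
#' states cannot arise from the built-in tables but can from user tables;
#' they are flagged with a warning, not an error.
#'
#' @param table A [rate_table()].
#' @param conc A [concentration_profile()]; default uniform.
#' @return An object of class `pilus_transition_model` with components
#'   `p` (5x6 matrix of transition probabilities, acceptor rows G,F,E,K,A,
#'   donor columns G..H; rows of stall states are all zero), `exit_rate`
#'   (named vector, \eqn{h^{-1}}), `stalled` (named logical), `initial`
#'   (`"G"`), `table_name`, `weights`.
#' @examples
#' m <- transition_model(builtin_rate_table("equal"))
#' m$p["A", "H"]   # 1/5
#' @export
transition_model <- function(table, conc = uniform_profile()) {
  stopifnot(inherits(table, "pilus_rate_table"))
  .validate_rate_table(unclass(table))
  w <- concentration_profile(unclass(conc))
  acc <- .acceptors()
  eff <- sweep(unclass(table)[acc, , drop = FALSE], 2, as.numeric(w), "*")
  tot <- rowSums(eff)
  stalled <- tot == 0
  if (any(stalled))
    warning("stall state(s) with zero total effective rate: acceptor ",
            paste(acc[stalled], collapse = ", "),
            "; growth arriving there terminates without PapH", call. = FALSE)
  p <- eff
  p[!stalled, ] <- eff[!stalled, , drop = FALSE] / tot[!stalled]
  structure(list(
    p = p,
    exit_rate = tot * 1e-3,     # table unit 1e-3/h -> 1/h
    stalled = stats::setNames(stalled, acc),
    initial = "G",
    table_name = attr(table, "name"),
    weights = as.numeric(w)
  ), class = "pilus_transition_model")
}

#' @export
print.pilus_transition_model <- function(x, ...) {
  cat(sprintf("pilus growth chain (rates: '%s')\n", x$table_name))
  cat("transition probabilities (acceptor -> next donor):\n")
  print(round(x$p, 5))
  cat("total exit rates (1/h):\n")
  print(round(x$exit_rate, 5))
  if (any(x$stalled))
    cat("stall states:", paste(names(x$stalled)[x$stalled], collapse = ", "),
        "\n")
  invisible(x)
}

# 5x5 substochastic matrix of the surviving chain (next acceptor state),
# rows/cols G,F,E,K,A; dropping the H column removes the absorbed mass.
.survival_matrix <- function(model) {
  acc <- .acceptors()
  model$p[, acc, drop = FALSE]
}
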