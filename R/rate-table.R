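#' Construct and validate a pairwise DSE rate table
#'
#' A rate table holds the apparent pseudo-first-order donor-strand-exchange
#' (DSE) rate constants \eqn{k_{AD}} for every acceptor (chaperone:subunit
#' complex, rows) and donor N-terminal extension (Nte, columns) pair.
#' Entries are stored in the measurement unit of the source experiments,
#' \eqn{10^{-3}\,h^{-1}}: a stored value of 5.5 means
#' \eqn{5.5\times10^{-3}\,h^{-1}}.  Conversion to \eqn{h^{-1}} happens only
#' where waiting times are computed (see [transition_model()]).
#'
#' Two structural zeros are enforced: the PapG column is all zero (the Nte
#' of PapG is part of its lectin domain and never donates) and the PapH row
#' is all zero (PapH cannot accept a donor strand, which is what terminates
#' growth).
#'
#' @param k A 6x6 numeric matrix of nonnegative rates in
#'   \eqn{10^{-3}\,h^{-1}}, rows = acceptors, columns = donors, both in
#'   canonical subunit order ([pilus_subunits()]).  Dimnames, if present,
#'   must match the canonical order.
#' @param name Text label carried along into outputs.
#' @return An object of class `pilus_rate_table`: the validated matrix with
#'   canonical dimnames and a `name` attribute.
#' @seealso [builtin_rate_table()], [read_rate_table()], [make_rate_table()]
#' @examples
#' k <- matrix(0, 6, 6)
#' k[1, 2] <- 5  # PapG acceptor, PapF donor
#' k[1:5, 6] <- 1
#' rate_table(k, name = "toy")
#' @export
rate_table <- function(k, name = "user") {
  subs <- pilus_subunits()
  if (!is.matrix(k) || !is.numeric(k) || !all(dim(k) == c(6L, 6L)))
    stop("rate table must be a 6x6 numeric matrix", call. = FALSE)
  if (!is.null(dimnames(k))) {
    if (!identical(rownames(k), subs) || !identical(colnames(k), subs))
      stop("rate table dimnames must follow the canonical subunit order ",
           paste(subs, collapse = ", "), call. = FALSE)
  }
  dimnames(k) <- list(acceptor = subs, donor = subs)
  .validate_rate_table(k)
  structure(k, name = as.character(name), class = "pilus_rate_table")
}

.validate_rate_table <- function(k, where = "rate table") {
  subs <- pilus_subunits()
  bad <- which(!is.finite(k) | k < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: entry (Pap%s, %s_Nte) is negative or not finite",
                 where, subs[bad[1, 1]], subs[bad[1, 2]]), call. = FALSE)
  if (any(k[, "G"] != 0))
    stop(where, ": donor column G must be all zero (PapG never donates)",
         call. = FALSE)
  if (any(k["H", ] != 0))
    stop(where, ": acceptor row H must be all zero (PapH never accepts)",
         call. = FALSE)
  invisible(k)
}

# Table of in vitro apparent pseudo-first-order DSE rate constants measured
# by non-covalent ESI mass spectrometry, units 10^-3 h^-1.  The two "~"
# entries of the source data (~0.7, ~1) are taken at face value.
.in_vitro_rates <- function() {
  k <- rbind(
    G = c(0,  5.5,   0.7,   0.7,  0.7,  0.7),
    F = c(0,  2.7,   9.4,   4.7,  2.8,  2.5),
    E = c(0, 65.7, 190.2, 210.8, 39.9, 48.6),
    K = c(0,  1.0,   1.0,   1.6, 53.6, 26.6),
    A = c(0,  2.9,   3.3,   9.0, 45.8, 22.9),
    H = c(0,  0,     0,     0,    0,    0))
  colnames(k) <- pilus_subunits()
  k
}

# Cognate (acceptor <- donor) pairs: adjacent in the natural pilus order.
# These are exactly the fast cells of the hypothetical rate scheme; note
# that termination (A <- H) is deliberately *not* fast, otherwise no long
# pilus could ever form.
.cognate_pairs <- function() {
  cbind(acceptor = c("G", "F", "E", "E", "K", "A"),
        donor    = c("F", "E", "E", "K", "A", "A"))
}

#' Built-in DSE rate tables
#'
#' @description
#' Returns one of the rate tables the analysis is built around:
#'
#' * `"in_vitro"` — the experimentally measured apparent pseudo-first-order
#'   DSE rate constants for each chaperone:subunit--Nte pair (ESI-MS, Nte
#'   peptide mimetics), in \eqn{10^{-3}\,h^{-1}}.
#' * `"hypothetical_R"` — the hypothetical scheme that warrants growth of
#'   correctly ordered pili at equal concentrations: every cognate pair
#'   reacts at \eqn{k_{fast} = 1000} and every other permitted pair 1000
#'   times slower (\eqn{k_{slow} = 1}).
#' * `"hypothetical_R_ratio"` — the same cognate/non-cognate pattern with
#'   \eqn{k_{slow} = k_{fast}/\mathrm{ratio}}.
#' * `"equal"` — every permitted entry equal to 1 (completely random
#'   growth; the G column and H row stay zero).
#'
#' @param name One of `"in_vitro"`, `"hypothetical_R"`,
#'   `"hypothetical_R_ratio"`, `"equal"`.
#' @param ratio Fast/slow rate ratio (>= 1), used only by
#'   `"hypothetical_R_ratio"`.
#' @return A [rate_table()].
#' @examples
#' builtin_rate_table("in_vitro")["E", "K"]   # 210.8
#' builtin_rate_table("hypothetical_R")["K", "A"]
#' @export
builtin_rate_table <- function(name = c("in_vitro", "hypothetical_R",
                                        "hypothetical_R_ratio", "equal"),
                               ratio = 1000) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("in_vitro", "hypothetical_R", "hypothetical_R_ratio",
                   "equal"))
    stop("unknown rate table; valid names are: in_vitro, hypothetical_R, ",
         "hypothetical_R_ratio, equal", call. = FALSE)
  switch(name,
    in_vitro = rate_table(.in_vitro_rates(), name = "in_vitro"),
    hypothetical_R = make_rate_table(ratio = 1000, k_fast = 1000,
                                     name = "hypothetical_R"),
    hypothetical_R_ratio = make_rate_table(ratio = ratio, k_fast = 1000,
      name = sprintf("hypothetical_R_ratio_%g", ratio)),
    equal = {
      k <- matrix(1, 6, 6)
      k[, 1] <- 0
      k[6, ] <- 0
      rate_table(k, name = "equal")
    })
}

#' @export
print.pilus_rate_table <- function(x, ...) {
  cat(sprintf("DSE rate table '%s' (units: 1e-3 / h)\n", attr(x, "name")))
  m <- unclass(x)
  attr(m, "name") <- NULL
  print(m, ...)
  invisible(x)
}

.rate_csv_header <- function() {
  c("acceptor", paste0(pilus_subunits(), "_Nte"))
}

#' Read / write a rate table in the package CSV dialect
#'
#' The on-disk format is a plain CSV with header
#' `acceptor,G_Nte,F_Nte,E_Nte,K_Nte,A_Nte,H_Nte` and six data rows labeled
#' `PapG ... PapH` in canonical order; values are decimal-point floats in
#' \eqn{10^{-3}\,h^{-1}}.  Reading validates all structural invariants and
#' names the offending cell on failure; writing then reading a table is
#' value-identical.
#'
#' @param path File path.
#' @param table A [rate_table()].
#' @return `read_rate_table()` returns a `pilus_rate_table`;
#'   `write_rate_table()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_rate_table(builtin_rate_table("equal"), f)
#' read_rate_table(f)
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  subs <- pilus_subunits()
  if (!identical(names(df), .rate_csv_header()))
    stop("rate table CSV must have header: ",
         paste(.rate_csv_header(), collapse = ","), call. = FALSE)
  if (!identical(df$acceptor, paste0("Pap", subs)))
    stop("rate table CSV must have rows PapG, PapF, PapE, PapK, PapA, PapH ",
         "in that order", call. = FALSE)
  k <- matrix(NA_real_, 6, 6)
  for (j in seq_len(6)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(df[[j + 1L]]))
    if (length(bad) > 0L)
      stop(sprintf("rate table CSV: non-numeric value at (Pap%s, %s_Nte)",
                   subs[bad[1]], subs[j]), call. = FALSE)
    k[, j] <- col
  }
  dimnames(k) <- list(acceptor = subs, donor = subs)
  .validate_rate_table(k, where = paste0("rate table '", path, "'"))
  rate_table(k, name = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_rate_table
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "pilus_rate_table"))
  df <- data.frame(acceptor = paste0("Pap", pilus_subunits()),
                   unclass(table)[, , drop = FALSE], check.names = FALSE)
  names(df) <- .rate_csv_header()
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
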