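#' Relative concentration profiles of the pilin subunits
#'
#' A concentration profile gives the relative abundance weight of each
#' chaperone:subunit complex at the usher.  Weights are dimensionless and
#' only their ratios matter: at every elongation step the next donor is
#' drawn with probability proportional to `weight * rate`, so rescaling all
#' six weights by a common factor changes nothing downstream.  Profiles are
#' therefore never normalized.
#'
#' @param weights Named (or canonically ordered) numeric vector of six
#'   nonnegative weights, at least one positive.  Default: uniform.
#' @return An object of class `pilus_concentration`, a named numeric vector.
#' @examples
#' uniform_profile()
#' scaled_profile(uniform_profile(), "A", 200)
#' @export
concentration_profile <- function(weights = stats::setNames(rep(1, 6),
                                                            pilus_subunits())) {
  subs <- pilus_subunits()
  if (!is.numeric(weights) || length(weights) != 6L)
    stop("a concentration profile needs six numeric weights", call. = FALSE)
  if (is.null(names(weights))) names(weights) <- subs
  if (!setequal(names(weights), subs))
    stop("weights must be named by the subunits ",
         paste(subs, collapse = ", "), call. = FALSE)
  weights <- weights[subs]
  if (any(!is.finite(weights) | weights < 0))
    stop("concentration weights must be finite and >= 0", call. = FALSE)
  if (all(weights == 0))
    stop("at least one concentration weight must be positive", call. = FALSE)
  structure(weights, class = "pilus_concentration")
}

#' @rdname concentration_profile
#' @export
uniform_profile <- function() concentration_profile()

#' @rdname concentration_profile
#' @param base A profile to modify.
#' @param subunit Which subunit's weight to scale.
#' @param factor Positive multiplicative fold-change (e.g. 200 for the
#'   "[PapA] 200 times larger" condition, 0.1 for "[PapH] 10 times smaller").
#' @export
scaled_profile <- function(base, subunit, factor) {
  base <- concentration_profile(unclass(base))
  .assert_subunit(subunit)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("factor must be a single positive number", call. = FALSE)
  base[subunit] <- base[subunit] * factor
  concentration_profile(unclass(base))
}

#' @export
print.pilus_concentration <- function(x, ...) {
  cat("relative subunit concentrations (only ratios matter)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read / write a concentration profile CSV
#'
#' Plain CSV with header `subunit,weight` and six rows in canonical subunit
#' order.
#'
#' @param path File path.
#' @param profile A [concentration_profile()].
#' @return `read_concentration()` returns a `pilus_concentration`;
#'   `write_concentration()` returns `path` invisibly.
#' @export
read_concentration <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("subunit", "weight")))
    stop("concentration CSV must have header: subunit,weight", call. = FALSE)
  w <- stats::setNames(as.numeric(df$weight), as.character(df$subunit))
  concentration_profile(w)
}

#' @rdname read_concentration
#' @export
write_concentration <- function(profile, path) {
  profile <- concentration_profile(unclass(profile))
  utils::write.csv(data.frame(subunit = names(profile),
                              weight = as.numeric(profile)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
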