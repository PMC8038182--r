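# Fractional-polynomial transforms. The power set is the standard 8-element
# set; power 0 denotes the natural log and a repeated power (p, p) denotes
# the pair (x^p, x^p * ln x).

#' The fractional-polynomial power set
#'
#' @return The eight candidate exponents `c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)`;
#'   0 stands for the natural logarithm.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# all 36 degree-2 power tuples: 28 distinct pairs + 8 repeated
fp_power_pairs <- function() {
  p <- fp_powers()
  pairs <- list()
  for (i in seq_along(p)) {
    for (j in i:length(p)) {
      pairs[[length(pairs) + 1L]] <- c(p[i], p[j])
    }
  }
  pairs
}

#' Construct a fractional-polynomial term
#'
#' @param variable Variable name.
#' @param powers One or two exponents from [fp_powers()]; a repeated power
#'   `(p, p)` requests the pair `(x^p, x^p ln x)`.
#' @param scale Positive divisor applied before powering (e.g. ALT/100).
#' @param shift Non-negative shift applied before scaling (0 unless needed
#'   for positivity).
#' @return An object of class `fl_fp_term`.
#' @export
fp_term <- function(variable, powers, scale = 1, shift = 0) {
  stopifnot(length(powers) %in% 1:2, all(powers %in% fp_powers()),
            scale > 0, shift >= 0)
  structure(list(variable = variable, powers = powers, scale = scale,
                 shift = shift),
            class = "fl_fp_term")
}

#' Evaluate a fractional-polynomial transform
#'
#' With `z = (x + shift) / scale`: power `p != 0` gives `z^p`, `p = 0` gives
#' `ln z`, and a repeated power `(p, p)` gives the two columns
#' `(z^p, z^p ln z)`.
#'
#' @param x Positive numeric vector (after shift and scale).
#' @param term An [fp_term()].
#' @return Matrix with one column per transformed term, named
#'   `<var>^<power>` (second repeated column `<var>^<power>*log`).
#' @export
fp_transform <- function(x, term) {
  stopifnot(inherits(term, "fl_fp_term"))
  z <- (x + term$shift) / term$scale
  if (any(z <= 0)) {
    stop_domain(sprintf(
      "non-positive value of %s after shift/scale at row %d; FP powers need a positive base",
      term$variable, which(z <= 0)[1L]
    ))
  }
  pw <- term$powers
  one <- function(p) if (p == 0) log(z) else z^p
  if (length(pw) == 1L) {
    out <- matrix(one(pw[1L]), ncol = 1)
    colnames(out) <- sprintf("%s^%g", term$variable, pw[1L])
  } else if (pw[1L] == pw[2L]) {
    out <- cbind(one(pw[1L]), one(pw[1L]) * log(z))
    colnames(out) <- sprintf(c("%s^%g", "%s^%g*log"), term$variable, pw[1L])
  } else {
    out <- cbind(one(pw[1L]), one(pw[2L]))
    colnames(out) <- sprintf("%s^%g", term$variable, pw)
  }
  out
}

# Precomputed transform cache for the FP search: for a data vector x,
# returns the scaled base z, log z, and the n x 8 matrix of single-power
# columns, from which any FP1/FP2 design is assembled by column picking.
fp_cache <- function(x, scale = 1, shift = 0) {
  z <- (x + shift) / scale
  if (any(z <= 0)) {
    stop_domain(sprintf("non-positive FP base at row %d", which(z <= 0)[1L]))
  }
  logz <- log(z)
  cols <- vapply(fp_powers(), function(p) if (p == 0) logz else z^p,
                 numeric(length(z)))
  colnames(cols) <- as.character(fp_powers())
  list(z = z, logz = logz, cols = cols)
}

# columns for a power tuple from a cache
fp_cols_from_cache <- function(cache, powers) {
  if (length(powers) == 1L) {
    cache$cols[, as.character(powers), drop = FALSE]
  } else if (powers[1L] == powers[2L]) {
    cbind(cache$cols[, as.character(powers[1L])],
          cache$cols[, as.character(powers[1L])] * cache$logz)
  } else {
    cache$cols[, as.character(powers), drop = FALSE]
  }
}
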