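# Gaussian copula construction: map target Spearman correlations to latent
# Pearson correlations, honouring discrete (thresholded) margins, and repair
# the latent matrix to positive definiteness if needed.

# Large-n Spearman correlation (mid-ranks for ties) between two margins
# joined by a Gaussian copula with latent correlation r.
#
# Both margins continuous: the classical closed form (6/pi) asin(r/2).
# Otherwise a 1-D Gaussian integral: with Z2 | Z1 = z ~ N(r z, 1 - r^2),
# E[F2*(X2) | z] is available in closed form (normal cdf terms), and the
# outer expectation over z is quadrature. F* denotes the mid-rank cdf.
spearman_copula <- function(r, m1 = NULL, m2 = NULL) {
  r <- max(min(r, 0.9995), -0.9995)
  if (is.null(m1) && is.null(m2)) return((6 / pi) * asin(r / 2))
  if (is.null(m1)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  h1 <- function(z) m1$fs[findInterval(z, m1$tau) + 1L]
  if (is.null(m2)) {
    g2 <- function(z) stats::pnorm(r * z / sqrt(2 - r^2))
    v2 <- 1 / 12
  } else {
    s <- sqrt(1 - r^2)
    g2 <- function(z) {
      out <- 0
      prev <- 0
      b <- c(m2$tau, Inf)
      for (k in seq_along(m2$fs)) {
        pk <- stats::pnorm((b[k] - r * z) / s)
        out <- out + m2$fs[k] * (pk - prev)
        prev <- pk
      }
      out
    }
    v2 <- m2$v
  }
  e <- stats::integrate(function(z) stats::dnorm(z) * h1(z) * g2(z),
                        -8, 8, subdivisions = 400L, rel.tol = 1e-9)$value
  (e - 0.25) / sqrt(m1$v * v2)
}

# invert spearman_copula in r for a target rho; clips to the attainable
# range (returns the boundary latent correlation with attribute "clipped")
latent_from_spearman <- function(rho, m1 = NULL, m2 = NULL) {
  if (abs(rho) >= 1) stop_domain("off-diagonal Spearman targets must be in (-1, 1)")
  if (is.null(m1) && is.null(m2)) return(2 * sin(pi * rho / 6))
  if (rho == 0) return(0)
  hi <- spearman_copula(0.9995, m1, m2)
  if (abs(rho) >= abs(hi)) {
    return(structure(sign(rho) * 0.9995, clipped = TRUE))
  }
  stats::uniroot(function(r) spearman_copula(r, m1, m2) - rho,
                 interval = c(-0.9995, 0.9995), tol = 1e-7)$root
}

#' Build the latent Gaussian copula for a set of Spearman targets
#'
#' Converts a symmetric matrix of target Spearman correlations into the
#' latent Pearson correlation matrix of a Gaussian copula. Continuous pairs
#' use the exact map `r = 2 sin(pi * rho / 6)`; pairs involving a discrete
#' (thresholded) margin invert the large-n mid-rank Spearman functional
#' numerically, so that e.g. the ordinal pubertal stage realises its target
#' correlation with age despite discretisation attenuation. If the assembled
#' matrix is not positive definite it is repaired by eigenvalue clipping and
#' rescaling to unit diagonal; the repair log records the largest entry
#' perturbation.
#'
#' @param targets Symmetric matrix of Spearman targets with unit diagonal and
#'   off-diagonal entries in (-1, 1); dimnames give the variable order.
#' @param marginals Named list of `fl_marginal` objects covering every row of
#'   `targets` (used to detect discrete margins).
#' @return An object of class `fl_copula`: list with `variables`, `targets`,
#'   `latent` (positive-definite latent correlation matrix), `repair`
#'   (list: `repaired`, `max_perturbation`), `clipped` (character vector of
#'   pairs whose target exceeded the attainable range).
#' @export
build_copula <- function(targets, marginals = default_marginals()) {
  stopifnot(is.matrix(targets), nrow(targets) == ncol(targets))
  if (max(abs(targets - t(targets))) > 1e-12 || any(diag(targets) != 1)) {
    stop("targets must be symmetric with unit diagonal")
  }
  vars <- rownames(targets)
  stopifnot(!is.null(vars), all(vars %in% names(marginals)))
  off <- targets[upper.tri(targets)]
  if (any(abs(off) >= 1)) {
    stop_domain("off-diagonal Spearman targets must be in (-1, 1)")
  }
  mid <- lapply(marginals[vars], marginal_midranks)
  p <- length(vars)
  latent <- diag(p)
  dimnames(latent) <- dimnames(targets)
  clipped <- character(0)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      r <- latent_from_spearman(targets[i, j], mid[[i]], mid[[j]])
      if (isTRUE(attr(r, "clipped"))) {
        clipped <- c(clipped, paste(vars[i], vars[j], sep = "-"))
      }
      latent[i, j] <- latent[j, i] <- as.numeric(r)
    }
  }
  repair <- list(repaired = FALSE, max_perturbation = 0)
  e <- eigen(latent, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    fixed <- e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors)
    d <- diag(1 / sqrt(diag(fixed)))
    fixed <- d %*% fixed %*% d
    dimnames(fixed) <- dimnames(latent)
    repair <- list(repaired = TRUE,
                   max_perturbation = max(abs(fixed - latent)))
    latent <- fixed
  }
  structure(
    list(variables = vars, targets = targets, latent = latent,
         repair = repair, clipped = clipped),
    class = "fl_copula"
  )
}

#' @export
print.fl_copula <- function(x, ...) {
  cat(sprintf("Gaussian copula over %d variables\n", length(x$variables)))
  cat(sprintf("  positive-definite repair: %s (max perturbation %.3g)\n",
              ifelse(x$repair$repaired, "yes", "no"),
              x$repair$max_perturbation))
  if (length(x$clipped) > 0L) {
    cat("  clipped targets:", paste(x$clipped, collapse = ", "), "\n")
  }
  invisible(x)
}
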