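#' Convert p-values to one-sided z-scores
#'
#' `z = qnorm(1 - p)` after clipping `p` into `[1e-15, 1 - 1e-15]`.  The
#' path p-values are omnibus tail probabilities, so evidence against a null
#' only ever shifts `z` to the right; the empirical-null machinery below
#' relies on that one-sided construction.
#'
#' @param p probability vector.
#' @return z-score vector of the same length.
#' @export
pvals_to_z <- function(p) {
  stats::qnorm(clip_p(p), lower.tail = FALSE)
}

clip_p <- function(p, lo = 1e-15) pmin(pmax(p, lo), 1 - lo)

## Truncated-normal maximum-likelihood fit of the empirical null
## N(delta, sigma^2) on the window [a, b] of z.
truncnorm_mle <- function(z, a, b, init = NULL) {
  zc <- z[z >= a & z <= b]
  n0 <- length(zc)
  if (n0 < 10L || stats::sd(zc) == 0) return(NULL)
  if (is.null(init)) init <- c(stats::median(zc), log(stats::sd(zc)))
  nll <- function(par) {
    d <- par[1L]; s <- exp(par[2L])
    pa <- stats::pnorm((b - d) / s) - stats::pnorm((a - d) / s)
    if (!is.finite(pa) || pa < 1e-300) return(1e10)
    n0 * log(pa) + n0 * log(s) + sum((zc - d)^2) / (2 * s^2)
  }
  opt <- tryCatch(stats::optim(init, nll), error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  list(delta = opt$par[1L], sigma = exp(opt$par[2L]), n_window = n0)
}

#' Estimate the null proportion of a z-score series
#'
#' Fits an empirical null `N(delta, sigma^2)` to the central bulk of the
#' z-scores by truncated-normal maximum likelihood on an iterated
#' asymmetric window `(delta - 2 sigma, delta + 0.8 sigma)` -- asymmetric
#' because the z-scores are one-sided by construction ([pvals_to_z()]):
#' alternatives shift right only, so the left flank is nearly pure null
#' while the right flank is contaminated.  The null mass is then estimated
#' from the left-of-center mass, `min(1, mean(z <= delta) / 0.5)`, which is
#' insensitive to right-tail alternatives.
#'
#' Below 100 scores the estimate is unreliable and 1 is returned with a
#' warning (conservative); a degenerate series (all equal) also returns 1.
#'
#' @param z z-score vector, as from [pvals_to_z()].
#' @return the null proportion in `[0, 1]`, with the fitted `delta` and
#'   `sigma` as attributes.
#' @export
estimate_null_proportion <- function(z) {
  if (length(z) < 100L) {
    warning("fewer than 100 z-scores: returning pi0 = 1 (conservative)")
    return(structure(1, delta = NA_real_, sigma = NA_real_))
  }
  if (stats::sd(z) == 0) {
    warning("degenerate z-scores (all equal): returning pi0 = 1")
    return(structure(1, delta = NA_real_, sigma = NA_real_))
  }
  d <- stats::median(z); s <- stats::mad(z)
  if (s == 0) s <- stats::sd(z)
  for (it in 1:4) {
    fit <- truncnorm_mle(z, d - 2 * s, d + 0.8 * s, init = c(d, log(s)))
    if (is.null(fit)) break
    d <- fit$delta; s <- fit$sigma
  }
  pi0 <- min(1, mean(z <= d) / 0.5)
  structure(max(0, pi0), delta = d, sigma = s)
}

#' Compose sub-null proportions from the two path series
#'
#' Given the estimated null proportions of the exposure-path and
#' outcome-path p-value series, the three composite sub-null probabilities
#' are composed under independence of the two null indicators,
#' `(pi00, pi01, pi10) = (pi0a pi0b, pi0a (1-pi0b), (1-pi0a) pi0b)`,
#' normalized over the three.
#'
#' @param pi0_alpha,pi0_beta null proportions of the two series, in
#'   `[0, 1]`.
#' @return list of class `"composite_weights"` with `pi00`, `pi01`, `pi10`
#'   summing to 1, and the source estimates.
#' @export
compose_weights <- function(pi0_alpha, pi0_beta) {
  if (pi0_alpha < 0 || pi0_alpha > 1 || pi0_beta < 0 || pi0_beta > 1)
    stop("null proportions must lie in [0, 1]")
  w <- c(pi00 = pi0_alpha * pi0_beta,
         pi01 = pi0_alpha * (1 - pi0_beta),
         pi10 = (1 - pi0_alpha) * pi0_beta)
  tot <- sum(w)
  if (tot <= 0)
    stop("both series are estimated fully non-null: the composite null is empty")
  w <- w / tot
  structure(list(pi00 = w[["pi00"]], pi01 = w[["pi01"]], pi10 = w[["pi10"]],
                 pi0_alpha = pi0_alpha, pi0_beta = pi0_beta),
            class = "composite_weights")
}

#' Weighted divide-aggregate composite-null (DACT) mediation p-value
#'
#' Mixes the case-specific null p-values of the three sub-nulls by their
#' estimated probabilities: under H01 the evidence is `p_alpha`, under H10
#' it is `p_beta`, and under H00 it is `max(p_alpha, p_beta)^2`, which is
#' Uniform(0,1) when the two inputs are independent uniforms.
#'
#' @param p_alpha,p_beta path p-value vectors in `(0, 1]`.
#' @param w a [compose_weights()] result.
#' @return the mediation p-value vector
#'   `pi01 p_alpha + pi10 p_beta + pi00 max(p_alpha, p_beta)^2`.
#' @examples
#' w <- compose_weights(0.9, 0.8)
#' dact_statistic(0.01, 0.04, w)
#' @export
dact_statistic <- function(p_alpha, p_beta, w) {
  stopifnot(inherits(w, "composite_weights"))
  if (length(p_alpha) != length(p_beta))
    stop("'p_alpha' and 'p_beta' must have equal length")
  if (any(p_alpha <= 0 | p_alpha > 1, na.rm = TRUE) ||
      any(p_beta <= 0 | p_beta > 1, na.rm = TRUE))
    stop("path p-values must lie in (0, 1]")
  w$pi01 * p_alpha + w$pi10 * p_beta + w$pi00 * pmax(p_alpha, p_beta)^2
}

#' Genome-wide empirical-null recalibration of mediation p-values
#'
#' The weighted composite-null statistic is only approximately uniform
#' under the null mixture, so with enough genes its p-values are
#' recalibrated against an empirical null: transform to z, fit
#' `N(delta, sigma^2)` by truncated-normal likelihood on the fixed window
#' `z` in `[-1, 2.5]` (right-of-center because that bulk sets the rejection
#' boundary, capped at 2.5 to exclude strong alternatives), and return
#' `1 - Phi((z - delta)/sigma)`.  The transform is monotone, so ranks are
#' preserved.  Below `min_genes` inputs the fit is unstable and the input
#' is returned unchanged with a message; a degenerate fit returns the input
#' with a warning.
#'
#' @param p_mediation mediation p-value vector.
#' @param min_genes minimum series length for recalibration (default 1000).
#' @return calibrated p-value vector.
#' @export
efron_recalibrate <- function(p_mediation, min_genes = 1000L) {
  ok <- !is.na(p_mediation)
  if (sum(ok) < min_genes) {
    message("fewer than ", min_genes,
            " genes: empirical-null recalibration skipped")
    return(p_mediation)
  }
  z <- pvals_to_z(p_mediation[ok])
  fit <- truncnorm_mle(z, -1, 2.5)
  if (is.null(fit) || !is.finite(fit$sigma) || fit$sigma <= 0) {
    warning("degenerate empirical-null fit: returning input p-values")
    return(p_mediation)
  }
  out <- p_mediation
  out[ok] <- clip_p(stats::pnorm((z - fit$delta) / fit$sigma,
                                 lower.tail = FALSE))
  attr(out, "null_fit") <- fit[c("delta", "sigma")]
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q_i = min_{j: p_(j) >= p_(i)} min(1, m p_(j) / j)`;
#' `NA` entries are excluded from the adjustment and propagated as `NA`.
#'
#' @param p p-value vector.
#' @return q-value vector of the same length.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
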