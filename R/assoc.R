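#' Fit the adjustment-only null model for a path test
#'
#' Fits the outcome (or inverse-regression exposure) on the adjustment
#' covariates alone: ordinary least squares for the Gaussian family,
#' logistic maximum likelihood for the binomial family.  The returned fit
#' carries everything the variance-component score test needs: residuals on
#' the response scale, the variance-function values, and the (possibly
#' rank-reduced) design matrix.
#'
#' @param response numeric vector (0/1 for binomial).
#' @param covariates numeric matrix of adjustment covariates (no intercept
#'   column; one is added).  Rank-deficient columns are dropped with a
#'   warning.
#' @param family `"gaussian"` or `"binomial"`.
#'
#' @return a list of class `"null_model"` with `family`, `design`, `mu`
#'   (fitted means), `residuals` (`response - mu`), `sigma2` (Gaussian
#'   residual variance estimate, RSS/(n-p)), `v` (variance-function values
#'   `mu (1-mu)` for binomial, 1 for Gaussian) and `qr` of the (weighted)
#'   design.
#' @export
fit_null_model <- function(response, covariates,
                           family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y <- as.numeric(response)
  if (anyNA(y)) stop("missing values in the response; drop samples first")
  D <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (anyNA(D)) stop("missing values in the covariates; drop samples first")
  n <- length(y)
  if (nrow(D) != n) stop("covariate rows do not match the response length")

  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    dropped <- colnames(D)[setdiff(seq_len(ncol(D)), keep)]
    warning("dropping rank-deficient covariate column(s): ",
            paste(dropped, collapse = ", "))
    D <- D[, sort(keep), drop = FALSE]
    qrD <- qr(D)
  }
  p <- ncol(D)

  if (family == "gaussian") {
    res <- qr.resid(qrD, y)
    sigma2 <- sum(res^2) / (n - p)
    if (sigma2 < 1e-12 * max(1, stats::var(y)))
      stop("zero residual variance: the response is explained exactly by the covariates")
    mu <- y - res
    out <- list(family = family, design = D, mu = mu, residuals = res,
                sigma2 = sigma2, v = rep(1, n), qr = qrD)
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
    if (length(unique(y)) < 2L) stop("binomial response has a single class")
    fit <- suppressWarnings(
      stats::glm.fit(D, y, family = stats::binomial()))
    if (!fit$converged)
      stop("logistic null model did not converge")
    mu <- fit$fitted.values
    if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
      cf <- fit$coefficients[-1L]
      worst <- names(cf)[which.max(abs(cf))]
      stop("perfect or quasi-perfect separation in the logistic null model; ",
           "suspect covariate: ", worst)
    }
    out <- list(family = family, design = D, mu = mu, residuals = y - mu,
                sigma2 = NA_real_, v = mu * (1 - mu), qr = qrD)
  }
  class(out) <- "null_model"
  out
}

#' Variance-component score test of a mediator block
#'
#' Tests whether a set of CpG M-values is associated with the null model's
#' response by treating the per-CpG coefficients as random effects with a
#' common variance component, i.e. the score test of zero random-effect
#' variance in a (generalised) linear mixed model with the unweighted
#' linear kernel `M M'`.  The statistic is `Q = r' M M' r` with `r` the
#' null-model residuals; its null distribution is the weighted chi-square
#' sum with weights given by the nonzero eigenvalues of `M' P0 M` (Gaussian:
#' scaled by the residual variance; binomial: with the weighted projection
#' `P0 = V - V D (D'V D)^{-1} D' V`).  Columns are standardized to mean
#' zero, unit variance before forming the kernel, so probe-scale
#' differences carry no implicit weighting; constant columns are dropped.
#'
#' @param null_fit a [fit_null_model()] result.
#' @param M numeric `n x K` mediator block (raw M-values; standardization is
#'   applied internally).
#' @param acc requested tail-probability accuracy.
#'
#' @return a list of class `"vc_test"` with `Q`, `lambdas`, `p`, `method`
#'   (`"davies"` or `"liu"`), `K_used` and `direction` (filled by the path
#'   wrappers).
#' @export
vc_score_test <- function(null_fit, M, acc = 1e-9) {
  stopifnot(inherits(null_fit, "null_model"))
  M <- as.matrix(M)
  if (nrow(M) != length(null_fit$residuals))
    stop("mediator rows do not match the null-model samples")
  sds <- apply(M, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep))
    stop("no non-constant mediator columns; gene skipped")
  M <- scale(M[, keep, drop = FALSE])
  K_used <- ncol(M)

  r <- null_fit$residuals
  s <- crossprod(M, r)
  Q <- sum(s * s)

  D <- null_fit$design
  if (null_fit$family == "gaussian") {
    Mp <- qr.resid(null_fit$qr, M)
    A <- crossprod(Mp) * null_fit$sigma2
  } else {
    v <- null_fit$v
    MV <- M * v
    DtVD <- crossprod(D, D * v)
    B <- crossprod(D, MV)
    A <- crossprod(M, MV) - crossprod(B, solve(DtVD, B))
  }
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (Q <= .Machine$double.eps * max(lam, 1)) {
    res <- list(p = 1, method = "davies", abs_error = 0)
  } else {
    res <- quadform_survival(lam, Q, acc = acc)
  }
  structure(list(Q = Q, lambdas = lam, p = res$p, method = res$method,
                 K_used = K_used, direction = NA_character_),
            class = "vc_test")
}

#' Exposure-to-mediator-set path test (inverse regression)
#'
#' Tests the association between a binary exposure and a gene's CpG set by
#' inverse regression: the mediators' effects on the exposure are treated
#' as random, so the test reduces to a variance-component score test
#' against the logistic null `X ~ C`.  The aggregated effect direction is
#' the sign of the summed per-CpG marginal exposure coefficients (each from
#' the linear model `M_k ~ X + C`).
#'
#' @param X binary 0/1 exposure with both classes present.
#' @param M `n x K` mediator block.
#' @param C adjustment covariate matrix.
#' @param null_fit optionally, a pre-fitted logistic `X ~ C` null model to
#'   reuse across genes.
#' @return a `"vc_test"` whose `p` is the exposure-path p-value, with
#'   per-CpG marginal estimates in `marginal` and aggregated `direction`.
#' @export
test_exposure_mediators <- function(X, M, C, null_fit = NULL) {
  X <- as.numeric(X)
  if (!all(X %in% c(0, 1)) || length(unique(X)) < 2L)
    stop("'X' must be binary 0/1 with both classes present")
  if (is.null(null_fit)) null_fit <- fit_null_model(X, C, "binomial")
  res <- vc_score_test(null_fit, M)
  D2 <- cbind(1, X, as.matrix(C))
  est <- drop(solve(crossprod(D2), crossprod(D2, as.matrix(M)))[2L, ])
  res$marginal <- est
  res$direction <- aggregate_direction(est)
  res
}

#' Mediator-set-to-outcome path test adjusting the direct effect
#'
#' Tests the association between a gene's CpG set and the outcome while
#' adjusting for the exposure's direct effect: the null model is
#' `Y ~ X + C` under the outcome family, and the mediator block enters as a
#' variance component.  The aggregated direction is the sign of the summed
#' per-CpG coefficients of `M_k` in `Y ~ M_k + X + C`.
#'
#' @param Y outcome vector.
#' @param M `n x K` mediator block.
#' @param X exposure (included in the adjustment design).
#' @param C adjustment covariate matrix.
#' @param family outcome family.
#' @param null_fit optionally, a pre-fitted `Y ~ X + C` null model.
#' @param compute_direction set `FALSE` to skip the per-CpG direction fits.
#' @return a `"vc_test"` whose `p` is the outcome-path p-value.
#' @export
test_mediators_outcome <- function(Y, M, X, C,
                                   family = c("gaussian", "binomial"),
                                   null_fit = NULL, compute_direction = TRUE) {
  family <- match.arg(family)
  Cx <- cbind(X = as.numeric(X), as.matrix(C))
  if (is.null(null_fit)) null_fit <- fit_null_model(Y, Cx, family)
  res <- vc_score_test(null_fit, M)
  if (compute_direction) {
    M <- as.matrix(M)
    est <- vapply(seq_len(ncol(M)), function(k) {
      Dk <- cbind(1, M[, k], Cx)
      if (family == "gaussian") {
        stats::lm.fit(Dk, as.numeric(Y))$coefficients[2L]
      } else {
        f <- suppressWarnings(stats::glm.fit(Dk, as.numeric(Y),
                                             family = stats::binomial()))
        f$coefficients[2L]
      }
    }, 0)
    res$marginal <- est
    res$direction <- aggregate_direction(est)
  }
  res
}

#' Total-effect test of the exposure on the outcome
#'
#' Estimates the exposure coefficient `c` from `Y ~ X + C` (OLS for the
#' Gaussian family, logistic regression for the binomial family, where the
#' estimate is the log odds ratio) with a Wald 95% confidence interval.
#'
#' @inheritParams test_mediators_outcome
#' @param conf_level confidence level of the Wald interval.
#' @return list of class `"total_effect"` with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `family`, and `odds_ratio`/`or_ci` for the binomial
#'   family.
#' @export
total_effect <- function(Y, X, C, family = c("gaussian", "binomial"),
                         conf_level = 0.95) {
  family <- match.arg(family)
  X <- as.numeric(X)
  if (stats::sd(X) == 0)
    stop("'X' is constant: the total-effect design is rank deficient")
  D <- cbind(`(Intercept)` = 1, X = X, as.matrix(C))
  if (anyNA(D) || anyNA(Y)) stop("missing values; drop samples first")
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("rank-deficient total-effect design")
  n <- nrow(D)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (family == "gaussian") {
    cf <- qr.coef(qrD, as.numeric(Y))
    res <- qr.resid(qrD, as.numeric(Y))
    sigma2 <- sum(res^2) / (n - ncol(D))
    XtXinv <- chol2inv(qr.R(qrD))
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    est <- cf[["X"]]
    p <- if (se == 0) as.numeric(est == 0) else
      2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
    out <- list(estimate = est, se = se, ci_low = est - z * se,
                ci_high = est + z * se, p = p, family = family)
  } else {
    fit <- suppressWarnings(stats::glm.fit(D, as.numeric(Y),
                                           family = stats::binomial()))
    if (!fit$converged) stop("logistic total-effect model did not converge")
    est <- fit$coefficients[["X"]]
    w <- fit$weights
    cov <- chol2inv(chol(crossprod(D, D * w)))
    se <- sqrt(cov[2L, 2L])
    p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
    out <- list(estimate = est, se = se, ci_low = est - z * se,
                ci_high = est + z * se, p = p, family = family,
                odds_ratio = exp(est),
                or_ci = exp(c(est - z * se, est + z * se)))
  }
  class(out) <- "total_effect"
  out
}

#' Per-CpG differential methylation between cases and controls
#'
#' For every probe, the coefficient of case status from the linear model of
#' the M-value on status plus covariates, with Benjamini-Hochberg q-values
#' across all probes tested.  Used to report, per gene, how many member
#' CpGs are individually differentially methylated at FDR 0.05.
#'
#' @param matrix a [methylation_matrix()] on the M-value scale (or a plain
#'   probe x sample matrix).
#' @param case_status binary 0/1 vector, both classes present.
#' @param C covariate matrix (may be `NULL`).
#' @return data.frame with `probe_id`, `estimate`, `p`, `q`.
#' @export
cpg_differential_test <- function(matrix, case_status, C = NULL) {
  vals <- if (inherits(matrix, "methylation_matrix")) matrix$values else
    as.matrix(matrix)
  ids <- if (inherits(matrix, "methylation_matrix")) matrix$probe_ids else
    rownames(vals)
  if (is.null(ids)) ids <- sprintf("probe%05d", seq_len(nrow(vals)))
  s <- as.numeric(case_status)
  if (length(unique(s)) < 2L) stop("both classes must be present")
  D <- if (is.null(C)) cbind(1, status = s) else cbind(1, status = s, as.matrix(C))
  n <- ncol(vals); p <- ncol(D)
  XtXinv <- chol2inv(chol(crossprod(D)))
  coefs <- XtXinv %*% crossprod(D, t(vals))      # p x probes
  fitted <- D %*% coefs
  rss <- colSums((t(vals) - fitted)^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  est <- coefs[2L, ]
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  pval <- 2 * stats::pt(abs(tstat), df = n - p, lower.tail = FALSE)
  data.frame(probe_id = ids, estimate = est, p = pval, q = bh_fdr(pval),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate per-CpG effect estimates into a direction
#'
#' The gene-level direction is the sign of the sum of per-CpG marginal
#' coefficient estimates; an exact zero sum gives `"0"`.
#'
#' @param estimates length-K numeric vector.
#' @return `"+"`, `"-"` or `"0"`.
#' @export
aggregate_direction <- function(estimates) {
  if (length(estimates) == 0L) stop("empty estimate vector")
  s <- sum(estimates)
  if (s > 0) "+" else if (s < 0) "-" else "0"
}
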