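#' ANOVA-type test for equality of predictive values across modalities
#'
#' Tests the hypothesis that all `M` modalities (or flattened
#' reader-by-method cells) share the same predictive value in a given risk
#' group, `H0: T p = 0` with `T = I_M - (1/M) 1 1'` the centering matrix,
#' or any user-supplied symmetric idempotent contrast projection. The
#' statistic is the quadratic form `p_hat' T p_hat / tr(T V)` with `V` the
#' delta-method covariance of the estimators; under `H0` it is approximated
#' by a scaled chi-square (Box-type) distribution `chi^2_f / f` with
#' estimated degrees of freedom `f = tr(T V)^2 / tr((T V)^2)`. For `M = 2`
#' the statistic reduces exactly to the squared standardised difference and
#' `f = 1`, so the p-value coincides with the two-sided normal test of the
#' difference.
#'
#' The test needs the full cross-modality covariance: predictive values of
#' modalities evaluated on the same subjects are dependent, so the test is
#' refused for accuracy built from published summaries
#' ([summary_accuracy()]), where those covariances are unavailable.
#'
#' On the `"logit"` scale the hypothesis is formulated on `logit(p)`; the
#' covariance is transformed by the delta method with the logit link.
#' P-values are reported per group and side without multiplicity
#' adjustment.
#'
#' @param pv a [predictive_values()] result with `M >= 2` modalities from
#'   subject-level data.
#' @param contrast optional `M x M` contrast projection matrix `T`;
#'   defaults to the centering matrix. A symmetric matrix that is not
#'   idempotent is replaced by the orthogonal projector onto its column
#'   space.
#' @param scale `"additive"` (probability scale) or `"logit"`.
#' @return An object of class `ats_result`: `statistic`, `df`, `p_value`,
#'   `contrast`, `scale`.
#' @export
#' @examples
#' tr <- generate_trial(se = c(0.85, 0.8), sp = c(0.9, 0.9), rho = 0.3,
#'                      n1 = 200, n0 = 200, seed = 7)
#' prev <- prevalence_spec("clinic", k = 250, m = 1000)
#' pv <- predictive_values(estimate_accuracy(tr), prev, side = "PPV")
#' ats_test(pv)
ats_test <- function(pv, contrast = NULL, scale = c("additive", "logit")) {
  stopifnot(inherits(pv, "pv_result"))
  scale <- match.arg(scale)
  M <- length(pv$estimates)
  if (M < 2L) stop("the ANOVA-type test needs M >= 2 modalities",
                   call. = FALSE)
  if (!pv$has_cross) {
    stop("the test statistic cannot be computed from summary-level ",
         "accuracy input: cross-modality covariances of the predictive ",
         "values are unavailable; supply subject-level data via ",
         "estimate_accuracy()", call. = FALSE)
  }
  if (any(pv$degenerate) || any(pv$estimates <= 0 | pv$estimates >= 1)) {
    stop("degenerate predictive-value estimates (0 or 1); ",
         "the asymptotic test does not apply", call. = FALSE)
  }
  Tm <- if (is.null(contrast)) {
    diag(M) - matrix(1 / M, M, M)
  } else {
    .as_projection(contrast, M)
  }
  p <- pv$estimates
  V <- pv$cov
  if (scale == "logit") {
    D <- 1 / (p * (1 - p))
    V <- V * tcrossprod(D)
    p <- stats::qlogis(p)
  }
  TV <- Tm %*% V
  tr1 <- sum(diag(TV))
  if (tr1 <= .Machine$double.eps) {
    stop("degenerate covariance: tr(T V) = 0", call. = FALSE)
  }
  stat <- drop(crossprod(p, Tm %*% p)) / tr1
  f <- tr1^2 / sum(TV * t(TV))
  p_value <- stats::pchisq(stat * f, df = f, lower.tail = FALSE)
  structure(
    list(statistic = stat, df = f, p_value = p_value,
         contrast = Tm, scale = scale, group = pv$group, side = pv$side),
    class = "ats_result"
  )
}

# Validate a user-supplied contrast matrix; replace a symmetric
# non-idempotent matrix by the projector onto its column space.
.as_projection <- function(Tm, M) {
  Tm <- as.matrix(Tm)
  if (!all(dim(Tm) == c(M, M))) {
    stop("contrast matrix must be M x M", call. = FALSE)
  }
  if (max(abs(Tm - t(Tm))) > 1e-8) {
    stop("contrast matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(Tm %*% Tm - Tm)) > 1e-8) {
    e <- eigen(Tm, symmetric = TRUE)
    keep <- abs(e$values) > 1e-10 * max(abs(e$values), 1)
    U <- e$vectors[, keep, drop = FALSE]
    Tm <- tcrossprod(U)
  }
  Tm
}

#' @export
print.ats_result <- function(x, ...) {
  cat(sprintf("ANOVA-type test of equal %s across modalities (group '%s', %s scale)\n",
              x$side, x$group, x$scale))
  cat(sprintf("  ATS = %.4f, df = %.3f, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
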