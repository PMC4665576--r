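.pv_methods <- c("additive-normal", "additive-t", "logistic-normal",
                 "logistic-t", "mercaldo-additive", "mercaldo-logistic")

# interval kernel shared with the simulation engine; everything vectorised.
# est, sd in [0,1]/>=0; q is the (vector of) quantiles; returns cbind(lo, hi)
.interval_additive <- function(est, sd, q) {
  cbind(lower = est - q * sd, upper = est + q * sd)
}

.interval_logistic <- function(est, sd, q) {
  lo <- stats::qlogis(est)
  se_logit <- sd / (est * (1 - est))
  cbind(lower = stats::plogis(lo - q * se_logit),
        upper = stats::plogis(lo + q * se_logit))
}

#' Confidence intervals for risk-group predictive values
#'
#' Six interval variants for the per-modality predictive values of one risk
#' group. `additive-*` intervals are `p_hat +/- q * sd` on the probability
#' scale and are deliberately not clipped to \[0, 1\]; `logistic-*`
#' intervals are constructed on the logit scale and back-transformed, so
#' they are range-preserving by construction. The `*-t` variants replace
#' the normal quantile by a t quantile with estimated degrees of freedom
#' ([t_degrees_of_freedom()]), which improves small-sample coverage.
#' `mercaldo-*` variants use the fixed-prevalence variance (prevalence
#' variance set to 0), the convention of treating the pre-test probability
#' as known; they are anti-conservative when the prevalence was in fact
#' estimated.
#'
#' When a point estimate is exactly 0 or 1, the logistic and t variants
#' are undefined (the logit diverges and the estimated df collapses); such
#' intervals are flagged `failed` rather than raising an error, because in
#' simulation use failure is an outcome to be tallied, not an exception.
#'
#' @param pv a [predictive_values()] result.
#' @param method one of `r paste0('"', .pv_methods, '"', collapse = ", ")`.
#' @param alpha two-sided nominal error level (default 0.05).
#' @return A data frame of class `interval_set` with columns `modality`,
#'   `method`, `estimate`, `lower`, `upper`, `df`, `failed`.
#' @export
#' @examples
#' acc <- summary_accuracy(0.8537, 0.8976, 164, 127)
#' prev <- prevalence_spec("nonanginal", k = 146, m = 913)
#' pv <- predictive_values(acc, prev, side = "PPV")
#' confidence_interval(pv, "logistic-normal")
confidence_interval <- function(pv, method = .pv_methods, alpha = 0.05) {
  stopifnot(inherits(pv, "pv_result"))
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  est <- pv$estimates
  M <- length(est)
  fixed <- grepl("^mercaldo", method)
  v <- diag(if (fixed) pv$cov_fixed else pv$cov)
  sdv <- sqrt(pmax(v, 0))
  boundary <- est <= 0 | est >= 1
  use_t <- grepl("-t$", method)
  df <- rep(NA_real_, M)
  if (use_t) {
    df <- unname(t_degrees_of_freedom(pv))
    q <- stats::qt(1 - alpha / 2, df)
  } else {
    q <- rep(stats::qnorm(1 - alpha / 2), M)
  }
  failed <- rep(FALSE, M)
  if (grepl("logistic", method) || use_t) failed <- failed | boundary
  if (use_t) failed <- failed | is.na(df)
  lohi <- matrix(NA_real_, M, 2, dimnames = list(NULL, c("lower", "upper")))
  ok <- !failed
  if (any(ok)) {
    lohi[ok, ] <- if (grepl("logistic", method)) {
      .interval_logistic(est[ok], sdv[ok], q[ok])
    } else {
      .interval_additive(est[ok], sdv[ok], q[ok])
    }
  }
  out <- data.frame(
    modality = names(est), method = method, estimate = unname(est),
    lower = lohi[, "lower"], upper = lohi[, "upper"],
    df = if (use_t) df else NA_real_, failed = failed,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "group") <- pv$group
  attr(out, "side") <- pv$side
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Confidence interval for the difference of two modalities
#'
#' Normal-approximation interval for `p(m1) - p(m2)` with variance
#' `v[m1,m1] + v[m2,m2] - 2 v[m1,m2]`; requires the cross-modality
#' covariance, i.e. accuracy estimated from subject-level data (or `M = 1`
#' duplicated, which degenerates to width zero). The `mercaldo-additive`
#' variant drops the prevalence variance. The t approximation is only
#' defined here for single predictive values, whose variance splits into
#' three binomial sources; for differences the normal quantile is used, as
#' in the defining formula.
#'
#' @param pv a [predictive_values()] result with full covariance.
#' @param m1,m2 modality labels or indices.
#' @param method `"additive-normal"` or `"mercaldo-additive"`.
#' @param alpha two-sided error level.
#' @return One-row data frame with `estimate`, `lower`, `upper`.
#' @export
difference_interval <- function(pv, m1, m2,
                                method = c("additive-normal",
                                           "mercaldo-additive"),
                                alpha = 0.05) {
  stopifnot(inherits(pv, "pv_result"))
  method <- match.arg(method)
  M <- length(pv$estimates)
  cvec <- numeric(M)
  idx <- function(m) {
    i <- if (is.character(m)) match(m, names(pv$estimates)) else as.integer(m)
    if (is.na(i) || i < 1L || i > M) {
      stop("unknown modality: ", m, call. = FALSE)
    }
    i
  }
  i1 <- idx(m1); i2 <- idx(m2)
  cvec[i1] <- cvec[i1] + 1
  cvec[i2] <- cvec[i2] - 1
  contrast_interval(pv, cvec, method = method, alpha = alpha)
}

#' Confidence interval for an arbitrary contrast of predictive values
#'
#' Normal-approximation interval for `c'p` with variance `c' V c`, e.g. a
#' reader-averaging vector `rep(1/M, M)` in a flattened reader-by-method
#' design, or a difference vector `(1, -1)`.
#'
#' @param pv a [predictive_values()] result.
#' @param contrast numeric weight vector of length `M`.
#' @inheritParams difference_interval
#' @return One-row data frame with `estimate`, `lower`, `upper`, `sd`.
#' @export
contrast_interval <- function(pv, contrast,
                              method = c("additive-normal",
                                         "mercaldo-additive"),
                              alpha = 0.05) {
  stopifnot(inherits(pv, "pv_result"))
  method <- match.arg(method)
  M <- length(pv$estimates)
  if (length(contrast) != M) stop("contrast must have length M", call. = FALSE)
  simple <- sum(contrast != 0) <= 1L
  if (!pv$has_cross && M > 1L && !simple) {
    stop("cross-modality covariances are unavailable for summary-level ",
         "input; contrasts over several modalities cannot be computed",
         call. = FALSE)
  }
  V <- if (method == "mercaldo-additive") pv$cov_fixed else pv$cov
  if (!pv$has_cross && simple) V[is.na(V)] <- 0
  est <- sum(contrast * pv$estimates)
  v <- drop(crossprod(contrast, V %*% contrast))
  v <- max(v, 0)
  q <- stats::qnorm(1 - alpha / 2)
  data.frame(estimate = est, sd = sqrt(v),
             lower = est - q * sqrt(v), upper = est + q * sqrt(v))
}

#' Fixed-prevalence (known-pi) predictive-value interval
#'
#' Convenience wrapper reproducing the classical interval that treats the
#' prevalence as a known constant: equivalent to building a fixed
#' [prevalence_spec()] and calling [confidence_interval()]. Useful for
#' comparing against the estimated-prevalence intervals, whose extra
#' variance term widens them whenever `var(pi) > 0`.
#'
#' @param se,sp,pi accuracy and (known) prevalence, strictly in (0, 1).
#' @param n1,n0 group sizes behind `se` and `sp`.
#' @param method `"additive"` or `"logistic"`.
#' @param alpha two-sided error level.
#' @return An `interval_set` data frame (single modality).
#' @export
#' @examples
#' mercaldo_interval(0.8537, 0.8976, 0.16, 164, 127, "logistic")
mercaldo_interval <- function(se, sp, pi, n1, n0,
                              method = c("additive", "logistic"),
                              alpha = 0.05) {
  method <- match.arg(method)
  acc <- summary_accuracy(se, sp, n1, n0)
  prev <- prevalence_spec("fixed", pi = pi, fixed = TRUE)
  pv <- predictive_values(acc, prev, side = "PPV")
  confidence_interval(pv, paste0("mercaldo-", method), alpha = alpha)
}

#' @export
print.interval_set <- function(x, digits = 4, ...) {
  cat(sprintf("%s %s intervals (%s, alpha = %s)\n",
              attr(x, "group") %||% "", attr(x, "side") %||% "",
              x$method[1L], format(attr(x, "alpha"))))
  print.data.frame(cbind(x[, c("modality", "method")],
                         round(x[, c("estimate", "lower", "upper")], digits),
                         x[, "failed", drop = FALSE]),
                   row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
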