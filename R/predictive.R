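# Vectorised kernels shared by the scalar API and the simulation engine.

.pv_check_side <- function(side) {
  side <- toupper(side)
  if (!side %in% c("PPV", "NPV")) stop("side must be 'PPV' or 'NPV'",
                                       call. = FALSE)
  side
}

.pv_point <- function(se, sp, pi, side) {
  if (side == "PPV") {
    se * pi / (se * pi + (1 - sp) * (1 - pi))
  } else {
    sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi)
  }
}

# Partial derivatives of the Bayes transforms w.r.t. (se, sp, pi).
.pv_grad <- function(se, sp, pi, side) {
  if (side == "PPV") {
    S2 <- (se * pi + (1 - sp) * (1 - pi))^2
    list(se = pi * (1 - sp) * (1 - pi) / S2,
         sp = se * pi * (1 - pi) / S2,
         pi = se * (1 - sp) / S2)
  } else {
    S2 <- (sp * (1 - pi) + (1 - se) * pi)^2
    list(se = sp * (1 - pi) * pi / S2,
         sp = (1 - se) * pi * (1 - pi) / S2,
         pi = -sp * (1 - se) / S2)
  }
}

# Degrees of freedom for the t approximation: nu = 2 v^2 / Var_hat(v), where
# v = c_se + c_sp + c_pi is the delta-method variance and Var_hat(v) plugs in
# the asymptotic variance of each binomial variance-component estimator,
# Var(c_i) = c_i^2 (1 - 2 p_i)^2 / (p_i (1 - p_i) n_i). When the point
# estimate sits at 0 or 1 every component vanishes and nu is undefined
# (the denominator is estimated to be 0); when every underlying proportion
# is exactly 1/2 the denominator vanishes while v > 0 and nu -> Inf,
# recovering the normal quantile.
.pv_nu <- function(cse, csp, cpi, se, sp, pi, n1, n0, mg) {
  term <- function(comp, p, n) {
    out <- rep(0, length(comp))
    pos <- is.finite(comp) & comp > 0
    out[pos] <- comp[pos]^2 * (1 - 2 * p[pos])^2 /
      (p[pos] * (1 - p[pos]) * n[pos])
    out
  }
  k <- max(length(cse), length(se))
  n1 <- rep_len(n1, k); n0 <- rep_len(n0, k); mg <- rep_len(mg, k)
  se <- rep_len(se, k); sp <- rep_len(sp, k); pi <- rep_len(pi, k)
  v <- cse + csp + cpi
  varv <- term(cse, se, n1) + term(csp, sp, n0) + term(cpi, pi, mg)
  nu <- ifelse(v > 0, ifelse(varv > 0, 2 * v^2 / varv, Inf), NA_real_)
  nu
}

.check_prob_open <- function(..., what = "arguments") {
  vals <- c(...)
  if (anyNA(vals) || any(vals <= 0 | vals >= 1)) {
    stop(what, " must lie strictly in (0, 1)", call. = FALSE)
  }
  invisible(vals)
}

#' Positive and negative predictive value via Bayes' theorem
#'
#' `ppv()` returns `se*pi / (se*pi + (1-sp)*(1-pi))`, the probability that
#' a subject with a positive test is diseased; `npv()` returns
#' `sp*(1-pi) / (sp*(1-pi) + (1-se)*pi)`, the probability that a subject
#' with a negative test is disease-free. Vectorised over all arguments.
#'
#' @param se,sp,pi sensitivity, specificity and pre-test prevalence, all
#'   strictly in (0, 1).
#' @return Numeric vector of predictive values in (0, 1).
#' @export
#' @examples
#' ppv(0.8537, 0.8976, 0.16)
#' npv(0.8537, 0.8976, 0.16)
ppv <- function(se, sp, pi) {
  .check_prob_open(se, sp, pi, what = "se, sp and pi")
  .pv_point(se, sp, pi, "PPV")
}

#' @rdname ppv
#' @export
npv <- function(se, sp, pi) {
  .check_prob_open(se, sp, pi, what = "se, sp and pi")
  .pv_point(se, sp, pi, "NPV")
}

#' Gradient of a predictive value in (se, sp, pi)
#'
#' Analytic partial derivatives of the Bayes transform, the building block
#' of the delta-method covariance of predictive-value estimators.
#'
#' @inheritParams ppv
#' @param side `"PPV"` or `"NPV"`.
#' @return Named numeric 3-vector `(se, sp, pi)` of partial derivatives.
#' @export
#' @examples
#' pv_gradient(0.85, 0.9, 0.16, side = "PPV")
pv_gradient <- function(se, sp, pi, side = c("PPV", "NPV")) {
  side <- .pv_check_side(match.arg(side))
  .check_prob_open(se, sp, pi, what = "se, sp and pi")
  g <- .pv_grad(se, sp, pi, side)
  c(se = g$se, sp = g$sp, pi = g$pi)
}

#' Risk-group predictive values with delta-method covariance
#'
#' Combines modality-level accuracy estimates with a risk group's
#' prevalence into the vector of positive (or negative) predictive values
#' for that group, together with the finite-sample covariance matrix of the
#' estimators obtained by the multivariate delta method. The three sources
#' of sampling variation — sensitivity (diseased group, size `n1`),
#' specificity (non-diseased group, size `n0`) and prevalence (prior study,
#' size `m_g`) — are independent; the prevalence estimate is shared across
#' modalities and therefore fully correlated between them. A second
#' covariance in which the prevalence variance is set to zero (the
#' fixed-prevalence convention) is carried along for the corresponding
#' interval variants.
#'
#' @param acc an [estimate_accuracy()] or [summary_accuracy()] result.
#' @param prev a [prevalence_spec()].
#' @param group label of the risk group to use; may be omitted when `prev`
#'   holds a single group.
#' @param side `"PPV"` or `"NPV"`.
#' @return An object of class `pv_result`: estimates, covariance `cov`,
#'   fixed-prevalence covariance `cov_fixed`, the inputs used, and the
#'   per-modality variance components needed by the t approximation.
#' @seealso [confidence_interval()], [ats_test()], [difference_interval()]
#' @export
#' @examples
#' acc <- summary_accuracy(0.8537, 0.8976, 164, 127)
#' prev <- prevalence_spec("nonanginal", k = 146, m = 913)
#' predictive_values(acc, prev, side = "PPV")
predictive_values <- function(acc, prev, group = NULL,
                              side = c("PPV", "NPV")) {
  stopifnot(inherits(acc, "accuracy_summary"),
            inherits(prev, "prevalence_spec"))
  side <- .pv_check_side(match.arg(side))
  if (is.null(group)) {
    if (nrow(prev) != 1L) {
      stop("prev holds several groups; specify `group`", call. = FALSE)
    }
    group <- prev$label[1L]
  }
  i <- match(group, prev$label)
  if (is.na(i)) stop("unknown risk group '", group, "'", call. = FALSE)
  pi <- prev$pi[i]
  var_pi <- prev$var_pi[i]
  mg <- if (prev$fixed[i]) Inf else prev$m[i]

  se <- acc$se
  sp <- acc$sp
  M <- length(se)
  degenerate <- se %in% c(0, 1) | sp %in% c(0, 1)
  g <- .pv_grad(se, sp, pi, side)
  est <- .pv_point(se, sp, pi, side)

  gse <- g$se; gsp <- g$sp; gpi <- g$pi
  cov_fixed <- tcrossprod(gse) * acc$cov_se + tcrossprod(gsp) * acc$cov_sp
  cov <- cov_fixed + var_pi * tcrossprod(gpi)
  dimnames(cov) <- dimnames(cov_fixed) <-
    list(acc$modality_labels, acc$modality_labels)
  names(est) <- acc$modality_labels

  components <- cbind(se = gse^2 * diag(acc$cov_se),
                      sp = gsp^2 * diag(acc$cov_sp),
                      pi = gpi^2 * var_pi)
  rownames(components) <- acc$modality_labels

  structure(
    list(group = group, side = side, estimates = est,
         cov = cov, cov_fixed = cov_fixed,
         components = components, degenerate = degenerate,
         se = se, sp = sp, pi = pi, var_pi = var_pi,
         n1 = acc$n1, n0 = acc$n0, m_g = mg,
         has_cross = acc$has_cross,
         acc = acc, prev = prev[i, , drop = FALSE]),
    class = "pv_result"
  )
}

#' @export
print.pv_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s for risk group '%s' (pi = %.4f%s)\n", x$side, x$group,
              x$pi, if (x$var_pi == 0) ", fixed" else ""))
  tab <- data.frame(modality = names(x$estimates),
                    estimate = round(x$estimates, digits),
                    sd = round(sqrt(diag(x$cov)), digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Degrees of freedom for the t-approximated interval
#'
#' Matches a scaled chi-square to the estimated delta-method variance of a
#' predictive value: `nu = 2 v^2 / Var(v)`, with `Var(v)` assembled from
#' the asymptotic variances of the three binomial variance components
#' (sensitivity, specificity, prevalence). When a single component carries
#' all the variance the formula collapses towards that component's own
#' effective df; when the point estimate is degenerate (0 or 1) the
#' variance is 0 and `nu` is undefined (`NA`), which is exactly the case
#' where the t interval is reported as failed.
#'
#' @param pv a [predictive_values()] result.
#' @param modality modality label or index (default: all).
#' @return Numeric vector of degrees of freedom (possibly `Inf` or `NA`).
#' @export
t_degrees_of_freedom <- function(pv, modality = NULL) {
  stopifnot(inherits(pv, "pv_result"))
  idx <- if (is.null(modality)) seq_along(pv$estimates) else modality
  if (is.character(idx)) idx <- match(idx, names(pv$estimates))
  comp <- pv$components[idx, , drop = FALSE]
  nu <- .pv_nu(comp[, "se"], comp[, "sp"], comp[, "pi"],
               pv$se[idx], pv$sp[idx], rep(pv$pi, length(idx)),
               pv$n1, pv$n0, pv$m_g)
  names(nu) <- names(pv$estimates)[idx]
  nu
}
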