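#' Estimate sensitivity and specificity with their joint covariance
#'
#' Per-modality sensitivity is the fraction of diseased subjects testing
#' positive; specificity the fraction of non-diseased subjects testing
#' negative. Because all modalities are applied to the same subjects, the
#' estimators are correlated within each disease group:
#' `cov(se_l, se_r) = (P_lr - se_l se_r) / n1`, with `P_lr` the proportion
#' of diseased subjects positive on both modalities (analogously for
#' specificity from joint negatives among the non-diseased). The diseased
#' and non-diseased blocks are independent, so the cross-covariance between
#' sensitivity and specificity estimators is identically zero. Covariances
#' use the plug-in (maximum-likelihood) denominator `n_i`, the binomial
#' convention under which the worked-example intervals reproduce.
#'
#' @param table a [trial_data()] object.
#' @return An object of class `accuracy_summary` with components `se`, `sp`
#'   (named numeric vectors), `n1`, `n0`, `cov_se`, `cov_sp` (M x M
#'   matrices) and `has_cross = TRUE`. Boundary estimates (0 or 1) are
#'   allowed but trigger a warning, since downstream asymptotics assume all
#'   probabilities strictly inside (0, 1).
#' @seealso [summary_accuracy()] for summary-level input without
#'   cross-modality covariance.
#' @export
#' @examples
#' tr <- generate_trial(se = c(0.85, 0.80), sp = c(0.9, 0.9), rho = 0.3,
#'                      n1 = 100, n0 = 100, seed = 1)
#' estimate_accuracy(tr)
estimate_accuracy <- function(table) {
  stopifnot(inherits(table, "trial_data"))
  d <- table$results[table$gold == 1L, , drop = FALSE]
  h <- 1L - table$results[table$gold == 0L, , drop = FALSE]
  n1 <- nrow(d)
  n0 <- nrow(h)
  se <- colMeans(d)
  sp <- colMeans(h)
  # joint positive (resp. negative) proportions give the covariances
  P1 <- crossprod(d) / n1
  P0 <- crossprod(h) / n0
  cov_se <- (P1 - tcrossprod(se)) / n1
  cov_sp <- (P0 - tcrossprod(sp)) / n0
  if (any(se %in% c(0, 1)) || any(sp %in% c(0, 1))) {
    warning("sensitivity or specificity estimated at 0 or 1; ",
            "asymptotic intervals and tests may be unreliable",
            call. = FALSE)
  }
  new_accuracy_summary(se, sp, n1, n0, cov_se, cov_sp, has_cross = TRUE)
}

#' Accuracy summary from published estimates
#'
#' Builds an `accuracy_summary` when only the published sensitivities,
#' specificities and group sizes of a trial are available. Variances are
#' the binomial `p(1-p)/n`; the cross-modality covariances cannot be
#' recovered from summaries, so the object is marked accordingly and the
#' ANOVA-type test (which needs them) refuses such input. Per-modality
#' confidence intervals remain available.
#'
#' @param se,sp numeric vectors in (0, 1), one entry per modality.
#' @param n1,n0 numbers of diseased and non-diseased subjects used to
#'   estimate `se` and `sp`.
#' @param modality_labels optional modality names.
#' @return An `accuracy_summary` with diagonal covariance matrices and
#'   `has_cross = FALSE`.
#' @export
#' @examples
#' summary_accuracy(se = 0.8537, sp = 0.8976, n1 = 164, n0 = 127)
summary_accuracy <- function(se, sp, n1, n0, modality_labels = NULL) {
  if (length(se) != length(sp)) stop("se and sp must have equal length",
                                     call. = FALSE)
  if (any(se <= 0 | se >= 1) || any(sp <= 0 | sp >= 1)) {
    stop("summary se and sp values must lie strictly in (0, 1)",
         call. = FALSE)
  }
  stopifnot(n1 >= 1, n0 >= 1)
  M <- length(se)
  if (is.null(modality_labels)) modality_labels <- paste0("mod", seq_len(M))
  names(se) <- names(sp) <- modality_labels
  cov_se <- diag(se * (1 - se) / n1, M)
  cov_sp <- diag(sp * (1 - sp) / n0, M)
  # off-diagonal joint proportions are unknown, not zero
  if (M > 1L) {
    cov_se[upper.tri(cov_se)] <- cov_se[lower.tri(cov_se)] <- NA_real_
    cov_sp[upper.tri(cov_sp)] <- cov_sp[lower.tri(cov_sp)] <- NA_real_
  }
  dimnames(cov_se) <- dimnames(cov_sp) <- list(modality_labels, modality_labels)
  new_accuracy_summary(se, sp, n1, n0, cov_se, cov_sp, has_cross = FALSE)
}

new_accuracy_summary <- function(se, sp, n1, n0, cov_se, cov_sp, has_cross) {
  labels <- names(se)
  structure(
    list(se = se, sp = sp, n1 = as.integer(n1), n0 = as.integer(n0),
         cov_se = cov_se, cov_sp = cov_sp,
         modality_labels = labels, has_cross = has_cross),
    class = "accuracy_summary"
  )
}

#' @export
print.accuracy_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Diagnostic accuracy (M = %d, n1 = %d, n0 = %d)\n",
              length(x$se), x$n1, x$n0))
  tab <- data.frame(
    modality = x$modality_labels,
    se = round(x$se, digits), `sd(se)` = round(sqrt(diag(x$cov_se)), digits),
    sp = round(x$sp, digits), `sd(sp)` = round(sqrt(diag(x$cov_sp)), digits),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  if (!x$has_cross && length(x$se) > 1L) {
    cat("(summary-level input: cross-modality covariances unavailable)\n")
  }
  invisible(x)
}
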