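#' Predictive-value report across risk groups, sides and methods
#'
#' Convenience wrapper assembling the full grid of predictive-value
#' estimates and confidence intervals: every risk group in `prev`, both
#' sides, every requested interval method, every modality. This is the
#' table a study report prints.
#'
#' @param acc an [estimate_accuracy()] or [summary_accuracy()] result.
#' @param prev a [prevalence_spec()] with one or more groups.
#' @param sides predictive values to include.
#' @param methods interval methods (see [confidence_interval()]).
#' @param alpha two-sided nominal error level.
#' @return A data frame with columns `group`, `side`, `modality`,
#'   `method`, `estimate`, `lower`, `upper`, `df`, `failed`.
#' @export
#' @examples
#' acc <- summary_accuracy(140 / 164, 114 / 127, 164, 127)
#' prev <- prevalence_spec(c("nonanginal", "atypical", "typical"),
#'                         k = c(146, 963, 1874), m = c(913, 1931, 2108))
#' pv_table(acc, prev, methods = "logistic-normal")
pv_table <- function(acc, prev, sides = c("PPV", "NPV"),
                     methods = c("additive-normal", "additive-t",
                                 "logistic-normal", "logistic-t"),
                     alpha = 0.05) {
  stopifnot(inherits(acc, "accuracy_summary"),
            inherits(prev, "prevalence_spec"))
  methods <- match.arg(methods, .pv_methods, several.ok = TRUE)
  out <- list()
  for (g in prev$label) {
    for (side in sides) {
      pv <- predictive_values(acc, prev, group = g, side = side)
      for (m in methods) {
        ci <- confidence_interval(pv, m, alpha = alpha)
        out[[length(out) + 1L]] <- data.frame(
          group = g, side = side, ci[, c("modality", "method", "estimate",
                                         "lower", "upper", "df", "failed")],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
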