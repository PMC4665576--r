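#' Risk-group prevalence specification
#'
#' Pre-test probabilities of disease for one or more risk groups, either
#' estimated from prior prevalence studies as `k/m` (diseased out of total,
#' with binomial variance `pi(1-pi)/m`) or fixed at a known value with
#' variance zero. The fixed-variance convention reproduces the classical
#' approach that treats the prevalence as a known parameter; supplying
#' counts lets the prevalence uncertainty propagate into predictive-value
#' variances, which is the point of this package.
#'
#' Prevalences of exactly 0 or 1 are rejected: the asymptotic theory
#' requires all probabilities in the open interval (0, 1).
#'
#' @param label character vector of group names.
#' @param k,m integer vectors: diseased count and total count per group
#'   (for estimated groups). Use `NA` entries for groups given by `pi`.
#' @param pi numeric vector of known prevalences for fixed groups.
#' @param fixed logical vector, `TRUE` for groups whose prevalence is
#'   treated as known (variance 0).
#'
#' @return An object of class `prevalence_spec`: a data frame with columns
#'   `label`, `k`, `m`, `pi`, `var_pi`, `fixed`.
#' @export
#' @examples
#' prevalence_spec(c("nonanginal", "atypical"), k = c(146, 963),
#'                 m = c(913, 1931))
#' prevalence_spec("screening", pi = 0.16, fixed = TRUE)
prevalence_spec <- function(label, k = NA_integer_, m = NA_integer_,
                            pi = NA_real_, fixed = FALSE) {
  G <- length(label)
  df <- data.frame(
    label = as.character(label),
    k = rep_len(as.numeric(k), G),
    m = rep_len(as.numeric(m), G),
    pi = rep_len(as.numeric(pi), G),
    var_pi = NA_real_,
    fixed = rep_len(as.logical(fixed), G),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$label)) stop("duplicated group labels", call. = FALSE)
  for (i in seq_len(G)) {
    if (df$fixed[i]) {
      if (is.na(df$pi[i])) stop("fixed group '", df$label[i],
                                "' needs a pi value", call. = FALSE)
      df$var_pi[i] <- 0
    } else {
      if (is.na(df$k[i]) || is.na(df$m[i])) {
        stop("estimated group '", df$label[i],
             "' needs counts k and m", call. = FALSE)
      }
      if (df$m[i] < 1 || df$k[i] < 0 || df$k[i] > df$m[i]) {
        stop("invalid counts for group '", df$label[i], "': k=", df$k[i],
             ", m=", df$m[i], call. = FALSE)
      }
      if (df$k[i] == 0 || df$k[i] == df$m[i]) {
        stop("group '", df$label[i], "' has prevalence estimate ",
             df$k[i] / df$m[i], "; prevalences must lie strictly in (0, 1) ",
             "for the asymptotic theory to apply", call. = FALSE)
      }
      df$pi[i] <- df$k[i] / df$m[i]
      df$var_pi[i] <- df$pi[i] * (1 - df$pi[i]) / df$m[i]
    }
    if (df$pi[i] <= 0 || df$pi[i] >= 1) {
      stop("group '", df$label[i], "' has prevalence ", df$pi[i],
           " outside (0, 1)", call. = FALSE)
    }
  }
  class(df) <- c("prevalence_spec", "data.frame")
  df
}

#' Build a prevalence specification from heterogeneous entries
#'
#' Accepts a list of per-group entries, each either `list(label, k = , m = )`
#' for an estimated prevalence or `list(label, pi = , fixed = TRUE)` for a
#' known one, or a data frame with those columns. Convenience front end for
#' [prevalence_spec()] used by the command-line interface.
#'
#' @param spec a list of entries or a data frame.
#' @return A `prevalence_spec` object.
#' @export
#' @examples
#' read_prevalence(list(
#'   list(label = "atypical angina", k = 963, m = 1931),
#'   list(label = "screening", pi = 0.16, fixed = TRUE)
#' ))
read_prevalence <- function(spec) {
  if (is.data.frame(spec)) {
    get <- function(nm, default) if (nm %in% names(spec)) spec[[nm]] else default
    return(prevalence_spec(spec$label,
                           k = get("k", NA), m = get("m", NA),
                           pi = get("pi", NA), fixed = get("fixed", FALSE)))
  }
  if (!is.list(spec) || length(spec) == 0L) {
    stop("spec must be a non-empty list or data frame", call. = FALSE)
  }
  one <- function(e) {
    e <- as.list(e)
    if (is.null(e$label)) e$label <- e[[1L]]
    data.frame(label = as.character(e$label),
               k = if (is.null(e$k)) NA_real_ else as.numeric(e$k),
               m = if (is.null(e$m)) NA_real_ else as.numeric(e$m),
               pi = if (is.null(e$pi)) NA_real_ else as.numeric(e$pi),
               fixed = isTRUE(e$fixed))
  }
  df <- do.call(rbind, lapply(spec, one))
  prevalence_spec(df$label, k = df$k, m = df$m, pi = df$pi, fixed = df$fixed)
}

#' @export
print.prevalence_spec <- function(x, ...) {
  cat(sprintf("Prevalence specification (%d risk group%s)\n", nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  for (i in seq_len(nrow(x))) {
    if (x$fixed[i]) {
      cat(sprintf("  %-24s pi = %.4f (fixed, var 0)\n", x$label[i], x$pi[i]))
    } else {
      cat(sprintf("  %-24s pi = %.4f  (%d/%d, var %.3e)\n", x$label[i],
                  x$pi[i], as.integer(x$k[i]), as.integer(x$m[i]),
                  x$var_pi[i]))
    }
  }
  invisible(x)
}
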