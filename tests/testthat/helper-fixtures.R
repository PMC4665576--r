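# Shared fixtures, all built in code.

# CAD worked example: 140 true positives, 13 false positives, 24 false
# negatives, 114 true negatives (n1 = 164 diseased, n0 = 127 non-diseased).
cad_counts <- c(tp = 140L, fp = 13L, fn = 24L, tn = 114L)

cad_trial <- function() {
  gold <- c(rep(1L, 140), rep(0L, 13), rep(1L, 24), rep(0L, 114))
  res <- c(rep(1L, 153), rep(0L, 138))
  trial_data(sprintf("p%03d", seq_along(gold)), gold,
             matrix(res, ncol = 1), modality_labels = "mdcta")
}

cad_prev <- function() {
  prevalence_spec(c("nonanginal", "atypical", "typical"),
                  k = c(146, 963, 1874), m = c(913, 1931, 2108))
}

cad_accuracy <- function() estimate_accuracy(cad_trial())

# Table of the published interval endpoints for the CAD example
# (rows: group x side; one column pair per interval method).
cad_reference_intervals <- function() {
  ref <- rbind(
    c("nonanginal", "PPV", 0.614, 0.483, 0.744, 0.480, 0.747, 0.478, 0.733, 0.474, 0.736),
    c("nonanginal", "NPV", 0.970, 0.958, 0.982, 0.957, 0.982, 0.955, 0.980, 0.955, 0.980),
    c("atypical",   "PPV", 0.892, 0.842, 0.943, 0.840, 0.945, 0.830, 0.933, 0.828, 0.935),
    c("atypical",   "NPV", 0.860, 0.814, 0.907, 0.814, 0.907, 0.807, 0.901, 0.807, 0.901),
    c("typical",    "PPV", 0.985, 0.977, 0.993, 0.977, 0.993, 0.975, 0.991, 0.975, 0.991),
    c("typical",    "NPV", 0.434, 0.336, 0.532, 0.335, 0.533, 0.339, 0.533, 0.338, 0.534)
  )
  out <- data.frame(group = ref[, 1], side = ref[, 2],
                    apply(ref[, -(1:2)], 2, as.numeric))
  names(out)[3:11] <- c("estimate", "add_lo", "add_hi", "addt_lo", "addt_hi",
                        "log_lo", "log_hi", "logt_lo", "logt_hi")
  out
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() system.file("cli", "pvtrial.R", package = "pvtrial")

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(rscript_bin(), c(shQuote(cli_script()), args),
            stdout = TRUE, stderr = TRUE)
  )
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
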