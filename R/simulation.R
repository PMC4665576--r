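#' Design of a coverage-probability study
#'
#' Fully crossed grid of true prevalence, sensitivity, specificity,
#' accuracy-study size (`n = n0 = n1`) and prevalence-study size `mg`. The
#' defaults are the benchmark design used throughout this package:
#' 48 (pi, se, sp) combinations crossed with 3 x 3 study sizes, i.e. 432
#' cells, 10,000 replicates each, at the 95% level. `n` and `mg` are
#' treated as fully crossed, not paired.
#'
#' @param pi,se,sp,n,mg grids of true parameter values.
#' @param reps replicates per cell.
#' @param alpha two-sided nominal error level.
#' @param seed base seed; each cell derives its own sub-stream seed from it
#'   so results do not depend on evaluation order.
#' @param sides which predictive values to study.
#' @return An object of class `simulation_design` with the cell grid.
#' @export
simulation_design <- function(pi = c(0.05, 0.25, 0.5),
                              se = c(0.5, 0.75, 0.85, 0.9),
                              sp = c(0.5, 0.75, 0.85, 0.9),
                              n = c(50, 100, 500),
                              mg = c(100, 500, 1000),
                              reps = 10000, alpha = 0.05, seed = 1,
                              sides = c("PPV", "NPV")) {
  .check_prob_open(pi, se, sp, what = "pi, se and sp grids")
  stopifnot(all(n >= 1), all(mg >= 1), reps >= 1, alpha > 0, alpha < 1)
  sides <- match.arg(toupper(sides), c("PPV", "NPV"), several.ok = TRUE)
  grid <- expand.grid(pi = pi, se = se, sp = sp, n = n, mg = mg,
                      KEEP.OUT.ATTRS = FALSE)
  structure(
    list(grid = grid, reps = as.integer(reps), alpha = alpha,
         seed = as.integer(seed), sides = sides, methods = .pv_methods),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("Coverage study design: %d cells x %d replicates, alpha = %s, sides: %s\n",
              nrow(x$grid), x$reps, format(x$alpha),
              paste(x$sides, collapse = ", ")))
  invisible(x)
}

# One simulation cell, fully vectorised over replicates. Draws plug-in
# binomial estimates of se, sp and pi, forms each interval variant and
# scores coverage of the true predictive value, interval length and
# failure. A replicate fails when the plug-in predictive value is 0, 1 or
# undefined; failed replicates are excluded from the coverage and length
# denominators of the methods for which the interval does not exist
# (logistic and t variants), and from every method's denominator when the
# estimate itself is undefined (0/0). The fixed-prevalence variants reuse
# the same draws but omit the prevalence variance.
.simulate_cell <- function(se, sp, pi, n, mg, reps, alpha, sides, seed) {
  set.seed(seed)
  seh <- stats::rbinom(reps, n, se) / n
  sph <- stats::rbinom(reps, n, sp) / n
  pih <- stats::rbinom(reps, mg, pi) / mg
  z <- stats::qnorm(1 - alpha / 2)
  out <- vector("list", length(sides))
  names(out) <- sides
  for (side in sides) {
    ptrue <- .pv_point(se, sp, pi, side)
    p <- .pv_point(seh, sph, pih, side)
    g <- .pv_grad(seh, sph, pih, side)
    cse <- g$se^2 * seh * (1 - seh) / n
    csp <- g$sp^2 * sph * (1 - sph) / n
    cpi <- g$pi^2 * pih * (1 - pih) / mg
    v <- cse + csp + cpi
    vfix <- cse + csp
    sdv <- sqrt(v)
    sdf <- sqrt(vfix)
    fail <- !is.finite(p) | p <= 0 | p >= 1
    nu <- .pv_nu(cse, csp, cpi, seh, sph, pih, n, n, mg)
    tq <- rep(NA_real_, reps)
    okn <- !is.na(nu)
    tq[okn] <- stats::qt(1 - alpha / 2, nu[okn])
    score <- function(bounds, valid) {
      cov <- (bounds[, 1L] <= ptrue & ptrue <= bounds[, 2L])[valid]
      len <- (bounds[, 2L] - bounds[, 1L])[valid]
      c(coverage = if (length(cov)) mean(cov) else NA_real_,
        length = if (length(len)) mean(len) else NA_real_,
        failure = mean(fail), n_used = sum(valid))
    }
    est_ok <- is.finite(p)
    ok <- !fail & !is.na(tq)
    res <- rbind(
      `additive-normal` = score(.interval_additive(p, sdv, z), est_ok),
      `additive-t` = score(.interval_additive(p, sdv, tq), ok),
      `logistic-normal` = score(.interval_logistic(p, sdv, z), !fail),
      `logistic-t` = score(.interval_logistic(p, sdv, tq), ok),
      `mercaldo-additive` = score(.interval_additive(p, sdf, z), est_ok),
      `mercaldo-logistic` = score(.interval_logistic(p, sdf, z), !fail)
    )
    out[[side]] <- res
  }
  out
}

#' Run a coverage-probability study
#'
#' For every cell of the design, draws `reps` independent binomial plug-in
#' estimates of sensitivity, specificity and prevalence, builds all six
#' interval variants per replicate, and records the empirical coverage of
#' the true predictive value, the mean interval length and the failure
#' rate. The point estimator is identical across methods, so a single
#' plug-in computation feeds all six intervals in each replicate. Seeded
#' per cell from the design's base seed, so results are reproducible and
#' independent of cell evaluation order.
#'
#' @param design a [simulation_design()].
#' @return An object of class `coverage_study`: component `cells` is a
#'   long data frame (one row per cell x side x method) with columns
#'   `coverage`, `mean_length`, `failure_rate`, `n_used`; `design` is the
#'   design. Use [summary.coverage_study()] for the marginal table.
#' @export
#' @examples
#' d <- simulation_design(pi = 0.25, se = 0.85, sp = 0.9, n = 100,
#'                        mg = 500, reps = 200, seed = 42)
#' run_coverage_study(d)
run_coverage_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  grid <- design$grid
  n_methods <- length(design$methods)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- (design$seed * 100003 + i) %% 2147483647
    res <- .simulate_cell(grid$se[i], grid$sp[i], grid$pi[i], grid$n[i],
                          grid$mg[i], design$reps, design$alpha,
                          design$sides, cell_seed)
    per_side <- lapply(design$sides, function(s) {
      m <- res[[s]]
      data.frame(grid[i, , drop = FALSE], side = s,
                 method = rownames(m), coverage = m[, "coverage"],
                 mean_length = m[, "length"], failure_rate = m[, "failure"],
                 n_used = m[, "n_used"], row.names = NULL)
    })
    rows[[i]] <- do.call(rbind, per_side)
  }
  cells <- do.call(rbind, rows)
  structure(list(cells = cells, design = design), class = "coverage_study")
}

#' Marginal summary of a coverage study
#'
#' Condenses the per-cell results in the conventional benchmark layout:
#' one row per fixed parameter value (each of `pi`, `se`, `sp`, `mg`, `n`
#' held fixed while averaging over all remaining parameters) plus an
#' `Overall` row, for each side and summary quantity. Marginal rows are
#' exact unweighted means of their constituent cells.
#'
#' @param object a [run_coverage_study()] result.
#' @param quantity `"coverage"`, `"mean_length"` or `"failure_rate"`.
#' @param ... unused.
#' @return A data frame: `side`, `parameter`, `value`, one column per
#'   interval method.
#' @export
summary.coverage_study <- function(object,
                                   quantity = c("coverage", "mean_length",
                                                "failure_rate"), ...) {
  quantity <- match.arg(quantity)
  cells <- object$cells
  methods <- object$design$methods
  out <- list()
  for (side in unique(cells$side)) {
    cs <- cells[cells$side == side, ]
    marg <- function(param, value) {
      sub <- if (param == "Overall") cs else cs[cs[[param]] == value, ]
      vals <- vapply(methods, function(m) {
        mean(sub[[quantity]][sub$method == m], na.rm = TRUE)
      }, numeric(1))
      data.frame(side = side, parameter = param,
                 value = if (param == "Overall") NA_real_ else value,
                 as.list(vals), check.names = FALSE)
    }
    for (param in c("pi", "se", "sp", "mg", "n")) {
      for (value in sort(unique(cs[[param]]))) {
        out[[length(out) + 1L]] <- marg(param, value)
      }
    }
    out[[length(out) + 1L]] <- marg("Overall", NA)
  }
  do.call(rbind, out)
}

#' @export
print.coverage_study <- function(x, ...) {
  cat(sprintf("Coverage study: %d cells x %d replicates\n",
              nrow(x$design$grid), x$design$reps))
  s <- summary(x, "coverage")
  ov <- s[s$parameter == "Overall", ]
  cat("Overall coverage:\n")
  print(cbind(ov["side"], round(ov[x$design$methods], 4)), row.names = FALSE)
  invisible(x)
}

#' Write a coverage study to CSV files
#'
#' Emits the marginal summary tables (coverage, mean length, failure rate)
#' and the long per-cell table.
#'
#' @param study a [run_coverage_study()] result.
#' @param prefix path prefix; files `<prefix>_coverage.csv`,
#'   `<prefix>_length.csv`, `<prefix>_failure.csv`, `<prefix>_cells.csv`
#'   are written.
#' @return Character vector of written paths, invisibly.
#' @export
write_coverage_study <- function(study, prefix) {
  stopifnot(inherits(study, "coverage_study"))
  paths <- c()
  for (q in c("coverage", "mean_length", "failure_rate")) {
    tag <- c(coverage = "coverage", mean_length = "length",
             failure_rate = "failure")[[q]]
    p <- paste0(prefix, "_", tag, ".csv")
    utils::write.csv(summary(study, q), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_cells.csv")
  utils::write.csv(study$cells, p, row.names = FALSE)
  invisible(c(paths, p))
}
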