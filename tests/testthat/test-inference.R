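make_pv <- function(seed = 1, se = c(0.85, 0.78), sp = c(0.9, 0.84),
                    rho = 0.35, n = 200, side = "PPV") {
  tr <- generate_trial(se = se, sp = sp, rho = rho, n1 = n, n0 = n,
                       seed = seed)
  predictive_values(estimate_accuracy(tr),
                    prevalence_spec("g", k = 250, m = 1000), side = side)
}

test_that("equal estimates give a null ATS with p-value 1", {
  tr <- generate_trial(se = 0.8, sp = 0.85, rho = 0, n1 = 100, n0 = 100,
                       seed = 4)
  tr2 <- trial_data(tr$subject_id, tr$gold, cbind(tr$results, tr$results),
                    modality_labels = c("a", "b"))
  pv <- predictive_values(estimate_accuracy(tr2),
                          prevalence_spec("g", k = 30, m = 100), side = "PPV")
  expect_error(ats_test(pv), "tr\\(T V\\) = 0") # duplicated: T V vanishes

  # distinct modalities, identical estimates by construction
  pv2 <- make_pv(seed = 8)
  pv2$estimates[2] <- pv2$estimates[1]
  at <- ats_test(pv2)
  expect_equal(at$statistic, 0, tolerance = 1e-12)
  expect_equal(at$p_value, 1)
})

test_that("for M = 2 the ATS is the squared standardised difference with df 1", {
  for (seed in c(3, 17, 29)) {
    pv <- make_pv(seed = seed)
    at <- ats_test(pv)
    expect_equal(at$df, 1, tolerance = 1e-12)
    v <- pv$cov
    zstat <- (pv$estimates[1] - pv$estimates[2]) /
      sqrt(v[1, 1] + v[2, 2] - 2 * v[1, 2])
    expect_equal(at$statistic, unname(zstat^2), tolerance = 1e-12)
    expect_equal(at$p_value, 2 * pnorm(-abs(unname(zstat))),
                 tolerance = 1e-12)
    # and the Wald interval of the difference excludes 0 iff p < alpha
    di <- difference_interval(pv, 1, 2)
    expect_equal((di$lower > 0 | di$upper < 0), at$p_value < 0.05)
  }
})

test_that("ATS is invariant under permutation of modality labels", {
  tr <- generate_trial(se = c(0.85, 0.7, 0.9), sp = c(0.9, 0.8, 0.75),
                       rho = 0.3, n1 = 150, n0 = 150, seed = 13)
  prev <- prevalence_spec("g", k = 200, m = 800)
  pv <- predictive_values(estimate_accuracy(tr), prev, side = "NPV")
  perm <- c(3, 1, 2)
  tr_p <- trial_data(tr$subject_id, tr$gold, tr$results[, perm],
                     modality_labels = tr$modality_labels[perm])
  pv_p <- predictive_values(estimate_accuracy(tr_p), prev, side = "NPV")
  a1 <- ats_test(pv)
  a2 <- ats_test(pv_p)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-12)
  expect_equal(a1$df, a2$df, tolerance = 1e-12)
  expect_equal(a1$p_value, a2$p_value, tolerance = 1e-12)
})

test_that("logit-scale ATS agrees with additive for M = 2 up to the link", {
  pv <- make_pv(seed = 23)
  at <- ats_test(pv, scale = "logit")
  expect_equal(at$df, 1, tolerance = 1e-12)
  expect_true(at$p_value > 0 && at$p_value <= 1)
})

test_that("contrast intervals reduce to difference intervals and respect PSD", {
  pv <- make_pv(seed = 19)
  ci_c <- contrast_interval(pv, c(1, -1))
  ci_d <- difference_interval(pv, 1, 2)
  expect_equal(ci_c$lower, ci_d$lower)
  expect_equal(ci_c$upper, ci_d$upper)

  tr <- generate_trial(se = rep(0.85, 4), sp = rep(0.8, 4), rho = 0.3,
                       n1 = 120, n0 = 120, seed = 41)
  pv4 <- predictive_values(estimate_accuracy(tr),
                           prevalence_spec("g", k = 100, m = 400),
                           side = "PPV")
  avg <- contrast_interval(pv4, rep(1 / 4, 4)) # reader-averaged interval
  expect_true(avg$lower <= sum(pv4$estimates) / 4 &&
              sum(pv4$estimates) / 4 <= avg$upper)
  set.seed(5)
  for (i in 1:50) {
    cvec <- rnorm(4)
    expect_gte(drop(crossprod(cvec, pv4$cov %*% cvec)), -1e-14)
  }
})

test_that("a user contrast matrix is validated and projected", {
  pv <- make_pv(seed = 53)
  M <- 2
  Tc <- diag(M) - matrix(1 / M, M, M)
  expect_equal(ats_test(pv, contrast = Tc)$statistic,
               ats_test(pv)$statistic)
  expect_error(ats_test(pv, contrast = matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
  # scaled projector: not idempotent, projected back to the projector
  expect_equal(ats_test(pv, contrast = 2 * Tc)$statistic,
               ats_test(pv)$statistic, tolerance = 1e-10)
})

test_that("power under a shifted alternative exceeds the type-I level", {
  reps <- 300
  prev <- prevalence_spec("g", k = 250, m = 1000)
  reject <- function(se2) {
    set.seed(61)
    mean(vapply(seq_len(reps), function(r) {
      tr <- generate_trial(se = c(0.85, se2), sp = c(0.85, 0.85), rho = 0.3,
                           n1 = 300, n0 = 300)
      pv <- predictive_values(estimate_accuracy(tr), prev, side = "PPV")
      ats_test(pv)$p_value < 0.05
    }, logical(1)))
  }
  # the PPV shift induced by a 0.1 sensitivity drop is modest, so this is
  # a monotonicity check, not a power benchmark
  expect_gt(reject(0.75), reject(0.85) + 0.02)
})
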