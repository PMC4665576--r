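test_that("Bayes transforms satisfy their exact identities", {
  # uninformative test (sp = 1 - se): predictive values reduce to the prior
  expect_equal(ppv(0.7, 0.3, 0.16), 0.16)
  expect_equal(npv(0.7, 0.3, 0.16), 0.84)
  # Bayes consistency: ppv * P(T+) = se * pi
  se <- 0.8537; sp <- 0.8976; pi <- 0.1599
  pt <- se * pi + (1 - sp) * (1 - pi)
  expect_equal(ppv(se, sp, pi) * pt, se * pi, tolerance = 1e-14)
  # domain errors
  expect_error(ppv(1, 0.9, 0.2), "strictly in")
  expect_error(npv(0.8, 0.9, 0), "strictly in")
})

test_that("ppv is strictly increasing in each argument, npv decreasing in pi", {
  set.seed(7)
  x <- matrix(runif(300, 0.02, 0.98), ncol = 3)
  h <- 1e-5
  for (r in seq_len(nrow(x))) {
    se <- x[r, 1]; sp <- x[r, 2]; pi <- x[r, 3]
    expect_gt(ppv(se + h, sp, pi), ppv(se, sp, pi))
    expect_gt(ppv(se, sp + h, pi), ppv(se, sp, pi))
    expect_gt(ppv(se, sp, pi + h), ppv(se, sp, pi))
    expect_lt(npv(se, sp, pi + h), npv(se, sp, pi))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(12)
  grid <- matrix(runif(300, 0.05, 0.95), ncol = 3)
  h <- 1e-6
  for (side in c("PPV", "NPV")) {
    f <- if (side == "PPV") ppv else npv
    for (r in seq_len(nrow(grid))) {
      se <- grid[r, 1]; sp <- grid[r, 2]; pi <- grid[r, 3]
      g <- pv_gradient(se, sp, pi, side)
      fd <- c((f(se + h, sp, pi) - f(se - h, sp, pi)) / (2 * h),
              (f(se, sp + h, pi) - f(se, sp - h, pi)) / (2 * h),
              (f(se, sp, pi + h) - f(se, sp, pi - h)) / (2 * h))
      expect_equal(unname(g), fd, tolerance = 1e-6)
    }
  }
})

test_that("gradient limits behave at a perfect test", {
  g <- pv_gradient(0.8, 1 - 1e-9, 0.3, "PPV")
  expect_lt(abs(g["se"]), 1e-6) # p+ -> 1 when sp -> 1, insensitive to se
})

test_that("nonanginal PPV variance reproduces the published half-width", {
  pv <- predictive_values(cad_accuracy(), cad_prev(), "nonanginal", "PPV")
  expect_equal(unname(diag(pv$cov)), 0.00440, tolerance = 0.002)
  expect_equal(1.96 * sqrt(unname(diag(pv$cov))), 0.130, tolerance = 0.001)
})

test_that("fixed prevalence drops the prevalence variance component", {
  acc <- summary_accuracy(0.85, 0.9, 150, 150)
  est <- predictive_values(acc, prevalence_spec("g", k = 48, m = 300),
                           side = "PPV")
  fix <- predictive_values(acc, prevalence_spec("g", pi = 0.16, fixed = TRUE),
                           side = "PPV")
  expect_equal(fix$cov, fix$cov_fixed)
  expect_equal(unname(diag(est$cov_fixed)), unname(diag(fix$cov)),
               tolerance = 1e-10)
  expect_gt(diag(est$cov), diag(est$cov_fixed))
})

test_that("duplicated modalities give a rank-1 predictive-value covariance", {
  tr <- generate_trial(se = 0.8, sp = 0.85, rho = 0, n1 = 80, n0 = 80,
                       seed = 9)
  tr2 <- trial_data(tr$subject_id, tr$gold, cbind(tr$results, tr$results),
                    modality_labels = c("a", "b"))
  pv <- predictive_values(estimate_accuracy(tr2),
                          prevalence_spec("g", k = 30, m = 100), side = "PPV")
  expect_equal(pv$cov[1, 2], pv$cov[1, 1], tolerance = 1e-12)
  ev <- eigen(pv$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2], 1e-12 * ev[1])
})

test_that("delta-method covariance matches parametric Monte-Carlo covariance", {
  se <- 0.85; sp <- 0.9; pi <- 0.25
  n <- 500; mg <- 1000; reps <- 10000
  set.seed(77)
  seh <- rbinom(reps, n, se) / n
  sph <- rbinom(reps, n, sp) / n
  pih <- rbinom(reps, mg, pi) / mg
  for (side in c("PPV", "NPV")) {
    f <- if (side == "PPV") ppv else npv
    p <- f(seh, sph, pih)
    emp <- var(p)
    pv <- predictive_values(summary_accuracy(se, sp, n1 = n, n0 = n),
                            prevalence_spec("g", k = pi * mg, m = mg),
                            side = side)
    mc_se <- sqrt(2 / (reps - 1)) * emp # ~sd of a sample variance
    expect_lt(abs(emp - unname(diag(pv$cov))), 3 * mc_se)
  }
})

test_that("interval variants behave at degenerate point estimates", {
  tr <- trial_data(sprintf("s%d", 1:8), c(rep(1, 4), rep(0, 4)),
                   matrix(c(rep(1, 4), rep(0, 4)), ncol = 1))
  acc <- suppressWarnings(estimate_accuracy(tr)) # se = sp = 1
  pv <- predictive_values(acc, prevalence_spec("g", k = 10, m = 50),
                          side = "PPV")
  expect_equal(unname(pv$estimates), 1)
  for (m in c("logistic-normal", "logistic-t", "additive-t")) {
    ci <- confidence_interval(pv, m)
    expect_true(ci$failed)
    expect_true(is.na(ci$lower))
  }
  add <- confidence_interval(pv, "additive-normal")
  expect_false(add$failed)
  expect_equal(add$upper - add$lower, 0) # plug-in variance collapses to 0
})

test_that("estimated-prevalence intervals are wider than fixed-prevalence ones", {
  set.seed(21)
  for (i in 1:25) {
    acc <- summary_accuracy(runif(1, 0.55, 0.95), runif(1, 0.55, 0.95),
                            sample(50:500, 1), sample(50:500, 1))
    m <- sample(c(100, 500, 1000), 1)
    k <- sample(seq(5, m - 5), 1)
    pv <- predictive_values(acc, prevalence_spec("g", k = k, m = m),
                            side = sample(c("PPV", "NPV"), 1))
    est <- confidence_interval(pv, "additive-normal")
    fix <- confidence_interval(pv, "mercaldo-additive")
    expect_lt(fix$upper - fix$lower, est$upper - est$lower)
    expect_gte(fix$lower, est$lower)
    expect_lte(fix$upper, est$upper)
  }
})

test_that("t degrees of freedom collapse to the dominant component's limit", {
  # prevalence component made dominant by a tiny prevalence study
  acc <- summary_accuracy(0.85, 0.9, 10^6, 10^6)
  pv <- predictive_values(acc, prevalence_spec("g", k = 10, m = 40),
                          side = "PPV")
  nu <- t_degrees_of_freedom(pv)
  comp <- pv$components
  expect_gt(comp[, "pi"] / sum(comp), 0.999)
  # single-component limit of nu = 2 v^2 / Var(v)
  nu_pi <- 2 * pv$pi * (1 - pv$pi) * 40 / (1 - 2 * pv$pi)^2
  expect_equal(unname(nu), nu_pi, tolerance = 0.01)
})

test_that("difference intervals degenerate correctly and match a bootstrap oracle", {
  tr <- generate_trial(se = c(0.85, 0.75), sp = c(0.9, 0.82), rho = 0.4,
                       n1 = 150, n0 = 150, seed = 31)
  prev <- prevalence_spec("g", k = 250, m = 1000)
  pv <- predictive_values(estimate_accuracy(tr), prev, side = "PPV")

  self <- difference_interval(pv, 1, 1)
  expect_equal(self$estimate, 0)
  expect_equal(self$upper - self$lower, 0)

  # bootstrap oracle: multinomial resampling of the joint outcome patterns
  # within each disease group, prevalence redrawn from its binomial
  reps <- 10000
  set.seed(99)
  boot_p <- function(block, n) {
    pat <- factor(block[, 1] * 2 + block[, 2], levels = 0:3)
    counts <- rmultinom(reps, n, as.numeric(table(pat)) / n)
    counts / n
  }
  d <- tr$results[tr$gold == 1, ]
  h <- tr$results[tr$gold == 0, ]
  cd <- boot_p(d, nrow(d))    # rows: patterns 00,01,10,11
  ch <- boot_p(h, nrow(h))
  se1 <- cd[3, ] + cd[4, ]; se2 <- cd[2, ] + cd[4, ]
  sp1 <- ch[1, ] + ch[2, ]; sp2 <- ch[1, ] + ch[3, ]
  pih <- rbinom(reps, 1000, 0.25) / 1000
  diffs <- ppv(se1, sp1, pih) - ppv(se2, sp2, pih)
  di <- difference_interval(pv, 1, 2)
  boot_ci <- quantile(diffs, c(0.025, 0.975))
  mc <- 3 * sd(diffs) / sqrt(reps) + 0.01
  expect_lt(abs(di$estimate - mean(diffs)), mc)
  expect_lt(abs(di$lower - boot_ci[[1]]), 0.02)
  expect_lt(abs(di$upper - boot_ci[[2]]), 0.02)
})

test_that("difference intervals refuse what they cannot compute", {
  sm <- summary_accuracy(c(0.8, 0.85), c(0.9, 0.88), 150, 150)
  pv <- predictive_values(sm, prevalence_spec("g", k = 30, m = 120),
                          side = "PPV")
  expect_error(difference_interval(pv, 1, 2), "summary-level")
  acc <- cad_accuracy()
  pv1 <- predictive_values(acc, cad_prev(), "nonanginal", "PPV")
  expect_error(difference_interval(pv1, 1, 2), "unknown modality")
})
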