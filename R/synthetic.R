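# Calibration cache: latent Gaussian correlation solved once per
# (marginal pair, target binary correlation).
.calib_cache <- new.env(parent = emptyenv())

# P(Z1 <= h, Z2 <= k) for standard bivariate normal with correlation r,
# by one-dimensional quadrature of phi(z) * Phi((k - r z)/sqrt(1 - r^2)).
.bvn_prob <- function(h, k, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  if (r > 0.99999) return(stats::pnorm(min(h, k)))
  if (r < -0.99999) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  f <- function(z) stats::dnorm(z) * stats::pnorm((k - r * z) / sqrt(1 - r^2))
  stats::integrate(f, -8.5, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Fréchet bounds on the correlation of two Bernoulli variables with
# success probabilities p and q.
.binary_corr_bounds <- function(p, q) {
  s <- sqrt(p * q * (1 - p) * (1 - q))
  c(lower = (max(0, p + q - 1) - p * q) / s,
    upper = (min(p, q) - p * q) / s)
}

# Latent correlation such that thresholded standard normals with marginals
# (p, q) have binary correlation rho.
.calibrate_latent <- function(p, q, rho) {
  if (rho == 0) return(0)
  key <- sprintf("%.12g|%.12g|%.12g", min(p, q), max(p, q), rho)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  zp <- stats::qnorm(p)
  zq <- stats::qnorm(q)
  target <- p * q + rho * sqrt(p * q * (1 - p) * (1 - q))
  root <- stats::uniroot(
    function(r) .bvn_prob(zp, zq, r) - target,
    lower = -0.9999, upper = 0.9999, tol = 1e-9
  )$root
  assign(key, root, envir = .calib_cache)
  root
}

# Correlated Bernoulli block: n draws of M binary outcomes with the given
# marginals and common pairwise binary correlation rho, via a Gaussian
# copula with pairwise-calibrated latent correlations.
.correlated_bernoulli <- function(n, marginals, rho) {
  M <- length(marginals)
  if (M == 1L || rho == 0) {
    return(matrix(stats::rbinom(n * M, 1L, rep(marginals, each = n)), n, M))
  }
  R <- diag(M)
  for (l in seq_len(M - 1L)) {
    for (r in (l + 1L):M) {
      R[l, r] <- R[r, l] <- .calibrate_latent(marginals[l], marginals[r], rho)
    }
  }
  U <- tryCatch(chol(R), error = function(e) {
    ev <- eigen(R, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-8)
    R2 <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(R2))
    chol(R2 / tcrossprod(d))
  })
  Z <- matrix(stats::rnorm(n * M), n, M) %*% U
  matrix(as.integer(Z <= rep(stats::qnorm(marginals), each = n)), n, M)
}

#' Generate a correlated multi-modality diagnostic trial
#'
#' Simulates subject-level binary results for `M` modalities applied to the
#' same subjects: the diseased block has marginal positive rates `se`, the
#' non-diseased block has marginal negative rates `sp`, and within each
#' block any two modalities have (approximately) pairwise binary
#' correlation `rho`. Dependence is induced by thresholding a latent
#' Gaussian vector whose pairwise correlations are calibrated numerically
#' so the realised binary correlations match `rho`; the calibration is
#' cached per (marginal pair, rho). The diseased and non-diseased blocks
#' are independent. Requested correlations outside the Fréchet bounds of a
#' marginal pair raise an error naming the admissible range.
#'
#' @param se,sp length-`M` vectors of sensitivities and specificities,
#'   strictly in (0, 1).
#' @param rho common pairwise binary correlation within each disease group.
#' @param n1,n0 numbers of diseased and non-diseased subjects.
#' @param seed optional integer seed for reproducibility.
#' @param modality_labels optional modality names.
#' @return A [trial_data()] object.
#' @export
#' @examples
#' generate_trial(se = c(0.85, 0.85), sp = c(0.9, 0.9), rho = 0.5,
#'                n1 = 50, n0 = 50, seed = 1)
generate_trial <- function(se, sp, rho = 0, n1, n0, seed = NULL,
                           modality_labels = NULL) {
  .check_prob_open(se, sp, what = "se and sp")
  if (length(sp) != length(se)) stop("se and sp must have equal length",
                                     call. = FALSE)
  stopifnot(n1 >= 1, n0 >= 1, length(rho) == 1L)
  M <- length(se)
  if (M > 1L) {
    for (marg in list(se, sp)) {
      for (l in seq_len(M - 1L)) {
        for (r in (l + 1L):M) {
          b <- .binary_corr_bounds(marg[l], marg[r])
          if (rho < b["lower"] - 1e-12 || rho > b["upper"] + 1e-12) {
            stop(sprintf(
              "correlation %.3f infeasible for marginals (%.3f, %.3f); admissible range [%.3f, %.3f]",
              rho, marg[l], marg[r], b["lower"], b["upper"]), call. = FALSE)
          }
        }
      }
    }
  }
  if (!is.null(seed)) set.seed(seed)
  d <- .correlated_bernoulli(n1, se, rho)
  h <- 1L - .correlated_bernoulli(n0, sp, rho) # positive result = failure for non-diseased
  res <- rbind(d, h)
  trial_data(
    subject_id = c(sprintf("d%04d", seq_len(n1)), sprintf("h%04d", seq_len(n0))),
    gold = c(rep(1L, n1), rep(0L, n0)),
    results = res,
    modality_labels = modality_labels
  )
}

#' Generate a prevalence study
#'
#' Draws the diseased count of a prior prevalence study as
#' `k ~ Binomial(m, pi)`. Boundary draws (`k` equal to 0 or `m`) would
#' violate the open-interval requirement on prevalences, so they are
#' redrawn; the number of redraws is recorded in the `"resampled"`
#' attribute. If a valid draw cannot be obtained (e.g. `m = 1`), an error
#' is raised.
#'
#' @param pi true prevalence, strictly in (0, 1).
#' @param m study size.
#' @param seed optional integer seed.
#' @param label group label for the resulting specification.
#' @param max_tries resampling cap before giving up.
#' @return A [prevalence_spec()] with one group and attribute
#'   `"resampled"` (number of boundary redraws).
#' @export
#' @examples
#' generate_prevalence_study(0.25, 1000, seed = 1)
generate_prevalence_study <- function(pi, m, seed = NULL, label = "group1",
                                      max_tries = 1000L) {
  .check_prob_open(pi, what = "pi")
  stopifnot(m >= 1)
  if (!is.null(seed)) set.seed(seed)
  resampled <- 0L
  repeat {
    k <- stats::rbinom(1L, m, pi)
    if (k > 0L && k < m) break
    resampled <- resampled + 1L
    if (resampled >= max_tries) {
      stop("could not draw a prevalence study with 0 < k < m after ",
           max_tries, " tries (m = ", m, ", pi = ", pi, ")", call. = FALSE)
    }
  }
  out <- prevalence_spec(label, k = k, m = m)
  attr(out, "resampled") <- resampled
  out
}
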