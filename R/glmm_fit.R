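# Random-intercept logistic estimation by adaptive Gauss-Hermite
# quadrature, plus the 1-D offset-logit fits used during tree growth.
# Leaf models are intercept-only, so the full likelihood machinery reduces
# to per-patient one-dimensional integrals.

pt_loglik_bern <- function(y, eta) {
  # numerically safe Bernoulli log-likelihood on the logit scale:
  # y*eta - log(1 + exp(eta)), with log(1+e^x) = max(x,0) + log1p(e^{-|x|})
  y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# Precomputed grouped-sum helper over integer cluster codes 1..n_grp:
# rows sorted by cluster once, group sums via cumulative-sum differences
# (much cheaper than repeated rowsum()).
pt_group_index <- function(gi, n_grp) {
  ord <- order(gi)
  ends <- cumsum(tabulate(gi, n_grp))
  if (any(ends == c(0, ends[-n_grp]))) stop("empty cluster group")
  list(ord = ord, ends = ends, n_grp = n_grp)
}

pt_group_sum <- function(v, gx) {
  cs <- cumsum(v[gx$ord])
  cs[gx$ends] - c(0, cs[gx$ends[-gx$n_grp]])
}

# Intercept-only logistic fit with fixed per-row offset.
# Solves sum(y - plogis(a + offset)) = 0 by damped Newton; the intercept is
# capped at +/-15 so pure nodes stay finite.
pt_fit_offset_logit <- function(y, offset, cap = 15) {
  n1 <- sum(y)
  if (n1 == 0 || n1 == length(y)) {
    a <- if (n1 == 0) -cap else cap
    p <- stats::plogis(a + offset)
    return(list(alpha = a, p = p, deviance = -2 * sum(pt_loglik_bern(y, a + offset))))
  }
  a <- stats::qlogis(mean(y)) - mean(offset)
  for (it in 1:50) {
    p <- stats::plogis(a + offset)
    g <- sum(y - p)
    if (abs(g) < 1e-10) break
    h <- sum(p * (1 - p))
    step <- g / max(h, 1e-12)
    a <- min(max(a + sign(step) * min(abs(step), 5), -cap), cap)
  }
  p <- stats::plogis(a + offset)
  list(alpha = a, p = p, deviance = -2 * sum(pt_loglik_bern(y, a + offset)))
}

# Posterior modes and curvatures of the patient random effects given
# (beta, sigma). eta0 = beta[leaf] per tooth; pat = integer patient index,
# gx = pt_group_index(pat, n_pat).
pt_posterior_modes <- function(y, eta0, pat, gx, sigma, start = NULL) {
  b <- if (is.null(start)) numeric(gx$n_grp) else start
  inv_s2 <- 1 / sigma^2
  for (it in 1:60) {
    p <- stats::plogis(eta0 + b[pat])
    g <- pt_group_sum(y - p, gx) - b * inv_s2
    if (max(abs(g)) < 1e-10) break
    h <- pt_group_sum(p * (1 - p), gx) + inv_s2
    step <- g / h
    b <- b + sign(step) * pmin(abs(step), 3)
  }
  p <- stats::plogis(eta0 + b[pat])
  curv <- pt_group_sum(p * (1 - p), gx) + inv_s2
  list(mode = b, curv = curv)
}

# Adaptive Gauss-Hermite marginal log-likelihood of the intercept-per-leaf
# random-intercept logistic model.
pt_marginal_loglik <- function(beta, sigma, y, leaf, pat, gx, gh) {
  eta0 <- beta[leaf]
  if (sigma < 1e-6) {
    return(list(ll = sum(pt_loglik_bern(y, eta0)), modes = numeric(gx$n_grp)))
  }
  pm <- pt_posterior_modes(y, eta0, pat, gx, sigma)
  m <- pm$mode
  s <- 1 / sqrt(pm$curv)
  h_at <- function(b) {
    pt_group_sum(pt_loglik_bern(y, eta0 + b[pat]), gx) +
      stats::dnorm(b, 0, sigma, log = TRUE)
  }
  h_m <- h_at(m)
  acc <- numeric(gx$n_grp)
  for (q in seq_along(gh$x)) {
    bq <- m + sqrt(2) * s * gh$x[q]
    acc <- acc + gh$w[q] * exp(gh$x[q]^2 + h_at(bq) - h_m)
  }
  ll_i <- h_m + log(acc * sqrt(2) * s)
  list(ll = sum(ll_i), modes = m)
}

#' Fit the random-intercept logistic model for fixed leaf assignments
#'
#' Maximises the marginal likelihood of `y_ij ~ Bernoulli(invlogit(
#' beta[leaf_ij] + b_i))`, `b_i ~ N(0, sigma_b^2)`, by adaptive
#' Gauss-Hermite quadrature (per-patient posterior-mode centring and
#' scaling). Leaf intercepts are box-constrained to `[-15, 15]` so leaves
#' with all-equal outcomes stay finite. Patient effects are returned as
#' posterior modes (BLUPs) at the estimates. The fit is deterministic given
#' its inputs.
#'
#' @param y binary outcome vector (one element per tooth).
#' @param leaf_index leaf assignment per tooth (factor or integer).
#' @param patient_index patient (cluster) identifier per tooth.
#' @param quadrature_points number of Gauss-Hermite nodes (default 15).
#' @param sigma_fixed fix the random-intercept SD at this value instead of
#'   estimating it; `sigma_fixed = 0` reduces the model to independent
#'   per-leaf binomials, whose intercepts are the closed-form leaf logits.
#' @return list: `beta` (named leaf intercepts), `sigma_b_hat`, `blups`
#'   (named by patient), `loglik`, `converged`, `n_eval`.
#' @export
fit_random_intercept <- function(y, leaf_index, patient_index,
                                 quadrature_points = 15, sigma_fixed = NULL) {
  y <- as.integer(y)
  leaf_f <- factor(leaf_index)
  pat_f <- factor(patient_index)
  leaf <- as.integer(leaf_f)
  pat <- as.integer(pat_f)
  L <- nlevels(leaf_f)
  n_pat <- nlevels(pat_f)
  if (min(tabulate(leaf, L)) < 1) stop("every leaf must contain >= 1 tooth")
  gh <- pracma::gaussHermite(quadrature_points)
  gx <- pt_group_index(pat, n_pat)

  rate <- rowsum(y, leaf, reorder = TRUE)[, 1] / tabulate(leaf, L)
  beta0 <- pmin(pmax(stats::qlogis(rate), -15), 15)
  beta0[!is.finite(beta0)] <- ifelse(rate[!is.finite(beta0)] > 0.5, 15, -15)

  if (!is.null(sigma_fixed) && sigma_fixed < 1e-6) {
    # closed form: independent binomial leaves
    ml <- pt_marginal_loglik(beta0, 0, y, leaf, pat, gx, gh)
    return(list(beta = stats::setNames(beta0, levels(leaf_f)),
                sigma_b_hat = 0,
                blups = stats::setNames(numeric(n_pat), levels(pat_f)),
                loglik = ml$ll, converged = TRUE, n_eval = 1L))
  }

  n_eval <- 0L
  if (is.null(sigma_fixed)) {
    par0 <- c(beta0, 0.3)
    lower <- c(rep(-15, L), 1e-4)
    upper <- c(rep(15, L), 10)
    obj <- function(par) {
      n_eval <<- n_eval + 1L
      -pt_marginal_loglik(par[1:L], par[L + 1], y, leaf, pat, gx, gh)$ll
    }
  } else {
    par0 <- beta0
    lower <- rep(-15, L)
    upper <- rep(15, L)
    obj <- function(par) {
      n_eval <<- n_eval + 1L
      -pt_marginal_loglik(par, sigma_fixed, y, leaf, pat, gx, gh)$ll
    }
  }
  opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 200, factr = 1e7))
  if (!is.finite(opt$value)) {
    stop("non-finite marginal likelihood in random-intercept fit (after ",
         n_eval, " evaluations)")
  }
  beta <- unname(opt$par[1:L])
  sigma <- if (is.null(sigma_fixed)) unname(opt$par[L + 1]) else sigma_fixed
  if (sigma <= 2e-4) sigma <- 0
  ml <- pt_marginal_loglik(beta, sigma, y, leaf, pat, gx, gh)
  list(beta = stats::setNames(beta, levels(leaf_f)),
       sigma_b_hat = sigma,
       blups = stats::setNames(ml$modes, levels(pat_f)),
       loglik = ml$ll,
       converged = opt$convergence == 0,
       n_eval = n_eval)
}

#' Marginal success probability of a leaf logit under the random intercept
#'
#' Integrates `invlogit(beta + b)` over `b ~ N(0, sigma_b^2)` with
#' Gauss-Hermite quadrature — the prediction for a tooth of an unseen
#' patient.
#'
#' @param beta leaf logit(s).
#' @param sigma_b random-intercept SD.
#' @param quadrature_points quadrature resolution (default 41).
#' @return probability vector, same length as `beta`.
#' @export
marginal_prob <- function(beta, sigma_b, quadrature_points = 41) {
  if (sigma_b < 1e-10) return(stats::plogis(beta))
  gh <- pracma::gaussHermite(quadrature_points)
  sapply(beta, function(b0) {
    sum(gh$w * stats::plogis(b0 + sqrt(2) * sigma_b * gh$x)) / sqrt(pi)
  })
}
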