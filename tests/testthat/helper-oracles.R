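# Independent oracles used by the tests.  These deliberately avoid the
# package's sampler code paths.

# Deterministic grid-quadrature posterior for the intercept-only two-stage
# model: 5-dimensional tensor-product Gauss-Legendre quadrature over
# (psi, theta11, theta10, p11, p10), with the latent z and w summed out
# exactly in the likelihood.  The occupancy prior is the logistic-normal
# induced by the N(qlogis(m), v) intercept prior; error probabilities get
# their Beta(m*c, (1-m)*c) priors; the ordering constraint (theta11 > theta10,
# p11 > p10) is applied as an indicator, matching the sampler's rejection
# step.
grid_posterior_oracle <- function(y, K, config, n_grid = 24) {
  gl <- pracma::gaussLegendre(n_grid, 0, 1)
  u <- gl$x; wq <- gl$w
  n <- n_grid
  a_tp <- config$prior_mean_tp * config$beta_concentration
  b_tp <- (1 - config$prior_mean_tp) * config$beta_concentration
  a_fp <- config$prior_mean_fp * config$beta_concentration
  b_fp <- (1 - config$prior_mean_fp) * config$beta_concentration

  w_psi <- wq * dnorm(qlogis(u), qlogis(config$prior_occupancy_mean),
                      sqrt(config$prior_occupancy_variance)) / (u * (1 - u))
  w_tp <- wq * dbeta(u, a_tp, b_tp)
  w_fp <- wq * dbeta(u, a_fp, b_fp)

  tab <- table(y)
  yv <- as.integer(names(tab)); ny <- as.integer(tab)

  # index arrays over the (psi, theta11, theta10) block: dim 1 = psi,
  # dim 2 = theta11, dim 3 = theta10 (column-major recycling)
  U_psi <- array(u, c(n, n, n))
  U_t11 <- array(rep(u, each = n), c(n, n, n))
  U_t10 <- array(rep(u, each = n * n), c(n, n, n))
  ord <- outer(u, u, ">")
  M_t <- array(rep(as.vector(ord), each = n), c(n, n, n))  # theta11 > theta10
  W3 <- array(w_psi, c(n, n, n)) *
    array(rep(w_tp, each = n), c(n, n, n)) *
    array(rep(w_fp, each = n * n), c(n, n, n)) * M_t

  lW3 <- log(W3)  # -Inf where the ordering mask excludes the cell

  block_ll <- function(i1, i0) {
    b1 <- dbinom(yv, K, u[i1]); b0 <- dbinom(yv, K, u[i0])
    # per-sample likelihood mixtures on the theta grids: theta * b1 + (1-theta) * b0
    A <- outer(u, b1) + outer(1 - u, b0)   # n x n_distinct_y
    ll <- 0
    for (j in seq_along(yv)) {
      t1 <- outer(u, A[, j])               # psi x theta11 (z = 1 branch)
      t0 <- outer(1 - u, A[, j])           # psi x theta10 (z = 0 branch)
      arr <- array(t1, c(n, n, n)) +
        aperm(array(t0, c(n, n, n)), c(1, 3, 2))
      ll <- ll + ny[j] * log(arr)
    }
    ll + lW3 + log(w_tp[i1] * w_fp[i0])
  }

  # pass 1: global log-scale offset, so exp() cannot over/underflow at any S
  pairs <- which(ord, arr.ind = TRUE)  # p11 > p10 cells
  M <- max(vapply(seq_len(nrow(pairs)), function(r)
    max(block_ll(pairs[r, 1], pairs[r, 2])), numeric(1)))

  # pass 2: accumulate evidence and first moments
  ev <- 0
  m <- c(psi = 0, theta11 = 0, theta10 = 0, p11 = 0, p10 = 0)
  for (r in seq_len(nrow(pairs))) {
    i1 <- pairs[r, 1]; i0 <- pairs[r, 2]
    g <- exp(block_ll(i1, i0) - M)
    ev_i <- sum(g)
    ev <- ev + ev_i
    m["psi"] <- m["psi"] + sum(g * U_psi)
    m["theta11"] <- m["theta11"] + sum(g * U_t11)
    m["theta10"] <- m["theta10"] + sum(g * U_t10)
    m["p11"] <- m["p11"] + ev_i * u[i1]
    m["p10"] <- m["p10"] + ev_i * u[i0]
  }
  m / ev
}

# Long random-walk Metropolis run on the Bayesian logistic-regression
# posterior p(beta | z, X) with independent normal priors -- the reference
# for the Polya-Gamma coefficient update.
metropolis_logistic_oracle <- function(z, X, m0, v0, n_iter = 60000,
                                       proposal_sd = 0.25, seed = 99) {
  set.seed(seed)
  p <- ncol(X)
  lpost <- function(b) {
    eta <- drop(X %*% b)
    sum(z * eta - log1p(exp(eta))) - sum((b - m0)^2 / (2 * v0))
  }
  b <- m0
  lp <- lpost(b)
  out <- matrix(NA_real_, n_iter, p)
  for (i in seq_len(n_iter)) {
    prop <- b + rnorm(p, 0, proposal_sd)
    lpp <- lpost(prop)
    if (log(runif(1)) < lpp - lp) { b <- prop; lp <- lpp }
    out[i, ] <- b
  }
  out[-seq_len(n_iter %/% 5), , drop = FALSE]
}
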