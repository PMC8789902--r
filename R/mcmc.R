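# Gibbs/Metropolis sampler for the two-stage occupancy model.
#
# Latent structure: z_i ~ Bern(psi_i) site occupancy; w_ij ~ Bern(theta11 or
# theta10 | z_i) sample DNA state; y_ij ~ Binom(K, p11 or p10 | w_ij)
# amplifying replicates.  psi_i = plogis(x_i' beta) with spike-and-slab
# selection over covariate groups; beta is updated by Polya-Gamma
# augmentation and gamma by Add-Delete-Swap Metropolis moves with beta
# integrated out analytically.  All likelihood products are in log space.

# prior mean / variance vectors for the design columns of an active set
prior_vecs <- function(cols, config) {
  m0 <- ifelse(cols == "(Intercept)", stats::qlogis(config$prior_occupancy_mean), 0)
  v0 <- ifelse(cols == "(Intercept)", config$prior_occupancy_variance,
               config$coefficient_variance)
  list(m0 = m0, v0 = v0)
}

#' Draw the latent site-occupancy indicators
#'
#' Full-conditional draw of `z` with the sample states `w` marginalized out:
#' `P(z_i = 1 | .)` is proportional to
#' `psi_i * prod_j [theta11 b(y_ij; K, p11) + (1 - theta11) b(y_ij; K, p10)]`
#' and `P(z_i = 0 | .)` to the analogous product with `theta10`, where `b` is
#' the binomial pmf.  Computation is in log space.
#'
#' @param y amplifying replicate counts (one per sample row).
#' @param K replicates per sample (scalar or per row).
#' @param site integer site index (1..S) per sample row.
#' @param psi occupancy probability per site.
#' @param theta11,theta10,p11,p10 current error probabilities.
#' @param prob if `TRUE`, return `P(z_i = 1 | .)` instead of a draw.
#' @return integer vector `z` of length S (or probabilities).
#' @export
sample_latent_z <- function(y, K, site, psi, theta11, theta10, p11, p10,
                            prob = FALSE) {
  S <- max(site)
  la <- log_binom_mix(y, K, theta11, p11, p10)  # per-sample, given z = 1
  lb <- log_binom_mix(y, K, theta10, p11, p10)  # given z = 0
  sla <- as.vector(rowsum(la, site, reorder = TRUE))
  slb <- as.vector(rowsum(lb, site, reorder = TRUE))
  psi <- rep_len(psi, S)
  lp1 <- log(psi) + sla
  lp0 <- log1p(-psi) + slb
  pz <- 1 / (1 + exp(lp0 - lp1))
  pz[is.infinite(lp1) & lp1 < 0] <- 0  # psi = 0 exactly
  if (prob) return(pz)
  stats::rbinom(S, 1L, pz)
}

#' Draw the latent sample DNA states
#'
#' With `theta = theta11` for occupied sites and `theta10` otherwise,
#' `P(w_ij = 1 | .) = theta b(y; K, p11) / [theta b(y; K, p11) +
#' (1 - theta) b(y; K, p10)]`.
#'
#' @inheritParams sample_latent_z
#' @param z occupancy indicator per site.
#' @param prob if `TRUE`, return the conditional probabilities.
#' @return integer vector `w` per sample row (or probabilities).
#' @export
sample_latent_w <- function(y, K, site, z, theta11, theta10, p11, p10,
                            prob = FALSE) {
  theta <- ifelse(z[site] == 1L, theta11, theta10)
  lo <- log(theta) - log1p(-theta) +
    stats::dbinom(y, K, p11, log = TRUE) - stats::dbinom(y, K, p10, log = TRUE)
  pw <- stats::plogis(lo)
  pw[theta == 0] <- 0
  pw[theta == 1] <- 1
  if (prob) return(pw)
  stats::rbinom(length(y), 1L, pw)
}

#' Conjugate update of the four error probabilities
#'
#' Beta priors `Beta(m c, (1 - m) c)` with means `m` 0.9 (true positives) and
#' 0.1 (false positives) and concentration `c`.  Posteriors are beta with the
#' latent tallies added: `theta11` over samples at occupied sites, `theta10`
#' over unoccupied sites, `p11` over replicates in DNA-positive samples,
#' `p10` over DNA-free samples.  When `enforce_ordering` is set, the pairs
#' are redrawn until `theta11 > theta10` and `p11 > p10` (capped at 100
#' tries, then the pair is sorted and flagged).
#'
#' @inheritParams sample_latent_z
#' @param z,w current latent states.
#' @param config a [model_config()].
#' @return list with `theta11`, `theta10`, `p11`, `p10`, and `sorted`
#'   (2-vector: whether the stage-1/stage-2 pair hit the rejection cap).
#' @export
update_error_probs <- function(y, K, site, z, w, config) {
  a_tp <- config$prior_mean_tp * config$beta_concentration
  b_tp <- (1 - config$prior_mean_tp) * config$beta_concentration
  a_fp <- config$prior_mean_fp * config$beta_concentration
  b_fp <- (1 - config$prior_mean_fp) * config$beta_concentration

  zrow <- z[site]
  K <- rep_len(K, length(y))
  s11 <- sum(w[zrow == 1L]); f11 <- sum(zrow == 1L) - s11
  s10 <- sum(w[zrow == 0L]); f10 <- sum(zrow == 0L) - s10
  yp <- sum(y[w == 1L]); fp <- sum(K[w == 1L]) - yp
  yn <- sum(y[w == 0L]); fn <- sum(K[w == 0L]) - yn

  draw_pair <- function(a1, b1, a0, b0) {
    if (!config$enforce_ordering)
      return(list(hi = stats::rbeta(1, a1, b1), lo = stats::rbeta(1, a0, b0),
                  sorted = FALSE))
    for (i in seq_len(100)) {
      hi <- stats::rbeta(1, a1, b1); lo <- stats::rbeta(1, a0, b0)
      if (hi > lo) return(list(hi = hi, lo = lo, sorted = FALSE))
    }
    list(hi = max(hi, lo), lo = min(hi, lo), sorted = TRUE)
  }
  st1 <- draw_pair(a_tp + s11, b_tp + f11, a_fp + s10, b_fp + f10)
  st2 <- draw_pair(a_tp + yp, b_tp + fp, a_fp + yn, b_fp + fn)
  list(theta11 = st1$hi, theta10 = st1$lo, p11 = st2$hi, p10 = st2$lo,
       sorted = c(stage1 = st1$sorted, stage2 = st2$sorted))
}

# Collapsed Metropolis refresh of the weakly identified Stage-1 block
# (intercept, theta11, theta10) with the latent z and w integrated out of the
# likelihood.  With one sample per site these three parameters are informed
# jointly mainly through the marginal DNA-positive rate
# psi * theta11 + (1 - psi) * theta10, a near-flat ridge along which the
# z-conditioned conjugate updates mix very slowly; random-walk moves against
# the marginal likelihood restore mobility.  Run before the z draw (so z is
# refreshed from its conditional under the new parameters), this is a valid
# partially collapsed Gibbs step.
mh_stage1_update <- function(y, K, site, r, beta0, th11, th10, p11, p10,
                             config, n_cycles) {
  m0 <- stats::qlogis(config$prior_occupancy_mean)
  v0 <- config$prior_occupancy_variance
  a_tp <- config$prior_mean_tp * config$beta_concentration
  b_tp <- (1 - config$prior_mean_tp) * config$beta_concentration
  a_fp <- config$prior_mean_fp * config$beta_concentration
  b_fp <- (1 - config$prior_mean_fp) * config$beta_concentration

  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  th11 <- clamp(th11); th10 <- clamp(th10)

  site_sum <- function(v) as.vector(rowsum(v, site, reorder = TRUE))
  sla <- site_sum(log_binom_mix(y, K, th11, p11, p10))
  slb <- site_sum(log_binom_mix(y, K, th10, p11, p10))
  llmarg <- function(b0) {
    psi <- stats::plogis(b0 + r)
    sum(log_add(log(psi) + sla, log1p(-psi) + slb))
  }
  # log prior of a probability parameter in logit coordinates
  lp_theta <- function(th, a, b)
    stats::dbeta(th, a, b, log = TRUE) + log(th) + log1p(-th)

  ll <- llmarg(beta0)
  for (i in seq_len(n_cycles)) {
    # intercept (random walk on the logit-occupancy scale)
    b0p <- beta0 + stats::rnorm(1, 0, 0.2)
    llp <- llmarg(b0p)
    if (log(stats::runif(1)) < llp - ll +
        stats::dnorm(b0p, m0, sqrt(v0), log = TRUE) -
        stats::dnorm(beta0, m0, sqrt(v0), log = TRUE)) {
      beta0 <- b0p; ll <- llp
    }
    # theta11 (random walk on the logit scale)
    t11p <- stats::plogis(stats::qlogis(th11) + stats::rnorm(1, 0, 0.3))
    if (!config$enforce_ordering || t11p > th10) {
      slap <- site_sum(log_binom_mix(y, K, t11p, p11, p10))
      psi <- stats::plogis(beta0 + r)
      llp <- sum(log_add(log(psi) + slap, log1p(-psi) + slb))
      if (log(stats::runif(1)) < llp - ll +
          lp_theta(t11p, a_tp, b_tp) - lp_theta(th11, a_tp, b_tp)) {
        th11 <- t11p; sla <- slap; ll <- llp
      }
    }
    # theta10
    t10p <- stats::plogis(stats::qlogis(th10) + stats::rnorm(1, 0, 0.3))
    if (!config$enforce_ordering || t10p < th11) {
      slbp <- site_sum(log_binom_mix(y, K, t10p, p11, p10))
      psi <- stats::plogis(beta0 + r)
      llp <- sum(log_add(log(psi) + sla, log1p(-psi) + slbp))
      if (log(stats::runif(1)) < llp - ll +
          lp_theta(t10p, a_fp, b_fp) - lp_theta(th10, a_fp, b_fp)) {
        th10 <- t10p; slb <- slbp; ll <- llp
      }
    }
  }
  list(beta0 = beta0, theta11 = th11, theta10 = th10)
}

# Gaussian full-conditional draw of beta given the Polya-Gamma auxiliaries.
# kappa = z - 1/2; precision X' Omega X + V0^-1; returns the draw and the
# Cholesky pieces (reused by the marginal-likelihood computation).
draw_beta_given_omega <- function(kappa, X, omega, m0, v0) {
  P <- crossprod(X, X * omega)
  diag(P) <- diag(P) + 1 / v0
  cvec <- crossprod(X, kappa) + m0 / v0
  R <- tryCatch(chol(P), error = function(e)
    stop("singular precision in the coefficient update; remove duplicated design columns",
         call. = FALSE))
  mu <- backsolve(R, backsolve(R, cvec, transpose = TRUE))
  drop(mu + backsolve(R, stats::rnorm(ncol(X))))
}

#' Polya-Gamma update of the occupancy coefficients
#'
#' One Gibbs step of the logistic regression of `z` on the active design
#' columns: draw `omega_i ~ PG(1, x_i' beta)`, then draw `beta` from its
#' conditionally Gaussian full conditional with precision
#' `X' Omega X + V0^-1` and mean solving
#' `(precision) mu = X' (z - 1/2) + V0^-1 m0`.
#'
#' @param z occupancy indicators (length S).
#' @param X active design matrix (intercept included).
#' @param beta current coefficient vector (used to tilt the `omega` draw).
#' @param m0,v0 prior mean and variance per column.
#' @return list with the new `beta` and the `omega` vector.
#' @export
update_beta_polya_gamma <- function(z, X, beta, m0, v0) {
  omega <- rpolyagamma(drop(X %*% beta))
  beta <- draw_beta_given_omega(z - 0.5, X, omega, m0, v0)
  list(beta = beta, omega = omega)
}

# log marginal likelihood (up to gamma-free constants) of the PG-augmented
# Gaussian model for inclusion vector `gamma`, beta integrated out.
log_marg_gamma <- function(gamma, omega, kappa, design, config) {
  act <- c(design$groups[["(Intercept)"]],
           unlist(design$groups[setdiff(names(design$groups), "(Intercept)")][gamma],
                  use.names = FALSE))
  X <- design$X[, act, drop = FALSE]
  pv <- prior_vecs(colnames(design$X)[act], config)
  P <- crossprod(X, X * omega)
  diag(P) <- diag(P) + 1 / pv$v0
  cvec <- crossprod(X, kappa) + pv$m0 / pv$v0
  R <- chol(P)
  u <- backsolve(R, cvec, transpose = TRUE)
  -0.5 * sum(log(pv$v0)) - sum(log(diag(R))) + 0.5 * sum(u^2)
}

#' Add-Delete-Swap update of the covariate inclusion indicators
#'
#' One Metropolis-Hastings move over covariate groups (the intercept is
#' always active; all dummy columns of a categorical move together).  A move
#' type is chosen uniformly among those available -- ADD an inactive group,
#' DELETE an active one, or SWAP one for the other -- and accepted using the
#' conditionally Gaussian marginal likelihood of the Polya-Gamma
#' representation with the coefficients integrated out.  The prior on
#' `gamma` is independent Bernoulli with inclusion probability
#' `expected_num_covariates / n_groups` per group.
#'
#' @param gamma logical inclusion vector over covariate groups.
#' @param omega Polya-Gamma auxiliaries (length S).
#' @param z occupancy indicators (length S).
#' @param design an `edna_design`.
#' @param config a [model_config()].
#' @param n_moves number of consecutive proposals.
#' @return list with the new `gamma`, `accepted` count and `proposed` count.
#' @export
update_gamma_ads <- function(gamma, omega, z, design, config, n_moves = 1) {
  groups <- setdiff(names(design$groups), "(Intercept)")
  G <- length(groups)
  if (G == 0L) return(list(gamma = gamma, accepted = 0L, proposed = 0L))
  h <- min(max(config$expected_num_covariates / G, 1e-6), 1 - 1e-6)
  kappa <- z - 0.5
  lprior <- function(g) sum(g) * log(h) + (G - sum(g)) * log1p(-h)
  # proposal mass of the specific move gamma -> gamma2
  move_types <- function(g) {
    c("add"[sum(!g) > 0], "delete"[sum(g) > 0], "swap"[sum(g) > 0 && sum(!g) > 0])
  }
  lcur <- log_marg_gamma(gamma, omega, kappa, design, config) + lprior(gamma)
  accepted <- 0L
  for (m in seq_len(n_moves)) {
    types <- move_types(gamma)
    type <- if (length(types) == 1L) types else sample(types, 1L)
    g2 <- gamma
    if (type == "add") {
      j <- which(!gamma); j <- if (length(j) == 1L) j else sample(j, 1L)
      g2[j] <- TRUE
      lq_fwd <- -log(length(types)) - log(sum(!gamma))
      lq_rev <- -log(length(move_types(g2))) - log(sum(g2))
    } else if (type == "delete") {
      j <- which(gamma); j <- if (length(j) == 1L) j else sample(j, 1L)
      g2[j] <- FALSE
      lq_fwd <- -log(length(types)) - log(sum(gamma))
      lq_rev <- -log(length(move_types(g2))) - log(sum(!g2))
    } else {
      ja <- which(gamma); ja <- if (length(ja) == 1L) ja else sample(ja, 1L)
      jb <- which(!gamma); jb <- if (length(jb) == 1L) jb else sample(jb, 1L)
      g2[ja] <- FALSE; g2[jb] <- TRUE
      lq_fwd <- lq_rev <- 0  # swap keeps the active count: symmetric
    }
    lnew <- log_marg_gamma(g2, omega, kappa, design, config) + lprior(g2)
    if (log(stats::runif(1)) < lnew - lcur + lq_rev - lq_fwd) {
      gamma <- g2; lcur <- lnew; accepted <- accepted + 1L
    }
  }
  list(gamma = gamma, accepted = accepted, proposed = n_moves)
}

#' Fit the two-stage occupancy model by MCMC
#'
#' Runs the Gibbs cycle `z -> w -> error probabilities -> omega -> gamma ->
#' beta` for `n_burn + n_iter` sweeps and retains `n_thinned_draws` evenly
#' spaced post-burn-in draws.  With `design = NULL` an intercept-only model
#' is fitted (constant occupancy, no variable selection).  Identical config
#' and seed give identical draws.
#'
#' @param detection a detection table (see [read_detection_table()]).
#' @param design optional `edna_design` from [build_design_matrix()]; its
#'   `site_id`s must cover the detection table's.
#' @param config a [model_config()].
#' @param verbose print sweep progress.
#' @return an object of class `edna_draws`: matrices `beta` (draws x columns,
#'   exact zeros outside active groups) and `gamma` (draws x groups), vectors
#'   `theta11`, `theta10`, `p11`, `p10`, `psi_bar` (site-averaged occupancy
#'   per draw), optionally `psi` (draws x sites), plus metadata.
#' @examples
#' sv <- simulate_survey(gen_params(S = 60, K = 6, seed = 2))
#' cfg <- model_config(n_burn = 200, n_iter = 200, n_thinned_draws = 50)
#' fit <- fit_occupancy(sv$detections, config = cfg)
#' summary(fit)
#' @export
fit_occupancy <- function(detection, design = NULL, config = model_config(),
                          verbose = FALSE) {
  detection <- validate_detection_table(as.data.frame(detection))
  if (is.null(design)) {
    sites <- sort(unique(detection$site_id))
    S <- length(sites)
    X <- matrix(1, S, 1, dimnames = list(NULL, "(Intercept)"))
    design_int <- list(X = X, groups = list(`(Intercept)` = 1L))
  } else {
    stopifnot(inherits(design, "edna_design"))
    sites <- design$site_id
    S <- nrow(design$X)
    if (!all(detection$site_id %in% sites))
      stop("detection table has site_ids absent from the design", call. = FALSE)
    design_int <- design
  }
  site <- match(detection$site_id, sites)
  y <- detection$y_positive
  K <- detection$k_replicates
  groups <- setdiff(names(design_int$groups), "(Intercept)")
  G <- length(groups)
  if (config$expected_num_covariates > G && G > 0L)
    stop("expected_num_covariates exceeds the number of candidate groups",
         call. = FALSE)
  Xfull <- design_int$X
  P <- ncol(Xfull)

  set.seed(config$seed)
  # initial state: naive occupancy, prior-mean error rates, empty model
  z <- as.integer(rowsum(as.integer(y > 0), site, reorder = TRUE)[, 1] > 0)
  gamma <- rep(FALSE, G)
  active <- function(g) c(design_int$groups[["(Intercept)"]],
                          unlist(design_int$groups[groups][g], use.names = FALSE))
  act <- active(gamma)
  beta_act <- stats::qlogis(config$prior_occupancy_mean)
  probs <- list(theta11 = config$prior_mean_tp, theta10 = config$prior_mean_fp,
                p11 = config$prior_mean_tp, p10 = config$prior_mean_fp)

  total <- config$n_burn + config$n_iter
  step <- floor(config$n_iter / config$n_thinned_draws)
  keep <- config$n_burn + step * seq_len(config$n_thinned_draws)

  nd <- config$n_thinned_draws
  out_beta <- matrix(0, nd, P, dimnames = list(NULL, colnames(Xfull)))
  out_gamma <- matrix(FALSE, nd, max(G, 0), dimnames = list(NULL, groups))
  out_th11 <- out_th10 <- out_p11 <- out_p10 <- out_psibar <- numeric(nd)
  out_psi <- if (config$store_psi) matrix(NA_real_, nd, S) else NULL
  n_sorted <- c(stage1 = 0L, stage2 = 0L)
  ads_acc <- ads_prop <- 0L
  d <- 0L

  for (sweep in seq_len(total)) {
    eta <- drop(Xfull[, act, drop = FALSE] %*% beta_act)
    if (config$marginal_moves > 0L) {
      mh <- mh_stage1_update(y, K, site, eta - beta_act[1], beta_act[1],
                             probs$theta11, probs$theta10,
                             probs$p11, probs$p10, config,
                             config$marginal_moves)
      beta_act[1] <- mh$beta0
      probs$theta11 <- mh$theta11; probs$theta10 <- mh$theta10
      eta <- drop(Xfull[, act, drop = FALSE] %*% beta_act)
    }
    psi <- stats::plogis(eta)
    z <- sample_latent_z(y, K, site, psi, probs$theta11, probs$theta10,
                         probs$p11, probs$p10)
    w <- sample_latent_w(y, K, site, z, probs$theta11, probs$theta10,
                         probs$p11, probs$p10)
    probs <- update_error_probs(y, K, site, z, w, config)
    n_sorted <- n_sorted + probs$sorted
    omega <- rpolyagamma(eta)
    if (G > 0L) {
      upd <- update_gamma_ads(gamma, omega, z, design_int, config,
                              n_moves = config$ads_moves)
      gamma <- upd$gamma
      ads_acc <- ads_acc + upd$accepted; ads_prop <- ads_prop + upd$proposed
      act <- active(gamma)
    }
    pv <- prior_vecs(colnames(Xfull)[act], config)
    beta_act <- draw_beta_given_omega(z - 0.5, Xfull[, act, drop = FALSE],
                                      omega, pv$m0, pv$v0)
    if (verbose && sweep %% 1000 == 0)
      message(sprintf("sweep %d/%d (ADS acceptance %.2f)", sweep, total,
                      if (ads_prop) ads_acc / ads_prop else NA_real_))
    if (d < nd && sweep == keep[d + 1L]) {
      d <- d + 1L
      out_beta[d, act] <- beta_act
      if (G > 0L) out_gamma[d, ] <- gamma
      out_th11[d] <- probs$theta11; out_th10[d] <- probs$theta10
      out_p11[d] <- probs$p11; out_p10[d] <- probs$p10
      psi_d <- stats::plogis(drop(Xfull[, act, drop = FALSE] %*% beta_act))
      out_psibar[d] <- mean(psi_d)
      if (config$store_psi) out_psi[d, ] <- psi_d
    }
  }

  structure(list(beta = out_beta, gamma = out_gamma,
                 theta11 = out_th11, theta10 = out_th10,
                 p11 = out_p11, p10 = out_p10,
                 psi_bar = out_psibar, psi = out_psi,
                 groups = groups, design = design, config = config,
                 sites = sites, S = S, K = K[1],
                 ads_acceptance = if (ads_prop) ads_acc / ads_prop else NA_real_,
                 ordering_fallbacks = n_sorted),
            class = "edna_draws")
}

#' @export
print.edna_draws <- function(x, ...) {
  cat(sprintf("Two-stage occupancy model: %d retained draws, %d sites, %d covariate group(s)\n",
              length(x$theta11), x$S, length(x$groups)))
  print(summary(x))
  invisible(x)
}

#' Posterior summaries of the error probabilities and mean occupancy
#'
#' @param object an `edna_draws` object.
#' @param ... unused.
#' @return data.frame with posterior mean and equal-tailed 95% credible
#'   interval for `theta11`, `theta10`, `p11`, `p10`, and the site-averaged
#'   occupancy.
#' @export
summary.edna_draws <- function(object, ...) {
  pars <- list(theta11 = object$theta11, theta10 = object$theta10,
               p11 = object$p11, p10 = object$p10,
               mean_occupancy = object$psi_bar)
  out <- do.call(rbind, lapply(names(pars), function(nm) {
    q <- stats::quantile(pars[[nm]], c(0.025, 0.975), names = FALSE)
    data.frame(parameter = nm, mean = mean(pars[[nm]]),
               lower95 = q[1], upper95 = q[2])
  }))
  rownames(out) <- NULL
  out
}
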