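#' Configuration of priors and MCMC schedule
#'
#' Defaults follow the settings used for national great crested newt eDNA
#' data: beta priors on the error probabilities with means 0.9 (true
#' positives, `theta11`/`p11`) and 0.1 (false positives, `theta10`/`p10`);
#' a normal prior on the logit-scale intercept with mean
#' `qlogis(prior_occupancy_mean)` and variance `prior_occupancy_variance`;
#' a slab variance `coefficient_variance` per covariate design column; and a
#' per-group prior inclusion probability of
#' `expected_num_covariates / n_groups`.  The schedule is 5,000 burn-in
#' sweeps, 3,000 sampling sweeps, one chain, and 100 evenly spaced retained
#' draws.
#'
#' Prior means alone leave the beta concentrations free; here each
#' error probability gets `Beta(m * c, (1 - m) * c)` with concentration
#' `c = beta_concentration` (default 10, i.e. Beta(9,1) / Beta(1,9)).
#'
#' @param prior_occupancy_mean prior mean occupancy (intercept prior mean on
#'   the logit scale is its logit).
#' @param prior_occupancy_variance prior variance of the intercept (logit
#'   scale).
#' @param coefficient_variance slab prior variance of each covariate design
#'   column.
#' @param expected_num_covariates prior expected number of included covariate
#'   groups.
#' @param prior_mean_tp,prior_mean_fp beta prior means of the true/false
#'   positive probabilities at both stages.
#' @param beta_concentration beta prior concentration `c`.
#' @param n_burn,n_iter,n_chains,n_thinned_draws MCMC schedule.
#' @param enforce_ordering require `theta11 > theta10` and `p11 > p10` in
#'   every draw (rejection within the conjugate update); guards against
#'   label switching in weakly identified fits.
#' @param ads_moves Add-Delete-Swap proposals per sweep.
#' @param marginal_moves per-sweep cycles of the collapsed Metropolis refresh
#'   of the intercept and Stage-1 error probabilities (latent states
#'   integrated out).  With one water sample per site these parameters are
#'   identified jointly mainly through the marginal DNA-positive rate, and
#'   the conjugate updates alone traverse that ridge very slowly; 0 disables.
#' @param store_psi keep the per-site occupancy probabilities of each
#'   retained draw (needed for site-resolved summaries).
#' @param seed integer RNG seed.
#' @return an object of class `model_config`.
#' @export
model_config <- function(prior_occupancy_mean = 0.5,
                         prior_occupancy_variance = 4,
                         coefficient_variance = 0.25,
                         expected_num_covariates = 2,
                         prior_mean_tp = 0.9,
                         prior_mean_fp = 0.1,
                         beta_concentration = 10,
                         n_burn = 5000,
                         n_iter = 3000,
                         n_chains = 1,
                         n_thinned_draws = 100,
                         enforce_ordering = TRUE,
                         ads_moves = 1,
                         marginal_moves = 3,
                         store_psi = TRUE,
                         seed = 1L) {
  check_prob(prior_occupancy_mean, "prior_occupancy_mean", open = TRUE)
  check_prob(prior_mean_tp, "prior_mean_tp", open = TRUE)
  check_prob(prior_mean_fp, "prior_mean_fp", open = TRUE)
  stopifnot(prior_occupancy_variance > 0, coefficient_variance > 0,
            beta_concentration > 0, expected_num_covariates >= 0)
  n_burn <- check_count(n_burn, "n_burn", min = 0L)
  n_iter <- check_count(n_iter, "n_iter")
  n_thinned_draws <- check_count(n_thinned_draws, "n_thinned_draws")
  if (n_thinned_draws > n_iter)
    stop("n_thinned_draws must not exceed n_iter", call. = FALSE)
  structure(list(prior_occupancy_mean = prior_occupancy_mean,
                 prior_occupancy_variance = prior_occupancy_variance,
                 coefficient_variance = coefficient_variance,
                 expected_num_covariates = expected_num_covariates,
                 prior_mean_tp = prior_mean_tp,
                 prior_mean_fp = prior_mean_fp,
                 beta_concentration = beta_concentration,
                 n_burn = n_burn, n_iter = n_iter,
                 n_chains = check_count(n_chains, "n_chains"),
                 n_thinned_draws = n_thinned_draws,
                 enforce_ordering = isTRUE(enforce_ordering),
                 ads_moves = check_count(ads_moves, "ads_moves"),
                 marginal_moves = check_count(marginal_moves, "marginal_moves",
                                              min = 0L),
                 store_psi = isTRUE(store_psi),
                 seed = as.integer(seed)),
            class = "model_config")
}
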