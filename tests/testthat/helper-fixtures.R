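# Shared fixtures: the fitted values of the national newt survey, used as
# generating truth throughout, and short MCMC schedules for unit tests.

fitted_values <- list(psi = 0.198, theta11 = 0.948, theta10 = 0.015,
                      p11 = 0.808, p10 = 0.020)

fitted_gen_params <- function(S, M = 1, K = 12, seed = 1L) {
  gen_params(S = S, M = M, K = K,
             theta11 = fitted_values$theta11, theta10 = fitted_values$theta10,
             p11 = fitted_values$p11, p10 = fitted_values$p10,
             psi = fitted_values$psi, seed = seed)
}

short_config <- function(...) {
  model_config(n_burn = 200, n_iter = 400, n_thinned_draws = 100, ...)
}

# assemble an edna_draws object by hand (for summary-level unit tests)
fake_draws <- function(beta, gamma, design = NULL,
                       theta11 = 0.9, theta10 = 0.1, p11 = 0.8, p10 = 0.02,
                       K = 12) {
  n <- nrow(beta)
  structure(list(beta = beta,
                 gamma = gamma,
                 theta11 = rep_len(theta11, n), theta10 = rep_len(theta10, n),
                 p11 = rep_len(p11, n), p10 = rep_len(p10, n),
                 psi_bar = plogis(beta[, 1]), psi = NULL,
                 groups = colnames(gamma), design = design,
                 config = NULL, sites = NULL, S = NA_integer_, K = K,
                 ads_acceptance = NA_real_,
                 ordering_fallbacks = c(stage1 = 0L, stage2 = 0L)),
            class = "edna_draws")
}
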