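# Posterior-predictive goodness of fit: simulate full surveys from retained
# draws and compare the distribution of amplifying-replicate counts (and the
# stage-wise true/false positive tallies) with the observed data.

#' Posterior-predictive simulation of amplifying-replicate counts
#'
#' Repeat `r` uses retained draw `r`'s parameters: occupancy probabilities
#' are computed from that draw's coefficients and the design (constant
#' `plogis(intercept)` for an intercept-only fit), then a full survey
#' (`z -> w -> y`) is simulated with the same generating process as
#' [simulate_survey()].  For each repeat the counts of samples with exactly
#' `k = 0..K` amplifying replicates are tabulated, together with the Stage-2
#' replicate-count distributions split by latent DNA state (false positives
#' among DNA-free samples; true positives among DNA-containing samples) and
#' the Stage-1 sample tallies.
#'
#' @param draws an `edna_draws` object.
#' @param S,M,K survey dimensions to simulate.
#' @param design optional `edna_design` with `S` rows; defaults to the
#'   fitted design (required when the draws contain covariate effects).
#' @param n_repeats number of repeats (default: all retained draws).
#' @param seed RNG seed for the simulation stage.
#' @return object of class `edna_gof`: `counts` (repeats x (K+1) matrix of
#'   samples with k amplifying replicates), `fp_replicates` / `tp_replicates`
#'   (same shape, restricted to DNA-free / DNA-containing samples),
#'   `stage1` (per repeat: true/false positive and negative sample counts),
#'   and `summary` (per k: median, quartiles, whiskers at quartile +/- 1.5
#'   IQR).
#' @export
gof_simulate <- function(draws, S, M = 1, K = draws$K, design = NULL,
                         n_repeats = NULL, seed = 1L) {
  stopifnot(inherits(draws, "edna_draws"))
  design <- design %||% draws$design
  nd <- length(draws$theta11)
  n_repeats <- n_repeats %||% nd
  if (n_repeats > nd)
    stop("n_repeats must not exceed the number of retained draws", call. = FALSE)
  covars <- length(draws$groups) > 0 &&
    any(draws$beta[seq_len(n_repeats), -1, drop = FALSE] != 0)
  if (covars && is.null(design))
    stop("draws contain covariate effects: a design is required", call. = FALSE)
  if (!is.null(design) && nrow(design$X) != S)
    stop("design must have S rows", call. = FALSE)

  set.seed(as.integer(seed))
  counts <- fp_rep <- tp_rep <- matrix(0L, n_repeats, K + 1,
                                       dimnames = list(NULL, 0:K))
  stage1 <- data.frame(true_pos = integer(n_repeats),
                       false_pos = integer(n_repeats),
                       false_neg = integer(n_repeats),
                       true_neg = integer(n_repeats))
  for (r in seq_len(n_repeats)) {
    psi <- if (is.null(design)) {
      stats::plogis(draws$beta[r, "(Intercept)"])
    } else stats::plogis(drop(design$X %*% draws$beta[r, ]))
    sim <- simulate_zwy(psi, draws$theta11[r], draws$theta10[r],
                        draws$p11[r], draws$p10[r], S, M, K)
    counts[r, ] <- tabulate(sim$y + 1L, K + 1)
    fp_rep[r, ] <- tabulate(sim$y[sim$w == 0L] + 1L, K + 1)
    tp_rep[r, ] <- tabulate(sim$y[sim$w == 1L] + 1L, K + 1)
    zs <- sim$z[sim$site]
    stage1$true_pos[r] <- sum(zs == 1L & sim$w == 1L)
    stage1$false_pos[r] <- sum(zs == 0L & sim$w == 1L)
    stage1$false_neg[r] <- sum(zs == 1L & sim$w == 0L)
    stage1$true_neg[r] <- sum(zs == 0L & sim$w == 0L)
  }
  qs <- apply(counts, 2, stats::quantile, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3, ] - qs[1, ]
  summ <- data.frame(k = 0:K, median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ],
                     whisker_lo = qs[1, ] - 1.5 * iqr,
                     whisker_hi = qs[3, ] + 1.5 * iqr)
  structure(list(counts = counts, fp_replicates = fp_rep,
                 tp_replicates = tp_rep, stage1 = stage1, summary = summ,
                 S = S, M = M, K = K, n_repeats = n_repeats),
            class = "edna_gof")
}

#' Compare observed replicate counts with the simulated envelope
#'
#' Flags, for each k, whether the observed number of samples with k
#' amplifying replicates falls inside the simulated whisker range
#' (quartile +/- 1.5 IQR over repeats).
#'
#' @param gof an `edna_gof` from [gof_simulate()].
#' @param observed a detection table with the same K.
#' @return data.frame per k: observed count, simulated median and whiskers,
#'   `inside` flag, and `direction` ("within", "observed > simulated
#'   envelope", "observed < simulated envelope").
#' @export
gof_compare <- function(gof, observed) {
  observed <- validate_detection_table(as.data.frame(observed))
  if (any(observed$k_replicates != gof$K))
    stop("observed data use a different K than the simulation", call. = FALSE)
  obs <- tabulate(observed$y_positive + 1L, gof$K + 1)
  out <- gof$summary
  out$observed <- obs
  out$inside <- obs >= out$whisker_lo & obs <= out$whisker_hi
  out$direction <- ifelse(out$inside, "within",
                          ifelse(obs > out$whisker_hi,
                                 "observed > simulated envelope",
                                 "observed < simulated envelope"))
  out[, c("k", "observed", "median", "q25", "q75",
          "whisker_lo", "whisker_hi", "inside", "direction")]
}

#' @export
print.edna_gof <- function(x, ...) {
  cat(sprintf("Posterior-predictive simulation: %d repeats of %d x %d samples, K = %d\n",
              x$n_repeats, x$S, x$M, x$K))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Build a draws object from fixed parameter values
#'
#' Replicates one parameter set across `n` pseudo-draws, so the
#' posterior-predictive machinery ([gof_simulate()], [conditional_absence()])
#' can be run at point estimates (e.g. published posterior means) without a
#' fit.
#'
#' @param psi,theta11,theta10,p11,p10 parameter values.
#' @param K replicates per sample.
#' @param n number of replicated draws.
#' @return an `edna_draws` object with constant draws.
#' @export
draws_from_values <- function(psi, theta11, theta10, p11, p10, K = 12,
                              n = 100) {
  structure(list(beta = matrix(stats::qlogis(psi), n, 1,
                               dimnames = list(NULL, "(Intercept)")),
                 gamma = matrix(FALSE, n, 0),
                 theta11 = rep(theta11, n), theta10 = rep(theta10, n),
                 p11 = rep(p11, n), p10 = rep(p10, n),
                 psi_bar = rep(psi, n), psi = NULL,
                 groups = character(0), design = NULL,
                 config = NULL, sites = NULL, S = NA_integer_, K = K,
                 ads_acceptance = NA_real_,
                 ordering_fallbacks = c(stage1 = 0L, stage2 = 0L)),
            class = "edna_draws")
}
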