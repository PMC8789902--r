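#' Parameters for a synthetic two-stage eDNA survey
#'
#' Bundles the generating values of the two-stage occupancy process:
#' site occupancy (`psi` or a covariate model), the Stage-1 (water sample)
#' true/false positive probabilities `theta11`/`theta10`, and the Stage-2
#' (qPCR replicate) true/false positive probabilities `p11`/`p10`.
#'
#' Occupancy is specified either as a constant `psi`, giving every site the
#' same occupancy probability, or as a design matrix plus coefficient vector
#' (`design`, `beta`), in which case `psi_i = plogis(x_i' beta)` using the
#' same encoding as [build_design_matrix()] so that generator and model share
#' one design-matrix code path.
#'
#' @param S number of sites.
#' @param M water samples per site.
#' @param K qPCR replicates per sample.
#' @param theta11,theta10 Stage-1 true/false positive probabilities.
#' @param p11,p10 Stage-2 true/false positive probabilities.
#' @param psi constant occupancy probability, or `NULL` when `design`/`beta`
#'   are supplied.
#' @param design an `edna_design` from [build_design_matrix()] (with `S` rows).
#' @param beta coefficient vector aligned with `colnames(design$X)`.
#' @param seed integer seed; identical seeds give byte-identical surveys.
#' @return an object of class `gen_params`.
#' @seealso [simulate_survey()]
#' @export
gen_params <- function(S, M = 1, K = 12,
                       theta11 = 0.948, theta10 = 0.015,
                       p11 = 0.808, p10 = 0.020,
                       psi = 0.198, design = NULL, beta = NULL,
                       seed = 1L) {
  S <- check_count(S, "S"); M <- check_count(M, "M"); K <- check_count(K, "K")
  check_prob(theta11, "theta11"); check_prob(theta10, "theta10")
  check_prob(p11, "p11"); check_prob(p10, "p10")
  if (is.null(design) != is.null(beta))
    stop("'design' and 'beta' must be supplied together", call. = FALSE)
  if (!is.null(design)) {
    if (!inherits(design, "edna_design"))
      stop("'design' must be an edna_design object", call. = FALSE)
    if (nrow(design$X) != S)
      stop("design matrix must have S rows", call. = FALSE)
    if (length(beta) != ncol(design$X))
      stop("'beta' must have one entry per design column", call. = FALSE)
    psi <- NULL
  } else {
    if (is.null(psi))
      stop("either a constant 'psi' or 'design' and 'beta' together must be supplied",
           call. = FALSE)
    check_prob(psi, "psi")
    if (length(psi) != 1L) stop("constant 'psi' must be a scalar", call. = FALSE)
  }
  structure(list(S = S, M = M, K = K,
                 theta11 = theta11, theta10 = theta10, p11 = p11, p10 = p10,
                 psi = psi, design = design, beta = beta,
                 seed = as.integer(seed)),
            class = "gen_params")
}

# The elementary generating process shared by the generator and the
# posterior-predictive simulator: z -> w -> y.  `psi` is length S (or scalar);
# draw order is fixed (z for all sites, then w for all samples in site-major
# order, then y) so outputs are stable across versions.
simulate_zwy <- function(psi, theta11, theta10, p11, p10, S, M, K) {
  z <- stats::rbinom(S, 1L, psi)
  site <- rep(seq_len(S), each = M)
  w <- stats::rbinom(S * M, 1L, ifelse(z[site] == 1L, theta11, theta10))
  y <- stats::rbinom(S * M, K, ifelse(w == 1L, p11, p10))
  list(z = z, w = w, y = y, site = site, sample = rep(seq_len(M), times = S))
}

#' Simulate a two-stage eDNA survey
#'
#' Draws latent site occupancy `z_i ~ Bernoulli(psi_i)`, latent sample DNA
#' states `w_ij ~ Bernoulli(theta11)` if `z_i = 1` (else `theta10`), and
#' amplifying replicate counts `y_ij ~ Binomial(K, p11)` if `w_ij = 1`
#' (else `p10`).
#'
#' @param params a [gen_params()] object.
#' @return an object of class `edna_survey`: a list with `detections`
#'   (data.frame `site_id`, `sample_id`, `k_replicates`, `y_positive`),
#'   latent truth `z` (per site) and `w` (per sample, site-major), the
#'   occupancy vector `psi`, and `params`.
#' @examples
#' sv <- simulate_survey(gen_params(S = 50, seed = 7))
#' head(sv$detections)
#' @export
simulate_survey <- function(params) {
  stopifnot(inherits(params, "gen_params"))
  set.seed(params$seed)
  psi <- if (!is.null(params$psi)) params$psi
         else as.numeric(stats::plogis(params$design$X %*% params$beta))
  sim <- simulate_zwy(psi, params$theta11, params$theta10,
                      params$p11, params$p10, params$S, params$M, params$K)
  detections <- data.frame(site_id = sim$site, sample_id = sim$sample,
                           k_replicates = params$K, y_positive = sim$y)
  structure(list(detections = detections, z = sim$z, w = sim$w,
                 psi = rep_len(psi, params$S), params = params),
            class = "edna_survey")
}

#' Simulate a site covariate table
#'
#' Continuous covariates are drawn standard normal, optionally with a target
#' correlation structure; categorical covariates are drawn from stated level
#' frequencies.  Where a categorical entry gives only a level count, an
#' unbalanced frequency vector is drawn once from a symmetric Dirichlet(0.5)
#' under the same seed, emulating the strongly unbalanced factor levels
#' (land cover, bedrock) typical of national survey data.
#'
#' @param S number of sites.
#' @param n_continuous number of continuous covariates (`cont1`, `cont2`, ...).
#' @param categorical named list; each entry is either an integer level count
#'   or a list with `levels` (character) and `freqs` (probabilities summing
#'   to 1).
#' @param corr optional correlation matrix for the continuous block.
#' @param seed integer seed.
#' @return a data.frame with `site_id`, continuous columns, and factor columns.
#' @export
simulate_covariate_table <- function(S, n_continuous = 2,
                                     categorical = list(),
                                     corr = NULL, seed = 1L) {
  S <- check_count(S, "S")
  n_continuous <- check_count(n_continuous, "n_continuous", min = 0L)
  set.seed(as.integer(seed))
  out <- data.frame(site_id = seq_len(S))
  if (n_continuous > 0L) {
    Z <- matrix(stats::rnorm(S * n_continuous), S, n_continuous)
    if (!is.null(corr)) {
      if (!isTRUE(all.equal(dim(corr), c(n_continuous, n_continuous))))
        stop("'corr' must be n_continuous x n_continuous", call. = FALSE)
      R <- suppressWarnings(chol(corr, pivot = TRUE))  # allow singular targets
      Z <- Z %*% R[, order(attr(R, "pivot")), drop = FALSE]
    }
    colnames(Z) <- paste0("cont", seq_len(n_continuous))
    out <- cbind(out, as.data.frame(Z))
  }
  for (nm in names(categorical)) {
    spec <- categorical[[nm]]
    if (is.numeric(spec) && length(spec) == 1L) {
      L <- check_count(spec, nm, min = 2L)
      levels <- paste0(nm, "_", seq_len(L))
      freqs <- stats::rgamma(L, 0.5)
      freqs <- freqs / sum(freqs)
    } else {
      levels <- spec$levels
      freqs <- spec$freqs
      if (abs(sum(freqs) - 1) > 1e-8)
        stop(sprintf("frequencies for '%s' must sum to 1", nm), call. = FALSE)
      if (length(levels) != length(freqs))
        stop(sprintf("levels/freqs length mismatch for '%s'", nm), call. = FALSE)
    }
    out[[nm]] <- factor(sample(levels, S, replace = TRUE, prob = freqs),
                        levels = levels)
  }
  out
}

#' Write the tables of a simulated survey to CSV
#'
#' Writes `detections.csv`, `covariates.csv` (when present), and the latent
#' truth (`latent_z.csv`, `latent_w.csv`) used by parameter-recovery checks.
#'
#' @param survey an `edna_survey`.
#' @param dir output directory (created if needed).
#' @param covariates optional covariate data.frame to write alongside.
#' @return invisibly, the paths written.
#' @export
write_survey <- function(survey, dir, covariates = NULL) {
  stopifnot(inherits(survey, "edna_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(detections = file.path(dir, "detections.csv"),
             latent_z = file.path(dir, "latent_z.csv"),
             latent_w = file.path(dir, "latent_w.csv"))
  utils::write.csv(survey$detections, paths["detections"], row.names = FALSE)
  utils::write.csv(data.frame(site_id = seq_along(survey$z), z = survey$z),
                   paths["latent_z"], row.names = FALSE)
  utils::write.csv(data.frame(site_id = survey$detections$site_id,
                              sample_id = survey$detections$sample_id,
                              w = survey$w),
                   paths["latent_w"], row.names = FALSE)
  if (!is.null(covariates)) {
    paths <- c(paths, covariates = file.path(dir, "covariates.csv"))
    utils::write.csv(covariates, paths[["covariates"]], row.names = FALSE)
  }
  invisible(paths)
}

#' @export
print.edna_survey <- function(x, ...) {
  cat(sprintf("eDNA survey simulation: %d sites x %d sample(s) x %d replicates\n",
              x$params$S, x$params$M, x$params$K))
  cat(sprintf("  occupied sites: %d (%.3f); DNA-positive samples: %d (%.3f)\n",
              sum(x$z), mean(x$z), sum(x$w), mean(x$w)))
  invisible(x)
}
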