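# Summaries computed from posterior draws: inclusion probabilities,
# coefficient and contrast tables, conditional-absence probabilities,
# naive-threshold occupancy, and replication error arithmetic.

#' Posterior inclusion probabilities and coefficient summaries
#'
#' The PIP of a covariate group is the fraction of retained draws in which it
#' is included; groups with PIP > 0.5 are flagged important.  Per design
#' column, the posterior mean and equal-tailed 95% credible interval of the
#' coefficient are reported both marginally (excluded draws contribute exact
#' zeros) and conditional on inclusion.
#'
#' @param draws an `edna_draws` object.
#' @return list of class `pip_report`: `groups` (group, pip, important) and
#'   `coefficients` (column, group, marginal and conditional summaries).
#' @export
compute_pip <- function(draws) {
  stopifnot(inherits(draws, "edna_draws"))
  if (length(draws$theta11) < 1) stop("no retained draws", call. = FALSE)
  G <- draws$groups
  pip <- if (length(G)) colMeans(draws$gamma) else numeric(0)
  groups <- data.frame(group = G, pip = as.numeric(pip),
                       important = as.numeric(pip) > 0.5)
  grp_of <- function(col) {
    for (g in c("(Intercept)", G))
      if (col %in% colnames(draws$beta)[col_span(draws, g)]) return(g)
    NA_character_
  }
  cols <- colnames(draws$beta)
  coef_tab <- do.call(rbind, lapply(cols, function(cn) {
    b <- draws$beta[, cn]
    g <- grp_of(cn)
    inc <- if (g == "(Intercept)") rep(TRUE, length(b)) else draws$gamma[, g]
    qm <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
    bc <- b[inc]
    qc <- if (length(bc)) stats::quantile(bc, c(0.025, 0.975), names = FALSE)
          else c(NA_real_, NA_real_)
    data.frame(column = cn, group = g,
               mean = mean(b), lower95 = qm[1], upper95 = qm[2],
               mean_incl = if (length(bc)) mean(bc) else NA_real_,
               lower95_incl = qc[1], upper95_incl = qc[2])
  }))
  rownames(coef_tab) <- NULL
  structure(list(groups = groups, coefficients = coef_tab),
            class = "pip_report")
}

# column indices of a group within the stored beta matrix
col_span <- function(draws, group) {
  if (is.null(draws$design)) {
    if (group == "(Intercept)") return(1L)
    stop("no covariate groups in an intercept-only fit", call. = FALSE)
  }
  draws$design$groups[[group]]
}

#' @export
print.pip_report <- function(x, ...) {
  cat("Posterior inclusion probabilities (important if PIP > 0.5):\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' All pairwise contrasts between the levels of a categorical covariate
#'
#' Level coefficients are differences from the baseline (whose coefficient is
#' identically zero).  For every unordered level pair the per-draw difference
#' of coefficients is summarized by its posterior mean and equal-tailed 95%
#' credible interval, both marginally (draws excluding the covariate
#' contribute zero differences) and conditional on inclusion.  A pair is
#' flagged when its marginal interval excludes zero.
#'
#' @param draws an `edna_draws` object.
#' @param covariate name of a categorical covariate in the design.
#' @return data.frame with one row per unordered pair (L levels give
#'   L(L-1)/2 rows).
#' @export
pairwise_contrasts <- function(draws, covariate) {
  if (is.null(draws$design) || !covariate %in% names(draws$design$levels))
    stop("not a categorical covariate of this fit: ", covariate, call. = FALSE)
  levs <- draws$design$levels[[covariate]]
  nd <- nrow(draws$beta)
  # per-draw coefficient of every level; baseline column of zeros first
  B <- cbind(0, draws$beta[, col_span(draws, covariate), drop = FALSE])
  colnames(B) <- levs
  inc <- draws$gamma[, covariate]
  pairs <- utils::combn(levs, 2)
  out <- do.call(rbind, apply(pairs, 2, function(pr) {
    d <- B[, pr[1]] - B[, pr[2]]
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    dc <- d[inc]
    qc <- if (length(dc)) stats::quantile(dc, c(0.025, 0.975), names = FALSE)
          else c(NA_real_, NA_real_)
    data.frame(level_a = pr[1], level_b = pr[2],
               mean = mean(d), lower95 = q[1], upper95 = q[2],
               mean_incl = if (length(dc)) mean(dc) else NA_real_,
               lower95_incl = qc[1], upper95_incl = qc[2],
               excludes_zero = q[1] > 0 | q[2] < 0)
  }))
  rownames(out) <- NULL
  out
}

# per-draw conditional occupancy probability given x of K replicates amplified
psi_given_x <- function(psi, theta11, theta10, p11, p10, x, K) {
  b1 <- stats::dbinom(x, K, p11)
  b0 <- stats::dbinom(x, K, p10)
  num <- psi * (theta11 * b1 + (1 - theta11) * b0)
  den <- num + (1 - psi) * (theta10 * b1 + (1 - theta10) * b0)
  num / den
}

#' Posterior conditional probability of species absence
#'
#' For each retained draw, the probability that a site is unoccupied given
#' that `x` of its `K` qPCR replicates amplified:
#' `1 - psi(x)` where
#' `psi(x) = psi (th11 b(x;K,p11) + (1-th11) b(x;K,p10)) / [same +
#' (1-psi)(th10 b(x;K,p11) + (1-th10) b(x;K,p10))]`.
#'
#' @param draws an `edna_draws` object.
#' @param x number(s) of amplifying replicates, each in `0..K`.
#' @param K replicates per sample (defaults to the fitted K).
#' @param psi_mode which occupancy probability enters the formula:
#'   `"mean"` (default) uses each draw's site-averaged occupancy;
#'   `"given"` uses the per-draw occupancy at covariates `at` (a one-row
#'   covariate data.frame re-encoded with the fitted design).
#' @param at covariate values for `psi_mode = "given"`.
#' @return data.frame with columns `x`, `mean`, `lower95`, `upper95`; the
#'   per-draw absence probabilities are attached as attribute `"draws"`
#'   (draws x length(x)).
#' @export
conditional_absence <- function(draws, x, K = draws$K,
                                psi_mode = c("mean", "given"), at = NULL) {
  psi_mode <- match.arg(psi_mode)
  if (any(x < 0 | x > K)) stop("x must lie in 0..K", call. = FALSE)
  psi_d <- if (psi_mode == "mean") draws$psi_bar else {
    if (is.null(draws$design) || is.null(at))
      stop("psi_mode = 'given' needs a fitted design and 'at'", call. = FALSE)
    xa <- apply_design(draws$design, at)
    stats::plogis(drop(draws$beta %*% t(xa)))
  }
  A <- vapply(x, function(xi)
    1 - psi_given_x(psi_d, draws$theta11, draws$theta10,
                    draws$p11, draws$p10, xi, K),
    numeric(length(psi_d)))
  A <- matrix(A, ncol = length(x))
  q <- apply(A, 2, stats::quantile, c(0.025, 0.975), names = FALSE)
  out <- data.frame(x = x, mean = colMeans(A),
                    lower95 = q[1, ], upper95 = q[2, ])
  attr(out, "draws") <- A
  out
}

#' Naive threshold-based occupancy
#'
#' A site is declared occupied when the maximum number of amplifying
#' replicates over its samples reaches the threshold; error rates are
#' ignored.  This is the conventional field rule that the model-based
#' estimate corrects.
#'
#' @param detection a detection table.
#' @param threshold vector of thresholds (each >= 1).
#' @return data.frame with `threshold`, `count` (occupied sites) and
#'   `proportion` (of all sites).
#' @export
naive_occupancy <- function(detection, threshold = 1L) {
  detection <- validate_detection_table(as.data.frame(detection))
  if (any(threshold < 1)) stop("threshold must be >= 1", call. = FALSE)
  ymax <- tapply(detection$y_positive, detection$site_id, max)
  S <- length(ymax)
  out <- data.frame(threshold = threshold,
                    count = vapply(threshold, function(t)
                      sum(ymax >= t), numeric(1)))
  out$proportion <- out$count / S
  out
}

#' False-positive magnification across qPCR replicates
#'
#' The probability that a unit with no target DNA yields at least one
#' amplification.  Stage-2 only (a DNA-free sample): `1 - (1 - p_fp)^K`.
#' With the Stage-1 path included (an unoccupied site that may still yield a
#' DNA-containing sample with probability `theta_fp`):
#' `theta_fp (1 - (1 - p_tp)^K) + (1 - theta_fp)(1 - (1 - p_fp)^K)`.
#'
#' @param p_fp per-replicate false-positive probability.
#' @param K number of qPCR replicates.
#' @param theta_fp Stage-1 false-positive probability (0 for the
#'   Stage-2-only quantity).
#' @param p_tp per-replicate true-positive probability; required when
#'   `theta_fp > 0`.
#' @return probability of at least one amplification.
#' @export
fp_magnification <- function(p_fp, K, theta_fp = 0, p_tp = NULL) {
  check_prob(p_fp, "p_fp"); check_prob(theta_fp, "theta_fp")
  K <- check_count(K, "K")
  s2 <- 1 - (1 - p_fp)^K
  if (all(theta_fp == 0)) return(s2)
  if (is.null(p_tp))
    stop("'p_tp' is required when theta_fp > 0", call. = FALSE)
  check_prob(p_tp, "p_tp")
  theta_fp * (1 - (1 - p_tp)^K) + (1 - theta_fp) * s2
}
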