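# CSV serialization of posterior draws with a JSON metadata sidecar.

#' Write posterior draws to CSV
#'
#' One row per retained draw; columns `beta_<column>`, `gamma_<group>`,
#' `theta11`, `theta10`, `p11`, `p10`, `psi_bar`.  A JSON sidecar
#' (`<path>.meta.json`) records the configuration, group structure and
#' sampler diagnostics.
#'
#' @param draws an `edna_draws` object.
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
write_draws <- function(draws, path) {
  tab <- data.frame(draw = seq_along(draws$theta11))
  B <- draws$beta; colnames(B) <- paste0("beta_", colnames(B))
  tab <- cbind(tab, B)
  if (length(draws$groups)) {
    Gm <- draws$gamma * 1L; colnames(Gm) <- paste0("gamma_", colnames(Gm))
    tab <- cbind(tab, Gm)
  }
  tab$theta11 <- draws$theta11; tab$theta10 <- draws$theta10
  tab$p11 <- draws$p11; tab$p10 <- draws$p10
  tab$psi_bar <- draws$psi_bar
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(groups = draws$groups, S = draws$S, K = draws$K,
               config = draws$config[setdiff(names(draws$config), "")],
               ads_acceptance = draws$ads_acceptance,
               ordering_fallbacks = as.list(draws$ordering_fallbacks))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read posterior draws from CSV
#'
#' Inverse of [write_draws()].  The reconstructed object supports all
#' posterior summaries except those needing the original design matrix
#' (pairwise contrasts, covariate-resolved occupancy).
#'
#' @param path CSV path written by [write_draws()].
#' @return an `edna_draws` object (without design).
#' @export
read_draws <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  bcols <- grep("^beta_", names(tab), value = TRUE)
  gcols <- grep("^gamma_", names(tab), value = TRUE)
  B <- as.matrix(tab[bcols]); colnames(B) <- sub("^beta_", "", bcols)
  Gm <- as.matrix(tab[gcols]) > 0
  colnames(Gm) <- sub("^gamma_", "", gcols)
  structure(list(beta = B, gamma = Gm,
                 theta11 = tab$theta11, theta10 = tab$theta10,
                 p11 = tab$p11, p10 = tab$p10, psi_bar = tab$psi_bar,
                 psi = NULL, groups = colnames(Gm), design = NULL,
                 config = meta$config, sites = NULL,
                 S = meta$S %||% NA_integer_, K = meta$K %||% NA_integer_,
                 ads_acceptance = meta$ads_acceptance %||% NA_real_,
                 ordering_fallbacks = unlist(meta$ordering_fallbacks %||%
                                              c(stage1 = 0L, stage2 = 0L))),
            class = "edna_draws")
}
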