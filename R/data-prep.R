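#' Read a detection table from CSV
#'
#' Expects columns `site_id`, `sample_id`, `k_replicates` (number of qPCR
#' replicates run, K) and `y_positive` (number that amplified).  Rows are
#' validated: counts must be non-negative integers with
#' `0 <= y_positive <= k_replicates`, and `(site_id, sample_id)` must be
#' unique.  Violations raise an error naming the offending row(s).
#'
#' @param path CSV file path.
#' @return a validated data.frame (invisibly classed `detection_table`).
#' @export
read_detection_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_detection_table(tbl)
}

#' Validate a detection table
#'
#' @param tbl data.frame with the columns described in
#'   [read_detection_table()].
#' @return the table, invisibly validated, with class `detection_table`.
#' @export
validate_detection_table <- function(tbl) {
  need <- c("site_id", "sample_id", "k_replicates", "y_positive")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  K <- tbl$k_replicates; y <- tbl$y_positive
  bad_int <- which(K != round(K) | y != round(y) | is.na(K) | is.na(y))
  if (length(bad_int))
    stop("non-integer or missing counts in row(s): ",
         paste(utils::head(bad_int, 5), collapse = ", "), call. = FALSE)
  bad <- which(y < 0 | K < 1 | y > K)
  if (length(bad))
    stop("0 <= y_positive <= k_replicates violated in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(tbl$site_id, tbl$sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (site_id, sample_id) in row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  class(tbl) <- c("detection_table", "data.frame")
  tbl
}

#' Write a detection table to CSV
#' @param tbl detection table.
#' @param path output path.
#' @export
write_detection_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl)[, c("site_id", "sample_id",
                                          "k_replicates", "y_positive")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table from CSV
#'
#' Character columns and any column named in `categorical` become factors;
#' everything else (bar `site_id`) is treated as continuous.
#'
#' @param path CSV file path.
#' @param categorical character vector of columns to force to factor.
#' @return data.frame with a `site_id` column.
#' @export
read_covariate_table <- function(path, categorical = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(tbl))
    stop("covariate table needs a 'site_id' column", call. = FALSE)
  for (nm in setdiff(names(tbl), "site_id")) {
    if (is.character(tbl[[nm]]) || nm %in% categorical)
      tbl[[nm]] <- factor(tbl[[nm]])
  }
  if (anyNA(tbl))
    stop("covariate table contains missing values; drop incomplete sites first",
         call. = FALSE)
  tbl
}

covariate_types <- function(tbl) {
  nms <- setdiff(names(tbl), "site_id")
  vapply(tbl[nms], function(col)
    if (is.factor(col) || is.character(col)) "categorical" else "continuous",
    character(1))
}

#' Prune collinear continuous covariates
#'
#' Computes the Pearson correlation for every pair of continuous covariates
#' and, for each pair with `|r| >=` the threshold, drops one member.  Which
#' member is dropped is decided greedily by a priority order (default: input
#' column order): columns are visited in priority order and kept only if not
#' collinear with an already-kept column.  Categorical covariates are never
#' pruned.  Constant columns have undefined correlation; they are flagged,
#' treated as uncorrelated, and a warning is raised.
#'
#' @param tbl covariate data.frame (with `site_id`).
#' @param threshold collinearity threshold on `|r|` (default 0.7).
#' @param priority character vector ordering covariates from most to least
#'   preferred; unlisted covariates follow in input order.
#' @return a list with `retained` (covariate names, categoricals included),
#'   `dropped` (data.frame: dropped column, the kept partner, their r), and
#'   `pairs` (every evaluated pair with its correlation).
#' @export
prune_correlated <- function(tbl, threshold = 0.7, priority = NULL) {
  types <- covariate_types(tbl)
  cont <- names(types)[types == "continuous"]
  if (length(cont) < 2)
    stop("need at least two continuous covariates to prune", call. = FALSE)
  X <- as.matrix(tbl[cont])
  const <- cont[apply(X, 2, stats::sd) == 0]
  if (length(const))
    warning("constant column(s) treated as uncorrelated: ",
            paste(const, collapse = ", "), call. = FALSE)
  R <- suppressWarnings(stats::cor(X))
  R[is.na(R)] <- 0
  ord <- unique(c(intersect(priority %||% character(), cont), cont))
  kept <- character(); dropped <- list()
  for (nm in ord) {
    hit <- kept[abs(R[nm, kept]) >= threshold]
    if (length(hit)) {
      dropped[[nm]] <- data.frame(dropped = nm, kept_partner = hit[1],
                                  r = R[nm, hit[1]])
    } else kept <- c(kept, nm)
  }
  ut <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- data.frame(var1 = rownames(R)[ut[, 1]], var2 = colnames(R)[ut[, 2]],
                      r = R[ut])
  list(retained = c(kept, names(types)[types == "categorical"]),
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(dropped = character(), kept_partner = character(),
                                 r = numeric()),
       pairs = pairs)
}

#' Build a grouped design matrix for the occupancy regression
#'
#' Continuous covariates are standardized (mean 0, sd 1); a categorical
#' covariate with L levels contributes L-1 dummy columns with the baseline
#' level omitted; an interaction `"A:B"` of two continuous covariates is the
#' elementwise product of the standardized parents and forms its own group.
#' The intercept is its own always-included group.  Each covariate is one
#' "group" for variable selection: all dummy columns of a factor enter or
#' leave the model together.
#'
#' @param tbl covariate data.frame (with `site_id`).
#' @param covariates character vector of covariate names to include;
#'   interactions written `"A:B"`.
#' @param baselines named list/character: baseline level per categorical
#'   covariate (default: first level in sorted order).
#' @return an object of class `edna_design`: list with `X` (S x P matrix,
#'   intercept first), `groups` (named list of column indices), `col_info`,
#'   `centers`/`scales` for continuous columns, `levels` and `baselines` for
#'   categorical covariates.
#' @export
build_design_matrix <- function(tbl, covariates, baselines = list()) {
  types <- covariate_types(tbl)
  plain <- covariates[!grepl(":", covariates)]
  inter <- covariates[grepl(":", covariates)]
  miss <- setdiff(plain, names(types))
  if (length(miss))
    stop("unknown covariate(s): ", paste(miss, collapse = ", "), call. = FALSE)

  S <- nrow(tbl)
  cols <- list(`(Intercept)` = matrix(1, S, 1,
                                      dimnames = list(NULL, "(Intercept)")))
  centers <- scales <- numeric(); levmap <- list(); basemap <- character()
  std <- list()  # standardized continuous columns, for interactions

  for (nm in plain) {
    if (types[[nm]] == "continuous") {
      x <- tbl[[nm]]
      mu <- mean(x); sdv <- sqrt(mean((x - mu)^2))  # population sd
      if (sdv == 0) stop("constant covariate cannot be standardized: ", nm,
                         call. = FALSE)
      zc <- (x - mu) / sdv
      centers[nm] <- mu; scales[nm] <- sdv; std[[nm]] <- zc
      cols[[nm]] <- matrix(zc, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(tbl[[nm]])
      base <- as.character(baselines[[nm]] %||% sort(levels(f))[1])
      if (!base %in% levels(f))
        stop(sprintf("baseline '%s' is not a level of '%s'", base, nm),
             call. = FALSE)
      f <- stats::relevel(f, ref = base)
      D <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(D) <- paste0(nm, "_", levels(f)[-1])
      levmap[[nm]] <- levels(f); basemap[nm] <- base
      cols[[nm]] <- D
    }
  }
  for (nm in inter) {
    parents <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% names(std)))
      stop("interaction parents must be continuous covariates in the model: ",
           nm, call. = FALSE)
    cols[[nm]] <- matrix(std[[parents[1]]] * std[[parents[2]]], ncol = 1,
                         dimnames = list(NULL, nm))
  }

  X <- do.call(cbind, cols)
  idx <- split(seq_len(ncol(X)),
               rep(names(cols), vapply(cols, ncol, integer(1))))
  idx <- idx[names(cols)]  # preserve declaration order
  col_info <- data.frame(column = colnames(X),
                         group = rep(names(cols), vapply(cols, ncol, integer(1))))
  structure(list(X = X, groups = idx, col_info = col_info,
                 centers = centers, scales = scales,
                 levels = levmap, baselines = basemap,
                 covariates = covariates,
                 site_id = tbl$site_id %||% seq_len(S)),
            class = "edna_design")
}

#' Re-encode new data with a fitted design
#'
#' Applies the stored standardization constants and factor encodings to a new
#' covariate table.  An unseen categorical level is an error.
#'
#' @param design an `edna_design`.
#' @param tbl new covariate data.frame.
#' @return design matrix with the same columns as `design$X`.
#' @export
apply_design <- function(design, tbl) {
  S <- nrow(tbl)
  std <- list()
  cols <- list(`(Intercept)` = matrix(1, S, 1))
  for (nm in setdiff(names(design$groups), "(Intercept)")) {
    if (grepl(":", nm)) {
      parents <- strsplit(nm, ":", fixed = TRUE)[[1]]
      cols[[nm]] <- matrix(std[[parents[1]]] * std[[parents[2]]], ncol = 1)
    } else if (nm %in% names(design$centers)) {
      zc <- (tbl[[nm]] - design$centers[nm]) / design$scales[nm]
      std[[nm]] <- zc
      cols[[nm]] <- matrix(zc, ncol = 1)
    } else {
      levs <- design$levels[[nm]]
      vals <- as.character(tbl[[nm]])
      unseen <- setdiff(unique(vals), levs)
      if (length(unseen))
        stop(sprintf("unseen level(s) for '%s': %s", nm,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      f <- factor(vals, levels = levs)
      D <- stats::model.matrix(~f)[, -1, drop = FALSE]
      cols[[nm]] <- D
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- colnames(design$X)
  X
}

#' Recover categorical labels from dummy columns
#'
#' Inverse of the dummy coding in [build_design_matrix()]: rows with all
#' dummies zero map to the baseline level.
#'
#' @param design an `edna_design`.
#' @param covariate name of a categorical covariate in the design.
#' @param X optional matrix (defaults to `design$X`).
#' @return character vector of level labels.
#' @export
decode_categorical <- function(design, covariate, X = design$X) {
  if (!covariate %in% names(design$levels))
    stop("not a categorical covariate in this design: ", covariate,
         call. = FALSE)
  D <- X[, design$groups[[covariate]], drop = FALSE]
  levs <- design$levels[[covariate]]
  lab <- rep(levs[1], nrow(D))  # baseline (relevel put it first)
  hit <- D %*% seq_len(ncol(D))
  lab[hit > 0] <- levs[-1][hit[hit > 0]]
  lab
}

#' Habitat Suitability Index score
#'
#' The HSI for great crested newts combines ten suitability indices, each in
#' \[0.01, 1\], into their geometric mean.
#'
#' @param si numeric vector of exactly ten suitability indices, or a matrix
#'   with ten columns (one row per site).
#' @return the geometric mean(s), in \[0.01, 1\].
#' @export
hsi_score <- function(si) {
  if (is.matrix(si)) {
    if (ncol(si) != 10) stop("HSI needs exactly ten indices", call. = FALSE)
    return(apply(si, 1, hsi_score))
  }
  if (length(si) != 10) stop("HSI needs exactly ten indices", call. = FALSE)
  if (any(si <= 0)) stop("suitability indices must be positive", call. = FALSE)
  if (any(si < 0.01 | si > 1))
    stop("suitability indices must lie in [0.01, 1]", call. = FALSE)
  exp(mean(log(si)))
}

#' Write a JSON design report
#'
#' Records everything needed to reproduce a fit: groups, baselines,
#' standardization constants, and any covariates dropped for collinearity.
#'
#' @param design an `edna_design`.
#' @param path output JSON path.
#' @param pruned optional result of [prune_correlated()].
#' @export
design_report <- function(design, path, pruned = NULL) {
  rep <- list(covariates = design$covariates,
              groups = lapply(design$groups, function(i) colnames(design$X)[i]),
              baselines = as.list(design$baselines),
              centers = as.list(design$centers),
              scales = as.list(design$scales))
  if (!is.null(pruned)) rep$dropped <- pruned$dropped
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
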