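#' Rarefy a count matrix without replacement
#'
#' Subsamples each sample's reads uniformly without replacement to a common
#' depth (via `vegan::rrarefy`); samples with fewer total reads than the
#' depth are dropped and reported.
#'
#' @param counts Samples x ASVs non-negative integer matrix (rownames =
#'   sample ids).
#' @param depth Target reads per sample (e.g. 8063 for 16S, 10718 for ITS).
#' @param seed Integer seed (rarefaction is performed once, with the seed
#'   recorded in the result).
#' @return A list: `counts` (rarefied matrix, every row summing exactly to
#'   `depth`), `dropped` (character vector of removed sample ids), `depth`,
#'   `seed`.
#' @export
rarefy_counts <- function(counts, depth, seed = 1) {
  if (depth <= 0) abort("rarefaction depth must be positive")
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  totals <- rowSums(counts)
  dropped <- rownames(counts)[totals < depth]
  keep <- counts[totals >= depth, , drop = FALSE]
  set.seed(seed)
  # inputs are validated above; vegan's smallest-count heuristic warning
  # misfires on legitimate sparse tables
  rar <- suppressWarnings(vegan::rrarefy(keep, depth))
  storage.mode(rar) <- "integer"
  list(counts = rar, dropped = dropped, depth = depth, seed = seed)
}

#' Remove sequencing singletons
#'
#' Drops ASVs whose total count across all samples is exactly 1.
#'
#' @param counts Samples x ASVs count matrix.
#' @return The matrix without singleton ASVs.
#' @export
remove_singletons <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0) return(counts)
  counts[, colSums(counts) != 1, drop = FALSE]
}

#' Identify the core microbiome
#'
#' An ASV is core when it is present (count > 0) in at least
#' `prevalence_threshold` of the samples. Also reports the mean per-sample
#' relative abundance of the core set.
#'
#' @param counts Samples x ASVs (typically rarefied) count matrix.
#' @param prevalence_threshold Fraction of samples in (0, 1]; default 0.8.
#' @return A list: `core` (character vector of core ASV ids), `prevalence`
#'   (named per-ASV prevalence fractions), `mean_core_abundance` (mean over
#'   samples of core reads / total reads).
#' @export
identify_core <- function(counts, prevalence_threshold = 0.8) {
  if (prevalence_threshold <= 0 || prevalence_threshold > 1) {
    abort("prevalence_threshold must be in (0, 1]")
  }
  counts <- as.matrix(counts)
  prev <- colMeans(counts > 0)
  core <- colnames(counts)[prev >= prevalence_threshold]
  tot <- rowSums(counts)
  frac <- if (length(core)) {
    rowSums(counts[, core, drop = FALSE])[tot > 0] / tot[tot > 0]
  } else 0
  list(core = core, prevalence = prev,
       mean_core_abundance = mean(frac))
}

#' Square-root transform counts
#'
#' Down-weights highly abundant ASVs ahead of spatial correction and
#' community analysis.
#' @param counts Count matrix (typically rarefied).
#' @return Element-wise square root, numeric matrix.
#' @export
sqrt_transform <- function(counts) {
  sqrt(as.matrix(counts))
}

#' First principal component of soil covariates
#'
#' Mean-imputes missing entries, z-scores each variable, and extracts PC1.
#' The score sign is fixed so the pH loading is positive.
#'
#' @param soil Data frame of numeric soil variables (>= 2 columns, >= 3
#'   rows); the pH column is matched by name (`ph`, case-insensitive) for the
#'   sign convention, else the first column is used.
#' @return A list: `scores` (length-n numeric, mean 0), `loadings` (named,
#'   unit norm), `var_explained` (fraction in (0, 1]), `n_imputed`.
#' @export
soil_pc1 <- function(soil) {
  x <- as.data.frame(soil)
  x <- x[vapply(x, is.numeric, TRUE)]
  if (ncol(x) < 2 || nrow(x) < 3) abort("need >= 2 numeric variables and >= 3 samples")
  n_imputed <- 0L
  for (v in names(x)) {
    miss <- is.na(x[[v]])
    if (any(miss)) {
      x[[v]][miss] <- mean(x[[v]], na.rm = TRUE)
      n_imputed <- n_imputed + sum(miss)
    }
  }
  sds <- vapply(x, sd, 0)
  if (any(sds < 1e-12)) {
    abort(paste0("zero-variance soil variable(s): ",
                 paste(names(x)[sds < 1e-12], collapse = ", ")))
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  load <- pc$rotation[, 1]
  ph_col <- grep("^ph$", names(x), ignore.case = TRUE)
  anchor <- if (length(ph_col)) ph_col[1] else 1L
  if (load[anchor] < 0) {
    scores <- -scores; load <- -load
  }
  list(scores = as.numeric(scores), loadings = load,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2), n_imputed = n_imputed)
}
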