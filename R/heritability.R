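#' Broad- and narrow-sense heritability from variance components
#'
#' `H2 = (genetic variance) / (total variance)` over all genetic components,
#' and `h2 = (additive variance) / (total variance)`. Standard errors are
#' first-order delta-method using the component covariance matrix from the
#' REML fit; significance is called at `|z| > 1.65` (one-sided alpha 0.05).
#'
#' @param fit A [reml_fit()] object. All components except `"residual"` are
#'   treated as genetic; the additive one is named by `additive`.
#' @param additive Name of the additive component (default `"additive"`; if
#'   absent, `h2` is 0 with `NA` standard error).
#' @param z_threshold Significance threshold on the z-score (default 1.65).
#' @return A tibble with one row: `H2`, `H2_se`, `H2_z`, `h2`, `h2_se`,
#'   `h2_z`, `significant_H2`, `significant_h2`, `converged`.
#' @export
heritability <- function(fit, additive = "additive", z_threshold = 1.65) {
  comps <- fit$components
  nm <- names(comps)
  gen <- setdiff(nm, "residual")
  total <- sum(comps)
  if (isTRUE(fit$degenerate) || total <= 0) {
    return(tibble::tibble(H2 = NA_real_, H2_se = NA_real_, H2_z = NA_real_,
                          h2 = NA_real_, h2_se = NA_real_, h2_z = NA_real_,
                          significant_H2 = FALSE, significant_h2 = FALSE,
                          converged = FALSE))
  }
  g <- sum(comps[gen])
  H2 <- g / total

  delta_se <- function(grad) {
    Vc <- fit$vcov
    if (is.null(Vc)) return(NA_real_)
    Vc[is.na(Vc)] <- 0
    sqrt(max(0, as.numeric(t(grad) %*% Vc %*% grad)))
  }
  # d(g/t)/d theta_i = (t - g)/t^2 for genetic i, -g/t^2 for residual
  grad_H2 <- ifelse(nm %in% gen, (total - g) / total^2, -g / total^2)
  H2_se <- delta_se(grad_H2)

  if (additive %in% nm) {
    a <- comps[[additive]]
    h2 <- a / total
    grad_h2 <- ifelse(nm == additive, (total - a) / total^2, -a / total^2)
    h2_se <- delta_se(grad_h2)
  } else {
    h2 <- 0; h2_se <- NA_real_
  }
  H2_z <- if (is.na(H2_se) || H2_se == 0) NA_real_ else H2 / H2_se
  h2_z <- if (is.na(h2_se) || h2_se == 0) NA_real_ else h2 / h2_se
  tibble::tibble(H2 = H2, H2_se = H2_se, H2_z = H2_z,
                 h2 = h2, h2_se = h2_se, h2_z = h2_z,
                 significant_H2 = isTRUE(abs(H2_z) > z_threshold),
                 significant_h2 = isTRUE(abs(h2_z) > z_threshold),
                 converged = fit$converged)
}

# build the fixed design and incidence matrices for the per-ASV animal model
build_mm_design <- function(metadata, A) {
  geno <- as.character(metadata$genotype)
  fam <- as.character(metadata$family)
  miss <- setdiff(unique(geno), rownames(A))
  if (length(miss)) {
    abort(paste0("genotype(s) missing from relationship matrix: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  glev <- rownames(A)[rownames(A) %in% geno]
  Asub <- A[glev, glev, drop = FALSE]
  Za <- model.matrix(~ 0 + factor(geno, levels = glev))
  Zf <- model.matrix(~ 0 + factor(fam))
  X <- if ("batch" %in% names(metadata) && "soil_pc1" %in% names(metadata)) {
    model.matrix(~ factor(batch) + soil_pc1, data = metadata)
  } else if ("batch" %in% names(metadata)) {
    model.matrix(~ factor(batch), data = metadata)
  } else {
    matrix(1, nrow(metadata), 1)
  }
  list(X = X,
       random = list(additive = list(Z = Za, K = Asub),
                     family = list(Z = Zf),
                     clone = list(Z = Za)))
}

#' Per-ASV heritability scan
#'
#' Fits the three-random-effect genetic model (additive with pedigree
#' relationship matrix, full-sib family, and genotype non-additive "clone"
#' term) to every column of a spatially-corrected residual matrix and
#' computes broad- and narrow-sense heritability with delta-method standard
#' errors and z-score significance calls. Fixed effects are intercept,
#' sequencing batch and soil PC1 (taken from `metadata` when present).
#' Per-ASV failures are recorded and skipped, never aborting the scan.
#'
#' @param residuals Samples x ASVs numeric matrix of unadjusted spline
#'   residuals (negative values allowed); rownames are sample ids matching
#'   `metadata$sample` (or `metadata$tree`).
#' @param metadata Data frame with columns `genotype`, `family`, and
#'   optionally `batch`, `soil_pc1`, keyed by `sample`/`tree`.
#' @param A Additive relationship matrix covering all genotypes present.
#' @param core Optional character vector of core ASV ids for the summary's
#'   core / non-core stratification.
#' @param z_threshold Significance threshold (default 1.65).
#' @return A `herit_scan` tibble (one row per ASV, sorted by `H2`
#'   descending): `asv_id`, `sigma_a2`, `sigma_f2`, `sigma_c2`, `sigma_e2`,
#'   `H2`, `H2_se`, `H2_z`, `h2`, `h2_se`, `h2_z`, `significant_H2`,
#'   `significant_h2`, `H2_p_adj` (Benjamini-Hochberg, informational only),
#'   `converged`, `core`. `glance()` returns the summary statistics.
#' @export
heritability_scan <- function(residuals, metadata, A, core = NULL,
                              z_threshold = 1.65) {
  residuals <- as.matrix(residuals)
  empty <- tibble::tibble(
    asv_id = character(0), sigma_a2 = numeric(0), sigma_f2 = numeric(0),
    sigma_c2 = numeric(0), sigma_e2 = numeric(0), H2 = numeric(0),
    H2_se = numeric(0), H2_z = numeric(0), h2 = numeric(0),
    h2_se = numeric(0), h2_z = numeric(0), significant_H2 = logical(0),
    significant_h2 = logical(0), H2_p_adj = numeric(0),
    converged = logical(0), core = logical(0))
  if (ncol(residuals) == 0) {
    return(structure(empty, class = c("herit_scan", class(empty)),
                     summary = summarise_herit(empty)))
  }
  key <- if ("sample" %in% names(metadata)) "sample" else "tree"
  pos <- match(rownames(residuals), metadata[[key]])
  if (anyNA(pos)) abort("residual matrix rows missing from metadata")
  md <- metadata[pos, ]
  des <- build_mm_design(md, A)

  rows <- purrr::map(seq_len(ncol(residuals)), function(j) {
    asv <- colnames(residuals)[j]
    out <- tryCatch({
      fit <- reml_fit(residuals[, j], X = des$X, random = des$random)
      h <- heritability(fit, additive = "additive",
                        z_threshold = z_threshold)
      dplyr::bind_cols(
        tibble::tibble(asv_id = asv,
                       sigma_a2 = fit$components[["additive"]],
                       sigma_f2 = fit$components[["family"]],
                       sigma_c2 = fit$components[["clone"]],
                       sigma_e2 = fit$components[["residual"]]),
        h)
    }, error = function(e) NULL)
    out
  })
  failed <- colnames(residuals)[vapply(rows, is.null, TRUE)]
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) tab <- empty
  tab$H2_p_adj <- stats::p.adjust(pnorm(tab$H2_z, lower.tail = FALSE),
                                  method = "BH")
  tab$core <- if (is.null(core)) NA else tab$asv_id %in% core
  tab <- dplyr::arrange(tab, dplyr::desc(.data$H2))
  structure(tab, class = c("herit_scan", class(tab)),
            summary = summarise_herit(tab), failed = failed)
}

summarise_herit <- function(tab) {
  strata <- if (!all(is.na(tab$core))) {
    list(all = tab, core = tab[which(tab$core), ],
         noncore = tab[which(!tab$core), ])
  } else {
    list(all = tab)
  }
  purrr::imap_dfr(strata, function(t, nm) {
    sigH <- t$H2[which(t$significant_H2)]
    sigh <- t$h2[which(t$significant_h2)]
    tibble::tibble(
      stratum = nm,
      n_asv = nrow(t),
      n_significant_H2 = sum(t$significant_H2, na.rm = TRUE),
      n_significant_h2 = sum(t$significant_h2, na.rm = TRUE),
      n_H2_gt_0.2 = sum(t$H2 > 0.2, na.rm = TRUE),
      mean_H2_significant = if (length(sigH)) mean(sigH) else NA_real_,
      mean_h2_significant = if (length(sigh)) mean(sigh) else NA_real_,
      mean_H2 = mean(t$H2, na.rm = TRUE),
      mean_h2 = mean(t$h2, na.rm = TRUE))
  })
}

#' @rdname heritability_scan
#' @param x A `herit_scan` object.
#' @param ... Unused.
#' @export
glance.herit_scan <- function(x, ...) {
  attr(x, "summary")
}
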