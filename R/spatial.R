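#' Fit a two-dimensional thin-plate spline surface
#'
#' Fits a penalised thin-plate smooth of `values` over planting coordinates
#' (via `mgcv::gam` with a `s(x, y, bs = "tp")` term). Smoothness is chosen
#' by generalised cross-validation when `smoothing = "auto"`, or fixed by
#' passing a numeric smoothing parameter. Residuals capture the
#' spatially-corrected signal.
#'
#' @param x,y Numeric coordinates (planting-grid units).
#' @param values Numeric response (e.g. square-root transformed counts).
#' @param smoothing `"auto"` (GCV) or a single non-negative number (the
#'   smoothing parameter passed through as `sp`).
#' @param k Basis dimension of the thin-plate smooth (default
#'   `min(n - 2, 60)`).
#' @return A `spline_fit` list: `fitted`, `residuals`, `sp` (smoothing
#'   parameter), `edf` (effective degrees of freedom), `x`, `y`.
#' @export
fit_tps <- function(x, y, values, smoothing = "auto", k = NULL) {
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 10) abort("need at least 10 points for a thin-plate surface")
  if (qr(cbind(1, x, y))$rank < 3) {
    abort("coordinates are collinear; no 2D surface can be fitted")
  }
  if (anyDuplicated(cbind(x, y))) {
    warn("duplicate coordinates; coincident points enter as replicate observations (equivalent to averaging)")
  }
  if (is.null(k)) k <- min(n - 2L, 60L)
  dat <- data.frame(x = x, y = y, v = values)
  if (identical(smoothing, "auto")) {
    fit <- mgcv::gam(v ~ s(x, y, bs = "tp", k = k), data = dat,
                     method = "GCV.Cp")
  } else {
    stopifnot(is.numeric(smoothing), smoothing >= 0)
    fit <- mgcv::gam(v ~ s(x, y, bs = "tp", k = k), data = dat,
                     sp = smoothing)
  }
  structure(list(fitted = as.numeric(fit$fitted.values),
                 residuals = as.numeric(values - fit$fitted.values),
                 sp = as.numeric(fit$sp), edf = sum(fit$edf),
                 x = x, y = y),
            class = "spline_fit")
}

#' Shift residuals to be non-negative
#'
#' Adds the absolute value of the minimum residual to all residuals of an
#' ASV, so the minimum becomes exactly 0 and downstream abundance-based
#' dissimilarities (Bray-Curtis) receive valid non-negative input. Residual
#' vectors that are already non-negative are returned unchanged (shift 0).
#'
#' @param residuals Numeric residual vector from [fit_tps()].
#' @return A list: `values` (non-negative), `shift` (amount added).
#' @export
adjust_nonzero <- function(residuals) {
  shift <- max(0, -min(residuals))
  list(values = residuals + shift, shift = shift)
}

#' Spatially correct a transformed count matrix
#'
#' Fits one thin-plate surface per ASV over the tree coordinates and returns
#' both the raw residuals (used for heritability modelling, negative values
#' retained) and the non-negative adjusted residuals (used for community
#' analyses), matching their dual downstream usage.
#'
#' @param values Samples x ASVs numeric matrix in square-root-transformed
#'   state; rownames are sample (tree) ids.
#' @param layout Data frame with columns `tree` (or `sample`), `x`, `y`
#'   giving coordinates for every row of `values`.
#' @param smoothing,k Passed to [fit_tps()].
#' @return A `spatial_correction` list: `residuals` and `adjusted` (matrices
#'   shaped like `values`), `shifts`, `sp`, `edf` (per-ASV named vectors).
#' @export
spatial_correct_matrix <- function(values, layout, smoothing = "auto",
                                   k = NULL) {
  values <- as.matrix(values)
  key <- if ("tree" %in% names(layout)) "tree" else "sample"
  pos <- match(rownames(values), layout[[key]])
  if (anyNA(pos)) {
    abort(paste0("samples without coordinates: ",
                 paste(rownames(values)[is.na(pos)], collapse = ", ")))
  }
  x <- layout$x[pos]; y <- layout$y[pos]
  res <- adj <- values
  shifts <- sp <- edf <- setNames(numeric(ncol(values)), colnames(values))
  for (j in seq_len(ncol(values))) {
    f <- fit_tps(x, y, values[, j], smoothing = smoothing, k = k)
    res[, j] <- f$residuals
    a <- adjust_nonzero(f$residuals)
    adj[, j] <- a$values
    shifts[j] <- a$shift
    sp[j] <- f$sp[1]
    edf[j] <- f$edf
  }
  structure(list(residuals = res, adjusted = adj, shifts = shifts,
                 sp = sp, edf = edf),
            class = "spatial_correction")
}
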