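#' Bray-Curtis dissimilarity
#'
#' `d(i,j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)` on non-negative inputs
#' (counts or non-negative adjusted residuals). Pairs in which both samples
#' are all-zero are set to 0 by convention, with a warning.
#'
#' @param x Samples x variables matrix of non-negative values.
#' @return A symmetric dissimilarity matrix in `[0, 1]` with zero diagonal
#'   and sample-id dimnames.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) {
    abort("negative values; Bray-Curtis needs non-negative input (see adjust_nonzero())")
  }
  # vegdist warns about all-zero rows; the convention for those pairs is
  # applied explicitly below
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (any(!is.finite(d))) {
    warn("sample pairs with no reads at all set to dissimilarity 0")
    d[!is.finite(d)] <- 0
  }
  d
}

#' PERMDISP: homogeneity of multivariate dispersion
#'
#' For each grouping factor, embeds the distance matrix by principal
#' coordinates (with negative-eigenvalue correction), measures each sample's
#' distance to its group centroid, and tests group differences in those
#' distances by a permutation F-test (`vegan::betadisper` +
#' `vegan::permutest`). Groups of size 1 are excluded with a warning.
#'
#' @param d Square distance matrix (or `dist`).
#' @param data Data frame aligned to the rows of `d`.
#' @param factors Character vector of column names in `data` to test.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A tibble: `factor`, `df`, `F`, `p_perm`, `n_groups`.
#' @export
permdisp <- function(d, data, factors, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  purrr::map_dfr(factors, function(f) {
    g <- as.character(data[[f]])
    tab <- table(g)
    small <- names(tab)[tab < 2]
    keep <- !(g %in% small)
    if (length(small)) {
      warn(paste0("excluding ", length(small), " group(s) of size 1 for '",
                  f, "'"))
    }
    gg <- factor(g[keep])
    if (nlevels(gg) < 2) {
      return(tibble::tibble(factor = f, df = NA_real_, F = NA_real_,
                            p_perm = NA_real_, n_groups = nlevels(gg)))
    }
    bd <- vegan::betadisper(stats::as.dist(dm[keep, keep]), gg,
                            type = "centroid")
    set.seed(seed)
    pt <- vegan::permutest(bd, permutations = n_perm)
    tibble::tibble(factor = f,
                   df = pt$tab$Df[1],
                   F = pt$tab$F[1],
                   p_perm = pt$tab$`Pr(>F)`[1],
                   n_groups = nlevels(gg))
  })
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# incidence "covariance" matrix for the EMS bookkeeping of one term
term_outer <- function(col) {
  if (is.numeric(col)) {
    xc <- col - mean(col)
    tcrossprod(xc)
  } else {
    z <- model.matrix(~ 0 + factor(col))
    tcrossprod(z)
  }
}

# design-matrix columns for one term
term_design <- function(col) {
  if (is.numeric(col)) matrix(col, ncol = 1) else model.matrix(~ 0 + factor(col))
}

#' Nested PERMANOVA with Type I SS and permutation of residuals
#'
#' Distance-based multivariate ANOVA on the Gower-centred inner-product
#' matrix, partitioned sequentially (Type I) over an ordered term list.
#' Pseudo-F denominators are derived from the expected mean squares of the
#' random terms (general quadratic-form EMS, valid for unbalanced nested
#' designs); when no single later mean square matches, a linear combination
#' of mean squares is synthesised. P-values come from permutation of
#' residuals under the reduced model containing all prior terms
#' (Freedman-Lane), with complete enumeration when the number of distinct
#' orderings does not exceed `n_perm`. Components of variation are estimated
#' from the EMS equations and reported with a sign-preserving square root
#' (negative components print as negative).
#'
#' @param d Square distance matrix (or `dist`) over samples.
#' @param data Data frame aligned to the rows of `d`.
#' @param terms Ordered character vector of column names, as fitted (e.g.
#'   `c("batch", "soil_pc1", "family", "genotype")`). Numeric columns enter
#'   as 1-df regression covariates, other columns as factors. Nesting is
#'   implied by the sequential fit; child factors whose levels repeat across
#'   parents should be pre-interacted by the caller.
#' @param random Character vector naming which of `terms` are random effects
#'   (contribute variance components to EMS of earlier terms).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `permanova_nested` object; `tidy()` returns the table with
#'   columns `term`, `df`, `ss`, `ms`, `pseudo_F`, `p_perm`, `cv`, `sqrt_cv`
#'   plus `Residual` and `Total` rows.
#' @export
permanova_nested <- function(d, data, terms,
                             random = character(0),
                             n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(nrow(data) == n)
  k <- length(terms)

  # Gower-centred inner-product matrix
  A <- -0.5 * dm^2
  Cc <- diag(n) - matrix(1 / n, n, n)
  G <- Cc %*% A %*% Cc
  ss_total <- sum(diag(G))

  # cumulative hat matrices (intercept first)
  X <- matrix(1, n, 1)
  H_prev <- tcrossprod(qr.Q(qr(X)))
  Hinc <- vector("list", k)
  Hcum <- vector("list", k)
  df <- numeric(k)
  rank_prev <- 1
  for (i in seq_len(k)) {
    X <- cbind(X, term_design(data[[terms[i]]]))
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    H <- tcrossprod(Q)
    df[i] <- qrX$rank - rank_prev
    if (df[i] <= 0) {
      abort(paste0("term '", terms[i], "' is aliased with earlier terms"))
    }
    Hinc[[i]] <- H - H_prev
    Hcum[[i]] <- H
    H_prev <- H
    rank_prev <- qrX$rank
  }
  H_full <- Hcum[[k]]
  R_full <- diag(n) - H_full
  df_res <- n - rank_prev
  if (df_res <= 0) abort("no residual degrees of freedom")

  ss <- vapply(Hinc, function(h) sum(h * G), 0)
  ss_res <- sum(R_full * G)
  ms <- ss / df
  ms_res <- ss_res / df_res

  # EMS coefficients: c[i, j] = tr(Hinc_i M_j) / df_i over random terms,
  # with an implicit residual coefficient of 1 for every mean square
  rnd <- which(terms %in% random)
  M <- lapply(rnd, function(j) term_outer(data[[terms[j]]]))
  n_r <- length(rnd)
  Cems <- matrix(0, k + 1, n_r + 1,
                 dimnames = list(c(terms, "Residual"),
                                 c(terms[rnd], "Residual")))
  for (i in seq_len(k)) {
    if (n_r) {
      Cems[i, seq_len(n_r)] <-
        vapply(M, function(m) sum(Hinc[[i]] * m), 0) / df[i]
    }
    Cems[i, n_r + 1] <- 1
  }
  if (n_r) {
    Cems[k + 1, seq_len(n_r)] <-
      vapply(M, function(m) sum(R_full * m), 0) / df_res
  }
  Cems[k + 1, n_r + 1] <- 1

  # components of variation for every term (fixed terms get the analogous
  # average-squared-effect quantity), solved from the EMS equations over the
  # full term list
  Mall <- lapply(seq_len(k), function(j) term_outer(data[[terms[j]]]))
  Call <- matrix(0, k + 1, k + 1)
  for (i in seq_len(k)) {
    Call[i, seq_len(k)] <- vapply(Mall, function(m) sum(Hinc[[i]] * m), 0) / df[i]
    Call[i, k + 1] <- 1
  }
  Call[k + 1, seq_len(k)] <- vapply(Mall, function(m) sum(R_full * m), 0) / df_res
  Call[k + 1, k + 1] <- 1
  cv_all <- tryCatch(solve(Call, c(ms, ms_res)),
                     error = function(e) rep(NA_real_, k + 1))
  cv <- cv_all[seq_len(k)]
  cv_res <- cv_all[k + 1]

  # pseudo-F denominators: weights over later mean squares (+ residual)
  # reproducing the null EMS of each term
  denom_w <- vector("list", k)
  for (i in seq_len(k)) {
    target <- Cems[i, ]
    own <- match(terms[i], colnames(Cems))
    if (!is.na(own)) target[own] <- 0          # H0: own component absent
    avail <- c(setdiff(which(rnd > i), integer(0)), 0)  # indices into rnd
    rows <- c(rnd[rnd > i], k + 1)             # later random terms + residual
    Cs <- Cems[rows, , drop = FALSE]
    w <- tryCatch(qr.solve(t(Cs), target), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) {
      w <- c(rep(0, length(rows) - 1), 1)      # fall back to residual MS
    }
    denom_w[[i]] <- list(rows = rows, w = w)
  }
  ms_vec <- c(ms, ms_res)
  denom_ms <- vapply(denom_w, function(dw) sum(dw$w * ms_vec[dw$rows]), 0)
  pseudo_F <- ms / denom_ms

  # permutation of residuals under the reduced model, per term
  set.seed(seed)
  exhaustive <- factorial(n) <= n_perm
  perms <- if (exhaustive) {
    all_perms(n)
  } else {
    lapply(seq_len(n_perm), function(i) sample.int(n))
  }
  p_perm <- numeric(k)
  for (i in seq_len(k)) {
    H_red <- if (i == 1) tcrossprod(rep(1 / sqrt(n), n)) else Hcum[[i - 1]]
    R_red <- diag(n) - H_red
    Gr <- R_red %*% G %*% R_red
    rows <- denom_w[[i]]$rows; w <- denom_w[[i]]$w
    stat <- function(Gp) {
      num <- sum(Hinc[[i]] * Gp) / df[i]
      ms_p <- vapply(rows, function(r) {
        if (r == k + 1) sum(R_full * Gp) / df_res
        else sum(Hinc[[r]] * Gp) / df[r]
      }, 0)
      num / sum(w * ms_p)
    }
    f_obs <- stat(Gr)   # equals pseudo_F[i] (reduced-model projection is
                        # orthogonal to Hinc_i and the denominator projectors)
    f_perm <- vapply(perms, function(pp) stat(Gr[pp, pp]), 0)
    p_perm[i] <- if (exhaustive) {
      mean(f_perm >= f_obs - 1e-12)
    } else {
      (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    }
  }

  cv_col <- c(cv, cv_res, NA)
  tab <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    ss = c(ss, ss_res, ss_total),
    ms = c(ms, ms_res, NA),
    pseudo_F = c(pseudo_F, NA, NA),
    p_perm = c(p_perm, NA, NA),
    cv = cv_col,
    sqrt_cv = sqrt_cv(cv_col))
  structure(list(table = tab, n = n, n_perm = n_perm,
                 exhaustive = exhaustive, random = random, seed = seed),
            class = "permanova_nested")
}

#' Sign-preserving square root of components of variation
#'
#' Negative variance components (a by-product of the EMS estimators) are
#' represented as negative square roots, `sign(cv) * sqrt(|cv|)`.
#' @param cv Numeric vector of components of variation.
#' @return Numeric vector of signed square roots.
#' @export
sqrt_cv <- function(cv) {
  sign(cv) * sqrt(abs(cv))
}

#' @export
print.permanova_nested <- function(x, ...) {
  cat("Nested PERMANOVA (Type I SS, permutation of residuals,",
      x$n_perm, "permutations", if (x$exhaustive) "- complete enumeration",
      ")\n", sep = " ")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname permanova_nested
#' @param x A `permanova_nested` object.
#' @param ... Unused.
#' @export
tidy.permanova_nested <- function(x, ...) {
  x$table
}
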