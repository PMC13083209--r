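#' Average-information REML for variance components
#'
#' Fits `y = Xb + sum_i Z_i u_i + e` with `u_i ~ N(0, K_i sigma_i^2)` and
#' `e ~ N(0, I sigma_e^2)` by residual maximum likelihood. Updates are
#' average-information (AI) steps with step-halving against the REML
#' log-likelihood and a multiplicative EM-style fallback; components are
#' constrained to at least `1e-8 * var(y)`. Standard errors come from the
#' inverse AI matrix at the optimum.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (including intercept). Default:
#'   intercept only.
#' @param random Named list of random terms; each element is a list with `Z`
#'   (n x q incidence matrix) and optionally `K` (q x q covariance structure,
#'   default identity).
#' @param maxit Maximum iterations (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param verbose Print iteration trace.
#' @return A `reml_fit` object: `components` (named, residual last), `se`,
#'   `vcov`, `loglik`, `converged`, `boundary` (logical per component),
#'   `iterations`, `n`.
#' @export
reml_fit <- function(y, X = NULL, random, maxit = 200, tol = 1e-8,
                     verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  qrx <- qr(X)
  X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]  # drop aliased columns
  stopifnot(nrow(X) == n)
  vy <- var(y)
  k <- length(random)
  nm <- names(random)
  if (is.null(nm) || any(nm == "")) nm <- paste0("vc", seq_len(k))

  if (!is.finite(vy) || vy < 1e-12) {
    comps <- setNames(c(rep(0, k), max(vy, 0)), c(nm, "residual"))
    return(structure(list(components = comps,
                          se = setNames(rep(NA_real_, k + 1), names(comps)),
                          vcov = NULL, loglik = NA_real_, converged = FALSE,
                          degenerate = TRUE,
                          boundary = setNames(rep(TRUE, k + 1), names(comps)),
                          iterations = 0L, n = n),
                     class = "reml_fit"))
  }

  # per-term n x n covariance contributions
  Vi <- lapply(random, function(r) {
    Z <- as.matrix(r$Z)
    stopifnot(nrow(Z) == n)
    if (is.null(r$K)) tcrossprod(Z) else Z %*% r$K %*% t(Z)
  })
  Vi[[k + 1]] <- diag(n)
  names(Vi) <- c(nm, "residual")

  floor_vc <- 1e-8 * vy
  theta <- rep(vy / (k + 1), k + 1)

  eval_ll <- function(th) {
    V <- Reduce(`+`, Map(`*`, Vi, th))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - W %*% chol2inv(chx) %*% t(W)
    Py <- as.numeric(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py)
  }

  st <- eval_ll(theta)
  if (is.null(st)) abort("initial covariance matrix not positive definite")
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(maxit)) {
    P <- st$P; Py <- st$Py
    Q <- vapply(Vi, function(v) as.numeric(v %*% Py), numeric(n))  # n x (k+1)
    PQ <- P %*% Q
    score <- vapply(seq_len(k + 1), function(i) {
      -0.5 * (sum(P * Vi[[i]]) - sum(Py * Q[, i]))
    }, 0)
    AI <- 0.5 * crossprod(Q, PQ)

    # KKT active set: components at the floor with a negative score stay
    # pinned; the AI step is solved on the free subset only
    pinned <- theta <= floor_vc * (1 + 1e-6) & score < 0
    free_i <- which(!pinned)
    if (!length(free_i)) { converged <- TRUE; break }
    step <- rep(0, k + 1)
    sf <- tryCatch(solve(AI[free_i, free_i, drop = FALSE], score[free_i]),
                   error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(sf) && all(is.finite(sf))) {
      step[free_i] <- sf
      h <- 1
      for (half in 1:10) {
        cand <- pmax(theta + h * step, floor_vc)
        st2 <- eval_ll(cand)
        if (!is.null(st2) && st2$ll >= st$ll - 1e-10) {
          theta_new <- cand; st_new <- st2; accepted <- TRUE
          break
        }
        h <- h / 2
      }
    }
    if (!accepted) {
      # EM-style multiplicative fallback on the free subset: fixed point of
      # the REML score, positive by construction
      ratio <- rep(1, k + 1)
      ratio[free_i] <- vapply(free_i, function(i) {
        tr <- sum(P * Vi[[i]])
        if (tr <= 0) 1 else sum(Py * Q[, i]) / tr
      }, 0)
      cand <- pmax(theta * ratio, floor_vc)
      st2 <- eval_ll(cand)
      if (is.null(st2) || st2$ll < st$ll - 1e-8) break  # give up cleanly
      theta_new <- cand; st_new <- st2
    }
    done <- abs(st_new$ll - st$ll) < tol * (abs(st$ll) + 1)
    theta <- theta_new; st <- st_new
    if (verbose) {
      cat(sprintf("it %3d  ll %.8f  theta %s\n", it, st$ll,
                  paste(signif(theta, 4), collapse = " ")))
    }
    if (done) { converged <- TRUE; break }
  }

  boundary <- theta <= floor_vc * (1 + 1e-6)
  # Covariance of the estimates from the projected (free-subset) inverse AI
  # matrix: components pinned at the floor are held fixed (zero rows/cols,
  # SE 0) and flagged, keeping the matrix positive semi-definite for the
  # delta method downstream.
  se <- rep(0, k + 1)
  vc_mat <- matrix(0, k + 1, k + 1)
  free <- which(!boundary)
  if (length(free)) {
    Vfree <- tryCatch(solve(AI[free, free, drop = FALSE]),
                      error = function(e) NULL)
    if (is.null(Vfree)) {  # ridge fallback for an ill-conditioned optimum
      Vfree <- tryCatch(
        solve(AI[free, free, drop = FALSE] +
                diag(1e-8 * max(diag(AI)), length(free))),
        error = function(e) NULL)
    }
    if (!is.null(Vfree)) {
      vc_mat[free, free] <- Vfree
      se[free] <- sqrt(pmax(diag(as.matrix(Vfree)), 0))
    } else {
      se[free] <- NA_real_
    }
  }
  names(theta) <- names(se) <- c(nm, "residual")
  dimnames(vc_mat) <- list(names(theta), names(theta))
  structure(list(components = theta, se = se, vcov = vc_mat,
                 loglik = st$ll, converged = converged, degenerate = FALSE,
                 boundary = setNames(boundary, names(theta)),
                 iterations = it, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML variance components (loglik ", signif(x$loglik, 8),
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  print(data.frame(component = names(x$components),
                   estimate = x$components, se = x$se,
                   boundary = x$boundary, row.names = NULL), digits = 4)
  invisible(x)
}

#' @rdname reml_fit
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(component = names(x$components),
                 estimate = unname(x$components),
                 std.error = unname(x$se),
                 boundary = unname(x$boundary))
}

#' @rdname reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations, nobs = x$n)
}
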