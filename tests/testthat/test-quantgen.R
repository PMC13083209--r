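# balanced clonal design fixture: g genotypes x k ramets, iid genotype effects
balanced_clonal <- function(g = 30, k = 4, sg2 = 0.5, se2 = 1, seed = 1) {
  set.seed(seed)
  geno <- rep(seq_len(g), each = k)
  y <- rnorm(g, 0, sqrt(sg2))[geno] + rnorm(g * k, 0, sqrt(se2))
  list(y = y, geno = geno,
       Z = model.matrix(~ 0 + factor(geno)))
}

test_that("REML equals the closed-form ANOVA estimator on balanced designs", {
  for (seed in c(1, 3, 9)) {
    bc <- balanced_clonal(seed = seed)
    fit <- reml_fit(bc$y, random = list(clone = list(Z = bc$Z)))
    ms <- anova(stats::aov(bc$y ~ factor(bc$geno)))$`Mean Sq`
    closed <- (ms[1] - ms[2]) / 4
    if (closed > 0) {
      expect_lt(abs(fit$components[["clone"]] - closed) / closed, 1e-6)
      expect_lt(abs(fit$components[["residual"]] - ms[2]) / ms[2], 1e-6)
    }
    expect_true(fit$converged)
  }
})

test_that("estimates are location invariant and scale equivariant", {
  bc <- balanced_clonal(seed = 5)
  f0 <- reml_fit(bc$y, random = list(clone = list(Z = bc$Z)))
  f1 <- reml_fit(bc$y + 100, random = list(clone = list(Z = bc$Z)))
  f2 <- reml_fit(3 * bc$y, random = list(clone = list(Z = bc$Z)))
  expect_equal(f0$components, f1$components, tolerance = 1e-5)
  expect_equal(unname(f2$components / f0$components), rep(9, 2),
               tolerance = 1e-5)
})

test_that("pure-noise responses put genetic components at the boundary", {
  st <- small_study(seed = 41, n_asv = 1)
  md <- st$metadata
  des <- microherit:::build_mm_design(md, st$A)
  set.seed(2)
  gen_means <- vapply(1:25, function(i) {
    fit <- reml_fit(rnorm(nrow(md)), X = des$X, random = des$random)
    sum(fit$components[c("additive", "family", "clone")])
  }, 0)
  expect_lt(mean(gen_means), 0.12)   # boundary mass near zero
  fit <- reml_fit(rnorm(nrow(md)), X = des$X, random = des$random)
  expect_true(all(fit$components >= 0))
})

test_that("constant responses degrade gracefully", {
  st <- small_study(seed = 42, n_asv = 1)
  des <- microherit:::build_mm_design(st$metadata, st$A)
  fit <- reml_fit(rep(1, nrow(st$metadata)), X = des$X, random = des$random)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  h <- heritability(fit)
  expect_false(h$significant_H2)
})

test_that("heritability ratios follow their definitions", {
  fake <- structure(list(
    components = c(additive = 1, family = 1, clone = 1, residual = 1),
    se = rep(0.1, 4), vcov = diag(0.01, 4), converged = TRUE,
    degenerate = FALSE, boundary = rep(FALSE, 4)), class = "reml_fit")
  h <- heritability(fake)
  expect_equal(h$H2, 0.75)
  expect_equal(h$h2, 0.25)
  expect_true(h$h2 <= h$H2)
  # all-genetic-zero null
  null <- fake
  null$components <- c(additive = 0, family = 0, clone = 0, residual = 1)
  h0 <- heritability(null)
  expect_equal(h0$H2, 0)
  expect_equal(h0$h2, 0)
})

test_that("delta-method SE agrees with a parametric bootstrap", {
  # small balanced clonal design, one simulated trait
  g <- 25; k <- 4
  geno <- rep(seq_len(g), each = k)
  Z <- model.matrix(~ 0 + factor(geno))
  sg2 <- 0.6; se2 <- 1
  set.seed(11)
  y <- rnorm(g, 0, sqrt(sg2))[geno] + rnorm(g * k, 0, sqrt(se2))
  fit <- reml_fit(y, random = list(clone = list(Z = Z)))
  h <- heritability(fit, additive = "none")
  boot <- vapply(1:200, function(b) {
    set.seed(1000 + b)
    yb <- rnorm(g, 0, sqrt(fit$components[["clone"]]))[geno] +
      rnorm(g * k, 0, sqrt(fit$components[["residual"]]))
    fb <- reml_fit(yb, random = list(clone = list(Z = Z)))
    heritability(fb, additive = "none")$H2
  }, 0)
  expect_lt(abs(h$H2_se - sd(boot)) / sd(boot), 0.25)
})

test_that("the REML log-likelihood never decreases across iterations", {
  st <- small_study(seed = 43, n_asv = 4)
  sq <- sqrt_transform(st$counts)
  spc <- spatial_correct_matrix(sq, st$metadata)
  des <- microherit:::build_mm_design(aligned_md(st, spc$residuals), st$A)
  for (j in 1:4) {
    out <- utils::capture.output(
      fit <- reml_fit(spc$residuals[, j], X = des$X, random = des$random,
                      verbose = TRUE))
    ll <- as.numeric(sub(".*ll ([-0-9.]+).*", "\\1", out))
    expect_true(all(diff(ll) > -1e-6))
  }
})

test_that("the per-ASV scan recovers strong simulated signal and ranks it", {
  st <- simulate_study(n_families = 10, n_genotypes = 36,
                       ramets_per_genotype = 4,
                       architecture = genetic_architecture(
                         n_loci = 60, additive_sd = 0.15, dominance_sd = 0.1),
                       params = asv_sim_params(n_asv = 16, genetic_sd = 0,
                                               spatial_sd = 0.2, depth = 2000),
                       seed = 51)
  # hand-pick: give half the ASVs a strong genetic slope by resimulating
  md <- st$metadata
  set.seed(52)
  g <- st$genetic_values$total[match(md$genotype, st$genetic_values$id)]
  g <- (g - mean(g)) / sd(g)
  n <- nrow(md); J <- 12
  resid <- matrix(rnorm(n * J, 0, 1), n,
                  dimnames = list(md$tree, sprintf("sim%02d", 1:J)))
  signal <- 1:4   # H2 target 0.5: var(g-term) = var(noise)
  for (j in signal) resid[, j] <- g + rnorm(n, 0, 1)
  scan <- heritability_scan(resid, md, st$A)
  expect_s3_class(scan, "herit_scan")
  expect_true(all(scan$h2 <= scan$H2 + 1e-10))
  top4 <- scan$asv_id[1:4]
  expect_gte(length(intersect(top4, sprintf("sim%02d", signal))), 3)
  expect_gt(mean(scan$H2[scan$asv_id %in% sprintf("sim%02d", signal)]), 0.25)
  expect_lt(mean(scan$H2[!scan$asv_id %in% sprintf("sim%02d", signal)]), 0.2)
  # summary structure
  gl <- glance(scan)
  expect_equal(gl$n_asv[gl$stratum == "all"], J)
  # empty input -> empty table
  empty <- heritability_scan(resid[, 0, drop = FALSE], md, st$A)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(glance(empty)), 1)
})
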