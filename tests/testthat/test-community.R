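test_that("Bray-Curtis matches hand evaluation and boundary cases", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3),
             d = c(0, 0, 5))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], (2 + 0 + 2) / 12)  # 1/3
  expect_equal(d["a", "c"], 0)                  # identical rows
  e <- rbind(a = c(2, 0), b = c(0, 3))
  expect_equal(bray_curtis(e)["a", "b"], 1)     # disjoint support
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
  # all-zero pair convention
  z <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_warning(dz <- bray_curtis(z), "no reads")
  expect_equal(dz["a", "b"], 0)
})

test_that("PERMDISP on univariate Euclidean input equals the classical F", {
  set.seed(5)
  y <- c(rnorm(20), rnorm(20, 0, 3))
  grp <- rep(c("a", "b"), each = 20)
  d <- as.matrix(dist(y))
  pd <- permdisp(d, data.frame(g = grp), "g", n_perm = 199, seed = 1)
  dev <- abs(y - ave(y, grp))
  Fc <- anova(stats::aov(dev ~ grp))$`F value`[1]
  expect_equal(pd$F, Fc, tolerance = 1e-8)
  expect_lt(pd$p_perm, 0.05)  # 5x dispersion inflation must be detected
  # size-1 groups are excluded with a warning
  grp2 <- grp; grp2[1] <- "solo"
  expect_warning(permdisp(d, data.frame(g = grp2), "g", n_perm = 49, seed = 1),
                 "size 1")
})

test_that("null PERMDISP p-values are not systematically small", {
  set.seed(8)
  ps <- vapply(1:30, function(i) {
    y <- matrix(rnorm(30 * 3), 30)
    d <- as.matrix(dist(y))
    permdisp(d, data.frame(g = rep(c("a", "b"), each = 15)), "g",
             n_perm = 99, seed = i)$p_perm
  }, 0)
  expect_gt(mean(ps), 0.25)
  expect_gt(mean(ps > 0.05), 0.75)
})

test_that("univariate Euclidean one-way pseudo-F equals the classical F", {
  set.seed(2)
  y <- rnorm(24) + rep(c(0, 0.5, 0, 1), each = 6)
  g <- rep(letters[1:4], each = 6)
  d <- as.matrix(dist(y))
  pm <- permanova_nested(d, data.frame(g = g), terms = "g",
                         n_perm = 99, seed = 1)
  Fc <- anova(stats::aov(y ~ g))$`F value`[1]
  expect_equal(tidy(pm)$pseudo_F[1], Fc, tolerance = 1e-10)
  expect_equal(tidy(pm)$df[1], 3)
})

test_that("sequential SS partition is exact and aliasing is caught", {
  st <- small_study(seed = 31, n_asv = 8)
  sq <- sqrt_transform(st$counts)
  spc <- spatial_correct_matrix(sq, st$metadata)
  d <- bray_curtis(spc$adjusted)
  md <- aligned_md(st, spc$adjusted)
  pm <- permanova_nested(d, md, terms = c("batch", "soil_pc1", "family",
                                          "genotype"),
                         random = c("family", "genotype"),
                         n_perm = 49, seed = 1)
  tab <- tidy(pm)
  k <- nrow(tab)
  expect_lt(abs(sum(tab$ss[1:(k - 1)]) - tab$ss[k]) / tab$ss[k], 1e-8)
  expect_true(all(tab$p_perm[1:4] >= 1 / 50 & tab$p_perm[1:4] <= 1))
  # residual CV is the residual MS; sqrt_cv preserves sign
  expect_equal(tab$cv[k - 1], tab$ms[k - 1])
  # genotype duplicated as an alias
  md2 <- md
  md2$geno_copy <- md$genotype
  expect_error(permanova_nested(d, md2,
                                terms = c("genotype", "geno_copy"),
                                n_perm = 9, seed = 1),
               "aliased")
})

test_that("exhaustive enumeration matches a brute-force univariate oracle", {
  y <- c(1.2, 0.3, 2.5, -0.4, 0.9, 3.1)
  g <- rep(c("a", "b"), each = 3)
  d <- as.matrix(dist(y))
  pm <- permanova_nested(d, data.frame(g = g), terms = "g",
                         n_perm = 999, seed = 1)
  expect_true(pm$exhaustive)
  # oracle: classical F over all 720 orderings of the response
  Fobs <- anova(stats::aov(y ~ g))$`F value`[1]
  perms <- microherit:::all_perms(6)
  fs <- vapply(perms, function(p) {
    anova(stats::aov(y[p] ~ g))$`F value`[1]
  }, 0)
  p_exact <- mean(fs >= Fobs - 1e-12)
  expect_equal(tidy(pm)$p_perm[1], p_exact, tolerance = 1e-12)
})

test_that("exhaustive p-values are invariant to input sample order", {
  y <- c(1.2, 0.3, 2.5, -0.4, 0.9, 3.1)
  g <- rep(c("a", "b"), each = 3)
  d <- as.matrix(dist(y))
  rownames(d) <- colnames(d) <- sprintf("s%d", 1:6)
  p1 <- tidy(permanova_nested(d, data.frame(g = g), terms = "g",
                              n_perm = 999, seed = 1))$p_perm[1]
  o <- c(4, 2, 6, 1, 3, 5)
  p2 <- tidy(permanova_nested(d[o, o], data.frame(g = g[o]), terms = "g",
                              n_perm = 999, seed = 1))$p_perm[1]
  expect_equal(p1, p2)
})

test_that("the family pseudo-F is tested against the genotype mean square", {
  # balanced nested design with a strong family effect and null genotype
  set.seed(6)
  nf <- 8; ng <- 3; nr <- 4
  fam <- rep(sprintf("f%d", 1:nf), each = ng * nr)
  geno <- rep(sprintf("g%d", 1:(nf * ng)), each = nr)
  y <- rnorm(nf, 0, 2)[as.integer(factor(fam))] + rnorm(length(fam))
  d <- as.matrix(dist(y))
  pm <- permanova_nested(d, data.frame(family = fam, genotype = geno),
                         terms = c("family", "genotype"),
                         random = c("family", "genotype"),
                         n_perm = 199, seed = 2)
  tab <- tidy(pm)
  # classical nested ANOVA oracle: F_family = MS_family / MS_genotype
  a <- anova(stats::aov(y ~ factor(fam) / factor(geno)))
  F_fam <- a$`Mean Sq`[1] / a$`Mean Sq`[2]
  expect_equal(tab$pseudo_F[tab$term == "family"], F_fam, tolerance = 1e-8)
  expect_lt(tab$p_perm[tab$term == "family"], 0.05)
})

test_that("signed square roots of components of variation", {
  expect_equal(sqrt_cv(c(4, -4, 0)), c(2, -2, 0))
})
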