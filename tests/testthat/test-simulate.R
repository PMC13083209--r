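test_that("default pedigree generator matches the study design", {
  gp <- generate_pedigree(seed = 1)
  expect_equal(nrow(gp$genotypes), 132)
  expect_equal(length(unique(gp$genotypes$family)), 28)
  sizes <- table(gp$genotypes$family)
  expect_true(all(sizes >= 3 & sizes <= 6))
  # full sibs share both parents
  one <- gp$genotypes[gp$genotypes$family == gp$genotypes$family[1], ]
  expect_equal(length(unique(one$sire)), 1)
  expect_equal(length(unique(one$dam)), 1)
  # determinism
  gp2 <- generate_pedigree(seed = 1)
  expect_identical(gp$ped, gp2$ped)
  expect_error(generate_pedigree(n_families = 10, n_genotypes = 5),
               "incompatible")
})

test_that("two-generation disjoint-parent pedigree gives block-diagonal A", {
  gp <- generate_pedigree(n_families = 5, n_genotypes = 20, generations = 2,
                          n_parents = 40, share_parents = FALSE, seed = 3)
  A <- additive_relationship(gp$ped, keep = gp$genotypes$genotype)
  same_fam <- outer(gp$genotypes$family, gp$genotypes$family, "==")
  expect_equal(unname(A[same_fam & upper.tri(A)]),
               rep(0.5, sum(same_fam & upper.tri(A))))
  expect_equal(unname(A[!same_fam]), rep(0, sum(!same_fam)))
})

test_that("layout satisfies the single-tree incomplete-block constraints", {
  gp <- generate_pedigree(seed = 5)
  lay <- generate_layout(gp$genotypes$genotype, seed = 5)
  expect_equal(nrow(lay), 528)
  expect_false(any(duplicated(lay[, c("x", "y")])))
  # each genotype at most once per block
  expect_equal(max(table(lay$genotype, lay$block)), 1)
  expect_true(all(table(lay$block) <= 36))
  # determinism and degenerate blocks
  expect_identical(lay, generate_layout(gp$genotypes$genotype, seed = 5))
  solo <- generate_layout(letters[1:4], ramets_per_genotype = 2,
                          block_capacity = 1, seed = 1)
  expect_equal(max(table(solo$block)), 1)
  expect_error(generate_layout(letters[1:9], ramets_per_genotype = 4,
                               block_capacity = 100),
               "infeasible")
})

test_that("gene dropping has the classical additive variance and null limits", {
  ped <- pedigree(sprintf("i%d", 1:300), rep(NA, 300), rep(NA, 300))
  # all scales zero -> values exactly zero
  zero <- gene_drop(ped, genetic_architecture(n_loci = 10, additive_sd = 0,
                                              dominance_sd = 0), seed = 1)
  expect_equal(zero$total, rep(0, 300))

  # purely additive, unrelated, p = 0.5: Var = sum 2p(1-p) a_l^2
  arch <- genetic_architecture(n_loci = 50, allele_freq = 0.5,
                               additive_sd = 0.3)
  gv <- gene_drop(ped, arch, seed = 9)
  set.seed(9)
  a_eff <- rnorm(50, 0, 0.3)
  expected <- sum(0.5 * a_eff^2)
  expect_lt(abs(var(gv$total) - expected) / expected, 0.15)
  expect_equal(gv$total, gv$additive)

  # determinism
  expect_identical(gv, gene_drop(ped, arch, seed = 9))
})

test_that("pure-dominance full-sib partition approaches 25/75", {
  dp <- dominance_partition(n_loci = 400, n_families = 120,
                            progeny_per_family = 25, seed = 5)
  expect_lt(abs(dp$between_pct - 25), 3)
  expect_lt(abs(dp$within_pct - 75), 3)
})

test_that("soil generator reproduces its configured moments", {
  s <- simulate_soil(20000, seed = 2)
  def <- soil_defaults()
  expect_lt(abs(mean(s$ph) - def$means["ph"]), 3 * def$sds["ph"] / sqrt(20000))
  expect_lt(abs(sd(s$moisture) - def$sds["moisture"]), 0.15)
  expect_lt(abs(cor(s$ph, s$total_c) - (-0.78)), 0.02)
  # identity correlation -> independent columns
  ind <- simulate_soil(5000, correlation = diag(4), seed = 3)
  expect_lt(max(abs(cor(as.matrix(ind))[upper.tri(diag(4))])), 0.05)
  # perfectly collinear pair -> PC1 of the pair explains ~100%
  R <- diag(4); R[1, 3] <- R[3, 1] <- 1
  expect_warning(col <- simulate_soil(500, correlation = R, seed = 4),
                 "positive definite")
  pc <- soil_pc1(col[, c(1, 3)])
  expect_gt(pc$var_explained, 0.99)
})

test_that("count simulation is deterministic with recorded variance shares", {
  st <- small_study(seed = 11, n_asv = 15)
  st2 <- small_study(seed = 11, n_asv = 15)
  expect_identical(st$counts, st2$counts)
  expect_identical(st$metadata, st2$metadata)
  expect_true(all(st$counts >= 0))
  expect_true(all(rowSums(st$counts) > 0))
  shares <- as.matrix(st$truth[, c("genetic", "spatial", "batch", "soil",
                                   "residual")])
  expect_true(all(shares >= 0))
  expect_equal(unname(rowSums(shares)), rep(1, nrow(shares)))
  # core ASVs are simulated at high prevalence
  core_asv <- st$truth$asv[st$truth$core]
  prev <- colMeans(st$counts[, core_asv, drop = FALSE] > 0)
  expect_true(all(prev >= 0.8))
})

test_that("null genetic signal leaves heritability centred at zero downstream", {
  st <- simulate_study(n_families = 6, n_genotypes = 18,
                       ramets_per_genotype = 3,
                       architecture = genetic_architecture(n_loci = 10,
                                                           additive_sd = 0,
                                                           dominance_sd = 0),
                       params = asv_sim_params(n_asv = 8, genetic_sd = 0,
                                               spatial_sd = 0, depth = 1500),
                       seed = 13)
  md <- st$metadata
  sq <- sqrt_transform(st$counts)
  spc <- spatial_correct_matrix(sq, md)
  scan <- heritability_scan(spc$residuals, md, st$A)
  expect_lt(mean(scan$H2, na.rm = TRUE), 0.15)
})
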