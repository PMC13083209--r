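#' Child seeds from a master seed
#'
#' Deterministically derives per-component seeds so pipeline stages can be
#' regenerated independently. Kept below 2^31 - 1.
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a multi-generation full-sib pedigree
#'
#' Builds a pedigree whose final generation holds the study genotypes grouped
#' into control-pollinated full-sib families. Earlier generations are crosses
#' of unrelated founders; the family parents are drawn (with reuse) from the
#' penultimate generation, so some families share a parent and are half-sib
#' related — the structure the study design relies on.
#'
#' @param n_families Number of full-sib families (default 28).
#' @param family_size_range Integer range of genotypes per family (default
#'   3:6).
#' @param n_genotypes Total number of study genotypes; family sizes are drawn
#'   from `family_size_range` and adjusted within the range to hit this total
#'   (default 132).
#' @param generations Pedigree depth including the genotype generation
#'   (default 3: founders, parents, genotypes).
#' @param n_parents Size of the parent pool the family crosses are drawn from.
#' @param share_parents If `TRUE` (default) parents may appear in several
#'   crosses, creating half-sib links between families; if `FALSE` families
#'   get disjoint parent pairs (requires `n_parents >= 2 * n_families`).
#' @param seed Integer seed.
#' @return A list with `ped` (sorted pedigree tibble) and `genotypes`
#'   (tibble: `genotype`, `family`, `sire`, `dam`).
#' @export
generate_pedigree <- function(n_families = 28, family_size_range = 3:6,
                              n_genotypes = 132, generations = 3,
                              n_parents = 40, share_parents = TRUE,
                              seed = 1) {
  stopifnot(generations >= 2, n_parents >= 4)
  lo <- min(family_size_range); hi <- max(family_size_range)
  if (n_genotypes < n_families * lo || n_genotypes > n_families * hi) {
    abort("n_genotypes incompatible with n_families and family_size_range")
  }
  if (n_families > choose(n_parents, 2)) {
    abort("not enough distinct parent pairs for the requested families")
  }
  set.seed(seed)

  # family sizes: draw then nudge within bounds to hit the total
  sizes <- sample(seq(lo, hi), n_families, replace = TRUE)
  excess <- sum(sizes) - n_genotypes
  while (excess != 0) {
    if (excess > 0) {
      k <- sample(which(sizes > lo), 1)
      sizes[k] <- sizes[k] - 1L; excess <- excess - 1L
    } else {
      k <- sample(which(sizes < hi), 1)
      sizes[k] <- sizes[k] + 1L; excess <- excess + 1L
    }
  }

  id <- character(0); sire <- character(0); dam <- character(0)
  add <- function(i, s, d) {
    id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
  }
  # generation 1: founders; with depth 2 the founders ARE the parent pool
  n_founders <- if (generations == 2) n_parents else
    max(4L, ceiling(n_parents / 2) + 2L)
  founders <- sprintf("F%03d", seq_len(n_founders))
  for (f in founders) add(f, NA, NA)
  pool <- founders
  # intermediate generations down to the parent pool
  for (g in seq_len(generations - 2)) {
    n_out <- if (g == generations - 2) n_parents else n_parents
    kids <- sprintf("G%d_%03d", g, seq_len(n_out))
    for (k in kids) {
      pr <- sample(pool, 2)
      add(k, pr[1], pr[2])
    }
    pool <- kids
  }
  # family crosses: distinct unordered parent pairs from the pool
  if (share_parents) {
    pairs <- list()
    seen <- character(0)
    while (length(pairs) < n_families) {
      pr <- sort(sample(pool, 2))
      key <- paste(pr, collapse = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        pairs[[length(pairs) + 1]] <- pr
      }
    }
  } else {
    if (length(pool) < 2 * n_families) {
      abort("share_parents = FALSE needs n_parents >= 2 * n_families")
    }
    picked <- sample(pool, 2 * n_families)
    pairs <- lapply(seq_len(n_families),
                    function(f) picked[c(2 * f - 1, 2 * f)])
  }
  genotype <- character(0); family <- character(0)
  gsire <- character(0); gdam <- character(0)
  for (f in seq_len(n_families)) {
    fam <- sprintf("FAM%02d", f)
    for (k in seq_len(sizes[f])) {
      g <- sprintf("%s_G%d", fam, k)
      add(g, pairs[[f]][1], pairs[[f]][2])
      genotype <- c(genotype, g); family <- c(family, fam)
      gsire <- c(gsire, pairs[[f]][1]); gdam <- c(gdam, pairs[[f]][2])
    }
  }
  ped <- ped_validate(tibble::tibble(id = id, sire = sire, dam = dam))
  list(ped = ped,
       genotypes = tibble::tibble(genotype = genotype, family = family,
                                  sire = gsire, dam = gdam))
}

#' Generate a single-tree incomplete-block trial layout
#'
#' Places `ramets_per_genotype` clonal copies of each genotype on a regular
#' planting grid tiled into contiguous square-ish blocks, such that no block
#' contains the same genotype twice (single-tree incomplete block design).
#'
#' @param genotypes Character vector of genotype ids.
#' @param ramets_per_genotype Clonal copies per genotype (default 4).
#' @param block_capacity Trees per block (default 36).
#' @param seed Integer seed.
#' @return A tibble with columns `tree`, `genotype`, `ramet`, `block`, `x`,
#'   `y` (planting-grid units).
#' @export
generate_layout <- function(genotypes, ramets_per_genotype = 4,
                            block_capacity = 36, seed = 1) {
  n_geno <- length(genotypes)
  n_trees <- n_geno * ramets_per_genotype
  n_blocks <- ceiling(n_trees / block_capacity)
  if (n_blocks < ramets_per_genotype) {
    abort("fewer blocks than ramets per genotype: incomplete-block constraint infeasible")
  }
  set.seed(seed)

  # assign each genotype to distinct blocks, weighted by remaining capacity
  assign_blocks <- function() {
    cap <- rep(block_capacity, n_blocks)
    out <- matrix(NA_integer_, n_geno, ramets_per_genotype)
    for (g in sample(n_geno)) {
      open <- which(cap > 0)
      if (length(open) < ramets_per_genotype) return(NULL)
      bl <- sample(open, ramets_per_genotype, prob = cap[open])
      out[g, ] <- bl
      cap[bl] <- cap[bl] - 1L
    }
    out
  }
  blocks <- NULL
  for (try in 1:200) {
    blocks <- assign_blocks()
    if (!is.null(blocks)) break
  }
  if (is.null(blocks)) abort("could not satisfy block capacities")

  # contiguous square tiles: block side, blocks tiled near-square
  side <- ceiling(sqrt(block_capacity))
  bcols <- ceiling(sqrt(n_blocks))
  brows <- ceiling(n_blocks / bcols)
  cells <- lapply(seq_len(n_blocks), function(b) {
    br <- (b - 1) %/% bcols; bc <- (b - 1) %% bcols
    expand.grid(x = bc * side + seq_len(side),
                y = br * side + seq_len(side))[seq_len(block_capacity), ]
  })
  used <- integer(n_blocks)
  rows <- vector("list", n_trees)
  k <- 0
  for (g in seq_len(n_geno)) {
    for (r in seq_len(ramets_per_genotype)) {
      b <- blocks[g, r]
      used[b] <- used[b] + 1L
      k <- k + 1
      rows[[k]] <- tibble::tibble(genotype = genotypes[g], ramet = r, block = b)
    }
  }
  layout <- dplyr::bind_rows(rows)
  # randomise positions within each block
  layout <- layout |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(cell = sample(seq_len(block_capacity), dplyr::n())) |>
    dplyr::ungroup()
  layout$x <- purrr::map2_dbl(layout$block, layout$cell,
                              ~ cells[[.x]]$x[.y])
  layout$y <- purrr::map2_dbl(layout$block, layout$cell,
                              ~ cells[[.x]]$y[.y])
  layout$cell <- NULL
  layout$tree <- sprintf("T%04d", seq_len(nrow(layout)))
  layout$block <- sprintf("B%02d", layout$block)
  dplyr::select(layout, "tree", "genotype", "ramet", "block", "x", "y")
}

#' Define a genetic architecture for gene dropping
#'
#' @param n_loci Number of independent biallelic loci.
#' @param allele_freq Founder allele frequency (in (0,1)).
#' @param additive_sd,dominance_sd,epistatic_sd Standard deviations of the
#'   per-locus (per-pair for epistasis) effect sizes, in latent-abundance
#'   units; 0 switches the component off.
#' @param n_epistatic_pairs Number of random locus pairs with
#'   additive-by-additive interaction effects.
#' @return A `genetic_architecture` list.
#' @export
genetic_architecture <- function(n_loci = 100, allele_freq = 0.5,
                                 additive_sd = 1, dominance_sd = 0,
                                 epistatic_sd = 0, n_epistatic_pairs = 0) {
  stopifnot(n_loci >= 1, allele_freq > 0, allele_freq < 1,
            additive_sd >= 0, dominance_sd >= 0, epistatic_sd >= 0)
  structure(list(n_loci = n_loci, allele_freq = allele_freq,
                 additive_sd = additive_sd, dominance_sd = dominance_sd,
                 epistatic_sd = epistatic_sd,
                 n_epistatic_pairs = n_epistatic_pairs),
            class = "genetic_architecture")
}

#' Drop genes through a pedigree and score genetic values
#'
#' Founders receive Hardy-Weinberg genotypes at independent biallelic loci;
#' alleles are transmitted by Mendelian sampling. Per-locus contributions are
#' `a * (dose - 2p)` (additive), `d * (het - 2pq)` (dominance deviation), and
#' optional additive-by-additive terms `e * (dose_i - 2p)(dose_j - 2p)` on
#' random locus pairs. Effects are drawn `N(0, sd^2)` per locus.
#'
#' @param ped A sorted pedigree.
#' @param architecture A [genetic_architecture()].
#' @param seed Integer seed.
#' @return A tibble with one row per pedigree individual: `id`, `additive`,
#'   `dominance`, `epistatic`, `total` (latent units).
#' @export
gene_drop <- function(ped, architecture = genetic_architecture(), seed = 1) {
  if (!isTRUE(attr(ped, "sorted"))) ped <- ped_validate(ped)
  arch <- architecture
  set.seed(seed)
  n <- nrow(ped); L <- arch$n_loci; p <- arch$allele_freq
  idx <- setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  a_eff <- if (arch$additive_sd > 0) rnorm(L, 0, arch$additive_sd) else numeric(L)
  d_eff <- if (arch$dominance_sd > 0) rnorm(L, 0, arch$dominance_sd) else numeric(L)
  n_ep <- arch$n_epistatic_pairs
  if (n_ep > 0 && arch$epistatic_sd > 0) {
    ep_i <- sample.int(L, n_ep, replace = TRUE)
    ep_j <- sample.int(L, n_ep, replace = TRUE)
    e_eff <- rnorm(n_ep, 0, arch$epistatic_sd)
  } else {
    n_ep <- 0
  }
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    a1[i, ] <- if (is.na(si[i])) rbinom(L, 1, p) else
      ifelse(runif(L) < 0.5, a1[si[i], ], a2[si[i], ])
    a2[i, ] <- if (is.na(di[i])) rbinom(L, 1, p) else
      ifelse(runif(L) < 0.5, a1[di[i], ], a2[di[i], ])
  }
  dose <- a1 + a2
  dose_c <- dose - 2 * p
  het_c <- (dose == 1L) - 2 * p * (1 - p)
  add_val <- as.numeric(dose_c %*% a_eff)
  dom_val <- as.numeric(het_c %*% d_eff)
  epi_val <- numeric(n)
  if (n_ep > 0) {
    for (k in seq_len(n_ep)) {
      epi_val <- epi_val + e_eff[k] * dose_c[, ep_i[k]] * dose_c[, ep_j[k]]
    }
  }
  tibble::tibble(id = ped$id, additive = add_val, dominance = dom_val,
                 epistatic = epi_val, total = add_val + dom_val + epi_val)
}

#' Full-sib dominance-partition experiment
#'
#' Gene-drops pure-dominance loci through independent full-sib families
#' (unrelated, non-inbred parents) and partitions the genetic variance into
#' between-family and within-family (among-genotype) components by one-way
#' random-effects ANOVA. Classical theory gives Cov(full sibs) = VA/2 + VD/4;
#' with a = 0 and p = 0.5 the additive variance vanishes, so the
#' between-family share of the dominance variance is 25% and the within-family
#' share 75%.
#'
#' Component sums of squares are accumulated per locus and pooled (loci are
#' independent), which estimates the same partition as the variance of summed
#' genetic values but with far smaller Monte-Carlo error.
#'
#' @param n_loci Number of dominance loci (default 2000).
#' @param n_families Number of full-sib families (default 200).
#' @param progeny_per_family Progeny (genotypes) per family (default 50).
#' @param allele_freq Founder allele frequency (default 0.5).
#' @param seed Integer seed.
#' @return A list: `between_pct`, `within_pct` (percentages of total genetic
#'   variance), and the raw components.
#' @export
dominance_partition <- function(n_loci = 2000, n_families = 200,
                                progeny_per_family = 50, allele_freq = 0.5,
                                seed = 1) {
  set.seed(seed)
  Fm <- n_families; L <- n_loci; n <- progeny_per_family; p <- allele_freq
  d_eff <- rnorm(L)
  # parent alleles: F x L matrices per parental haplotype
  s1 <- matrix(rbinom(Fm * L, 1, p), Fm); s2 <- matrix(rbinom(Fm * L, 1, p), Fm)
  m1 <- matrix(rbinom(Fm * L, 1, p), Fm); m2 <- matrix(rbinom(Fm * L, 1, p), Fm)
  hsum <- matrix(0, Fm, L)     # per-family sums of het indicators
  # value per progeny/locus is d_l * (het - c); het is Bernoulli so sums of
  # het and het^2 coincide, and all SS reduce to hsum and totals
  for (k in seq_len(n)) {
    pa <- ifelse(matrix(runif(Fm * L), Fm) < 0.5, s1, s2)
    ma <- ifelse(matrix(runif(Fm * L), Fm) < 0.5, m1, m2)
    het <- (pa + ma) == 1L
    hsum <- hsum + het
  }
  tot <- colSums(hsum)                       # per-locus totals over all progeny
  N <- Fm * n
  # per-locus one-way ANOVA on het (0/1), scaled by d_l^2
  ss_b <- colSums(hsum^2) / n - tot^2 / N    # between-family SS (het scale)
  ss_w <- tot - colSums(hsum^2) / n          # within SS: sum het - sum nbar_f^2
  ms_b <- d_eff^2 * ss_b / (Fm - 1)
  ms_w <- d_eff^2 * ss_w / (N - Fm)
  sig_b <- sum((ms_b - ms_w) / n)            # pooled between-family component
  sig_w <- sum(ms_w)                         # pooled within-family component
  total <- sig_b + sig_w
  list(between_pct = 100 * sig_b / total,
       within_pct = 100 * sig_w / total,
       sigma_between = sig_b, sigma_within = sig_w)
}

#' Default soil covariate parameters
#'
#' Means and SDs: pH 4.63 (0.18), gravimetric moisture 43.9% (6.0), total C
#' 9.79% (2.46), total N 0.45% (0.10). Correlations: pH–C -0.78, pH–N -0.70,
#' C–N 0.89; the moisture correlations are not pinned down by the field data
#' summary and default to -0.3 (with pH) and +0.3 (with C and N), an arbitrary
#' but positive-definite completion.
#' @return A list with `means`, `sds`, `correlation`.
#' @export
soil_defaults <- function() {
  vars <- c("ph", "moisture", "total_c", "total_n")
  R <- matrix(c(1, -0.3, -0.78, -0.70,
                -0.3, 1, 0.3, 0.3,
                -0.78, 0.3, 1, 0.89,
                -0.70, 0.3, 0.89, 1), 4, 4, dimnames = list(vars, vars))
  list(means = c(ph = 4.63, moisture = 43.9, total_c = 9.79, total_n = 0.45),
       sds = c(ph = 0.18, moisture = 6.0, total_c = 2.46, total_n = 0.10),
       correlation = R)
}

#' Simulate soil covariates
#'
#' Multivariate-Gaussian soil physicochemical covariates (pH, gravimetric
#' moisture %, total carbon %, total nitrogen %) with configurable means, SDs
#' and correlation structure. A non-positive-definite correlation matrix is
#' repaired to the nearest PD matrix with a warning.
#'
#' @param n_samples Number of samples.
#' @param means,sds Named numeric vectors (defaults from [soil_defaults()]).
#' @param correlation Correlation matrix (defaults from [soil_defaults()]).
#' @param seed Integer seed.
#' @return A tibble of soil covariates, one row per sample.
#' @export
simulate_soil <- function(n_samples, means = soil_defaults()$means,
                          sds = soil_defaults()$sds,
                          correlation = soil_defaults()$correlation,
                          seed = 1) {
  stopifnot(length(means) == length(sds),
            nrow(correlation) == length(means))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    warn("correlation matrix not positive definite; repairing to nearest PD")
    correlation <- as.matrix(Matrix::nearPD(correlation, corr = TRUE)$mat)
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("correlation matrix not repairable to PD")
  }
  set.seed(seed)
  Sigma <- diag(sds) %*% correlation %*% diag(sds)
  x <- MASS::mvrnorm(n_samples, mu = means, Sigma = Sigma)
  colnames(x) <- names(means)
  tibble::as_tibble(x)
}

#' Default ASV-count simulation parameters
#'
#' @param n_asv Number of ASVs.
#' @param prop_core Fraction of ASVs simulated as core (high baseline).
#' @param core_baseline,noncore_baseline Mean log-abundance (relative to the
#'   library) for core / non-core ASVs.
#' @param genetic_sd SD of the per-ASV genetic slope on the standardised
#'   genotype genetic value (0 = no heritable signal).
#' @param spatial_sd SD of per-ASV spatial-trend amplitude.
#' @param batch_sd SD of per-ASV batch offsets (two batches).
#' @param soil_sd SD of per-ASV soil-covariate slopes (on soil PC1-like score).
#' @param resid_sd Residual latent (log-scale) noise SD.
#' @param dispersion Negative-binomial overdispersion (0 = Poisson).
#' @param depth Mean library size (reads).
#' @param libsize_cv Coefficient of variation of library size factors.
#' @return Parameter list for [simulate_asv_counts()].
#' @export
asv_sim_params <- function(n_asv = 200, prop_core = 0.15,
                           core_baseline = -4.5, noncore_baseline = -8,
                           genetic_sd = 0.5, spatial_sd = 0.5,
                           batch_sd = 0.3, soil_sd = 0.3,
                           resid_sd = 0.8, dispersion = 0.3,
                           depth = 8063, libsize_cv = 0.2) {
  as.list(environment())
}

# smooth low-frequency surface over the trial grid: 2-4 random sinusoids
random_spatial_surface <- function(x, y, n_waves = sample(2:4, 1)) {
  xs <- (x - mean(x)) / max(1, diff(range(x)))
  ys <- (y - mean(y)) / max(1, diff(range(y)))
  s <- numeric(length(x))
  for (k in seq_len(n_waves)) {
    fx <- runif(1, 0.5, 2); fy <- runif(1, 0.5, 2)
    ph <- runif(2, 0, 2 * pi)
    s <- s + sin(2 * pi * fx * xs + ph[1]) * cos(2 * pi * fy * ys + ph[2])
  }
  as.numeric(scale(s))
}

#' Simulate an ASV count matrix with known structure
#'
#' Latent per-sample log abundance for each ASV is baseline + genetic signal
#' (per-genotype latent value) + smooth spatial surface + batch offset + soil
#' effect + Gaussian noise; counts are negative-binomial (Poisson when
#' `dispersion = 0`) around `exp(latent) * library size`. The returned truth
#' object records the realised variance share of every component per ASV.
#'
#' @param layout Trial layout tibble from [generate_layout()], with an added
#'   `batch` column (see [simulate_study()]); one sample per tree.
#' @param genetic_values Tibble from [gene_drop()] (or any tibble with `id`
#'   and `total`), indexed by genotype id.
#' @param soil_score Numeric vector, one value per tree (e.g. a soil PC1-like
#'   score); standardised internally.
#' @param params Parameter list from [asv_sim_params()].
#' @param seed Integer seed.
#' @return A list: `counts` (samples x ASVs integer matrix, rownames = tree
#'   ids), `truth` (per-ASV tibble of realised variance shares and simulation
#'   parameters).
#' @export
simulate_asv_counts <- function(layout, genetic_values, soil_score,
                                params = asv_sim_params(), seed = 1) {
  stopifnot(nrow(layout) == length(soil_score))
  if (!"batch" %in% names(layout)) {
    layout$batch <- ifelse(layout$x <= median(layout$x), "batch1", "batch2")
  }
  set.seed(seed)
  n <- nrow(layout); J <- params$n_asv
  g <- genetic_values$total[match(layout$genotype, genetic_values$id)]
  if (anyNA(g)) abort("genotype in layout missing from genetic_values")
  g_std <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g * 0
  soil_std <- as.numeric(scale(soil_score))
  batch_ind <- as.integer(factor(layout$batch))

  is_core <- seq_len(J) <= round(params$prop_core * J)
  baseline <- ifelse(is_core, params$core_baseline, params$noncore_baseline) +
    rnorm(J, 0, 0.5)
  # normalise so expected relative abundances sum to ~1 and `depth` is the
  # expected library size
  baseline <- baseline - log(sum(exp(baseline)))
  slope_g <- rnorm(J, 0, params$genetic_sd)
  amp_s <- abs(rnorm(J, 0, params$spatial_sd))
  slope_soil <- rnorm(J, 0, params$soil_sd)
  libfac <- exp(rnorm(n, 0, params$libsize_cv))
  libfac <- libfac / mean(libfac)

  counts <- matrix(0L, n, J,
                   dimnames = list(layout$tree, sprintf("ASV%04d", seq_len(J))))
  shares <- matrix(0, J, 6,
                   dimnames = list(colnames(counts),
                                   c("genetic", "spatial", "batch", "soil",
                                     "residual", "total_var")))
  for (j in seq_len(J)) {
    surf <- random_spatial_surface(layout$x, layout$y)
    b_off <- rnorm(2, 0, params$batch_sd)
    comp <- cbind(genetic = slope_g[j] * g_std,
                  spatial = amp_s[j] * surf,
                  batch = b_off[batch_ind],
                  soil = slope_soil[j] * soil_std,
                  residual = rnorm(n, 0, params$resid_sd))
    eta <- baseline[j] + rowSums(comp)
    mu <- exp(eta) * params$depth * libfac
    counts[, j] <- if (params$dispersion > 0) {
      rnbinom(n, mu = mu, size = 1 / params$dispersion)
    } else {
      rpois(n, mu)
    }
    v <- apply(comp, 2, var)
    shares[j, ] <- c(v / sum(v), sum(v))
  }
  truth <- tibble::as_tibble(shares, rownames = "asv") |>
    dplyr::mutate(core = is_core, baseline = baseline,
                  genetic_slope = slope_g, spatial_amp = amp_s)
  list(counts = counts, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' One call produces everything downstream stages consume: pedigree, trial
#' layout (with two sequencing batches assigned by contiguous layout regions),
#' soil covariates, gene-dropped genetic values, and ASV counts with recorded
#' truth. The master seed spawns per-component child seeds so stages are
#' individually reproducible.
#'
#' @param n_families,family_size_range,n_genotypes,ramets_per_genotype Study
#'   design; defaults 28 families of 3–6 genotypes, 132 genotypes, 4 ramets
#'   (528 trees).
#' @param block_capacity Trees per block; shrunk automatically for small
#'   designs so the incomplete-block constraint stays feasible.
#' @param architecture A [genetic_architecture()].
#' @param params ASV simulation parameters from [asv_sim_params()].
#' @param seed Master integer seed.
#' @return A list: `ped`, `genotypes`, `metadata` (per-sample tibble joining
#'   layout, family, batch, ancestry label and soil covariates), `A`
#'   (additive relationship matrix over study genotypes), `genetic_values`,
#'   `soil`, `counts`, `truth`.
#' @export
simulate_study <- function(n_families = 28, family_size_range = 3:6,
                           n_genotypes = 132, ramets_per_genotype = 4,
                           architecture = genetic_architecture(
                             n_loci = 100, additive_sd = 0.1,
                             dominance_sd = 0.1),
                           params = asv_sim_params(), block_capacity = 36,
                           seed = 1) {
  seeds <- spawn_seeds(seed, 6)
  gp <- generate_pedigree(n_families = n_families,
                          family_size_range = family_size_range,
                          n_genotypes = n_genotypes, seed = seeds[1])
  n_trees <- n_genotypes * ramets_per_genotype
  block_capacity <- min(block_capacity,
                        floor(n_trees / ramets_per_genotype))
  layout <- generate_layout(gp$genotypes$genotype,
                            ramets_per_genotype = ramets_per_genotype,
                            block_capacity = block_capacity,
                            seed = seeds[2])
  layout$batch <- ifelse(layout$x <= median(layout$x), "batch1", "batch2")
  soil <- simulate_soil(nrow(layout), seed = seeds[3])
  gv <- gene_drop(gp$ped, architecture, seed = seeds[4])
  pc <- soil_pc1(soil)
  sim <- simulate_asv_counts(layout, gv, pc$scores, params, seed = seeds[5])
  set.seed(seeds[6])
  anc <- sample(c("mainland", "mixed", "island"), n_families, replace = TRUE,
                prob = c(0.65, 0.25, 0.10))
  fam_anc <- setNames(anc, sprintf("FAM%02d", seq_len(n_families)))
  metadata <- layout |>
    dplyr::left_join(gp$genotypes[, c("genotype", "family")], by = "genotype") |>
    dplyr::mutate(ancestry = fam_anc[.data$family], sample = .data$tree) |>
    dplyr::bind_cols(soil) |>
    dplyr::mutate(soil_pc1 = pc$scores)
  A <- additive_relationship(gp$ped, keep = gp$genotypes$genotype)
  list(ped = gp$ped, genotypes = gp$genotypes, metadata = metadata, A = A,
       genetic_values = gv, soil = soil, counts = sim$counts,
       truth = sim$truth)
}
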