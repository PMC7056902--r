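small_cfg <- function(n_f2 = 60, ...) {
  sim_config(n_f2 = n_f2, n_markers = 300, n_qtl = 8, n_chromosomes = 5, ...)
}

test_that("gene dropping yields valid Mendelian dosages and half-sib structure", {
  sim <- simulate_cross(small_cfg(seed = 7))
  dos <- sim$genotypes_complete$dosages
  expect_true(all(dos %in% 0:2))
  expect_equal(dim(dos), c(60, 300))
  ped <- sim$pedigree
  expect_equal(length(unique(ped$sire)), 8)
  # all members of a family share the sire; dams vary within family
  expect_true(all(tapply(ped$sire, ped$family, function(s) length(unique(s))) == 1))
})

test_that("meiosis returns a parental allele everywhere and respects linkage", {
  set.seed(17)
  m <- 50
  h1 <- rep(1L, m); h2 <- rep(0L, m)
  chrom <- rep(1:2, each = 25)
  # zero recombination: each chromosome inherited as a single block
  gam <- gpsel:::meiosis(h1, h2, chrom, rec = rep(0, m))
  for (c_ in 1:2) expect_equal(length(unique(gam[chrom == c_])), 1)
  # free recombination across all intervals still yields parental alleles
  gam2 <- gpsel:::meiosis(h1, h2, chrom, rec = rep(0.5, m))
  expect_true(all(gam2 %in% 0:1))
})

test_that("relatives within a half-sib family are more related in G", {
  set.seed(27)
  sims <- replicate(5, {
    sim <- simulate_cross(small_cfg(n_f2 = 80, seed = sample.int(1e6, 1)))
    G <- suppressWarnings(build_grm(sim$genotypes_complete))$values
    fam <- sim$pedigree$family
    same <- outer(fam, fam, "==") & upper.tri(G)
    diff <- !outer(fam, fam, "==") & upper.tri(G)
    mean(G[same]) - mean(G[diff])
  })
  expect_gt(mean(sims), 0)
  expect_gt(sum(sims > 0), 3)
})

test_that("heritability 1 makes the phenotype minus fixed effects the TBV", {
  cfg <- small_cfg(h2_target = 1, seed = 37)
  sim <- simulate_cross(cfg)
  ph <- sim$phenotypes
  fixed <- cfg$trait_mean +
    ifelse(ph$sex == "M", 0.5, -0.5) * cfg$sex_effect +
    cfg$batch_effects[as.integer(as.character(ph$batch))]
  expect_equal(ph$trait - fixed, unname(sim$tbv), tolerance = 1e-8)
  expect_equal(sim$realized_h2, 1)
})

test_that("heritability 0 leaves the phenotype uncorrelated with the TBV", {
  sim <- simulate_cross(sim_config(n_f2 = 400, n_markers = 400, n_qtl = 20,
                                   n_chromosomes = 10, h2_target = 0,
                                   seed = 47))
  ph <- sim$phenotypes
  cfg <- sim$config
  fixed <- cfg$trait_mean +
    ifelse(ph$sex == "M", 0.5, -0.5) * cfg$sex_effect +
    cfg$batch_effects[as.integer(as.character(ph$batch))]
  expect_lt(abs(cor(sim$tbv, ph$trait - fixed)), 0.15)
  expect_gt(sd(sim$tbv), 0)  # truth is still reported
})

test_that("realized heritability is consistent with the variance components", {
  sim <- simulate_cross(small_cfg(h2_target = 0.37, seed = 57))
  v_g <- var(sim$tbv)
  expect_equal(sim$realized_h2, v_g / (v_g + sim$sigma_e2), tolerance = 1e-10)
  expect_equal(sim$realized_h2, 0.37, tolerance = 1e-10)
})

test_that("trait scale and fixed-effect levels match the configuration", {
  sim <- simulate_cross(sim_config(n_f2 = 395, n_markers = 500, n_qtl = 30,
                                   n_chromosomes = 10, seed = 67))
  ph <- sim$phenotypes
  expect_equal(nrow(ph), 395)
  expect_setequal(unique(ph$sex), c("M", "F"))
  expect_equal(nlevels(ph$batch), 6)
  expect_equal(mean(ph$trait), 2034, tolerance = 0.05)   # relative tolerance
  expect_equal(sd(ph$trait), 360, tolerance = 0.15)
})

test_that("missingness mask is Bernoulli at the requested rate and seeded", {
  set.seed(77)
  g <- sim_hwe_genotypes(100, 200)
  expect_identical(apply_missingness(g, 0), g)
  g1 <- apply_missingness(g, 0.3, seed = 5)
  g2 <- apply_missingness(g, 0.3, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  n_na <- sum(is.na(g1$dosages))
  bounds <- qbinom(c(0.005, 0.995), 100 * 200, 0.3)
  expect_gte(n_na, bounds[1])
  expect_lte(n_na, bounds[2])
})

test_that("the same configuration reproduces the identical dataset", {
  cfg <- small_cfg(missing_rate = 0.05, seed = 87)
  s1 <- simulate_cross(cfg)
  s2 <- simulate_cross(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$tbv, s2$tbv)
})

test_that("QTLs can be excluded from the panel yet remain tagged by linked markers", {
  set.seed(97)
  hits <- replicate(5, {
    sim <- simulate_cross(sim_config(n_f2 = 150, n_markers = 600, n_qtl = 10,
                                     n_chromosomes = 6, h2_target = 0.6,
                                     qtl_in_panel = FALSE,
                                     seed = sample.int(1e6, 1)))
    expect_false(any(sim$qtl$marker_id %in% marker_ids(sim$genotypes)))
    yc <- correct_phenotypes(sim$phenotypes)
    sel <- select_pms(pms_scores(sim$genotypes, yc), 0.05)
    map <- sim$genotypes_complete$map
    qtl_pos <- map[map$marker_id %in% sim$qtl$marker_id, c("chrom", "pos")]
    dist_to_qtl <- function(mids) {
      mm <- map[map$marker_id %in% mids, ]
      mean(vapply(seq_len(nrow(mm)), function(i) {
        same <- qtl_pos$chrom == mm$chrom[i]
        if (!any(same)) return(1e8)
        min(abs(qtl_pos$pos[same] - mm$pos[i]))
      }, numeric(1)))
    }
    dist_to_qtl(sel) < dist_to_qtl(marker_ids(sim$genotypes))
  })
  expect_gte(sum(hits), 3)
})

test_that("crossing divergent lines shifts the F2 MAF spectrum inward", {
  set.seed(107)
  # strongly divergent founder lines: Beta precision 1 puts most line
  # frequencies near fixation, so line-level MAF is mostly small
  frac_f2 <- mean(replicate(4, {
    sim <- simulate_cross(small_cfg(n_f2 = 100, line_divergence = 1,
                                    seed = sample.int(1e6, 1)))
    mean(marker_maf(sim$genotypes_complete) > 0.2, na.rm = TRUE)
  }))
  # founder-line baseline by direct Monte Carlo of the same frequency model
  p0 <- runif(2e4, 0.05, 0.5)
  q <- rbeta(2e4, p0, 1 - p0)
  frac_founder <- mean(pmin(q, 1 - q) > 0.2)
  expect_gt(frac_f2, frac_founder)
})
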