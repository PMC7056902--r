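#' Configuration for the F2-cross simulator
#'
#' The defaults emulate a small broiler resource population: 395 F2 birds
#' in 8 paternal half-sib families descended from 20 founders (6 males of
#' one line, 14 females of another), 28 autosomes of 1 Morgan each, body
#' weight-like trait scale (mean 2034, SD 360), sex (2 levels) and batch
#' (6 levels) fixed effects, and heritability around 0.7. Founder lines
#' carry divergent allele frequencies drawn around a common base
#' frequency, mimicking a cross between a selected line and an indigenous
#' breed.
#'
#' @param n_f0_males,n_f0_females founder counts per line (defaults 6, 14).
#' @param n_families number of paternal half-sib F2 families (default 8).
#' @param dams_per_sire F1 dams mated to each F1 sire (default 4).
#' @param n_f2 total F2 individuals (default 395).
#' @param n_chromosomes autosome count (default 28).
#' @param chromosome_length genetic length per chromosome in Morgans
#'   (default 1).
#' @param n_markers panel size (default 5000).
#' @param n_qtl number of additive QTLs (default 50).
#' @param qtl_in_panel keep QTL markers in the genotype panel (default
#'   `TRUE`); if `FALSE` they are dropped after phenotypes are built.
#' @param h2_target narrow-sense heritability in \[0, 1\] (default 0.7).
#' @param trait_mean,trait_sd phenotype scale in trait units (defaults
#'   2034, 360).
#' @param sex_effect male-female difference in trait units; default
#'   `0.3 * trait_sd`, split symmetrically around the mean.
#' @param n_batches number of rearing batches (default 6).
#' @param batch_effects numeric vector of batch deviations (centered to
#'   sum to zero); default evenly spaced spanning `0.4 * trait_sd`.
#' @param maf_range range of the base allele frequency per marker
#'   (default c(0.05, 0.5)).
#' @param line_divergence Beta precision of founder-line frequencies
#'   around the base frequency; smaller means more divergent lines
#'   (default 5).
#' @param missing_rate per-genotype missing probability (default 0).
#' @param seed integer seed used by [simulate_cross()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_f0_males = 6, n_f0_females = 14, n_families = 8,
                       dams_per_sire = 4, n_f2 = 395, n_chromosomes = 28,
                       chromosome_length = 1.0, n_markers = 5000,
                       n_qtl = 50, qtl_in_panel = TRUE, h2_target = 0.7,
                       trait_mean = 2034, trait_sd = 360,
                       sex_effect = 0.3 * trait_sd, n_batches = 6,
                       batch_effects = NULL, maf_range = c(0.05, 0.5),
                       line_divergence = 5, missing_rate = 0, seed = 1) {
  if (is.null(batch_effects))
    batch_effects <- seq(-0.2, 0.2, length.out = n_batches) * trait_sd
  cfg <- list(n_f0_males = n_f0_males, n_f0_females = n_f0_females,
              n_families = n_families, dams_per_sire = dams_per_sire,
              n_f2 = n_f2, n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length, n_markers = n_markers,
              n_qtl = n_qtl, qtl_in_panel = qtl_in_panel,
              h2_target = h2_target, trait_mean = trait_mean,
              trait_sd = trait_sd, sex_effect = sex_effect,
              n_batches = n_batches,
              batch_effects = batch_effects - mean(batch_effects),
              maf_range = maf_range, line_divergence = line_divergence,
              missing_rate = missing_rate, seed = seed)
  stopifnot(cfg$n_f2 > 0, cfg$n_markers > 0, cfg$n_chromosomes > 0,
            cfg$h2_target >= 0, cfg$h2_target <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            length(cfg$batch_effects) == cfg$n_batches)
  if (cfg$n_markers < cfg$n_qtl) stop("n_markers must be >= n_qtl")
  class(cfg) <- "sim_config"
  cfg
}

# one gamete from a diploid parent: Haldane (no-interference) crossover
# process along each chromosome, random starting phase
meiosis <- function(h1, h2, chrom, rec) {
  switches <- stats::rbinom(length(rec), 1, rec)
  first <- !duplicated(chrom)
  switches[first] <- stats::rbinom(sum(first), 1, 0.5)
  phase <- cumsum(switches) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate F2 genotypes by gene dropping
#'
#' Founder haplotypes are drawn per marker from two divergent line
#' frequency profiles (males from line A, females from line B). F1
#' individuals are produced from random line-A x line-B matings; a set of
#' F1 sires, each mated to several F1 dams, then founds the paternal
#' half-sib F2 families. Gametes recombine under a Haldane map with
#' marker positions uniform on each chromosome.
#'
#' Uses the current RNG state; seed via [simulate_cross()] or `set.seed()`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a [geno_matrix()] of the F2, dosages of
#'   the line-B-tagged allele), `pedigree` (id, sire, dam, family), and
#'   `map_morgans` (per-marker genetic positions).
#' @export
simulate_genotypes <- function(cfg) {
  m <- cfg$n_markers
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- numeric(m)
  for (c_ in unique(chrom)) {
    i <- chrom == c_
    pos[i] <- sort(stats::runif(sum(i), 0, cfg$chromosome_length))
  }
  gap <- c(0, diff(pos))
  gap[!duplicated(chrom)] <- 0
  rec <- 0.5 * (1 - exp(-2 * gap))   # Haldane map function

  p0 <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  nu <- cfg$line_divergence
  pA <- stats::rbeta(m, p0 * nu, (1 - p0) * nu)
  pB <- stats::rbeta(m, p0 * nu, (1 - p0) * nu)

  draw_hap <- function(p) stats::rbinom(m, 1, p)
  f0_m <- lapply(seq_len(cfg$n_f0_males),
                 function(i) list(h1 = draw_hap(pA), h2 = draw_hap(pA)))
  f0_f <- lapply(seq_len(cfg$n_f0_females),
                 function(i) list(h1 = draw_hap(pB), h2 = draw_hap(pB)))

  make_child <- function(sire, dam) {
    list(h1 = meiosis(sire$h1, sire$h2, chrom, rec),
         h2 = meiosis(dam$h1, dam$h2, chrom, rec))
  }
  n_f1 <- cfg$n_families * (1 + cfg$dams_per_sire)
  f1 <- lapply(seq_len(n_f1), function(i)
    make_child(f0_m[[sample.int(length(f0_m), 1)]],
               f0_f[[sample.int(length(f0_f), 1)]]))
  sires <- f1[seq_len(cfg$n_families)]
  dams <- f1[-seq_len(cfg$n_families)]

  fam_of <- rep(seq_len(cfg$n_families), length.out = cfg$n_f2)
  dos <- matrix(0L, cfg$n_f2, m)
  ped <- data.frame(id = sprintf("F2_%03d", seq_len(cfg$n_f2)),
                    sire = sprintf("F1_S%d", fam_of),
                    dam = NA_character_, family = fam_of,
                    stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_f2)) {
    f <- fam_of[i]
    d_idx <- (f - 1) * cfg$dams_per_sire + sample.int(cfg$dams_per_sire, 1)
    ped$dam[i] <- sprintf("F1_D%d", d_idx)
    child <- make_child(sires[[f]], dams[[d_idx]])
    dos[i, ] <- child$h1 + child$h2
  }
  mids <- sprintf("snp_%05d", seq_len(m))
  dimnames(dos) <- list(ped$id, mids)
  map <- data.frame(marker_id = mids, chrom = as.character(chrom),
                    pos = as.integer(round(pos * 1e8)),  # 100 Mb per Morgan
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  list(genotypes = geno_matrix(dos, map), pedigree = ped,
       map_morgans = data.frame(marker_id = mids, chrom = chrom,
                                morgans = pos))
}

#' Simulate phenotypes with an additive QTL architecture
#'
#' A random subset of markers becomes QTLs with normal additive effects.
#' The true breeding value (TBV) is the centered sum of dosage x effect,
#' rescaled so its sample variance equals `h2_target * trait_sd^2`; the
#' residual variance is `(1 - h2_target) * trait_sd^2`, so the realized
#' variance ratio equals the target exactly. Sex is assigned at random
#' (male/female deviations of plus/minus half the `sex_effect`), batches
#' round-robin with the configured sum-to-zero deviations. With
#' `h2_target = 1` the phenotype minus fixed effects is the TBV exactly;
#' with `h2_target = 0` the (still reported) TBV contributes nothing to
#' the phenotype.
#'
#' Uses the current RNG state; seed via [simulate_cross()] or `set.seed()`.
#'
#' @param g a [geno_matrix()] of complete (pre-missingness) genotypes.
#' @param cfg a [sim_config()].
#' @return list with `phenotypes` (data.frame id, trait, sex, batch),
#'   `tbv` (named), `qtl` (marker_id, effect), `sigma_e2`, `realized_h2`.
#' @export
simulate_phenotypes <- function(g, cfg) {
  n <- n_individuals(g)
  ids <- individual_ids(g)
  qtl_ids <- sort(sample(marker_ids(g), cfg$n_qtl))
  eff <- stats::rnorm(cfg$n_qtl)
  tbv_raw <- drop(g$dosages[, qtl_ids, drop = FALSE] %*% eff)
  v_raw <- stats::var(tbv_raw)
  h2 <- cfg$h2_target
  if (v_raw == 0 && h2 > 0)
    stop("zero TBV variance with positive h2_target; QTLs are monomorphic")
  scale <- if (v_raw > 0) sqrt(max(h2, .Machine$double.eps) *
                               cfg$trait_sd^2 / v_raw) else 0
  if (h2 == 0) scale <- if (v_raw > 0) cfg$trait_sd / sqrt(v_raw) else 0
  tbv <- scale * (tbv_raw - mean(tbv_raw))
  eff_scaled <- eff * scale
  sigma_e2 <- (1 - h2) * cfg$trait_sd^2
  e <- stats::rnorm(n, 0, sqrt(sigma_e2))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex_dev <- ifelse(sex == "M", 0.5, -0.5) * cfg$sex_effect
  batch <- rep(seq_len(cfg$n_batches), length.out = n)
  genetic <- if (h2 > 0) tbv else 0
  y <- cfg$trait_mean + sex_dev + cfg$batch_effects[batch] + genetic + e
  v_g <- if (h2 > 0) stats::var(tbv) else 0
  realized_h2 <- if (v_g + sigma_e2 > 0) v_g / (v_g + sigma_e2) else 0
  list(phenotypes = data.frame(id = ids, trait = y, sex = sex,
                               batch = factor(batch),
                               stringsAsFactors = FALSE),
       tbv = stats::setNames(tbv, ids),
       qtl = data.frame(marker_id = qtl_ids, effect = eff_scaled,
                        stringsAsFactors = FALSE),
       sigma_e2 = sigma_e2, realized_h2 = realized_h2)
}

#' Random missingness mask
#'
#' Sets each genotype entry to missing independently with probability
#' `rate`. The same seed yields the identical mask.
#'
#' @param g a [geno_matrix()].
#' @param rate per-entry missing probability in \[0, 1).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a [geno_matrix()] with entries masked.
#' @export
apply_missingness <- function(g, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(g)
  dos <- g$dosages
  mask <- if (is.null(seed)) {
    stats::runif(length(dos)) < rate
  } else {
    withr_seed(seed, stats::runif(length(dos)) < rate)
  }
  dos[mask] <- NA_integer_
  geno_matrix(dos, g$map)
}

#' Simulate a complete study dataset
#'
#' End-to-end wrapper: genotypes by gene dropping, phenotypes on top,
#' then the missingness mask. Everything is driven by `cfg$seed`, so a
#' configuration fully determines the dataset.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_output`: `genotypes` (with missingness),
#'   `genotypes_complete`, `phenotypes`, `tbv`, `qtl`, `pedigree`,
#'   `sigma_e2`, `realized_h2`, `config`.
#' @examples
#' sim <- simulate_cross(sim_config(n_f2 = 40, n_markers = 200,
#'                                  n_qtl = 5, seed = 42))
#' sim$genotypes
#' @export
simulate_cross <- function(cfg = sim_config()) {
  out <- withr_seed(cfg$seed, {
    gd <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(gd$genotypes, cfg)
    g <- apply_missingness(gd$genotypes, cfg$missing_rate)
    if (!cfg$qtl_in_panel) {
      keep <- setdiff(marker_ids(g), ph$qtl$marker_id)
      g <- geno_matrix(g$dosages[, keep, drop = FALSE],
                       g$map[g$map$marker_id %in% keep, , drop = FALSE])
    }
    list(genotypes = g, genotypes_complete = gd$genotypes,
         phenotypes = ph$phenotypes, tbv = ph$tbv, qtl = ph$qtl,
         pedigree = gd$pedigree, sigma_e2 = ph$sigma_e2,
         realized_h2 = ph$realized_h2, config = cfg)
  })
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("simulated F2 cross: %d individuals, %d markers, %d QTLs, realized h2 = %.3f\n",
              n_individuals(x$genotypes), n_markers(x$genotypes),
              nrow(x$qtl), x$realized_h2))
  invisible(x)
}

#' Unlinked Hardy-Weinberg genotypes
#'
#' Independent binomial(2, p) dosages with per-marker frequencies uniform
#' on `freq_range` — the idealized panmictic panel used for numerical
#' checks of the relationship matrix and REML machinery (no family
#' structure, no linkage).
#'
#' @param n individuals; `m` markers.
#' @param m number of markers.
#' @param freq_range allele-frequency range (default c(0.05, 0.5)).
#' @return a [geno_matrix()].
#' @export
sim_hwe_genotypes <- function(n, m, freq_range = c(0.05, 0.5)) {
  p <- stats::runif(m, freq_range[1], freq_range[2])
  dos <- vapply(p, function(pp) stats::rbinom(n, 2, pp), integer(n))
  dimnames(dos) <- list(sprintf("id_%04d", seq_len(n)),
                        sprintf("m_%05d", seq_len(m)))
  geno_matrix(dos)
}
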