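#' Homozygote-contrast (PMS) marker scores
#'
#' For each marker, the pre-marker-selection statistic is the absolute
#' difference between the mean corrected phenotypes of the two homozygote
#' classes in the reference subset,
#' `d = |mean(yc | dosage 0) - mean(yc | dosage 2)|`. Heterozygotes and
#' missing genotypes contribute nothing. Markers with fewer than one
#' individual in either homozygote class are ineligible and can never be
#' selected. Scores are normalized by the maximum over eligible markers,
#' `d' = d / max(d)`, so `d'` lies in \[0, 1\] with at least one marker at 1.
#'
#' @param g a [geno_matrix()]
#' @param yc named numeric vector of corrected phenotypes
#'   (see [correct_phenotypes()]).
#' @param reference_ids ids forming the reference (training) subset;
#'   defaults to all phenotyped individuals present in `g`. In
#'   cross-validation the left-out individual must be excluded here, and
#'   `d'` is renormalized within every fold.
#' @return data.frame of class `pms_scores`: `marker_id`, `n_hom1`,
#'   `n_hom2`, `d`, `d_prime`, `eligible`.
#' @export
pms_scores <- function(g, yc, reference_ids = NULL) {
  ids <- intersect(individual_ids(g), names(yc))
  if (is.null(reference_ids)) reference_ids <- ids
  if (!all(reference_ids %in% ids))
    stop("reference_ids must have both genotypes and phenotypes")
  dos <- g$dosages[reference_ids, , drop = FALSE]
  y <- yc[reference_ids]
  hom1 <- !is.na(dos) & dos == 0L
  hom2 <- !is.na(dos) & dos == 2L
  n1 <- colSums(hom1)
  n2 <- colSums(hom2)
  s1 <- colSums(hom1 * y)
  s2 <- colSums(hom2 * y)
  eligible <- n1 >= 1L & n2 >= 1L
  d <- rep(NA_real_, ncol(dos))
  d[eligible] <- abs(s1[eligible] / n1[eligible] - s2[eligible] / n2[eligible])
  if (!any(eligible)) stop("no marker has both homozygote classes in the reference subset")
  dmax <- max(d[eligible])
  d_prime <- rep(NA_real_, length(d))
  if (dmax > 0) {
    d_prime[eligible] <- d[eligible] / dmax
  } else {
    warning("all homozygote contrasts are zero; d' set to 0")
    d_prime[eligible] <- 0
  }
  structure(data.frame(marker_id = marker_ids(g), n_hom1 = n1, n_hom2 = n2,
                       d = d, d_prime = d_prime, eligible = eligible,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("pms_scores", "data.frame"))
}

#' Select markers by PMS score
#'
#' Retains eligible markers with `d'` strictly greater than the cutoff,
#' in input order.
#'
#' @param scores a [pms_scores()] table.
#' @param cutoff `d'` threshold in (0, 1\]; default 0.05.
#' @return character vector of selected marker ids.
#' @export
select_pms <- function(scores, cutoff = 0.05) {
  sel <- scores$eligible & !is.na(scores$d_prime) & scores$d_prime > cutoff
  out <- scores$marker_id[sel]
  if (!length(out)) warning("no markers selected at d' > ", cutoff)
  out
}

#' Single-marker GWAS scan
#'
#' Ordinary least squares of the corrected phenotype on the allele dosage,
#' `yc = mu + x q + e`, fitted marker by marker on the reference subset
#' (individuals with a missing genotype at a marker are dropped for that
#' marker only). The two-sided p-value uses a t reference with
#' `n_used - 2` degrees of freedom. Markers with no genotype variance or
#' fewer than 3 usable individuals are flagged untestable.
#'
#' @inheritParams pms_scores
#' @return data.frame of class `gwas_result`: `marker_id`, `n_used`,
#'   `slope`, `slope_se`, `t_stat`, `p_value`, `residual_variance`,
#'   `testable`.
#' @export
gwas_scan <- function(g, yc, reference_ids = NULL) {
  ids <- intersect(individual_ids(g), names(yc))
  if (is.null(reference_ids)) reference_ids <- ids
  if (!all(reference_ids %in% ids))
    stop("reference_ids must have both genotypes and phenotypes")
  dos <- g$dosages[reference_ids, , drop = FALSE]
  y <- yc[reference_ids]
  ok <- !is.na(dos)
  x0 <- dos; x0[!ok] <- 0L
  n <- colSums(ok)
  sx <- colSums(x0)
  sxx <- colSums(x0 * x0)
  sy <- colSums(ok * y)
  syy <- colSums(ok * y * y)
  sxy <- colSums(x0 * y)
  # centered sums of squares/products on the per-marker complete cases
  cxx <- sxx - sx^2 / n
  cxy <- sxy - sx * sy / n
  cyy <- syy - sy^2 / n
  testable <- n >= 3L & cxx > .Machine$double.eps * pmax(1, sxx)
  slope <- se <- tval <- p <- rv <- rep(NA_real_, ncol(dos))
  i <- which(testable)
  slope[i] <- cxy[i] / cxx[i]
  rss <- pmax(cyy[i] - slope[i] * cxy[i], 0)
  rv[i] <- rss / (n[i] - 2)
  se[i] <- sqrt(rv[i] / cxx[i])
  tval[i] <- ifelse(se[i] > 0, slope[i] / se[i],
                    sign(slope[i]) * Inf)
  p[i] <- 2 * stats::pt(abs(tval[i]), df = n[i] - 2, lower.tail = FALSE)
  structure(data.frame(marker_id = marker_ids(g), n_used = n, slope = slope,
                       slope_se = se, t_stat = tval, p_value = p,
                       residual_variance = rv, testable = testable,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("gwas_result", "data.frame"))
}

#' Select markers by GWAS p-value
#'
#' Retains testable markers with `p` strictly less than `alpha`.
#'
#' @param result a [gwas_scan()] table.
#' @param alpha raw p-value threshold in (0, 1\]; default 0.01. No
#'   multiple-testing correction is applied: the threshold acts as a
#'   screening knob, not an inference claim.
#' @return character vector of selected marker ids.
#' @export
select_gwas <- function(result, alpha = 0.01) {
  sel <- result$testable & !is.na(result$p_value) & result$p_value < alpha
  out <- result$marker_id[sel]
  if (!length(out)) warning("no markers selected at p < ", alpha)
  out
}

#' Preselect markers by a named method
#'
#' Dispatcher used by the cross-validation driver and the command line:
#' `"pms"` and `"gwas"` run the corresponding screen on the reference
#' subset; `"all"` returns every marker and ignores the cutoff.
#'
#' @inheritParams pms_scores
#' @param method one of `"all"`, `"pms"`, `"gwas"`.
#' @param cutoff selection threshold: `d'` cutoff for PMS (default 0.05),
#'   p-value cutoff for GWAS (default 0.01).
#' @return character vector of selected marker ids.
#' @export
preselect_markers <- function(g, yc, method = c("all", "pms", "gwas"),
                              cutoff = NULL, reference_ids = NULL) {
  method <- match.arg(method)
  switch(method,
    all = marker_ids(g),
    pms = select_pms(pms_scores(g, yc, reference_ids),
                     cutoff = if (is.null(cutoff)) 0.05 else cutoff),
    gwas = select_gwas(gwas_scan(g, yc, reference_ids),
                       alpha = if (is.null(cutoff)) 0.01 else cutoff))
}
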