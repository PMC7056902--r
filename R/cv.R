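#' Prediction accuracy
#'
#' Pearson correlation between out-of-fold GEBV and corrected phenotypes,
#' pooled over all individuals. With leave-one-out validation each fold
#' yields a single prediction, so accuracy is necessarily one pooled
#' correlation rather than a mean of per-fold correlations.
#'
#' @param gebv named numeric vector of (out-of-fold) breeding values.
#' @param yc named numeric vector of corrected phenotypes; matched by name
#'   when both are named.
#' @return scalar correlation, or `NA` with a warning if either input is
#'   constant.
#' @export
accuracy <- function(gebv, yc) {
  m <- match_pairs(gebv, yc)
  if (length(m$a) < 3) stop("need at least 3 prediction/phenotype pairs")
  if (stats::sd(m$a) == 0 || stats::sd(m$b) == 0) {
    warning("constant input; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(m$a, m$b)
}

#' Unbiasedness of genomic predictions
#'
#' Ordinary least-squares regression of the corrected phenotype on the
#' GEBV (with intercept). A slope of 1 indicates an unbiased prediction;
#' slopes below 1 indicate over-dispersed (inflated) GEBV.
#'
#' @inheritParams accuracy
#' @return list with `slope` and `se`.
#' @export
unbiasedness <- function(gebv, yc) {
  m <- match_pairs(gebv, yc)
  x <- m$a; y <- m$b
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  vx <- stats::var(x)
  if (vx == 0) {
    warning("zero-variance GEBV; slope undefined")
    return(list(slope = NA_real_, se = NA_real_))
  }
  slope <- stats::cov(x, y) / vx
  res <- (y - mean(y)) - slope * (x - mean(x))
  se <- sqrt(sum(res^2) / (n - 2) / ((n - 1) * vx))
  list(slope = slope, se = se)
}

match_pairs <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    ids <- intersect(names(a), names(b))
    if (!length(ids)) stop("no shared ids between inputs")
    list(a = unname(a[ids]), b = unname(b[ids]), ids = ids)
  } else {
    if (length(a) != length(b)) stop("unnamed inputs must have equal length")
    list(a = unname(a), b = unname(b), ids = names(a))
  }
}

#' Leave-one-out cross-validation of genomic prediction
#'
#' For each phenotyped individual k: (1) markers are preselected on the
#' remaining n - 1 individuals only (the left-out bird never influences the
#' screen); (2) the relationship matrix is rebuilt on the selected markers
#' over all individuals (allele frequencies stay fixed at their full-data
#' values); (3) variance components are re-estimated by REML on the n - 1
#' training phenotypes (unless `refit_per_fold = FALSE`); (4) individual
#' k's GEBV is predicted with its phenotype withheld. Accuracy and the
#' unbiasedness slope are computed once over the n pooled out-of-fold
#' predictions, with bootstrap standard errors over individuals.
#'
#' @param g a [geno_matrix()] (post-QC).
#' @param yc named numeric vector of corrected phenotypes.
#' @param method marker preselection method: `"all"`, `"pms"`, `"gwas"`.
#' @param cutoff preselection threshold (see [preselect_markers()]).
#' @param refit_per_fold re-estimate variance components inside every fold
#'   (default `TRUE`); `FALSE` reuses the full-data REML fit, trading a
#'   little orthodoxy for speed.
#' @param n_boot bootstrap resamples for the accuracy/slope standard
#'   errors (default 1000).
#' @param seed integer master seed recorded in the result; drives the
#'   bootstrap resampling.
#' @param on_empty what to do when a fold selects no marker: `"error"`
#'   (default) or `"skip"` the fold.
#' @return object of class `loo_cv`: list with `gebv_oof`, `accuracy`,
#'   `accuracy_se`, `bias_slope`, `bias_slope_se`, `per_fold_markers`,
#'   `skipped`, `method`, `cutoff`, `seed`, `vc_full`.
#' @export
loo_cv <- function(g, yc, method = c("all", "pms", "gwas"), cutoff = NULL,
                   refit_per_fold = TRUE, n_boot = 1000, seed = 1,
                   on_empty = c("error", "skip")) {
  method <- match.arg(method)
  on_empty <- match.arg(on_empty)
  ids <- intersect(individual_ids(g), names(yc))
  n <- length(ids)
  if (n < 10) stop("need at least 10 phenotyped, genotyped individuals")
  cm <- center_markers(g)
  G_all <- build_grm(cm)
  vc_full <- reml_fit(G_all, yc, ids = ids)
  gebv_oof <- stats::setNames(rep(NA_real_, n), ids)
  n_sel <- stats::setNames(rep(NA_integer_, n), ids)
  skipped <- character(0)
  for (k in seq_len(n)) {
    ref <- ids[-k]
    sel <- suppressWarnings(preselect_markers(g, yc, method, cutoff,
                                              reference_ids = ref))
    n_sel[k] <- length(sel)
    if (!length(sel)) {
      if (on_empty == "error")
        stop("fold for individual '", ids[k], "' selected no markers")
      skipped <- c(skipped, ids[k])
      next
    }
    Gk <- if (method == "all") G_all else build_grm(cm, markers = sel)
    vck <- if (refit_per_fold) reml_fit(Gk, yc, ids = ref) else vc_full
    fit <- gblup(yc, Gk, train_ids = ref, vc = vck)
    gebv_oof[k] <- fit$gebv[ids[k]]
  }
  used <- !is.na(gebv_oof)
  acc <- accuracy(gebv_oof[used], yc[ids][used])
  bias <- unbiasedness(gebv_oof[used], yc[ids][used])
  bse <- bootstrap_se(gebv_oof[used], yc[ids][used], n_boot, seed)
  structure(list(gebv_oof = gebv_oof, accuracy = acc,
                 accuracy_se = bse$accuracy_se, bias_slope = bias$slope,
                 bias_slope_se = bias$se, per_fold_markers = n_sel,
                 skipped = skipped, method = method, cutoff = cutoff,
                 n_boot = n_boot, seed = seed, vc_full = vc_full),
            class = "loo_cv")
}

# bootstrap over individuals: SE of the pooled accuracy
bootstrap_se <- function(gebv, yc, n_boot, seed) {
  n <- length(gebv)
  accs <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(gebv[i], yc[i]))
    }, numeric(1))
  })
  list(accuracy_se = stats::sd(accs, na.rm = TRUE))
}

# evaluate 'expr' under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.loo_cv <- function(x, ...) {
  cat(sprintf("leave-one-out CV (%s%s): n = %d\n", x$method,
              if (!is.null(x$cutoff)) paste0(", cutoff ", x$cutoff) else "",
              length(x$gebv_oof)))
  cat(sprintf("  accuracy   = %.3f +/- %.3f (bootstrap SE, %d resamples)\n",
              x$accuracy, x$accuracy_se, x$n_boot))
  cat(sprintf("  bias slope = %.3f +/- %.3f\n", x$bias_slope, x$bias_slope_se))
  cat(sprintf("  markers per fold: median %d [%d, %d]\n",
              as.integer(stats::median(x$per_fold_markers)),
              min(x$per_fold_markers), max(x$per_fold_markers)))
  if (length(x$skipped)) cat("  skipped folds:", length(x$skipped), "\n")
  invisible(x)
}

#' Bootstrapped paired comparison of two prediction scenarios
#'
#' Resamples individuals with replacement `n_boot` times; in each
#' resample both scenario accuracies (correlations with `yc`) are
#' recomputed, and a paired t-test over the resampled accuracy pairs
#' tests whether the scenarios differ. Both scenarios see identical
#' resamples, so the comparison is paired at the individual level.
#'
#' @param gebv_a,gebv_b named out-of-fold GEBV vectors from two scenarios,
#'   aligned to the same individuals.
#' @param yc named corrected phenotypes.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed; identical seeds give bit-identical results.
#' @return object of class `scenario_comparison`: `accuracy_a`,
#'   `accuracy_b`, `accuracy_se_a`, `accuracy_se_b`, `t_stat`, `p_value`,
#'   `n_boot`, `seed`.
#' @export
compare_scenarios <- function(gebv_a, gebv_b, yc, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  ma <- match_pairs(gebv_a, yc)
  mb <- match_pairs(gebv_b, yc)
  if (!is.null(ma$ids) && !is.null(mb$ids)) {
    ids <- intersect(ma$ids, mb$ids)
    a <- gebv_a[ids]; b <- gebv_b[ids]; y <- yc[ids]
  } else {
    if (length(ma$a) != length(mb$a)) stop("scenarios must align")
    a <- ma$a; b <- mb$a; y <- ma$b
  }
  n <- length(y)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      i <- sample.int(n, n, replace = TRUE)
      c(suppressWarnings(stats::cor(a[i], y[i])),
        suppressWarnings(stats::cor(b[i], y[i])))
    }, numeric(2))
  })
  diffs <- boot[1, ] - boot[2, ]
  ok <- is.finite(diffs)
  if (all(abs(diffs[ok]) < .Machine$double.eps * 4) || !any(ok)) {
    t_stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(diffs[ok])
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(accuracy_a = suppressWarnings(stats::cor(a, y)),
                 accuracy_b = suppressWarnings(stats::cor(b, y)),
                 accuracy_se_a = stats::sd(boot[1, ], na.rm = TRUE),
                 accuracy_se_b = stats::sd(boot[2, ], na.rm = TRUE),
                 t_stat = t_stat, p_value = p, n_boot = n_boot, seed = seed),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("bootstrapped paired comparison of prediction scenarios\n")
  cat(sprintf("  accuracy A = %.3f +/- %.3f, accuracy B = %.3f +/- %.3f\n",
              x$accuracy_a, x$accuracy_se_a, x$accuracy_b, x$accuracy_se_b))
  cat(sprintf("  paired t = %.3f, p = %.4g (%d resamples, seed %d)\n",
              x$t_stat, x$p_value, x$n_boot, x$seed))
  invisible(x)
}
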