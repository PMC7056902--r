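#' Center a genotype matrix for the VanRaden relationship matrix
#'
#' Column i of the centered matrix M takes values `0 - 2 p_i`, `1 - 2 p_i`
#' and `2 - 2 p_i` for the three genotypes, where `p_i` is the observed
#' second-allele frequency at marker i over all genotyped individuals.
#' Missing genotypes become 0 after centering (the expected score).
#' Monomorphic markers are dropped with a warning since they contribute
#' nothing to the denominator `sum(2 p_i (1 - p_i))`.
#'
#' Frequencies are computed once from every individual in `g` and are not
#' meant to be recomputed per cross-validation fold; fold-specific
#' relationship matrices are obtained by subsetting markers in
#' [build_grm()].
#'
#' @param g a [geno_matrix()]
#' @param markers optional character vector of marker ids to keep.
#' @return object of class `centered_markers`: list with `M` (n x m real
#'   matrix), `freqs`, `denominator`, `ids`, `marker_ids`.
#' @export
center_markers <- function(g, markers = NULL) {
  if (!is.null(markers)) {
    miss <- setdiff(markers, marker_ids(g))
    if (length(miss)) stop("unknown marker id(s): ",
                           paste(utils::head(miss, 3), collapse = ", "))
    dos <- g$dosages[, markers, drop = FALSE]
  } else {
    dos <- g$dosages
  }
  n_ok <- colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / (2 * n_ok)
  p[n_ok == 0] <- NA_real_
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; cannot center")
  if (!all(poly))
    warning(sum(!poly), " monomorphic marker(s) dropped before centering")
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(dos, 2, 2 * p)
  M[is.na(M)] <- 0
  structure(list(M = M, freqs = p, denominator = sum(2 * p * (1 - p)),
                 ids = rownames(dos), marker_ids = colnames(dos)),
            class = "centered_markers")
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / sum(2 p_i (1 - p_i))` over the markers used. Under
#' Hardy-Weinberg proportions the diagonal of G averages about 1, so G
#' plays the role of the pedigree relationship matrix with marker-realized
#' rather than expected relationships.
#'
#' @param x a [geno_matrix()] or [center_markers()] result.
#' @param markers optional marker-id subset (e.g. a preselected set); the
#'   denominator is recomputed over the subset.
#' @param jitter non-negative value added to the diagonal, default 0.
#'   [gblup()] retries its solve with a small jitter automatically if G
#'   makes the phenotypic covariance singular.
#' @return object of class `grm`: list with `values` (n x n symmetric),
#'   `ids`, `marker_ids`, `denominator`, `jitter`.
#' @examples
#' d <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "m1"))
#' build_grm(geno_matrix(d))$values   # [[2, -2], [-2, 2]]
#' @export
build_grm <- function(x, markers = NULL, jitter = 0) {
  stopifnot(jitter >= 0)
  if (inherits(x, "geno_matrix")) x <- center_markers(x, markers)
  else if (!inherits(x, "centered_markers")) stop("unsupported input")
  else if (!is.null(markers)) {
    keep <- x$marker_ids %in% markers
    if (!any(keep)) stop("no polymorphic markers in the requested subset")
    x <- list(M = x$M[, keep, drop = FALSE], freqs = x$freqs[keep],
              denominator = sum(2 * x$freqs[keep] * (1 - x$freqs[keep])),
              ids = x$ids, marker_ids = x$marker_ids[keep])
  }
  if (x$denominator <= 0) stop("zero scaling denominator")
  G <- tcrossprod(x$M) / x$denominator
  if (jitter > 0) diag(G) <- diag(G) + jitter
  dimnames(G) <- list(x$ids, x$ids)
  structure(list(values = G, ids = x$ids, marker_ids = x$marker_ids,
                 denominator = x$denominator, jitter = jitter),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("genomic relationship matrix: %d individuals, %d markers, mean diag %.3f\n",
              length(x$ids), length(x$marker_ids), mean(diag(x$values))))
  invisible(x)
}

grm_values <- function(G) {
  if (inherits(G, "grm")) G$values else as.matrix(G)
}

#' Export / import a relationship matrix as TSV
#'
#' Plain symmetric matrix with ids as header and first column, for
#' interchange with external mixed-model software.
#'
#' @param G a `grm` or plain symmetric matrix with dimnames.
#' @param path output (input) file path.
#' @export
write_grm <- function(G, path) {
  V <- grm_values(G)
  tab <- data.frame(id = rownames(V), V, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(tab[, -1, drop = FALSE])
  rownames(V) <- as.character(tab[[1]])
  structure(list(values = V, ids = rownames(V), marker_ids = NULL,
                 denominator = NA_real_, jitter = 0), class = "grm")
}

# Restricted log-likelihood of y = 1*mu + g + e profiled over h2, in the
# eigenbasis of G: Var(y) = sigma_p^2 * W with W = h2*D + (1-h2)*I diagonal.
reml_profile <- function(h2, d, ytil, xtil) {
  n <- length(ytil)
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  xwx <- sum(xtil^2 / w)
  beta <- sum(xtil * ytil / w) / xwx
  r <- ytil - xtil * beta
  rss <- sum(r^2 / w)
  s2 <- rss / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi * s2) + sum(log(w)) + log(xwx) + (n - 1))
}

#' REML variance components for a single genomic random effect
#'
#' Fits `y = 1 mu + g + e` with `g ~ N(0, G sigma_g^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. The model is
#' rotated into the eigenbasis of (the phenotyped submatrix of) G, where
#' the covariance is diagonal for any heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`; the restricted likelihood
#' profiled over the total variance is then maximized over `h2` on
#' `[1e-6, 1 - 1e-6]` with Brent's method. This is exact (no EM/AI
#' iteration) and fast enough to refit hundreds of times in leave-one-out
#' cross-validation.
#'
#' The standard error of `h2` comes from the curvature (numerical second
#' derivative) of the profiled restricted log-likelihood at the optimum.
#' Estimates within 1e-6 of the `h2` box are flagged as boundary solutions.
#'
#' @param G a `grm` or symmetric matrix with ids as dimnames.
#' @param yc named numeric vector of corrected phenotypes.
#' @param ids individuals to use; default: all phenotyped ids present in G.
#' @param tol convergence tolerance on h2 for [stats::optimize()].
#' @return object of class `reml_fit`: list with `sigma_g2`, `sigma_e2`,
#'   `h2`, `se_h2`, `loglik`, `boundary`, `n`.
#' @export
reml_fit <- function(G, yc, ids = NULL, tol = 1e-8) {
  V <- grm_values(G)
  if (is.null(ids)) ids <- intersect(rownames(V), names(yc))
  if (length(ids) < 3) stop("need at least 3 phenotyped individuals")
  y <- yc[ids]
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  eg <- eigen(V[ids, ids], symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ytil <- drop(crossprod(eg$vectors, y))
  xtil <- drop(crossprod(eg$vectors, rep(1, length(y))))
  lo <- 1e-6; hi <- 1 - 1e-6
  opt <- stats::optimize(reml_profile, c(lo, hi), d = d, ytil = ytil,
                         xtil = xtil, maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  # optimize() never lands exactly on the box ends; probe them too
  ll_ends <- c(reml_profile(lo, d, ytil, xtil),
               reml_profile(hi, d, ytil, xtil))
  if (max(ll_ends) > opt$objective) {
    h2 <- c(lo, hi)[which.max(ll_ends)]
    opt$objective <- max(ll_ends)
  }
  n <- length(y)
  w <- h2 * d + (1 - h2)
  beta <- sum(xtil * ytil / w) / sum(xtil^2 / w)
  s2 <- sum((ytil - xtil * beta)^2 / w) / (n - 1)
  sigma_g2 <- h2 * s2
  sigma_e2 <- (1 - h2) * s2
  boundary <- h2 <= lo + 1e-6 || h2 >= hi - 1e-6
  step <- min(1e-4, (h2 - lo) / 2, (hi - h2) / 2)
  se_h2 <- NA_real_
  if (step > 0) {
    hess <- (reml_profile(h2 + step, d, ytil, xtil) - 2 * opt$objective +
             reml_profile(h2 - step, d, ytil, xtil)) / step^2
    if (is.finite(hess) && hess < 0) se_h2 <- sqrt(-1 / hess)
  }
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
                 se_h2 = se_h2, loglik = opt$objective,
                 boundary = boundary, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML (n = %d): sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              x$n, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f (SE %.4f)%s, restricted logLik = %.3f\n",
              x$h2, x$se_h2, if (x$boundary) " [boundary]" else "",
              x$loglik))
  invisible(x)
}

#' Heritability from variance components
#'
#' @param vc a [reml_fit()] object or list with `sigma_g2`, `sigma_e2`.
#' @return `sigma_g2 / (sigma_g2 + sigma_e2)`.
#' @export
heritability <- function(vc) {
  if (vc$sigma_g2 < 0 || vc$sigma_e2 < 0) stop("negative variance component")
  tot <- vc$sigma_g2 + vc$sigma_e2
  if (tot == 0) stop("both variance components are zero")
  vc$sigma_g2 / tot
}

#' Genomic BLUP of breeding values
#'
#' Fits the GBLUP model `y = 1 mu + Z g + e`, `g ~ N(0, G sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)`, estimating the variance components by REML on
#' the training individuals (unless `vc` is supplied) and predicting
#' genomic breeding values (GEBV) for every individual in G — including
#' those without phenotypes — via
#' `ghat = sigma_g^2 G[., t] V^-1 (y_t - 1 mu)` with
#' `V = G_tt sigma_g^2 + I sigma_e^2` and the generalized-least-squares
#' intercept `mu`.
#'
#' @param yc named numeric vector of corrected phenotypes.
#' @param G a `grm` from [build_grm()] (or symmetric matrix with ids).
#' @param train_ids individuals whose phenotypes enter the fit; defaults
#'   to all phenotyped individuals in G. Everyone else is predicted
#'   without contributing a phenotype.
#' @param vc optional fixed variance components (a [reml_fit()] or list
#'   with `sigma_g2`, `sigma_e2`); skips REML when given.
#' @return object of class `gblup`: list with `mu`, `gebv` (named, all
#'   individuals of G), `vc`, `train_ids`, `jitter_used`, `call`.
#' @seealso [reml_fit()], [build_grm()], [loo_cv()]
#' @examples
#' set.seed(1)
#' d <- matrix(sample(0:2, 200, TRUE), 20, 10,
#'             dimnames = list(paste0("id", 1:20), paste0("m", 1:10)))
#' g <- geno_matrix(d)
#' y <- stats::rnorm(20); names(y) <- rownames(d)
#' fit <- gblup(y, build_grm(g))
#' coef(fit)[1:3]
#' @export
gblup <- function(yc, G, train_ids = NULL, vc = NULL) {
  V <- grm_values(G)
  all_ids <- rownames(V)
  if (is.null(train_ids)) train_ids <- intersect(all_ids, names(yc))
  if (!all(train_ids %in% all_ids)) stop("train_ids missing from G")
  if (!all(train_ids %in% names(yc))) stop("train_ids must have phenotypes")
  if (is.null(vc)) vc <- reml_fit(G, yc, ids = train_ids)
  y <- yc[train_ids]
  nt <- length(y)
  Vt <- vc$sigma_g2 * V[train_ids, train_ids] + diag(vc$sigma_e2, nt)
  jitter_used <- 0
  ch <- tryCatch(chol(Vt), error = function(e) NULL)
  if (is.null(ch)) {
    jitter_used <- 1e-6 * mean(diag(Vt))
    message("phenotypic covariance singular; retrying with diagonal jitter ",
            format(jitter_used))
    ch <- chol(Vt + diag(jitter_used, nt))
  }
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, nt)))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  alpha <- backsolve(ch, forwardsolve(t(ch), y - mu))
  gebv <- drop(vc$sigma_g2 * V[, train_ids, drop = FALSE] %*% alpha)
  names(gebv) <- all_ids
  structure(list(mu = mu, gebv = gebv, vc = vc, train_ids = train_ids,
                 jitter_used = jitter_used, call = match.call()),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit\n")
  cat(sprintf("  training individuals: %d; predicted: %d\n",
              length(x$train_ids), length(x$gebv)))
  cat(sprintf("  mu = %.4g; h2 = %.4f (sigma_g2 %.4g, sigma_e2 %.4g)\n",
              x$mu, heritability(x$vc), x$vc$sigma_g2, x$vc$sigma_e2))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  g <- object$gebv
  out <- list(n_train = length(object$train_ids), n_pred = length(g),
              mu = object$mu, vc = object$vc,
              h2 = heritability(object$vc),
              gebv_range = range(g), gebv_sd = stats::sd(g))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("GBLUP model summary\n")
  cat(sprintf("  n(train) = %d, n(predicted) = %d\n", x$n_train, x$n_pred))
  cat(sprintf("  intercept mu = %.4g\n", x$mu))
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.4f (SE %.4f)\n",
              x$vc$sigma_g2, x$vc$sigma_e2, x$h2, x$vc$se_h2))
  cat(sprintf("  GEBV: sd %.4g, range [%.4g, %.4g]\n",
              x$gebv_sd, x$gebv_range[1], x$gebv_range[2]))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$gebv

#' @export
fitted.gblup <- function(object, ...) {
  object$mu + object$gebv[object$train_ids]
}

#' @export
residuals.gblup <- function(object, yc = NULL, ...) {
  if (is.null(yc)) stop("supply the phenotype vector 'yc' used in the fit")
  yc[object$train_ids] - fitted(object)
}

#' Predict method for GBLUP fits
#'
#' @param object a [gblup()] fit.
#' @param ids individuals to predict (default: everyone in G).
#' @param type `"gebv"` for breeding values, `"response"` for `mu + gebv`.
#' @param ... unused.
#' @export
predict.gblup <- function(object, ids = NULL, type = c("gebv", "response"), ...) {
  type <- match.arg(type)
  g <- object$gebv
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(g))
    if (length(miss)) stop("no prediction for id(s): ",
                           paste(utils::head(miss, 3), collapse = ", "))
    g <- g[ids]
  }
  if (type == "response") g <- g + object$mu
  g
}
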