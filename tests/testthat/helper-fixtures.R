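# shared fixture builders; everything is generated in code

# genotype matrix from a plain integer matrix, ids auto-named
gm <- function(dos, ids = NULL, mids = NULL) {
  dos <- as.matrix(dos)
  storage.mode(dos) <- "integer"
  rownames(dos) <- ids %||% paste0("ind", seq_len(nrow(dos)))
  colnames(dos) <- mids %||% paste0("m", seq_len(ncol(dos)))
  geno_matrix(dos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random HWE panel (polymorphic markers only) plus a phenotype with a
# genomic signal
rand_dataset <- function(n, m, h2 = 0.5, n_qtl = 10) {
  g <- sim_hwe_genotypes(n, m)
  poly <- marker_maf(g) > 0
  g <- geno_matrix(g$dosages[, poly, drop = FALSE],
                   g$map[poly, , drop = FALSE])
  qtl <- sample(marker_ids(g), n_qtl)
  tbv <- drop(g$dosages[, qtl, drop = FALSE] %*% rnorm(n_qtl))
  tbv <- tbv - mean(tbv)
  if (sd(tbv) > 0 && h2 > 0) tbv <- tbv * sqrt(h2) / sd(tbv)
  y <- tbv + rnorm(n, 0, sqrt(max(1 - h2, 1e-12)))
  names(y) <- individual_ids(g)
  list(g = g, yc = y, tbv = tbv)
}

# dense, independently coded restricted log-likelihood of
# y = 1*mu + g + e at heritability h2 (total variance profiled out)
dense_reml_loglik <- function(h2, G, y) {
  n <- length(y)
  W <- h2 * G + (1 - h2) * diag(n)
  Wi <- solve(W)
  one <- rep(1, n)
  xwx <- drop(crossprod(one, Wi %*% one))
  beta <- drop(crossprod(one, Wi %*% y)) / xwx
  r <- y - beta
  s2 <- drop(crossprod(r, Wi %*% r)) / (n - 1)
  ld <- as.numeric(determinant(W, logarithm = TRUE)$modulus)
  -0.5 * ((n - 1) * log(2 * pi * s2) + ld + log(xwx) + (n - 1))
}
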