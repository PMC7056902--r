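#' Read a phenotype table
#'
#' Expects a CSV or TSV with columns `id`, `trait`, `sex`, `batch` (extra
#' columns pass through). `sex` and `batch` become factors.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return data.frame with `id` as character, `sex`/`batch` as factors.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("id", "trait", "sex", "batch")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype file lacks column(s): ",
                         paste(miss, collapse = ", "))
  tab$id <- as.character(tab$id)
  tab$sex <- factor(tab$sex)
  tab$batch <- factor(tab$batch)
  if (anyDuplicated(tab$id)) stop("duplicate individual ids in phenotypes")
  if (any(!is.finite(tab$trait))) stop("non-finite trait values")
  tab
}

#' Correct phenotypes for fixed effects
#'
#' Fits ordinary least squares of the trait on sex and batch with
#' sum-to-zero effect coding, then subtracts the estimated sex and batch
#' effects (the intercept is retained), giving the corrected phenotype
#' `yc = y - sex effect - batch effect`. With sum-to-zero contrasts the
#' effects are deviations from the overall mean, so in balanced designs
#' `mean(yc) == mean(y)`. Correcting once on the full data (rather than
#' per cross-validation fold) uses every record to estimate the nuisance
#' effects.
#'
#' @param pheno data.frame with columns `id`, `trait`, `sex`, `batch`
#'   (single-level factors are allowed and contribute no correction).
#' @return named numeric vector `yc`, names are individual ids.
#' @export
correct_phenotypes <- function(pheno) {
  stopifnot(is.data.frame(pheno),
            all(c("id", "trait", "sex", "batch") %in% names(pheno)))
  if (nrow(pheno) < 2) stop("need at least 2 individuals")
  y <- pheno$trait
  sex <- droplevels(factor(pheno$sex))
  batch <- droplevels(factor(pheno$batch))
  terms <- list()
  if (nlevels(sex) > 1) terms$sex <- sex
  if (nlevels(batch) > 1) terms$batch <- batch
  if (!length(terms)) {
    yc <- y
  } else {
    df <- as.data.frame(terms)
    form <- stats::as.formula(paste("~", paste(names(terms), collapse = " + ")))
    X <- stats::model.matrix(form, df,
                             contrasts.arg = lapply(terms, function(z) "contr.sum"))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("confounded fixed effects; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
    beta <- qr.coef(qx, y)
    eff <- X[, -1, drop = FALSE] %*% beta[-1]
    yc <- y - drop(eff)
  }
  names(yc) <- as.character(pheno$id)
  yc
}
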