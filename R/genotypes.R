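#' Genotype matrix container
#'
#' Bundles an individuals x markers integer dosage matrix (copies of the
#' second allele: 0, 1, 2, or `NA` for a missing call) with per-marker
#' metadata. This is the common currency of the package: quality control,
#' marker preselection, the genomic relationship matrix and the simulator
#' all consume and produce `geno_matrix` objects.
#'
#' @param dosages integer matrix, individuals in rows (rownames are unique
#'   individual ids), markers in columns (colnames are unique marker ids).
#'   Non-missing entries must be 0, 1 or 2.
#' @param map optional data.frame of marker metadata with columns
#'   `marker_id`, `chrom`, `pos`, `allele1`, `allele2`, one row per marker
#'   in column order. A minimal map is built when omitted.
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   and `map`.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("a", "b"), c("m1", "m2")))
#' g <- geno_matrix(d)
#' n_individuals(g)
#' @export
geno_matrix <- function(dosages, map = NULL) {
  if (!is.matrix(dosages)) stop("'dosages' must be a matrix")
  storage.mode(dosages) <- "integer"
  ids <- rownames(dosages)
  mids <- colnames(dosages)
  if (is.null(ids) || anyDuplicated(ids))
    stop("rownames(dosages) must be unique individual ids")
  if (is.null(mids) || anyDuplicated(mids))
    stop("colnames(dosages) must be unique marker ids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing dosages must be in {0, 1, 2}")
  if (is.null(map)) {
    map <- data.frame(marker_id = mids, chrom = "1", pos = seq_along(mids),
                      allele1 = "A", allele2 = "B",
                      stringsAsFactors = FALSE)
  }
  if (nrow(map) != ncol(dosages) || !identical(map$marker_id, mids))
    stop("'map' must have one row per marker, in marker order")
  if (any(map$pos < 0)) stop("marker positions must be non-negative")
  structure(list(dosages = dosages, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`
#' @export
n_individuals <- function(g) nrow(g$dosages)

#' @rdname geno_matrix
#' @export
n_markers <- function(g) ncol(g$dosages)

#' @rdname geno_matrix
#' @export
individual_ids <- function(g) rownames(g$dosages)

#' @rdname geno_matrix
#' @export
marker_ids <- function(g) colnames(g$dosages)

gt_to_dosage <- function(gt) {
  # "0/1", "0|1", "./." -> allele count; half calls are invalid
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  miss <- is.na(clean) | clean %in% c("./.", ".", "")
  hit <- clean %in% names(known)
  if (any(!miss & !hit)) {
    bad <- unique(clean[!miss & !hit])
    stop("unsupported genotype call(s): ", paste(bad, collapse = ", "),
         " (half calls and multi-allelic genotypes are not supported)")
  }
  out[hit] <- known[clean[hit]]
  out
}

#' Read genotypes from VCF or a tabular dosage file
#'
#' VCF genotypes are converted to ALT-allele counts; multi-allelic records
#' and half calls are rejected. The tabular alternative is a TSV whose
#' first column is the individual id, whose header row carries marker ids,
#' and whose entries are 0/1/2/NA.
#'
#' @param path file path (VCF may be plain or bgzipped).
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported; split or drop them first")
  gt <- vcfR::extract.gt(v, element = "GT")
  mids <- fix[, "ID"]
  noid <- is.na(mids) | mids == "."
  mids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  if (anyDuplicated(mids)) stop("duplicate marker ids in VCF")
  ids <- colnames(gt)
  if (anyDuplicated(ids)) stop("duplicate individual ids in VCF")
  dos <- matrix(gt_to_dosage(as.vector(gt)), nrow = nrow(gt))
  map <- data.frame(marker_id = mids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    allele1 = fix[, "REF"], allele2 = alt,
                    stringsAsFactors = FALSE)
  dos <- t(dos)
  dimnames(dos) <- list(ids, mids)
  geno_matrix(dos, map)
}

read_genotypes_dosage <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage file needs an id column plus >= 1 marker")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate individual ids in dosage file")
  dos <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "integer")
  rownames(dos) <- ids
  geno_matrix(dos)
}

#' Write genotypes to VCF or tabular dosage format
#'
#' @param g a [geno_matrix()]
#' @param path output file path
#' @param format `"vcf"` or `"dosage"`
#' @export
write_genotypes <- function(g, path, format = c("dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage") {
    tab <- data.frame(id = individual_ids(g), g$dosages,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    map <- g$map
    gt <- c("0/0", "0/1", "1/1")[g$dosages + 1L]
    gt[is.na(gt)] <- "./."
    gt <- matrix(gt, nrow = nrow(g$dosages))
    body <- cbind(map$chrom, map$pos, map$marker_id, map$allele1, map$allele2,
                  ".", "PASS", ".", "GT", t(gt))
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", individual_ids(g)), collapse = "\t"),
               apply(body, 1, paste, collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Per-marker call rate
#'
#' Fraction of individuals with a non-missing genotype at each marker.
#'
#' @param g a [geno_matrix()]
#' @return named numeric vector in \[0, 1\], one entry per marker.
#' @export
marker_call_rate <- function(g) {
  colMeans(!is.na(g$dosages))
}

#' Per-marker minor allele frequency
#'
#' The second-allele frequency is the number of allele-2 copies over twice
#' the non-missing count; MAF folds it onto \[0, 0.5\]. Markers with no
#' non-missing call get `NA`.
#'
#' @param g a [geno_matrix()]
#' @param folded if `FALSE`, return the raw allele-2 frequency instead.
#' @return named numeric vector, one entry per marker.
#' @export
marker_maf <- function(g, folded = TRUE) {
  n_ok <- colSums(!is.na(g$dosages))
  p <- colSums(g$dosages, na.rm = TRUE) / (2 * n_ok)
  p[n_ok == 0] <- NA_real_
  if (folded) pmin(p, 1 - p) else p
}

#' Marker quality control
#'
#' Retains markers whose call rate exceeds `call_rate_min` (strictly) and
#' whose minor allele frequency is at least `maf_min`. Individuals are
#' never removed. The removal log is attached as attribute `"qc_log"`.
#'
#' @param g a [geno_matrix()]
#' @param call_rate_min call-rate threshold; markers must exceed it
#'   (default 0.70).
#' @param maf_min minimum MAF retained (default 0.01); markers below it are
#'   deleted. Markers with an undefined MAF (no calls) are removed.
#' @return filtered [geno_matrix()] with attribute `qc_log`, a data.frame
#'   of `marker_id`, `call_rate`, `maf`, `kept`, `reason`.
#' @export
qc_filter <- function(g, call_rate_min = 0.70, maf_min = 0.01) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  cr <- marker_call_rate(g)
  mf <- marker_maf(g)
  keep <- cr > call_rate_min & !is.na(mf) & mf >= maf_min
  reason <- rep("", length(keep))
  reason[cr <= call_rate_min] <- "call_rate"
  low_maf <- !keep & cr > call_rate_min
  reason[low_maf] <- ifelse(is.na(mf[low_maf]), "no_calls", "maf")
  log <- data.frame(marker_id = marker_ids(g), call_rate = cr, maf = mf,
                    kept = keep, reason = reason,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(keep)) warning("no markers pass quality control")
  out <- geno_matrix(g$dosages[, keep, drop = FALSE],
                     g$map[keep, , drop = FALSE])
  attr(out, "qc_log") <- log
  out
}

#' MAF spectrum summary
#'
#' Bins marker MAF into half-open intervals `[start, start + w), ...`, the
#' last bin closed at 0.5, and reports the coefficient of variation of the
#' bin counts (sample SD over mean). A more even spread of markers across
#' the allele-frequency spectrum gives a smaller CV; SNP chips are
#' typically more uniform than sequencing panels on this measure.
#'
#' @param g a [geno_matrix()]
#' @param bin_width bin width on the MAF axis (default 0.05).
#' @param start lower bound of the first bin (default 0).
#' @return list of class `maf_summary` with `bin_edges`, `counts`, `cv`.
#' @export
maf_distribution <- function(g, bin_width = 0.05, start = 0) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  mf <- marker_maf(g)
  mf <- mf[!is.na(mf) & mf > 0 & mf >= start]
  if (!length(mf)) stop("no polymorphic markers to summarize")
  edges <- seq(start, 0.5 + bin_width, by = bin_width)
  edges <- edges[seq_len(which(edges >= 0.5)[1])]
  edges[length(edges)] <- 0.5
  idx <- findInterval(mf, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  cv <- if (length(counts) > 1) stats::sd(counts) / mean(counts) else 0
  structure(list(bin_edges = edges, counts = counts, cv = cv),
            class = "maf_summary")
}

#' @export
print.maf_summary <- function(x, ...) {
  cat("MAF spectrum:", sum(x$counts), "markers in",
      length(x$counts), "bins; CV of bin counts =",
      format(x$cv, digits = 4), "\n")
  invisible(x)
}
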