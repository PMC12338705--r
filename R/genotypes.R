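#' Construct a GenotypeMatrix
#'
#' Wraps an allele-dosage matrix (rows = lines, columns = variants) with
#' validation. Dosages count copies of one allele, so they lie in [0, 2];
#' for fully inbred lines only 0 and 2 occur. Heterozygous dosages are
#' accepted but flagged with a warning, since panels like the DGRP are
#' expected to be fully inbred.
#'
#' @param dosages numeric matrix; NA marks missing genotypes.
#' @param lineIds,variantIds optional identifiers; default to the dimnames
#'   or to `L1..Ln` / `V1..Vp`.
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosages, lineIds = rownames(dosages),
                           variantIds = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(lineIds)) lineIds <- paste0("L", seq_len(nrow(dosages)))
  if (is.null(variantIds)) variantIds <- paste0("V", seq_len(ncol(dosages)))
  dimnames(dosages) <- list(as.character(lineIds), as.character(variantIds))
  het <- dosages[!is.na(dosages)]
  het <- het[het > 0 & het < 2]
  if (length(het))
    warning(sprintf(
      "%d heterozygous dosages found; lines are expected to be fully inbred",
      length(het)))
  new("GenotypeMatrix", dosages = dosages)
}

#' Filter variants on minor allele frequency and missing rate
#'
#' Keeps exactly the variants with MAF >= `mafMin` and missing rate
#' <= `missMax` (the study's filters: MAF < 0.05 and missing rate > 0.2
#' removed). MAF is computed from the mean dosage: p = mean(dosage)/2 over
#' non-missing lines, MAF = min(p, 1 - p). Remaining missing dosages are
#' imputed to the variant mean, so the result is ready for
#' [computeGRM()]. Line order is preserved; the operation is idempotent.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param mafMin minimum minor allele frequency, in [0, 0.5).
#' @param missMax maximum missing genotype rate, in [0, 1].
#' @return a filtered, fully imputed [GenotypeMatrix-class].
#' @export
filterVariants <- function(geno, mafMin = 0.05, missMax = 0.2) {
  stopifnot(is(geno, "GenotypeMatrix"),
            mafMin >= 0, mafMin < 0.5, missMax >= 0, missMax <= 1)
  d <- geno@dosages
  missRate <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= mafMin & missRate <= missMax
  if (!any(keep)) stop("empty genotype matrix: no variants pass the filters")
  d <- d[, keep, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  new("GenotypeMatrix", dosages = d)
}

#' Genomic relationship matrix (VanRaden form)
#'
#' G = W W' / (2 * sum_j p_j (1 - p_j)) with p_j the allele frequency of
#' variant j (mean dosage / 2) and W the column-centered dosage matrix
#' (dosage - 2 p_j). For fully inbred lines (dosages in \{0, 2\}) the
#' diagonal of G averages about 2 rather than 1, reflecting the doubled
#' homozygosity of inbred genomes.
#'
#' @param geno a filtered, complete [GenotypeMatrix-class] (no NA).
#' @return symmetric n x n matrix with line ids as dimnames.
#' @export
computeGRM <- function(geno) {
  stopifnot(is(geno, "GenotypeMatrix"))
  d <- geno@dosages
  if (anyNA(d)) stop("genotypes contain missing values; filter/impute first")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all variants monomorphic: GRM denominator is zero")
  W <- sweep(d, 2, 2 * p)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(d), rownames(d))
  symmetrize(G)
}
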