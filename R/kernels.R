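#' Expand the GRM to record level and form the interaction kernel
#'
#' Computes ZGZ' (the line-level genomic kernel expanded to the q records)
#' and the Hadamard product ZGZ' * E, which is the covariance of the
#' gene-environment interaction effect. By the Schur product theorem the
#' Hadamard product of two PSD matrices is PSD, so all members of the
#' returned set are valid covariance kernels.
#'
#' @param G n x n genomic relationship matrix.
#' @param Z q x n incidence matrix (one 1 per row).
#' @param E q x q environmental kernel.
#' @return a [KernelSet-class].
#' @export
expandAndInteract <- function(G, Z, E) {
  if (ncol(Z) != nrow(G)) stop("Z and G dimensions do not conform")
  if (nrow(Z) != nrow(E)) stop("Z and E dimensions do not conform")
  ZGZt <- symmetrize(Z %*% G %*% t(Z))
  GxE <- ZGZt * E
  dimnames(ZGZt) <- dimnames(E)
  dimnames(GxE) <- dimnames(E)
  ## PSD of the q x q kernels follows from PSD of the factors: ZGZ' is a
  ## congruence of G, E is built as an outer product, and the Hadamard
  ## product of PSD matrices is PSD (Schur). Checking G at line level keeps
  ## the construction O(n^3) instead of O(q^3).
  checkKernel(G, "G")
  new("KernelSet", G = G, Z = Z, ZGZt = ZGZt, E = symmetrize(E), GxE = GxE)
}

#' Build the full kernel set from genotypes and the environment design
#'
#' Convenience wrapper: GRM from the genotypes, E from the design, Z from
#' the record-to-line mapping, then [expandAndInteract()].
#'
#' @param geno a filtered [GenotypeMatrix-class].
#' @param design an [EnvDesign-class] whose records reference lines of
#'   `geno`.
#' @param G optional precomputed GRM (avoids recomputation across folds).
#' @return a [KernelSet-class].
#' @export
makeKernels <- function(geno, design, G = NULL) {
  if (is.null(G)) G <- computeGRM(geno)
  Z <- incidenceMatrix(design, rownames(G))
  E <- computeEnvKernel(design)
  expandAndInteract(G, Z, E)
}

#' Write a labelled kernel to CSV
#'
#' @param K matrix with dimnames.
#' @param path output file.
#' @export
writeKernel <- function(K, path) {
  write.csv(as.data.frame(K), path, row.names = TRUE)
  invisible(path)
}
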