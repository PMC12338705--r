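#' Accessors for the core containers
#'
#' `dosages()`, `lineIds()`, `variantIds()` extract the pieces of a
#' [GenotypeMatrix-class]; `envIds()` and `envCovariates()` those of an
#' [EnvDesign-class]; `kernel()` pulls a named kernel out of a
#' [KernelSet-class]; `varComponents()` and `restrictedLogLikOf()` read a
#' [RemlFit-class].
#'
#' @param x object to access.
#' @param name for `kernel()`, one of "G", "Z", "ZGZt", "E", "GxE".
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("envIds", function(x) standardGeneric("envIds"))
#' @rdname accessors
#' @export
setGeneric("envCovariates", function(x) standardGeneric("envCovariates"))
#' @rdname accessors
#' @export
setGeneric("recordTable", function(x) standardGeneric("recordTable"))
#' @rdname accessors
#' @export
setGeneric("kernel", function(x, name) standardGeneric("kernel"))
#' @rdname accessors
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
#' @rdname accessors
setMethod("lineIds", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname accessors
setMethod("variantIds", "GenotypeMatrix", function(x) colnames(x@dosages))
#' @rdname accessors
setMethod("envIds", "EnvDesign", function(x) x@envIds)
#' @rdname accessors
setMethod("envCovariates", "EnvDesign", function(x) x@covariates)
#' @rdname accessors
setMethod("recordTable", "EnvDesign", function(x) x@records)
#' @rdname accessors
setMethod("kernel", "KernelSet", function(x, name) {
  name <- match.arg(name, c("G", "Z", "ZGZt", "E", "GxE"))
  slot(x, name)
})
#' @rdname accessors
setMethod("varComponents", "RemlFit", function(x) x@varComponents)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypeMatrix: %d lines x %d variants (%.3f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
})

setMethod("show", "EnvDesign", function(object) {
  cat(sprintf("EnvDesign: %d records, %d environments, %d covariates\n",
              nrow(object@records), length(object@envIds),
              ncol(object@covariates)))
  cat("  environments:", paste(object@envIds, collapse = ", "), "\n")
})

setMethod("show", "KernelSet", function(object) {
  cat(sprintf("KernelSet: q = %d records, n = %d lines\n",
              nrow(object@Z), ncol(object@Z)))
  cat("  kernels: ZGZt, E, GxE (q x q); G (n x n)\n")
})

setMethod("show", "RemlFit", function(object) {
  cat(sprintf("%s REML fit (%s), logLik = %.4f\n", object@model,
              if (object@converged) "converged" else "NOT converged",
              object@loglik))
  cat(sprintf("  mu = %.4f\n", object@mu))
  vc <- object@varComponents
  for (nm in names(vc)) cat(sprintf("  sigma2[%s] = %.6g\n", nm, vc[nm]))
})

setMethod("show", "MTMFit", function(object) {
  cat(sprintf("MTMFit: %d lines x %d traits, %d stored draws\n",
              length(object@lineIds), length(object@traitIds),
              nrow(object@samples$sigmaR)))
})

setMethod("show", "RRMFit", function(object) {
  cat(sprintf("RRMFit (order %d), logLik = %.4f, %s\n",
              length(object@beta) - 1, object@loglik,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s under %s, mean R2 = %.3f over %d replicates\n",
              object@model, object@scheme, object@meanR2,
              length(object@perReplicateR2)))
})
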