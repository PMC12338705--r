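#' @import methods
#' @importFrom stats var sd optim rnorm runif rbinom setNames lm predict cor
#' @importFrom utils read.csv write.csv read.table packageVersion
#' @importFrom tools md5sum
#' @useDynLib gxePredict, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Central data containers. Dimnames carry the identifiers: rownames of the
## dosage matrix are line ids, colnames are variant ids, so the matrix and
## its labels can never drift apart.

#' GenotypeMatrix: allele dosages for a panel of inbred lines
#'
#' Stores an n x p matrix of counted-allele dosages in [0, 2] (NA allowed
#' before filtering). Rows are lines, columns are variants; identifiers live
#' in the dimnames. Fully inbred lines carry dosages in \{0, 2\}; a
#' heterozygous dosage is accepted on input but flagged with a warning by
#' [genotypeMatrix()].
#'
#' @slot dosages numeric matrix with rownames (line ids) and colnames
#'   (variant ids).
#' @export
setClass("GenotypeMatrix", representation(dosages = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosage matrix must have row (line) and column (variant) names")
  if (anyDuplicated(rownames(d)))
    return("duplicate line ids")
  if (anyDuplicated(colnames(d)))
    return("duplicate variant ids")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    return("dosage values must lie in [0, 2]")
  TRUE
})

#' EnvDesign: discrete environments, their covariates and record structure
#'
#' Describes the r discrete environments (sex x temperature combinations),
#' the standardized environment-level covariate matrix X (r x c), and the
#' mapping of each of the q records to its (line, environment) cell.
#'
#' @slot records data.frame with columns line, sex, temperature, env; one
#'   row per record, in input order.
#' @slot envIds character vector of the r environment labels.
#' @slot covariates numeric r x c matrix of standardized covariates
#'   (rownames = envIds); columns are the sex code and temperature.
#' @slot center,scale numeric length-c standardization constants (record
#'   -level mean and population standard deviation used for each column).
#' @export
setClass("EnvDesign", representation(
  records = "data.frame", envIds = "character",
  covariates = "matrix", center = "numeric", scale = "numeric"))

setValidity("EnvDesign", function(object) {
  if (!all(c("line", "sex", "temperature", "env") %in% names(object@records)))
    return("records must have columns line, sex, temperature, env")
  if (length(object@envIds) != nrow(object@covariates))
    return("one covariate row per environment required")
  if (!all(object@records$env %in% object@envIds))
    return("every record must map to a known environment")
  if (ncol(object@covariates) < 1) return("at least one covariate required")
  TRUE
})

#' KernelSet: the covariance kernels shared by the RKHS mixed models
#'
#' Holds the n x n genomic relationship matrix G, the q x n incidence matrix
#' Z (one 1 per row), the expanded genomic kernel ZGZ', the environmental
#' kernel E and the Hadamard interaction kernel ZGZ' * E.
#'
#' @slot G,Z,ZGZt,E,GxE numeric matrices as described above; record ids are
#'   the rownames of Z and of the q x q kernels.
#' @export
setClass("KernelSet", representation(
  G = "matrix", Z = "matrix", ZGZt = "matrix", E = "matrix", GxE = "matrix"))

setValidity("KernelSet", function(object) {
  q <- nrow(object@Z); n <- ncol(object@Z)
  if (nrow(object@G) != n || ncol(object@G) != n)
    return("G must be n x n with n = ncol(Z)")
  for (nm in c("ZGZt", "E", "GxE")) {
    K <- slot(object, nm)
    if (nrow(K) != q || ncol(K) != q) return(sprintf("%s must be q x q", nm))
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
      return(sprintf("%s is not symmetric", nm))
  }
  rs <- rowSums(object@Z)
  if (any(abs(rs - 1) > 1e-12)) return("Z rows must each contain a single 1")
  if (max(abs(object@GxE - object@ZGZt * object@E)) >
      1e-8 * max(1, max(abs(object@GxE))))
    return("GxE must equal ZGZt * E elementwise")
  TRUE
})

#' RemlFit: REML estimates and BLUPs for one RKHS mixed model
#'
#' @slot model model name, one of "G-BLUP", "E-BLUP", "GE-BLUP", "GxE-BLUP".
#' @slot mu intercept estimate (days).
#' @slot varComponents named numeric: one variance (days^2) per kernel plus
#'   "residual".
#' @slot blups numeric matrix, one column per kernel, one row per training
#'   record: predicted random effects.
#' @slot alpha numeric vector V^-1 (y - mu 1) on the training records, kept
#'   so BLUPs extend to unobserved records.
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot converged logical convergence flag.
#' @slot trainIds character ids of the training records.
#' @slot kernelDiag named mean kernel diagonal per component (residual =
#'   1); converts variance components to phenotypic-variance scale.
#' @export
setClass("RemlFit", representation(
  model = "character", mu = "numeric", varComponents = "numeric",
  blups = "matrix", alpha = "numeric", loglik = "numeric",
  converged = "logical", trainIds = "character", kernelDiag = "numeric"))

setValidity("RemlFit", function(object) {
  if (any(object@varComponents < 0)) return("variances must be >= 0")
  if (!"residual" %in% names(object@varComponents))
    return("varComponents must include 'residual'")
  TRUE
})

#' MTMFit: posterior summaries of the Bayesian multi-trait model
#'
#' @slot intercepts posterior mean trait intercepts (length r).
#' @slot SigmaA r x r posterior mean genetic covariance.
#' @slot sigmaR posterior mean residual variances (diagonal of Sigma_R).
#' @slot Ahat n x r posterior mean genetic values.
#' @slot samples list with `SigmaA` (r*r columns, one row per stored draw)
#'   and `sigmaR` (r columns) thinned post-burn-in draws.
#' @slot chain list: iterations, burnin, thin, seed.
#' @slot lineIds,traitIds identifiers.
#' @export
setClass("MTMFit", representation(
  intercepts = "numeric", SigmaA = "matrix", sigmaR = "numeric",
  Ahat = "matrix", samples = "list", chain = "list",
  lineIds = "character", traitIds = "character"))

setValidity("MTMFit", function(object) {
  r <- length(object@traitIds)
  if (!all(dim(object@SigmaA) == r)) return("SigmaA must be r x r")
  if (length(object@sigmaR) != r || any(object@sigmaR <= 0))
    return("sigmaR must be r positive residual variances")
  ev <- eigen(object@SigmaA, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) return("SigmaA must be PSD")
  TRUE
})

#' RRMFit: random-regression (reaction norm) model fit
#'
#' @slot beta fixed Legendre coefficients, length T + 1.
#' @slot SigmaA (T+1) x (T+1) genetic covariance of the random coefficients.
#' @slot residVars named per-environment residual variances.
#' @slot coefBlups n x (T+1) predicted random coefficients (rownames =
#'   line ids).
#' @slot envValues named standardized environmental value in [-1, 1] per
#'   training environment.
#' @slot envMeans named raw training-mean phenotype per environment (the
#'   quantity the standardized value is derived from).
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot converged logical flag.
#' @export
setClass("RRMFit", representation(
  beta = "numeric", SigmaA = "matrix", residVars = "numeric",
  coefBlups = "matrix", envValues = "numeric", envMeans = "numeric",
  loglik = "numeric", converged = "logical"))

#' CVFold: one train/test split of the record set
#'
#' @slot scheme "RandomLines", "RandomObservations" or "NewEnvironment".
#' @slot train,test disjoint integer record indices covering all records.
#' @slot replicate replicate number.
#' @slot seed seed the split was drawn from (NA for the deterministic
#'   NewEnvironment folds).
#' @export
setClass("CVFold", representation(
  scheme = "character", train = "integer", test = "integer",
  replicate = "integer", seed = "integer"))

setValidity("CVFold", function(object) {
  if (length(intersect(object@train, object@test)))
    return("train and test must be disjoint")
  if (!length(object@test)) return("test set must be nonempty")
  TRUE
})

#' CVResult: accuracy of one model under one cross-validation scheme
#'
#' @slot scheme,model identifiers.
#' @slot perReplicateR2 numeric R^2 per replicate.
#' @slot meanR2 arithmetic mean of the replicate R^2.
#' @slot perEnvironmentR2 named numeric, one value per test environment
#'   (NewEnvironment scheme only; empty otherwise).
#' @export
setClass("CVResult", representation(
  scheme = "character", model = "character", perReplicateR2 = "numeric",
  meanR2 = "numeric", perEnvironmentR2 = "numeric"))

setValidity("CVResult", function(object) {
  if (abs(object@meanR2 - mean(object@perReplicateR2)) > 1e-12)
    return("meanR2 must equal the mean of perReplicateR2")
  TRUE
})
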