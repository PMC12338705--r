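#' Build the environment design from record-level metadata
#'
#' Each record is a (line, sex, temperature) combination; an environment is
#' a distinct sex x temperature cell. The covariate matrix X has one row
#' per environment and columns [sex code, temperature], each standardized
#' to mean 0 and (population) variance 1 across the q records, so a
#' balanced binary sex code becomes exactly +/-1. No intercept column is
#' included: the mixed models carry a global intercept.
#'
#' @param records data.frame with columns `line`, `sex`, `temperature`
#'   (sex a 2-level factor/character, temperature numeric).
#' @param standardizeOn optional integer indices of the records whose mean
#'   and variance define the standardization (training records during
#'   cross-validation); default all records.
#' @return an [EnvDesign-class].
#' @export
buildEnvDesign <- function(records, standardizeOn = seq_len(nrow(records))) {
  stopifnot(all(c("line", "sex", "temperature") %in% names(records)))
  records <- as.data.frame(records)
  sexLevels <- sort(unique(as.character(records$sex)))
  if (length(sexLevels) > 2) stop("sex must have at most 2 levels")
  if (!is.numeric(records$temperature)) stop("temperature must be numeric")
  env <- paste(records$sex, records$temperature, sep = "_")
  Xraw <- cbind(sex = as.numeric(match(records$sex, sexLevels) - 1),
                temperature = records$temperature)
  std <- standardizeCols(Xraw[standardizeOn, , drop = FALSE])
  Xq <- standardizeCols(Xraw, center = std$center, scale = std$scale)$X
  envIds <- unique(env)
  covariates <- Xq[match(envIds, env), , drop = FALSE]
  rownames(covariates) <- envIds
  rec <- data.frame(line = as.character(records$line),
                    sex = as.character(records$sex),
                    temperature = records$temperature,
                    env = env, stringsAsFactors = FALSE)
  new("EnvDesign", records = rec, envIds = envIds, covariates = covariates,
      center = std$center, scale = std$scale)
}

## q x c record-level covariate matrix (rows follow the record order).
recordCovariates <- function(design) {
  X <- design@covariates[match(design@records$env, design@envIds), ,
                         drop = FALSE]
  rownames(X) <- recordIds(design)
  X
}

recordIds <- function(design) {
  paste(design@records$line, design@records$env, sep = ":")
}

#' Environmental similarity kernel
#'
#' E = X_q X_q' / c where X_q is the q x c record-level standardized
#' covariate matrix. The division by c is a normalization convention that
#' puts the average diagonal near 1; any proportionality constant would be
#' absorbed by the environmental variance component. Records sharing an
#' environment have identical rows, so E has rank at most c.
#'
#' @param design an [EnvDesign-class].
#' @return symmetric PSD q x q matrix.
#' @export
computeEnvKernel <- function(design) {
  stopifnot(is(design, "EnvDesign"))
  Xq <- recordCovariates(design)
  E <- tcrossprod(Xq) / ncol(Xq)
  symmetrize(E)
}

#' Incidence matrix mapping records to lines
#'
#' @param design an [EnvDesign-class].
#' @param lineIds line identifiers defining the column order (typically
#'   `lineIds(geno)`).
#' @return q x n 0/1 matrix with exactly one 1 per row.
#' @export
incidenceMatrix <- function(design, lineIds) {
  j <- match(design@records$line, lineIds)
  if (anyNA(j)) stop("records refer to lines absent from lineIds: ",
                     paste(unique(design@records$line[is.na(j)]),
                           collapse = ", "))
  Z <- matrix(0, nrow(design@records), length(lineIds),
              dimnames = list(recordIds(design), lineIds))
  Z[cbind(seq_len(nrow(Z)), j)] <- 1
  Z
}
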