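#' Read a genotype matrix
#'
#' Two text dialects are supported. `csv`: first column = line id, header
#' = variant ids, cells = dosages. `plink_raw`: whitespace-separated with
#' the six PLINK metadata columns (FID IID PAT MAT SEX PHENOTYPE) before
#' the dosage block; IID is used as the line id. `auto` picks `plink_raw`
#' when the header starts with FID/IID. Missing dosages are NA; values
#' outside [0, 2] raise an error naming the offending cell.
#'
#' @param path input file.
#' @param format "auto", "csv" or "plink_raw".
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "csv", "plink_raw")) {
  format <- match.arg(format)
  if (format == "auto") {
    head1 <- readLines(path, n = 1)
    format <- if (grepl("^\\s*FID[\\s,]", head1, perl = TRUE) ||
                  startsWith(head1, "FID ")) "plink_raw" else "csv"
  }
  if (format == "plink_raw") {
    tab <- read.table(path, header = TRUE, check.names = FALSE,
                      na.strings = c("NA", "-9"))
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(tab)[1:6]))
      stop("malformed PLINK .raw header: expected columns ",
           paste(meta, collapse = " "))
    lineId <- as.character(tab$IID)
    d <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    tab <- read.csv(path, check.names = FALSE)
    lineId <- as.character(tab[[1]])
    d <- as.matrix(tab[, -1, drop = FALSE])
  }
  if (anyDuplicated(lineId))
    stop("duplicate line id: ",
         paste(unique(lineId[duplicated(lineId)]), collapse = ", "))
  if (!is.numeric(d)) {
    bad <- colnames(d)[!apply(d, 2, function(v)
      is.numeric(v) || all(is.na(v) | grepl("^-?[0-9.]+$", v)))]
    stop("non-numeric dosage in column(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage out of [0, 2] at line '%s', variant '%s'",
                 lineId[bad[1, 1]], colnames(d)[bad[1, 2]]))
  rownames(d) <- lineId
  genotypeMatrix(d)
}

#' Write a genotype matrix as CSV
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output file (dialect readable by [readGenotypes()]).
#' @export
writeGenotypes <- function(geno, path) {
  d <- dosages(geno)
  out <- data.frame(line = rownames(d), d, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects columns line, sex, temperature, lifespan. As in the source
#' panel, lines with a missing value in any sex/temperature combination
#' are dropped entirely (complete-case by line), so the returned table is
#' balanced: every retained line has one record per environment.
#'
#' @param path CSV file.
#' @return data.frame with columns line, sex, temperature, lifespan.
#' @export
readPhenotypes <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "sex", "temperature", "lifespan")
  if (!all(need %in% names(tab)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  tab$line <- as.character(tab$line)
  env <- envLabel(tab$sex, tab$temperature)
  if (anyDuplicated(paste(tab$line, env)))
    stop("duplicate line x environment rows")
  envsU <- unique(env)
  ok <- tapply(!is.na(tab$lifespan), tab$line, sum)[tab$line] ==
    length(envsU) &
    tapply(rep(1, nrow(tab)), tab$line, sum)[tab$line] == length(envsU)
  tab <- tab[ok & !is.na(tab$lifespan), need]
  if (!nrow(tab)) stop("no complete lines left after filtering")
  if (any(!is.finite(tab$lifespan))) stop("non-finite lifespan values")
  rownames(tab) <- NULL
  tab
}

#' Write a phenotype table as CSV
#'
#' @param pheno data.frame with columns line, sex, temperature, lifespan.
#' @param path output file.
#' @export
writePhenotypes <- function(pheno, path) {
  write.csv(pheno[, c("line", "sex", "temperature", "lifespan")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value file with any of: genotypes, phenotypes, outDir, models,
#' scheme, fraction, replicates, seed, chain (iterations/burnin/thin) and
#' simulation settings. Unset keys fall back to the defaults shown in the
#' function signatures of [runCV()] and [simulationConfig()]; the seed
#' defaults to 1.
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Serialize a model fit to JSON
#'
#' @param fit a [RemlFit-class], [MTMFit-class] or [RRMFit-class].
#' @param path output JSON file.
#' @export
writeFitJSON <- function(fit, path) {
  obj <- if (is(fit, "RemlFit")) {
    list(model = fit@model, mu = fit@mu,
         varComponents = as.list(fit@varComponents),
         loglik = fit@loglik, converged = fit@converged)
  } else if (is(fit, "MTMFit")) {
    list(intercepts = as.list(fit@intercepts),
         SigmaA = fit@SigmaA, sigmaR = as.list(fit@sigmaR),
         chain = fit@chain)
  } else if (is(fit, "RRMFit")) {
    list(beta = as.list(fit@beta), SigmaA = fit@SigmaA,
         residVars = as.list(fit@residVars),
         envValues = as.list(fit@envValues), loglik = fit@loglik,
         converged = fit@converged)
  } else stop("unsupported fit class: ", class(fit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the settings, seed, package version and input digests of a
#' run, sufficient to reproduce it exactly.
#'
#' @param path output JSON file.
#' @param settings named list of run settings (must include `seed`).
#' @param inputs named character vector of input file paths (digested by
#'   size and md5 when they exist).
#' @export
writeManifest <- function(path, settings, inputs = character(0)) {
  digests <- lapply(inputs, function(p)
    if (file.exists(p)) list(path = p, size = file.size(p),
                             md5 = unname(tools::md5sum(p))) else
      list(path = p, size = NA, md5 = NA))
  obj <- list(package = "gxePredict",
              version = as.character(packageVersion("gxePredict")),
              timestamp = format(Sys.time(), tz = "UTC"),
              settings = settings, inputs = digests)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
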