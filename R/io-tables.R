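# tab-delimited table I/O: local ancestry, phenotypes, scan results.
# All files are UTF-8 TSV with '#' comment lines carrying provenance.

.readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.writeTsv <- function(df, path, seed = NA, config = NULL,
                      extra = character()) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write: ", path))
  on.exit(close(con))
  writeLines(.provenanceHeader(seed, config, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write diploid local-ancestry calls
#'
#' The on-disk format is a TSV with one header row of marker ids, a first
#' column `individual_id`, and one row per individual; cells are the diploid
#' local African ancestry proportion and must be in \{0, 0.5, 1\}. Any other
#' value is a validation error reporting its (individual, marker)
#' coordinates.
#'
#' @param path TSV file.
#' @param markers optional `GRanges` of marker metadata (as in an
#'   [AdmixtureExperiment-class]); when given, columns are aligned to it by
#'   marker id and any mismatch is an error listing the offending ids.
#' @return `readLocalAncestry`: an `AdmixtureExperiment` with an `ancestry`
#'   assay (markers from `markers` when supplied, else bare ids at unknown
#'   positions parsed from ids of the form `chrom:pos` if possible).
#' @export
readLocalAncestry <- function(path, markers = NULL) {
  df <- .readTsv(path)
  if (names(df)[1] != "individual_id")
    stop("first column must be 'individual_id'")
  ids <- df$individual_id
  L <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(L) <- ids
  bad <- which(matrix(!(L %in% c(0, 0.5, 1)), nrow(L)), arr.ind = TRUE)
  if (nrow(bad))
    stop("local ancestry outside {0, 0.5, 1} at individual ",
         colnames(L)[bad[1, 2]], ", marker ", rownames(L)[bad[1, 1]],
         " (value ", L[bad[1, , drop = FALSE]], ")")
  if (!is.null(markers)) {
    off <- setdiff(rownames(L), S4Vectors::mcols(markers)$id)
    off2 <- setdiff(S4Vectors::mcols(markers)$id, rownames(L))
    if (length(off) || length(off2))
      stop("marker ids do not match metadata: ",
           paste(c(off, off2), collapse = ", "))
    gr <- markers
    L <- L[S4Vectors::mcols(gr)$id, , drop = FALSE]
  } else {
    parts <- strsplit(rownames(L), ":", fixed = TRUE)
    ok <- all(lengths(parts) == 2) &&
      !anyNA(suppressWarnings(as.integer(vapply(parts, `[`, "", 2))))
    if (ok) {
      gr <- GenomicRanges::GRanges(
        vapply(parts, `[`, "", 1),
        IRanges::IRanges(as.integer(vapply(parts, `[`, "", 2)), width = 1),
        id = rownames(L))
    } else {
      gr <- GenomicRanges::GRanges(
        "un", IRanges::IRanges(seq_len(nrow(L)), width = 1),
        id = rownames(L))
    }
  }
  AdmixtureExperiment(markers = gr, ancestry = L)
}

#' @rdname readLocalAncestry
#' @param x an `AdmixtureExperiment` with an `ancestry` assay.
#' @param seed,config optional provenance recorded in the header.
#' @export
writeLocalAncestry <- function(x, path, seed = NA, config = NULL) {
  L <- ancestry(x)
  df <- data.frame(individual_id = colnames(L),
                   t(L), check.names = FALSE)
  .writeTsv(df, path, seed, config)
}

#' Read / write the cohort phenotype table
#'
#' TSV with columns `individual_id`, `age`, `sex` (female/male), `bmi`,
#' `on_bp_meds` (TRUE/FALSE), `dbp_raw`, `sbp_raw`. Optional second-reading
#' columns `dbp_raw2` / `sbp_raw2` are averaged with the first reading on
#' load. Rows with missing required fields are dropped with a message
#' giving the count; remaining rows must satisfy `age > 0`, `bmi > 0` and
#' `dbp_raw < sbp_raw`, and ids must be unique.
#'
#' @param path TSV file.
#' @return `readCohort`: a `data.frame` of the validated cohort.
#' @export
readCohort <- function(path) {
  df <- .readTsv(path)
  need <- c("individual_id", "age", "sex", "bmi", "on_bp_meds",
            "dbp_raw", "sbp_raw")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (second in c("dbp", "sbp")) {
    c2 <- paste0(second, "_raw2")
    if (c2 %in% names(df)) {
      c1 <- paste0(second, "_raw")
      df[[c1]] <- rowMeans(df[, c(c1, c2)])
      df[[c2]] <- NULL
    }
  }
  complete <- stats::complete.cases(df[, need])
  if (any(!complete))
    message(sum(!complete), " row(s) with missing fields dropped")
  df <- df[complete, need]
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids")
  if (any(df$age <= 0)) stop("age must be > 0")
  if (any(df$bmi <= 0)) stop("bmi must be > 0")
  if (any(df$dbp_raw >= df$sbp_raw))
    stop("dbp_raw must be < sbp_raw for every individual")
  if (!all(df$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  df$on_bp_meds <- as.logical(df$on_bp_meds)
  df
}

#' @rdname readCohort
#' @param cohort a cohort `data.frame` (as from [simulatePhenotypes()] or
#'   [cohort()]).
#' @param seed,config optional provenance recorded in the header.
#' @export
writeCohort <- function(cohort, path, seed = NA, config = NULL) {
  if (!"individual_id" %in% names(cohort))
    cohort <- cbind(individual_id = rownames(cohort), cohort)
  .writeTsv(cohort, path, seed, config)
}

#' Write / read admixture-scan results
#'
#' TSV with columns `chrom`, `pos`, `id`, `beta2`, `se`, `p`, `lod`,
#' `n_used`; numeric columns are serialized with full double precision
#' (`%.17g`), so a round trip reproduces p-values to better than 1e-12.
#' Header comment lines record the package version, seed, config hash,
#' phenotype and any conditioning SNPs.
#'
#' @param scan a [ScanResult-class].
#' @param path output TSV path.
#' @param seed,config optional provenance recorded in the header.
#' @return `writeScanResults`: `path` invisibly. `readScanResults`: a
#'   `ScanResult` (alpha and metadata restored from the header).
#' @export
writeScanResults <- function(scan, path, seed = NA, config = NULL) {
  stopifnot(is(scan, "ScanResult"))
  df <- scanStats(scan)
  if (!nrow(df)) stop("empty scan")
  for (col in c("beta2", "se", "p", "lod"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  extra <- c(sprintf("# phenotype=%s", scan@phenotype),
             sprintf("# alpha=%.17g", scan@alpha),
             sprintf("# conditioned=%s",
                     paste(scan@conditioned, collapse = ",")))
  .writeTsv(df, path, seed, config, extra = extra)
}

#' @rdname writeScanResults
#' @export
readScanResults <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, "="), "", ln[1]) else NA
  }
  df <- .readTsv(path, colClasses = c(chrom = "character"))
  cond <- getv("conditioned")
  new("ScanResult", stats = S4Vectors::DataFrame(df),
      phenotype = as.character(getv("phenotype")),
      covariates = character(),
      alpha = suppressWarnings(as.numeric(getv("alpha"))),
      conditioned = if (is.na(cond) || !nzchar(cond)) character()
        else strsplit(cond, ",", fixed = TRUE)[[1]])
}
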