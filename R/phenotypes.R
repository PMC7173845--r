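#' Medication adjustment of measured blood pressure
#'
#' For individuals on antihypertensive medication the measured pressures
#' understate the untreated values; the standard fixed-offset correction
#' adds 5 mmHg to diastolic and 10 mmHg to systolic readings. Unmedicated
#' readings pass through unchanged.
#'
#' @param dbp_raw,sbp_raw measured diastolic / systolic BP, mmHg
#'   (positive, `dbp_raw < sbp_raw` element-wise).
#' @param on_meds logical, on antihypertensive medication.
#' @return list with `dbp_adj` and `sbp_adj`.
#' @examples
#' adjustForMedication(73, 125, TRUE)   # 78 / 135
#' adjustForMedication(73, 125, FALSE)  # unchanged
#' @export
adjustForMedication <- function(dbp_raw, sbp_raw, on_meds) {
  if (any(dbp_raw <= 0) || any(sbp_raw <= 0))
    stop("blood pressure must be positive")
  if (any(dbp_raw >= sbp_raw))
    stop("dbp_raw must be < sbp_raw")
  list(dbp_adj = dbp_raw + 5 * as.numeric(on_meds),
       sbp_adj = sbp_raw + 10 * as.numeric(on_meds))
}

#' Mean arterial pressure
#'
#' `MAP = SBP / 3 + 2 DBP / 3`, computed from the medication-adjusted
#' pressures. Always strictly between its two inputs.
#'
#' @param sbp_adj,dbp_adj adjusted systolic / diastolic BP, mmHg.
#' @return MAP in mmHg.
#' @examples
#' meanArterialPressure(120, 90)  # 100
#' @export
meanArterialPressure <- function(sbp_adj, dbp_adj) {
  if (any(dbp_adj <= 0) || any(sbp_adj <= 0))
    stop("blood pressure must be positive")
  if (any(dbp_adj >= sbp_adj))
    stop("dbp_adj must be < sbp_adj")
  sbp_adj / 3 + 2 * dbp_adj / 3
}

#' Base-10 log transform of systolic blood pressure
#'
#' Raw systolic BP is right-skewed; its base-10 logarithm is the scale on
#' which the scan treats it as normal.
#'
#' @param sbp_adj adjusted systolic BP, mmHg (positive).
#' @return `log10(sbp_adj)`.
#' @export
transformSbp <- function(sbp_adj) {
  if (any(sbp_adj <= 0)) stop("sbp_adj must be positive")
  log10(sbp_adj)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] returning the W statistic
#' and p-value, used to verify that each analysis phenotype is close enough
#' to normal for the OLS scan.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normalityCheck <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("need 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant vector")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Construct the analysis phenotypes on a cohort
#'
#' Applies [adjustForMedication()], [meanArterialPressure()] and
#' [transformSbp()] to the cohort table of an `AdmixtureExperiment`, adding
#' `dbp_adj`, `sbp_adj`, `map` and `log10_sbp` columns, and records
#' Shapiro-Wilk checks for the three scan phenotypes in
#' `metadata(x)$normality`.
#'
#' @param x an `AdmixtureExperiment` whose cohort has `dbp_raw`, `sbp_raw`,
#'   `on_bp_meds`.
#' @return the updated `AdmixtureExperiment`.
#' @export
preparePhenotypes <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  need <- c("dbp_raw", "sbp_raw", "on_bp_meds")
  if (!all(need %in% names(cd)))
    stop("cohort lacks columns: ",
         paste(setdiff(need, names(cd)), collapse = ", "))
  adj <- adjustForMedication(cd$dbp_raw, cd$sbp_raw, cd$on_bp_meds)
  cd$dbp_adj <- adj$dbp_adj
  cd$sbp_adj <- adj$sbp_adj
  cd$map <- meanArterialPressure(adj$sbp_adj, adj$dbp_adj)
  cd$log10_sbp <- transformSbp(adj$sbp_adj)
  SummarizedExperiment::colData(x) <- cd
  S4Vectors::metadata(x)$normality <- lapply(
    list(dbp_adj = cd$dbp_adj, map = cd$map, log10_sbp = cd$log10_sbp),
    function(v) tryCatch(normalityCheck(v), error = function(e) NULL))
  x
}
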