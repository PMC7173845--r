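#' Run configuration
#'
#' Builds (and validates) the configuration object consumed by
#' [runPipeline()] and the per-stage functions: QC thresholds, LD-pruning
#' parameters, the family-wise error rate, the ancestry-differential cutoff
#' for regional fine-mapping, the number of principal components, simulator
#' parameters and the run seed.
#'
#' Defaults follow the analysis this package implements: HWE exact-test
#' p < 5.7e-7, call rate < 0.98 and MAF < 0.005 remove a marker; LD pruning
#' in 200-marker windows stepping by 20 at r^2 > 0.1; FWER 0.05;
#' delta cutoff 0.4; 10 PCs.
#'
#' @param maf_min minimum minor allele frequency (markers strictly below are
#'   removed).
#' @param callrate_min minimum call rate (strict).
#' @param hwe_p_min minimum HWE exact-test p-value (strict).
#' @param ld_window,ld_step,ld_r2_max LD-pruning window (markers), step and
#'   r^2 threshold.
#' @param fwer family-wise error rate.
#' @param delta_cutoff minimum ancestral allele-frequency differential for
#'   regional fine-mapping (strict).
#' @param n_pcs number of principal components in the SNP model.
#' @param drop_scale scale on which the 1-unit drop delimiting significant
#'   regions is taken: `"lod"` (default) or `"mlog10p"`.
#' @param min_stratum_n minimum per-stratum n in the stratified meta-analysis.
#' @param sim simulator parameter list, see [simParams()].
#' @param seed integer run seed.
#' @return A list of class `admixConfig`.
#' @export
admixConfig <- function(maf_min = 0.005, callrate_min = 0.98,
                        hwe_p_min = 5.7e-7,
                        ld_window = 200L, ld_step = 20L, ld_r2_max = 0.1,
                        fwer = 0.05, delta_cutoff = 0.4, n_pcs = 10L,
                        drop_scale = c("lod", "mlog10p"),
                        min_stratum_n = 30L,
                        sim = simParams(), seed = 1L) {
  drop_scale <- match.arg(drop_scale)
  .assertProb(c(maf_min, callrate_min, hwe_p_min, fwer, ld_r2_max),
              "thresholds")
  if (delta_cutoff < 0 || delta_cutoff > 1) stop("delta_cutoff in [0, 1]")
  if (ld_window < ld_step) stop("ld_window must be >= ld_step")
  if (n_pcs < 0) stop("n_pcs must be >= 0")
  cfg <- list(maf_min = maf_min, callrate_min = callrate_min,
              hwe_p_min = hwe_p_min, ld_window = as.integer(ld_window),
              ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max,
              fwer = fwer, delta_cutoff = delta_cutoff,
              n_pcs = as.integer(n_pcs), drop_scale = drop_scale,
              min_stratum_n = as.integer(min_stratum_n),
              sim = sim, seed = as.integer(seed))
  class(cfg) <- "admixConfig"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `readConfig` returns an `admixConfig`; unknown keys are an error.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(admixConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$sim)) raw$sim <- do.call(simParams, raw$sim)
  do.call(admixConfig, raw)
}

#' @rdname readConfig
#' @param config an `admixConfig`.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "admixConfig"))
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}
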