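#' Simulator parameters
#'
#' Parameters of the generative model for admixed cohorts. Defaults emulate
#' an African American exome cohort: 484 individuals; individual African
#' ancestry proportion q ~ Beta with mean 0.767 and SD 0.128; a single
#' admixture pulse g = 6 generations ago, giving Markov ancestry tracts
#' along a 22-autosome genetic map of ~35.6 Morgans with exome-sparse
#' markers every 0.5 cM (~127 observed diploid ancestry switch points per
#' individual at these settings); age ~ U(45, 65), 74% female,
#' BMI ~ N(32, 10) truncated at 15; diastolic BP with mean ~73 and SD ~9
#' mmHg, pulse pressure ~ N(52, 10.7^2) truncated at 10 so systolic BP has
#' mean ~125 and SD ~14; ~45% of the cohort on antihypertensive medication
#' (assigned by a logistic model in true systolic BP and calibrated to that
#' rate).
#'
#' @param nIndividuals cohort size.
#' @param g generations since the admixture pulse (tract-breaking rate per
#'   Morgan).
#' @param chromosomes named numeric vector of per-chromosome genetic lengths
#'   in Morgans.
#' @param markerSpacingCM marker spacing along the map, centimorgans.
#' @param ancestryBetaMean,ancestryBetaSD mean and SD of the Beta
#'   distribution of individual African ancestry q (SD 0 fixes q at the
#'   mean).
#' @param deltaFrac fraction of markers drawn as ancestry-informative
#'   (delta > 0.4); the rest get a small differential.
#' @param effects named list of generative coefficients on the mmHg scale:
#'   `beta0` intercept, `beta1` global-ancestry effect, `beta2` effect of
#'   (G - L) at the causal locus, `betaSnp` per-alt-allele effect of the
#'   causal SNP, `betaAge`, `betaAge2`, `betaSex`, `betaBmi`.
#' @param causalLocus,causalSnp marker index (or id) of the causal
#'   local-ancestry locus / causal SNP; `NA` for none.
#' @param noiseSd residual SD of true diastolic BP, mmHg.
#' @param pulseMean,pulseSd,pulseMin pulse-pressure distribution (SBP - DBP),
#'   mmHg, truncated below at `pulseMin`.
#' @param medRate target antihypertensive-medication rate.
#' @param medScale logistic scale (mmHg) of the medication model.
#' @param ageRange,maleP,bmiMean,bmiSd,bmiMin covariate distributions.
#' @param depthRange range of simulated mean sequencing depth per marker.
#' @param seed integer seed; all stages derive deterministic sub-streams.
#' @return list of class `simParams`.
#' @export
simParams <- function(nIndividuals = 484L, g = 6,
                      chromosomes = .defaultChromosomes(),
                      markerSpacingCM = 0.5,
                      ancestryBetaMean = 0.767, ancestryBetaSD = 0.128,
                      deltaFrac = 0.1,
                      effects = list(beta0 = 62.3, beta1 = 8, beta2 = 0,
                                     betaSnp = 0, betaAge = 0.05,
                                     betaAge2 = 0, betaSex = 1,
                                     betaBmi = 0.05),
                      causalLocus = NA, causalSnp = NA,
                      noiseSd = 8.8,
                      pulseMean = 52, pulseSd = 10.7, pulseMin = 10,
                      medRate = 0.45, medScale = 10,
                      ageRange = c(45, 65), maleP = 0.26,
                      bmiMean = 32, bmiSd = 10, bmiMin = 15,
                      depthRange = c(20, 80),
                      seed = 1L) {
  if (g < 1) stop("g must be >= 1")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (ancestryBetaMean <= 0 || ancestryBetaMean >= 1)
    stop("ancestryBetaMean must be in (0, 1)")
  if (is.null(names(chromosomes)))
    names(chromosomes) <- as.character(seq_along(chromosomes))
  defaults <- eval(formals(simParams)$effects)
  missing <- setdiff(names(defaults), names(effects))
  effects[missing] <- defaults[missing]
  p <- list(nIndividuals = as.integer(nIndividuals), g = g,
            chromosomes = chromosomes, markerSpacingCM = markerSpacingCM,
            ancestryBetaMean = ancestryBetaMean,
            ancestryBetaSD = ancestryBetaSD,
            deltaFrac = deltaFrac, effects = effects,
            causalLocus = causalLocus, causalSnp = causalSnp,
            noiseSd = noiseSd, pulseMean = pulseMean, pulseSd = pulseSd,
            pulseMin = pulseMin, medRate = medRate, medScale = medScale,
            ageRange = ageRange, maleP = maleP, bmiMean = bmiMean,
            bmiSd = bmiSd, bmiMin = bmiMin, depthRange = depthRange,
            seed = as.integer(seed))
  class(p) <- "simParams"
  p
}

# autosome genetic lengths (Morgans), sex-averaged, rounded; total ~35.6 M
.defaultChromosomes <- function() {
  stats::setNames(
    c(2.86, 2.69, 2.23, 2.14, 2.04, 1.92, 1.87, 1.70, 1.68, 1.81,
      1.58, 1.75, 1.26, 1.20, 1.42, 1.35, 1.30, 1.19, 1.08, 1.08,
      0.62, 0.74),
    as.character(1:22))
}

# marker grid along the genetic map; physical position from cM at 1 cM/Mb
.simMarkerGrid <- function(params) {
  if (!length(params$chromosomes)) stop("empty genetic map")
  sp <- params$markerSpacingCM / 100  # Morgans
  per <- lapply(names(params$chromosomes), function(chr) {
    len <- params$chromosomes[[chr]]
    cm <- seq(sp, len, by = sp) * 100
    data.frame(chrom = chr, cM = cm, pos = as.integer(round(cm * 1e6)))
  })
  grid <- do.call(rbind, per)
  grid$id <- paste0("c", grid$chrom, "m",
                    unlist(lapply(per, function(d) seq_len(nrow(d)))))
  grid
}

#' Simulate local ancestry tracts
#'
#' Each haplotype follows a two-state Markov chain along the genetic map
#' with stationary distribution (q, 1 - q) — q the individual's African
#' proportion drawn from the Beta prior — and inter-marker transition
#' P(copy previous state) = exp(-g d) for map distance d Morgans, otherwise
#' a fresh draw from the stationary distribution. This is the
#' hybrid-isolation (single-pulse) tract model: ancestry segments have
#' exponential length 1/g Morgans. Diploid local ancestry is the mean of
#' the two haplotypes.
#'
#' @param params a [simParams()] list.
#' @return list of class `ancestrySim`: `markers` (`GRanges`), `hap1`/`hap2`
#'   (markers x individuals, 1 = African), `L` (diploid, in \{0, 0.5, 1\}),
#'   `q` (per-individual African proportion). Deterministic given
#'   `params$seed`.
#' @export
simulateAncestry <- function(params = simParams()) {
  grid <- .simMarkerGrid(params)
  if (!nrow(grid)) stop("empty genetic map")
  n <- params$nIndividuals
  .withSeed(.stageSeed(params$seed, "ancestry"), {
    m <- params$ancestryBetaMean; s <- params$ancestryBetaSD
    q <- if (s > 0) {
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) stop("ancestry Beta SD too large for its mean")
      stats::rbeta(n, m * nu, (1 - m) * nu)
    } else rep(m, n)
    hap <- function() {
      H <- matrix(0L, nrow(grid), n)
      for (chr in unique(grid$chrom)) {
        idx <- which(grid$chrom == chr)
        d <- diff(grid$cM[idx]) / 100
        H[idx[1], ] <- stats::rbinom(n, 1L, q)
        for (k in seq_along(d)) {
          stay <- stats::runif(n) < exp(-params$g * d[k])
          fresh <- stats::rbinom(n, 1L, q)
          H[idx[k + 1], ] <- ifelse(stay, H[idx[k], ], fresh)
        }
      }
      H
    }
    h1 <- hap(); h2 <- hap()
    ids <- sprintf("ind%04d", seq_len(n))
    dimnames(h1) <- dimnames(h2) <- list(grid$id, ids)
    gr <- GenomicRanges::GRanges(
      grid$chrom, IRanges::IRanges(grid$pos, width = 1),
      id = grid$id, cM = grid$cM)
    names(gr) <- grid$id
    structure(list(markers = gr, hap1 = h1, hap2 = h2,
                   L = (h1 + h2) / 2, q = stats::setNames(q, ids)),
              class = "ancestrySim")
  })
}

# reference allele frequencies: a deltaFrac share of markers is strongly
# ancestry-differentiated (delta ~ U(0.45, 0.9)); the rest nearly shared
.simFrequencies <- function(m, params) {
  big <- stats::runif(m) < params$deltaFrac
  delta <- ifelse(big, stats::runif(m, 0.45, 0.9),
                  abs(stats::rnorm(m, 0, 0.05)))
  delta <- pmin(delta, 0.98)
  lo <- stats::runif(m, 0, 1 - delta)
  swap <- stats::runif(m) < 0.5
  f_eur <- ifelse(swap, lo + delta, lo)
  f_afr <- ifelse(swap, lo, lo + delta)
  data.frame(f_eur = f_eur, f_afr = f_afr)
}

#' Simulate genotypes conditional on local ancestry
#'
#' Each of the two alleles at a marker is Bernoulli(`f_afr`) if its
#' haplotype is African there and Bernoulli(`f_eur`) otherwise; the dosage
#' is their sum. Markers are therefore independent given ancestry (no
#' within-population LD); cross-population LD — the admixture LD the scan
#' exploits — arises from the shared tracts.
#'
#' @param sim an `ancestrySim` from [simulateAncestry()].
#' @param params a [simParams()] list.
#' @param freqs optional data.frame with columns `f_eur`, `f_afr` (one row
#'   per marker); drawn from the frequency model when omitted.
#' @return list: `dosage` (markers x individuals), `markers` (`GRanges` with
#'   `ref`, `alt`, `f_eur`, `f_afr`, `depth` filled in).
#' @export
simulateGenotypes <- function(sim, params = simParams(), freqs = NULL) {
  stopifnot(inherits(sim, "ancestrySim"))
  m <- length(sim$markers)
  .withSeed(.stageSeed(params$seed, "genotypes"), {
    if (is.null(freqs)) freqs <- .simFrequencies(m, params)
    .assertProb(c(freqs$f_eur, freqs$f_afr), "allele frequencies")
    draw <- function(H) {
      pr <- ifelse(H == 1L, freqs$f_afr, freqs$f_eur)  # recycles by column
      matrix(stats::rbinom(length(pr), 1L, pr), nrow = m)
    }
    dos <- draw(sim$hap1) + draw(sim$hap2)
    dimnames(dos) <- dimnames(sim$hap1)
    gr <- sim$markers
    S4Vectors::mcols(gr)$ref <- "A"
    S4Vectors::mcols(gr)$alt <- "G"
    S4Vectors::mcols(gr)$f_eur <- freqs$f_eur
    S4Vectors::mcols(gr)$f_afr <- freqs$f_afr
    S4Vectors::mcols(gr)$depth <-
      round(stats::runif(m, params$depthRange[1], params$depthRange[2]), 1)
    list(dosage = dos, markers = gr)
  })
}

# resolve a causal index given as NA, integer index or marker id
.causalIndex <- function(locus, markers) {
  if (length(locus) != 1 || is.na(locus)) return(NA_integer_)
  if (is.character(locus)) {
    i <- match(locus, names(markers))
    if (is.na(i)) stop("causal marker id not found: ", locus)
    return(i)
  }
  i <- as.integer(locus)
  if (i < 1 || i > length(markers)) stop("causal index out of range")
  i
}

#' Simulate blood-pressure phenotypes
#'
#' True (pre-medication) diastolic BP follows the same linear model the
#' ancestry scan fits:
#' `beta0 + beta1 G + beta2 (G - L_causal) + betaSnp dosage_causal +
#' betaAge age + betaAge2 age^2 + betaSex sex + betaBmi BMI + e`,
#' `e ~ N(0, noiseSd^2)`. Systolic BP adds a truncated-normal pulse
#' pressure. Medication is assigned by a logistic model in true systolic BP
#' whose intercept is calibrated so the cohort medication rate matches
#' `medRate`; *stored* raw BP subtracts the usual treatment offsets
#' (5 mmHg DBP, 10 mmHg SBP) for medicated individuals so that
#' [adjustForMedication()] recovers the generative scale.
#'
#' @param sim an `ancestrySim`.
#' @param geno output of [simulateGenotypes()] (may be `NULL` when no SNP
#'   effect is simulated).
#' @param params a [simParams()] list.
#' @return `data.frame` cohort table: `individual_id`, `age`, `sex`, `bmi`,
#'   `on_bp_meds`, `dbp_raw`, `sbp_raw`.
#' @export
simulatePhenotypes <- function(sim, geno = NULL, params = simParams()) {
  stopifnot(inherits(sim, "ancestrySim"))
  n <- params$nIndividuals
  ids <- colnames(sim$L)
  ef <- params$effects
  ci <- .causalIndex(params$causalLocus, sim$markers)
  if (!is.na(params$causalSnp) && is.null(geno))
    stop("causalSnp set but no genotypes supplied")
  si <- if (is.null(geno)) NA_integer_ else
    .causalIndex(params$causalSnp, geno$markers)

  covars <- .withSeed(.stageSeed(params$seed, "covariates"), {
    age <- stats::runif(n, params$ageRange[1], params$ageRange[2])
    sex <- ifelse(stats::runif(n) < params$maleP, "male", "female")
    bmi <- pmax(params$bmiMin, stats::rnorm(n, params$bmiMean, params$bmiSd))
    data.frame(age = age, sex = sex, bmi = bmi)
  })

  G <- colMeans(sim$L)
  lp <- ef$beta0 + ef$beta1 * G +
    ef$betaAge * covars$age + ef$betaAge2 * covars$age^2 +
    ef$betaSex * (covars$sex == "male") + ef$betaBmi * covars$bmi
  if (!is.na(ci)) lp <- lp + ef$beta2 * (G - sim$L[ci, ])
  if (!is.na(si)) lp <- lp + ef$betaSnp * geno$dosage[si, ]

  .withSeed(.stageSeed(params$seed, "phenotypes"), {
    dbp_true <- lp + stats::rnorm(n, 0, params$noiseSd)
    # pulse pressure truncated below so SBP > DBP always holds
    plo <- stats::pnorm(params$pulseMin, params$pulseMean, params$pulseSd)
    pp <- stats::qnorm(stats::runif(n, plo, 1),
                       params$pulseMean, params$pulseSd)
    sbp_true <- dbp_true + pp

    # medication: logistic in true SBP, intercept calibrated to medRate
    med <- if (params$medRate <= 0) rep(FALSE, n) else {
      f <- function(c0) mean(stats::plogis((sbp_true - c0) /
                                             params$medScale)) -
        params$medRate
      c0 <- stats::uniroot(f, range(sbp_true) + c(-200, 200))$root
      stats::runif(n) < stats::plogis((sbp_true - c0) / params$medScale)
    }
    data.frame(individual_id = ids,
               age = covars$age, sex = covars$sex, bmi = covars$bmi,
               on_bp_meds = med,
               dbp_raw = dbp_true - 5 * med,
               sbp_raw = sbp_true - 10 * med)
  })
}

#' Simulate a complete admixed cohort
#'
#' Runs [simulateAncestry()], [simulateGenotypes()] and
#' [simulatePhenotypes()] and assembles the result into an
#' [AdmixtureExperiment-class] with `dosage` and `ancestry` assays. The
#' generative truth (per-individual q, causal indices, the parameter list)
#' is kept in `metadata(x)$truth`.
#'
#' @param params a [simParams()] list.
#' @param genotypes simulate the genotype assay (set `FALSE` for an
#'   ancestry-only cohort).
#' @return An `AdmixtureExperiment`.
#' @examples
#' ex <- simulateAdmixedCohort(simParams(nIndividuals = 20,
#'                                       chromosomes = c(`1` = 0.5)))
#' ex
#' @export
simulateAdmixedCohort <- function(params = simParams(), genotypes = TRUE) {
  sim <- simulateAncestry(params)
  geno <- if (genotypes) simulateGenotypes(sim, params) else NULL
  pheno <- simulatePhenotypes(sim, geno, params)
  markers <- if (genotypes) geno$markers else sim$markers
  x <- AdmixtureExperiment(markers = markers,
                           dosage = if (genotypes) geno$dosage,
                           ancestry = sim$L, cohort = pheno)
  S4Vectors::metadata(x)$truth <- list(
    q = sim$q,
    causalLocus = .causalIndex(params$causalLocus, sim$markers),
    causalSnp = if (genotypes)
      .causalIndex(params$causalSnp, geno$markers) else NA_integer_,
    params = params)
  x
}
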