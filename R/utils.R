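# internal helpers shared across modules

# deterministic per-stage sub-seed derived from the run seed; kept < 2^31
.stageSeed <- function(seed, stage) {
  stages <- c(ancestry = 1L, genotypes = 2L, covariates = 3L,
              phenotypes = 4L, medication = 5L, frequencies = 6L)
  off <- stages[[stage]]
  (as.integer(seed) %% 1000000000L) + off * 1000003L
}

# evaluate expr with a local RNG state so package code never disturbs the
# caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# provenance comment lines written at the top of every tabular output
.provenanceHeader <- function(seed = NA, config = NULL, extra = character()) {
  c(sprintf("# admixscan %s",
            as.character(utils::packageVersion("admixscan"))),
    sprintf("# seed=%s", seed),
    sprintf("# config_hash=%s",
            if (is.null(config)) "none" else rlang::hash(config)),
    extra)
}

.assertProb <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop(what, " must lie in [0, 1]")
  invisible(x)
}
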