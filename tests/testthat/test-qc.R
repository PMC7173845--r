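test_that("HWE exact test matches closed-form cases", {
  expect_equal(hweExactTest(5, 0, 0), 1)
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)
  expect_error(hweExactTest(0, 0, 0), "zero")
  expect_error(hweExactTest(-1, 2, 0), "non-negative")
  p <- hweExactTest(10, 2, 10)
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("HWE exact test equals the enumeration oracle, totals <= 30", {
  worst <- 0
  for (tot in 1:30) for (a in 0:tot) for (h in 0:(tot - a)) {
    b <- tot - a - h
    worst <- max(worst, abs(hweExactTest(a, h, b) - hweOracle(a, h, b)))
  }
  expect_lt(worst, 1e-12)
})

test_that("qc filter applies the strict thresholds and is idempotent", {
  # 6 markers x 200 individuals: m2, m3 fail MAF; m5 monomorphic
  set.seed(77)
  n <- 200
  dos <- rbind(
    m1 = rbinom(n, 2, 0.3),
    m2 = c(1L, rep(0L, n - 1)),          # MAF 1/400 < 0.005: removed
    m3 = c(1L, rep(0L, n - 1)),          # MAF 1/400 < 0.005: removed
    m4 = rbinom(n, 2, 0.5),
    m5 = rep(2L, n),                     # monomorphic
    m6 = rbinom(n, 2, 0.15))
  dos["m6", 1] <- NA                     # call rate 199/200 = 0.995, passes
  colnames(dos) <- paste0("i", seq_len(n))
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:6 * 100, width = 1),
                               id = rownames(dos))
  x <- AdmixtureExperiment(markers = gr, dosage = dos)
  out <- qcFilter(x, admixConfig())
  kept <- rownames(dosage(out$experiment))
  expect_setequal(kept, c("m1", "m4", "m6"))
  fl <- out$report@flags
  expect_true(all(fl[c("m2", "m3"), "fail_maf"]))
  expect_true(fl["m5", "monomorphic"])

  again <- qcFilter(out$experiment, admixConfig())
  expect_identical(rownames(dosage(again$experiment)), kept)
  expect_error(qcFilter(x[0, ], admixConfig()), "empty")
})

test_that("call rate exactly at the threshold is retained", {
  n <- 100
  set.seed(8)
  dos <- rbind(m1 = rbinom(n, 2, 0.5), m2 = rbinom(n, 2, 0.5))
  dos["m1", 1:2] <- NA          # 98/100 = 0.98 exactly: retained (strict <)
  dos["m2", 1:3] <- NA          # 0.97: removed
  colnames(dos) <- paste0("i", seq_len(n))
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(10, 20), width = 1),
                               id = c("m1", "m2"))
  out <- qcFilter(AdmixtureExperiment(markers = gr, dosage = dos),
                  admixConfig())
  expect_identical(rownames(dosage(out$experiment)), "m1")
})

test_that("qc filter removes markers far from Hardy-Weinberg", {
  n <- 400
  set.seed(9)
  dos <- rbind(ok = rbinom(n, 2, 0.4),
               bad = rep(c(0L, 2L), n / 2))  # no hets at 50% frequency
  colnames(dos) <- paste0("i", seq_len(n))
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(5, 15), width = 1),
                               id = rownames(dos))
  out <- qcFilter(AdmixtureExperiment(markers = gr, dosage = dos),
                  admixConfig())
  expect_false("bad" %in% rownames(dosage(out$experiment)))
  expect_true(out$report@flags["bad", "fail_hwe"])
})

test_that("LD pruning keeps the higher-depth member of correlated pairs", {
  set.seed(10)
  n <- 150
  base <- rbinom(n, 2, 0.5)
  dos <- rbind(m1 = base, m2 = base, m3 = rbinom(n, 2, 0.5))
  colnames(dos) <- paste0("i", seq_len(n))
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(10, 20, 30),
                                                     width = 1),
                               id = rownames(dos),
                               depth = c(30, 20, 25))
  x <- AdmixtureExperiment(markers = gr, dosage = dos)
  kept <- ldPrune(x, window = 200, step = 20, r2_max = 0.1)
  expect_true("m1" %in% kept)    # depth 30 beats 20
  expect_false("m2" %in% kept)
  expect_true("m3" %in% kept)
  expect_error(ldPrune(x, window = 10, step = 20), "window")
})

test_that("independent markers are untouched and pruning bounds r2", {
  set.seed(11)
  n <- 120; m <- 60
  indep <- matrix(rbinom(m * n, 2, 0.5), m,
                  dimnames = list(paste0("u", 1:m), paste0("i", 1:n)))
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:m * 50, width = 1),
                               id = rownames(indep), depth = runif(m, 10, 50))
  # independence check at a lenient r2 so sampling noise cannot prune
  kept <- ldPrune(AdmixtureExperiment(markers = gr, dosage = indep),
                  window = 200, step = 20, r2_max = 0.3)
  expect_length(kept, m)

  # blocky structure: post-hoc max within-window r2 <= threshold
  blocks <- do.call(rbind, lapply(1:25, function(b) {
    core <- rbinom(n, 2, 0.5)
    out <- rbind(core, core, rbinom(n, 2, 0.5))
    out
  }))
  rownames(blocks) <- paste0("b", seq_len(nrow(blocks)))
  colnames(blocks) <- paste0("i", 1:n)
  gr2 <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(seq_len(nrow(blocks)) * 10, width = 1),
    id = rownames(blocks), depth = runif(nrow(blocks), 10, 50))
  x2 <- AdmixtureExperiment(markers = gr2, dosage = blocks)
  kept2 <- ldPrune(x2, window = 20, step = 5, r2_max = 0.1)
  dk <- dosage(x2)[kept2, ]
  ord <- match(kept2, rownames(dosage(x2)))
  for (start in seq(1, nrow(dosage(x2)), by = 5)) {
    inwin <- which(ord >= start & ord <= start + 19)
    if (length(inwin) < 2) next
    r2 <- suppressWarnings(cor(t(dk[inwin, , drop = FALSE])))^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.1)
  }
})
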