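#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file (via `VariantAnnotation::readVcf`) into an
#' [AdmixtureExperiment-class] with a `dosage` assay. Only biallelic SNP
#' records are accepted; multiallelic records are an error (split them
#' upstream with e.g. `bcftools norm`). Dosage is the alt-allele count of
#' the GT field; half calls and `./.` become `NA`. The INFO keys `FEUR`,
#' `FAFR`, `DP` and `CM` populate the marker metadata columns `f_eur`,
#' `f_afr`, `depth` and `cM` when present (these are the keys
#' [writeGenotypes()] emits).
#'
#' @param path VCF file (plain or bgzipped).
#' @return An `AdmixtureExperiment` with assay `dosage`.
#' @export
readGenotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (anyDuplicated(colnames(vcf)))
    stop("duplicate sample ids in VCF")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt) != 1L))
    stop("multiallelic records are not supported; split them first")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  lookup <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
              "1|0" = 1, "1/1" = 2, "1|1" = 2)
  dos <- matrix(as.integer(lookup[gt]), nrow = nrow(gt),
                dimnames = dimnames(gt))

  info <- VariantAnnotation::info(vcf)
  geti <- function(key) if (key %in% names(info))
    suppressWarnings(as.numeric(info[[key]])) else NULL
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(rr),
    IRanges::IRanges(GenomicRanges::start(rr), width = 1),
    id = names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)))
  keymap <- c(f_eur = "FEUR", f_afr = "FAFR", depth = "DP", cM = "CM")
  for (nm in names(keymap)) {
    v <- geti(keymap[[nm]])
    if (!is.null(v)) S4Vectors::mcols(gr)[[nm]] <- v
  }
  AdmixtureExperiment(markers = gr, dosage = dos)
}

#' Write genotypes to a plain-text VCF file
#'
#' Emits a minimal VCFv4.2 file with a GT-only FORMAT and the marker
#' metadata (`f_eur`, `f_afr`, `depth`, `cM`) as INFO keys `FEUR`, `FAFR`,
#' `DP`, `CM`, so that [readGenotypes()] round-trips the full
#' `AdmixtureExperiment` marker state. Dosage 0/1/2 is written as unphased
#' `0/0`, `0/1`, `1/1`; `NA` as `./.`.
#'
#' @param x an `AdmixtureExperiment` with a `dosage` assay.
#' @param path output file path (plain text).
#' @param seed,config optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path, seed = NA, config = NULL) {
  dos <- dosage(x)
  gr <- markerInfo(x)
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  fmt <- function(v, digits = 6) ifelse(is.na(v), ".",
                                        formatC(v, digits = digits,
                                                format = "g"))
  infos <- character(n)
  keymap <- c(FEUR = "f_eur", FAFR = "f_afr", DP = "depth", CM = "cM")
  for (tag in names(keymap)) {
    col <- keymap[[tag]]
    if (col %in% names(mc)) {
      piece <- paste0(tag, "=", fmt(mc[[col]]))
      infos <- ifelse(nzchar(infos), paste(infos, piece, sep = ";"), piece)
    }
  }
  infos[!nzchar(infos)] <- "."
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gtcode[dos[ok] + 1L]

  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  hdr <- c("##fileformat=VCFv4.2",
           sub("^# ", "##source=", .provenanceHeader(seed, config)[1]),
           sprintf("##admixscan_seed=%s", seed),
           sprintf("##contig=<ID=%s>", chroms),
           "##INFO=<ID=FEUR,Number=1,Type=Float,Description=\"Alt allele frequency, European reference\">",
           "##INFO=<ID=FAFR,Number=1,Type=Float,Description=\"Alt allele frequency, African reference\">",
           "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean sequencing depth\">",
           "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position, cM\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  ref <- if ("ref" %in% names(mc)) mc$ref else "A"
  alt <- if ("alt" %in% names(mc)) mc$alt else "G"
  body <- paste(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), mc$id, ref, alt, ".", "PASS",
                infos, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write: ", path))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
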