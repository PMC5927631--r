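## Plain-text table readers/writers for the pipeline's file dialects.
## Coordinates are 0-based half-open throughout.

#' Read a mutation table (TSV)
#'
#' Expected columns: patient, sample, chrom, pos, ref, alt, alt_reads,
#' total_reads, trinucleotide (mutation_id optional; synthesised from
#' chrom:pos if absent).
#' @param path file path.
#' @return data.frame in the package's long mutation-table format.
#' @export
read_mutation_table <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  need <- c("patient", "sample", "chrom", "pos", "alt_reads", "total_reads")
  if (!all(need %in% names(m)))
    stopf("mutation table missing column(s): %s",
          paste(setdiff(need, names(m)), collapse = ", "))
  if (any(m$alt_reads > m$total_reads))
    stopf("alt_reads exceeds total_reads")
  if (!"mutation_id" %in% names(m))
    m$mutation_id <- paste0(m$chrom, ":", m$pos)
  m
}

#' Read an allele-specific copy-number segment table (TSV)
#' @param path file path (columns patient, sample, chrom, start, end,
#'   major_cn, minor_cn, purity).
#' @return validated data.frame.
#' @export
read_cn_segments <- function(path) {
  cn <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  need <- c("sample", "chrom", "start", "end", "major_cn", "minor_cn",
            "purity")
  if (!all(need %in% names(cn)))
    stopf("segment table missing column(s): %s",
          paste(setdiff(need, names(cn)), collapse = ", "))
  if (any(cn$purity <= 0 | cn$purity > 1)) stopf("purity must lie in (0, 1]")
  if (any(cn$major_cn < cn$minor_cn)) stopf("major_cn must be >= minor_cn")
  cn
}

#' Read an incidence cohort (CSV with columns group, age, censored)
#' @param path file path.
#' @return data.frame usable by [run_gibbs()].
#' @export
read_incidence <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "age", "censored") %in% names(d)))
  d$censored <- as.logical(d$censored)
  d
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mutation read counts from a VCF with FORMAT/AD
#'
#' Maps the per-sample allelic depths (AD) of biallelic SNVs to
#' alt/total read counts in the package's long mutation-table format.
#' Requires the VariantAnnotation package.
#'
#' @param path VCF path (plain or bgzipped).
#' @param patient patient id recorded in the output.
#' @return mutation table data.frame.
#' @export
read_vcf_mutations <- function(path, patient = "P1") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stopf("VCF ingestion requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stopf("VCF has no FORMAT/AD field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  out <- list()
  for (s in colnames(ad)) {
    counts <- ad[, s]
    ref_n <- vapply(counts, function(x) as.numeric(x[1]), numeric(1))
    alt_n <- vapply(counts, function(x) as.numeric(x[2]), numeric(1))
    out[[s]] <- data.frame(
      patient = patient, sample = s,
      mutation_id = names(rr),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1L,
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a[[1]]), ""),
      alt_reads = alt_n, total_reads = ref_n + alt_n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
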