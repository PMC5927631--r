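## Per-cell per-year rate of driver mutations in a tumor-suppressor CDS.
##
## The genome-wide substitution rate is split across the 96 pyrimidine-
## centred (mutation type x trinucleotide context) classes in proportion to
## the cohort mutation spectrum, normalised per available context site.
## Every possible single-base substitution in the coding sequence is then
## enumerated and annotated with its amino-acid consequence; the per-site
## class rates of those classified as drivers are summed. Driver indels are
## handled through the cohort-level linear association between indel and
## substitution counts.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
         function(b) paste(rev(b), collapse = ""), "")
}

## "ACA" + alt "G" -> "A[C>G]A", collapapsed to the pyrimidine strand
pyr_class <- function(context, alt) {
  mid <- substr(context, 2L, 2L)
  flip <- mid %in% c("A", "G")
  context[flip] <- revcomp(context[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  sprintf("%s[%s>%s]%s", substr(context, 1L, 1L), substr(context, 2L, 2L),
          alt, substr(context, 3L, 3L))
}

#' All 96 substitution class labels (pyrimidine-centred)
#' @return character vector like "A[C>A]A".
#' @export
substitution_classes <- function() {
  out <- character()
  for (ref in c("C", "T")) for (alt in setdiff(DNA_BASES, ref))
    for (l in DNA_BASES) for (r in DNA_BASES)
      out <- c(out, sprintf("%s[%s>%s]%s", l, ref, alt, r))
  sort(out)
}

#' Per-site per-year rates for the 96 substitution classes
#'
#' `rate(class) = total_rate * spectrum_fraction(class) / sites(context)`,
#' so that summing `rate x sites` over classes recovers the genome-wide
#' rate exactly.
#'
#' @param spectrum named counts (or fractions) for the 96 classes, names as
#'   in [substitution_classes()].
#' @param genome_context_counts named numeric: number of genome sites per
#'   pyrimidine-centred trinucleotide context (32 contexts).
#' @param total_rate genome-wide substitution rate (mutations/year/cell).
#' @return named numeric vector of per-site per-year rates per class.
#' @export
spectrum_context_rates <- function(spectrum, genome_context_counts,
                                   total_rate) {
  assert_positive(total_rate, "total_rate")
  if (any(spectrum < 0)) stopf("spectrum counts must be non-negative")
  if (sum(spectrum) == 0) stopf("spectrum is all zero")
  ctx <- paste0(substr(names(spectrum), 1L, 1L),
                substr(names(spectrum), 3L, 3L),
                substr(names(spectrum), 7L, 7L))
  sites <- genome_context_counts[ctx]
  active <- spectrum > 0
  if (any(active & (is.na(sites) | sites <= 0)))
    stopf("context counts missing for observed class(es): %s",
          paste(names(spectrum)[active & (is.na(sites) | sites <= 0)][1:3],
                collapse = ", "))
  frac <- spectrum / sum(spectrum)
  rate <- total_rate * frac / as.numeric(sites)
  rate[is.na(rate)] <- 0
  setNames(rate, names(spectrum))
}

#' Enumerate and annotate every single-base substitution in a CDS
#'
#' @param cds coding sequence (character string or `DNAString`), must start
#'   with ATG, end with a stop codon, have length divisible by 3 and no
#'   internal stop codon.
#' @return data.frame with 3L rows: pos (1-based), ref, alt, codon,
#'   codon_pos, ref_aa, alt_aa, consequence (one of start_lost, stop_lost,
#'   stop_gained, synonymous, missense) and class (pyrimidine-centred
#'   substitution class; NA at the terminal bases where no flanking base
#'   exists within the CDS).
#' @export
enumerate_cds_substitutions <- function(cds) {
  cds <- toupper(as.character(cds))
  L <- nchar(cds)
  if (L %% 3 != 0) stopf("CDS length must be divisible by 3")
  bases <- strsplit(cds, "")[[1]]
  if (!all(bases %in% DNA_BASES)) stopf("CDS contains non-ACGT characters")
  codons <- substring(cds, seq(1, L, 3), seq(3, L, 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  if (codons[1] != "ATG") stopf("CDS must start with ATG")
  if (aa[length(aa)] != "*") stopf("CDS must end with a stop codon")
  if (any(aa[-length(aa)] == "*")) stopf("internal stop codon in CDS")

  pos <- rep(seq_len(L), each = 3L)
  ref <- bases[pos]
  alt <- unlist(lapply(bases, function(b) setdiff(DNA_BASES, b)),
                use.names = FALSE)
  codon_idx <- (pos - 1L) %/% 3L + 1L
  codon_pos <- (pos - 1L) %% 3L + 1L
  alt_codon <- codons[codon_idx]
  substr_vec <- function(s, at, rep_) {
    substr(s, at, at) <- rep_
    s
  }
  alt_codon <- mapply(substr_vec, alt_codon, codon_pos, alt,
                      USE.NAMES = FALSE)
  ref_aa <- aa[codon_idx]
  alt_aa <- unname(gc[alt_codon])
  n_codons <- length(codons)
  consequence <- ifelse(codon_idx == 1L, "start_lost",
    ifelse(ref_aa == "*" & alt_aa != "*", "stop_lost",
    ifelse(ref_aa != "*" & alt_aa == "*", "stop_gained",
    ifelse(ref_aa == alt_aa, "synonymous", "missense"))))
  context <- ifelse(pos > 1L & pos < L,
                    paste0(bases[pmax(pos - 1L, 1L)], ref,
                           bases[pmin(pos + 1L, L)]),
                    NA_character_)
  cls <- rep(NA_character_, length(pos))
  ok <- !is.na(context)
  cls[ok] <- pyr_class(context[ok], alt[ok])
  data.frame(pos = pos, ref = ref, alt = alt, codon = codon_idx,
             codon_pos = codon_pos, ref_aa = ref_aa, alt_aa = alt_aa,
             consequence = consequence, class = cls,
             stringsAsFactors = FALSE)
}

#' Define the set of driver consequences
#'
#' @param start_lost,stop_lost,stop_gained logical flags.
#' @param aa_subs data.frame of admissible amino-acid substitutions with
#'   columns `position` (codon) and `alt_residue` (one-letter code), e.g.
#'   previously observed hotspot missense changes; NULL for none.
#' @param indels_are_drivers treat all in-CDS indels as drivers.
#' @return a `driver_set` list.
#' @export
driver_consequence_set <- function(start_lost = TRUE, stop_lost = TRUE,
                                   stop_gained = TRUE, aa_subs = NULL,
                                   indels_are_drivers = TRUE) {
  if (!is.null(aa_subs))
    stopifnot(all(c("position", "alt_residue") %in% names(aa_subs)))
  structure(list(start_lost = start_lost, stop_lost = stop_lost,
                 stop_gained = stop_gained, aa_subs = aa_subs,
                 indels_are_drivers = indels_are_drivers),
            class = "driver_set")
}

is_driver_substitution <- function(subs, drivers) {
  hit <- rep(FALSE, nrow(subs))
  if (drivers$start_lost) hit <- hit | subs$consequence == "start_lost"
  if (drivers$stop_lost) hit <- hit | subs$consequence == "stop_lost"
  if (drivers$stop_gained) hit <- hit | subs$consequence == "stop_gained"
  if (!is.null(drivers$aa_subs) && nrow(drivers$aa_subs) > 0) {
    key <- paste(subs$codon, subs$alt_aa)
    dk <- paste(drivers$aa_subs$position, drivers$aa_subs$alt_residue)
    hit <- hit | (subs$consequence == "missense" & key %in% dk)
  }
  hit
}

#' Driver substitution rate per cell per year
#'
#' Sums the per-site class rates over all enumerated substitutions
#' classified as drivers.
#'
#' @param subs output of [enumerate_cds_substitutions()].
#' @param drivers a [driver_consequence_set()].
#' @param class_rates named per-site class rates from
#'   [spectrum_context_rates()], or a single number applied uniformly.
#' @return driver substitution rate (/cell/year).
#' @export
driver_substitution_rate <- function(subs, drivers, class_rates) {
  hit <- is_driver_substitution(subs, drivers)
  if (!any(hit)) return(0)
  d <- subs[hit, , drop = FALSE]
  if (length(class_rates) == 1L && is.null(names(class_rates)))
    return(sum(rep(class_rates, nrow(d))))
  r <- class_rates[d$class]
  if (anyNA(r))
    stopf("no class rate for driver substitution class(es): %s",
          paste(unique(d$class[is.na(r)])[1:3], collapse = ", "))
  sum(r)
}

#' Driver indel rate per cell per year
#'
#' Fits the zero-intercept least-squares slope of per-patient indel counts
#' on substitution counts, converts the genome-wide substitution rate to an
#' indel rate per year, and scales by the fraction of the callable genome
#' occupied by the CDS (all in-CDS indels are treated as drivers).
#'
#' @param sub_counts,indel_counts per-patient genome-wide counts.
#' @param substitution_rate cohort substitution rate (mutations/year).
#' @param cds_length CDS length in bp.
#' @param G callable diploid genome size in bp.
#' @return driver indel rate (/cell/year).
#' @export
indel_driver_rate <- function(sub_counts, indel_counts, substitution_rate,
                              cds_length, G = 5.32e9) {
  if (length(sub_counts) != length(indel_counts) || length(sub_counts) < 2L)
    stopf("need matched counts for >= 2 patients")
  if (any(sub_counts < 0) || any(indel_counts < 0))
    stopf("counts must be non-negative")
  if (all(sub_counts == 0)) stopf("all substitution counts are zero")
  slope <- sum(indel_counts * sub_counts) / sum(sub_counts^2)
  slope * substitution_rate * cds_length / G
}

#' Combine driver substitution and indel rates
#' @param sub_rate,indel_rate component rates (/cell/year).
#' @return a `vhl_rates` list with `substitution_rate`, `indel_rate`,
#'   `total`.
#' @export
total_vhl_rate <- function(sub_rate, indel_rate) {
  if (sub_rate < 0 || indel_rate < 0) stopf("rates must be non-negative")
  structure(list(substitution_rate = sub_rate, indel_rate = indel_rate,
                 total = sub_rate + indel_rate),
            class = "vhl_rates")
}

#' @export
print.vhl_rates <- function(x, ...) {
  cat(sprintf(
    "VHL driver rate: %.2g /cell/year (substitutions %.2g + indels %.2g)\n",
    x$total, x$substitution_rate, x$indel_rate))
  invisible(x)
}
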