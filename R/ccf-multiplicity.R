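## VAF -> mutation copy number conversion and pre/post-duplication calls.
##
## A variant allele fraction is converted to the expected number of mutated
## chromosomal copies per cancer cell using the sample purity and the local
## allele-specific copy number. In a region carrying a clonal single-copy
## gain (total CN 3), clonal mutations acquired before the gain sit on two
## copies (copies estimate close to 2) while later mutations sit on one.

#' Mutation copies per cancer cell from a variant allele fraction
#'
#' Standard purity/ploidy-corrected estimator:
#' `vaf * (purity * tumor_cn + (1 - purity) * normal_cn) / purity`, which
#' equals multiplicity x CCF under the usual sampling model.
#'
#' @param vaf variant allele fraction(s) in [0, 1].
#' @param purity tumor cell fraction in (0, 1].
#' @param tumor_total_cn total tumor copy number at the locus (>= 1).
#' @param normal_cn copy number in contaminating normal cells (2 for
#'   autosomes).
#' @return numeric vector of copies per cancer cell. Values above the
#'   attainable maximum (`tumor_total_cn`) trigger a warning but are
#'   returned unmodified.
#' @export
mutation_copies <- function(vaf, purity, tumor_total_cn, normal_cn = 2) {
  if (any(purity <= 0)) stopf("purity must be positive")
  if (any(purity > 1)) stopf("purity must not exceed 1")
  if (any(vaf < 0 | vaf > 1)) stopf("vaf must lie in [0, 1]")
  if (any(tumor_total_cn < 1)) stopf("tumor_total_cn must be >= 1")
  copies <- vaf * (purity * tumor_total_cn + (1 - purity) * normal_cn) / purity
  if (any(copies > tumor_total_cn + 1e-9))
    warnf("%d value(s) exceed the attainable maximum copies (tumor CN)",
          sum(copies > tumor_total_cn + 1e-9))
  copies
}

#' Classify a mutation as pre- or post-duplication from its copies estimate
#'
#' Copies near 2 indicate acquisition before a single-copy gain; near 1,
#' after. Values between the boundaries are abstained on as "uncertain".
#'
#' @param copies numeric copies-per-cell estimates.
#' @param boundaries numeric `(low, high)` with `0 < low < high`; copies
#'   `>= high` are "pre", `<= low` are "post".
#' @return character vector of labels "pre"/"post"/"uncertain".
#' @export
classify_pre_post <- function(copies, boundaries = c(1.25, 1.75)) {
  if (length(boundaries) != 2L || boundaries[1] <= 0 ||
      boundaries[1] >= boundaries[2])
    stopf("boundaries must satisfy 0 < low < high")
  ifelse(copies >= boundaries[2], "pre",
         ifelse(copies <= boundaries[1], "post", "uncertain"))
}

#' Consensus timing vote across samples
#'
#' A strict majority among the non-uncertain per-sample labels wins; ties
#' and all-uncertain inputs yield "uncertain".
#'
#' @param labels character vector of per-sample labels
#'   ("pre"/"post"/"uncertain").
#' @return a single consensus label.
#' @export
consensus_vote <- function(labels) {
  if (length(labels) == 0L) stopf("consensus_vote needs at least one label")
  bad <- setdiff(unique(labels), c("pre", "post", "uncertain"))
  if (length(bad)) stopf("unknown labels: %s", paste(bad, collapse = ", "))
  n_pre <- sum(labels == "pre"); n_post <- sum(labels == "post")
  if (n_pre > n_post) "pre" else if (n_post > n_pre) "post" else "uncertain"
}

## locate the copy-number segment covering each (chrom, pos) for one sample;
## segments are 0-based half-open
match_segment <- function(chrom, pos, segments) {
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(segments))) {
    hit <- chrom == segments$chrom[i] & pos >= segments$start[i] &
      pos < segments$end[i]
    idx[hit] <- i
  }
  idx
}

#' Label mutations in a gained region as pre- or post-duplication
#'
#' For every mutation falling inside `region`, computes the per-sample
#' copies estimate from the read counts, purity and local copy number,
#' classifies per sample, and takes the cross-sample consensus. Only
#' samples in which the mutation has at least one alt read cast a vote:
#' a mutation absent from a sample carries no timing information for a
#' clonal gain.
#'
#' @param mutations mutation table (long format; columns patient, sample,
#'   mutation_id, chrom, pos, alt_reads, total_reads).
#' @param cn_segments copy-number segment table (columns sample, chrom,
#'   start, end, major_cn, minor_cn, purity), 0-based half-open.
#' @param region list with `chrom`, `start`, `end` delimiting the gained
#'   region (0-based half-open).
#' @param boundaries classification boundaries, see [classify_pre_post()].
#' @return data.frame with one row per mutation in the region: mutation_id,
#'   mean copies across voting samples, per-sample vote counts and the
#'   consensus `label`.
#' @export
label_gain_mutations <- function(mutations, cn_segments, region,
                                 boundaries = c(1.25, 1.75)) {
  stopifnot(all(c("sample", "mutation_id", "chrom", "pos", "alt_reads",
                  "total_reads") %in% names(mutations)))
  in_region <- mutations$chrom == region$chrom &
    mutations$pos >= region$start & mutations$pos < region$end
  m <- mutations[in_region, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(mutation_id = character(), copies = numeric(),
                      n_pre_votes = integer(), n_post_votes = integer(),
                      label = character(), stringsAsFactors = FALSE))
  m$copies <- NA_real_
  for (s in unique(m$sample)) {
    seg <- cn_segments[cn_segments$sample == s, , drop = FALSE]
    rows <- which(m$sample == s)
    si <- match_segment(m$chrom[rows], m$pos[rows], seg)
    if (anyNA(si)) stopf("mutation outside any copy-number segment in %s", s)
    vaf <- ifelse(m$total_reads[rows] > 0,
                  m$alt_reads[rows] / m$total_reads[rows], 0)
    m$copies[rows] <- mutation_copies(vaf, seg$purity[si][1],
                                      seg$major_cn[si] + seg$minor_cn[si])
  }
  m$label_sample <- classify_pre_post(m$copies, boundaries)
  ids <- unique(m$mutation_id)
  n_samples <- length(unique(m$sample))
  out <- data.frame(mutation_id = ids, copies = NA_real_,
                    min_copies = NA_real_,
                    n_pre_votes = 0L, n_post_votes = 0L,
                    n_present = 0L, n_samples = n_samples,
                    label = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- m[m$mutation_id == ids[i] & m$alt_reads >= 1, , drop = FALSE]
    out$n_present[i] <- nrow(rows)
    if (nrow(rows) == 0L) {
      out$label[i] <- "uncertain"
      next
    }
    out$copies[i] <- mean(rows$copies)
    out$min_copies[i] <- min(rows$copies)
    out$n_pre_votes[i] <- sum(rows$label_sample == "pre")
    out$n_post_votes[i] <- sum(rows$label_sample == "post")
    out$label[i] <- consensus_vote(rows$label_sample)
  }
  out
}
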