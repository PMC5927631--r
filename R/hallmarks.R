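## Quantitative chromothripsis hallmark checks.
##
## Chromothripsis shatters a chromosome in one catastrophe and rejoins the
## fragments in random order, so the four join orientation classes
## (deletion-type, tandem-duplication-type, head-to-head inverted,
## tail-to-tail inverted) appear in roughly equal numbers and the copy
## number track oscillates between two states. Stepwise rearrangement
## accumulation instead biases orientations and builds a staircase of
## copy-number states.

#' Goodness-of-fit of join orientations to the uniform 4-class multinomial
#'
#' @param cluster a `rearrangement_cluster` (or data.frame with an
#'   `orientation` column).
#' @param min_breakpoints power floor; fewer joins are reported as
#'   insufficient rather than tested.
#' @return list with `counts` (per orientation class), `statistic`
#'   (chi-square), `p_value`, and `sufficient`.
#' @export
orientation_uniformity <- function(cluster, min_breakpoints = 8L) {
  bp <- if (inherits(cluster, "rearrangement_cluster"))
    cluster$breakpoints else cluster
  classes <- c("deletion", "tandem-duplication", "head-to-head",
               "tail-to-tail")
  bad <- setdiff(unique(bp$orientation), classes)
  if (length(bad)) stopf("unknown orientation class: %s", bad[1])
  counts <- table(factor(bp$orientation, levels = classes))
  n <- sum(counts)
  if (n < min_breakpoints)
    return(list(counts = counts, statistic = NA_real_, p_value = NA_real_,
                sufficient = FALSE))
  expected <- n / 4
  stat <- sum((counts - expected)^2 / expected)
  list(counts = counts, statistic = stat,
       p_value = pchisq(stat, df = 3, lower.tail = FALSE),
       sufficient = TRUE)
}

#' Copy-number oscillation statistics
#'
#' Counts the distinct copy-number states in the track and the fraction of
#' adjacent transitions that alternate between the two modal states. A
#' constant track has one state and, by convention, fraction 0.
#'
#' @param cn_track ordered total copy number per segment (length >= 3).
#' @return list with `n_states` and `oscillation_fraction`.
#' @export
cn_oscillation <- function(cn_track) {
  if (length(cn_track) == 0L) stopf("empty copy-number track")
  if (length(cn_track) < 3L) stopf("track must have length >= 3")
  if (any(cn_track < 0)) stopf("copy numbers must be >= 0")
  states <- sort(unique(cn_track))
  if (length(states) == 1L)
    return(list(n_states = 1L, oscillation_fraction = 0))
  tab <- sort(table(cn_track), decreasing = TRUE)
  modal <- as.numeric(names(tab)[1:2])
  a <- cn_track[-length(cn_track)]
  b <- cn_track[-1]
  alternating <- (a %in% modal) & (b %in% modal) & a != b
  list(n_states = length(states),
       oscillation_fraction = mean(alternating))
}

#' Classify a rearrangement cluster against the chromothripsis hallmarks
#'
#' Positive verdict requires: enough joins, orientation counts compatible
#' with the uniform multinomial (p above threshold), and a copy-number
#' track dominated by two-state oscillation.
#'
#' @param cluster a `rearrangement_cluster`.
#' @param thresholds list with `p_orientation` (default 0.05),
#'   `oscillation` (default 0.7) and `min_breakpoints` (default 8).
#' @return list with `verdict` ("chromothripsis-consistent" or "not") and
#'   `report` carrying all sub-statistics.
#' @export
hallmark_classify <- function(cluster,
                              thresholds = list(p_orientation = 0.05,
                                                oscillation = 0.7,
                                                min_breakpoints = 8L)) {
  ori <- orientation_uniformity(cluster,
                                min_breakpoints = thresholds$min_breakpoints)
  osc <- cn_oscillation(cluster$cn_track)
  positive <- isTRUE(ori$sufficient) &&
    !is.na(ori$p_value) && ori$p_value > thresholds$p_orientation &&
    osc$oscillation_fraction > thresholds$oscillation
  list(verdict = if (positive) "chromothripsis-consistent" else "not",
       report = list(orientation = ori, oscillation = osc,
                     thresholds = thresholds))
}
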