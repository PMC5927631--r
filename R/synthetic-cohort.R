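## Synthetic multi-region ccRCC cohort generator.
##
## All inputs consumed by the downstream modules can be generated here with
## known ground truth: multi-region mutation read-count tables under a clone
## tree carrying a timed single-copy arm gain, matched allele-specific copy
## number profiles, incidence cohorts drawn from the generative three-stage
## waiting-time model, and clustered rearrangement breakpoints.

PYRIMIDINE_CONTEXTS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, paste0(c("C", "T"), rep(b, each = 2L)),
                  function(x, y) paste0(x, y)))
}

#' Construct the ground truth for a synthetic multi-region tumor
#'
#' The defaults describe a typical sporadic ccRCC: a somatic substitution
#' rate of 87 mutations per year over a callable diploid genome of 5.32 Gb,
#' surgery at age 60, a single-copy 5q gain acquired at age 10 (childhood),
#' and a most recent common ancestor (MRCA) emerging at age 40.
#'
#' @param rate mutations per year accrued over the callable diploid genome.
#' @param age age at surgery in years.
#' @param t_dup age in years at which the arm gain occurred, or `NA` for a
#'   fully diploid tumor with no gain.
#' @param t_mrca age in years at which the MRCA emerged.
#' @param purity per-sample tumor purity, recycled across samples.
#' @param depth sequencing depth (reads) per sample, a single integer.
#' @param L length in bp of the gained region (one haplotype).
#' @param G callable diploid genome size in bp.
#' @param tree clone tree as a list with elements `parent` (integer vector,
#'   `NA` for the root), `ccf` (clones x samples matrix of cancer cell
#'   fractions) and `duration` (branch lengths in years). Defaults to a
#'   trunk with two terminal subclones over two samples.
#' @param patient patient identifier.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(rate = 87, age = 60, t_dup = 10, t_mrca = 40,
                            purity = 0.7, depth = 100L,
                            L = 1.33e8, G = 5.32e9,
                            tree = NULL, patient = "P1") {
  assert_positive(rate, "rate"); assert_positive(age, "age")
  assert_positive(G, "G"); assert_positive(L, "L")
  if (L > G) stopf("region length L exceeds callable genome G")
  if (any(depth <= 0)) stopf("depth must be positive")
  if (any(purity <= 0) || any(purity > 1)) stopf("purity must lie in (0, 1]")
  if (!is.na(t_dup)) {
    if (t_dup <= 0 || t_dup > t_mrca)
      stopf("need 0 < t_dup <= t_mrca")
  }
  if (t_mrca > age) stopf("t_mrca must not exceed age at surgery")
  if (is.null(tree)) {
    tree <- list(
      parent = c(NA_integer_, 1L, 1L),
      ccf = rbind(c(1, 1), c(0.6, 0.2), c(0.3, 0.7)),
      duration = c(t_mrca, age - t_mrca, age - t_mrca)
    )
  }
  validate_clone_tree(tree)
  n_samples <- ncol(tree$ccf)
  purity <- rep_len(purity, n_samples)
  out <- list(rate = rate, age = age, t_dup = t_dup, t_mrca = t_mrca,
              purity = purity, depth = as.integer(depth), L = L, G = G,
              tree = tree, patient = patient,
              samples = paste0(patient, "_R", seq_len(n_samples)))
  class(out) <- "synthetic_truth"
  out
}

validate_clone_tree <- function(tree, tol = 1e-8) {
  parent <- tree$parent
  ccf <- tree$ccf
  if (sum(is.na(parent)) != 1L) stopf("clone tree must have exactly one root")
  if (nrow(ccf) != length(parent)) stopf("ccf rows must match clones")
  if (any(ccf < 0) || any(ccf > 1 + tol)) stopf("clone CCFs must lie in [0, 1]")
  for (k in which(!is.na(parent))) {
    sibs <- which(!is.na(parent) & parent == parent[k])
    kid_sum <- colSums(ccf[sibs, , drop = FALSE])
    if (any(kid_sum > ccf[parent[k], ] + tol))
      stopf("pigeonhole violation: children of clone %d exceed parent CCF",
            parent[k])
  }
  invisible(tree)
}

## expected VAF under the standard purity/ploidy model
expected_vaf <- function(ccf, multiplicity, purity, tumor_cn, normal_cn = 2) {
  ccf * purity * multiplicity / (purity * tumor_cn + (1 - purity) * normal_cn)
}

random_context <- function(n) sample(PYRIMIDINE_CONTEXTS, n, replace = TRUE)

random_alt <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
}

#' Simulate a multi-region mutation table and copy-number profile
#'
#' Per-branch mutation counts are Poisson with mean rate x branch duration,
#' partitioned between the diploid background and the gained region in
#' proportion to callable haplotype-years (per-haplotype rate `rate / G` per
#' bp per year). Mutations acquired on the duplicated haplotype before the
#' gain carry multiplicity 2; all others multiplicity 1. Read counts are
#' Binomial at the expected VAF given purity, local copy number and
#' multiplicity.
#'
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed; identical seeds give identical tables.
#' @param exact_vaf if TRUE, report noise-free fractional alt read counts
#'   (`alt_reads = depth x expected VAF`), used to validate closed forms.
#' @return list with `mutations` (one row per mutation per sample),
#'   `cn_segments` (allele-specific segments with purity) and
#'   `mutation_truth` (per-mutation clone, multiplicity, timing class).
#' @export
simulate_mutation_table <- function(truth, seed = 1L, exact_vaf = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    tr <- truth$tree
    n_clones <- length(tr$parent)
    has_gain <- !is.na(truth$t_dup)
    L <- truth$L; G <- truth$G
    root <- which(is.na(tr$parent))
    rec <- list()
    for (k in seq_len(n_clones)) {
      dur <- tr$duration[k]
      if (k == root && has_gain) {
        gc <- simulate_gain_counts(truth$t_dup, truth$t_mrca, truth$rate,
                                   L, G, seed = NULL)
        n_bg <- rpois(1L, truth$rate * dur * (G - 2 * L) / G)
        rec[[length(rec) + 1L]] <- data.frame(
          clone = k, region = rep(c("background", "gain", "gain"),
                                  c(n_bg, gc$n_pre, gc$n_post_clonal)),
          multiplicity = rep(c(1L, 2L, 1L), c(n_bg, gc$n_pre, gc$n_post_clonal)))
      } else {
        ## per-haplotype rate is rate/G; the gained region carries 3 copies
        ## on every post-MRCA branch when a gain is present
        region_copies <- if (has_gain) 3 else 2
        mean_region <- truth$rate / G * region_copies * L * dur
        n_reg <- if (has_gain) rpois(1L, mean_region) else 0L
        n_bg <- rpois(1L, truth$rate * dur * (G - 2 * L * has_gain) / G)
        rec[[length(rec) + 1L]] <- data.frame(
          clone = k, region = rep(c("background", "gain"), c(n_bg, n_reg)),
          multiplicity = 1L)
      }
    }
    mt <- do.call(rbind, rec)
    n_mut <- nrow(mt)
    if (n_mut == 0L) stopf("no mutations simulated; increase rate or age")
    mt$id <- sprintf("%s_m%05d", truth$patient, seq_len(n_mut))
    mt$chrom <- ifelse(mt$region == "gain", "5", "1")
    region_start <- 1e6
    mt$pos <- ifelse(mt$region == "gain",
                     floor(runif(n_mut, region_start, region_start + L)),
                     floor(runif(n_mut, 1e6, 2e8)))
    ctx <- random_context(n_mut)
    mt$ref <- substr(ctx, 2L, 2L)
    mt$alt <- random_alt(mt$ref)
    mt$trinucleotide <- ctx
    mt$timing <- ifelse(mt$region == "gain" & mt$multiplicity == 2L, "pre",
                        ifelse(mt$region == "gain" & mt$clone == root, "post",
                               "other"))

    samples <- truth$samples
    rows <- vector("list", length(samples))
    for (s in seq_along(samples)) {
      ccf <- tr$ccf[mt$clone, s]
      tumor_cn <- ifelse(mt$region == "gain" & has_gain, 3, 2)
      p <- expected_vaf(ccf, mt$multiplicity, truth$purity[s], tumor_cn)
      alt <- if (exact_vaf) p * truth$depth
             else rbinom(n_mut, truth$depth, p)
      rows[[s]] <- data.frame(
        patient = truth$patient, sample = samples[s], mutation_id = mt$id,
        chrom = mt$chrom, pos = mt$pos, ref = mt$ref, alt = mt$alt,
        alt_reads = alt, total_reads = truth$depth,
        trinucleotide = mt$trinucleotide, stringsAsFactors = FALSE)
    }
    mutations <- do.call(rbind, rows)
    rownames(mutations) <- NULL

    segs <- vector("list", length(samples))
    for (s in seq_along(samples)) {
      seg <- data.frame(
        patient = truth$patient, sample = samples[s],
        chrom = c("1", "5", "5"),
        start = c(0, 0, region_start + L),
        end = c(2.5e8, region_start + L, 2e8 + region_start + L),
        major_cn = c(1L, if (has_gain) 2L else 1L, 1L),
        minor_cn = 1L,
        purity = truth$purity[s], stringsAsFactors = FALSE)
      if (has_gain) seg$start[2] <- region_start
      segs[[s]] <- seg
    }
    cn_segments <- do.call(rbind, segs)
    rownames(cn_segments) <- NULL

    list(mutations = mutations, cn_segments = cn_segments,
         mutation_truth = mt[, c("id", "clone", "region", "multiplicity",
                                 "timing", "chrom", "pos")])
  })
}

#' Simulate pre- and post-duplication clonal mutation counts in a gained region
#'
#' Forward model for timing a clonal single-copy gain: before the gain the
#' later-duplicated haplotype accrues mutations at `rate * L / G` per year
#' (these end up on two of the three copies); single-copy clonal mutations
#' come from the other pre-gain haplotype plus all three copies after the
#' gain.
#'
#' @param t_dup age of the gain in years.
#' @param t_mrca age of MRCA emergence in years.
#' @param rate mutations per year over the callable diploid genome.
#' @param L gained region length (bp); @param G callable diploid genome (bp).
#' @param seed integer seed or NULL to draw from the current stream.
#' @return list with integer `n_pre` and `n_post_clonal`.
#' @export
simulate_gain_counts <- function(t_dup, t_mrca, rate, L, G, seed = 1L) {
  if (t_dup <= 0 || t_dup > t_mrca) stopf("need 0 < t_dup <= t_mrca")
  assert_positive(c(rate, L, G), "rate/L/G")
  with_seed(seed, {
    per_hap_year <- rate * L / G
    n_pre <- rpois(1L, per_hap_year * t_dup)
    n_post <- rpois(1L, per_hap_year * t_dup +
                        3 * per_hap_year * (t_mrca - t_dup))
    list(n_pre = n_pre, n_post_clonal = n_post)
  })
}

#' Simulate an age-incidence cohort from the three-stage waiting-time model
#'
#' Sporadic ages are `Z1 + Z2 + Z3` with `Z1 ~ Gamma(z1_shape, z1_rate)`,
#' `Z2 ~ Exponential(nu * mu)` (the somatic VHL hit in a precursor clone of
#' `nu` cells mutating at `mu` per cell per year) and
#' `Z3 ~ Gamma(z3_shape, z3_rate)`; inherited ages are `Z1 + Z3`.
#' Individuals whose sum exceeds `censor_age` are administratively censored.
#'
#' @param nu number of 3p-loss precursor cells.
#' @param mu VHL driver mutation rate per cell per year.
#' @param z1_shape,z1_rate gamma parameters of the time to 3p loss.
#' @param z3_shape,z3_rate gamma parameters of the time from biallelic VHL
#'   loss to diagnosis.
#' @param n_sporadic,n_inherited cohort sizes.
#' @param censor_age administrative censoring age in years.
#' @param seed integer seed.
#' @return data.frame with columns group ("sporadic"/"inherited"),
#'   age (event or censoring age) and censored (logical).
#' @export
simulate_incidence_cohort <- function(nu, mu,
                                      z1_shape = 2.5, z1_rate = 0.17,
                                      z3_shape = 4, z3_rate = 0.2,
                                      n_sporadic = 500L, n_inherited = 200L,
                                      censor_age = 85, seed = 1L) {
  assert_positive(c(nu, mu, z1_shape, z1_rate, z3_shape, z3_rate, censor_age),
                  "waiting-time parameters")
  with_seed(seed, {
    lambda <- nu * mu
    n <- n_sporadic + n_inherited
    group <- rep(c("sporadic", "inherited"), c(n_sporadic, n_inherited))
    z1 <- rgamma(n, z1_shape, z1_rate)
    z3 <- rgamma(n, z3_shape, z3_rate)
    z2 <- ifelse(group == "sporadic", rexp(n, lambda), 0)
    y <- z1 + z2 + z3
    censored <- y > censor_age
    data.frame(group = group,
               age = ifelse(censored, censor_age, y),
               censored = censored, stringsAsFactors = FALSE)
  })
}

#' Simulate a cluster of rearrangement breakpoints
#'
#' `kind = "chromothripsis"` emulates a single catastrophic event: clustered
#' breakpoints with the four join orientations drawn uniformly and a
#' two-state oscillating copy-number track. `kind = "sequential"` emulates
#' stepwise rearrangement accumulation: orientation-biased joins and a
#' staircase (non-oscillating) copy-number track.
#'
#' @param kind "chromothripsis" or "sequential".
#' @param n_breakpoints number of rearrangement joins (>= 4).
#' @param seed integer seed.
#' @return object of class `rearrangement_cluster` with `breakpoints`
#'   (chrom1, pos1, chrom2, pos2, orientation), `cn_track` and `kind`.
#' @export
simulate_breakpoint_cluster <- function(kind = c("chromothripsis", "sequential"),
                                        n_breakpoints = 20L, seed = 1L) {
  kind <- match.arg(kind)
  if (n_breakpoints < 4L) stopf("need at least 4 breakpoints")
  with_seed(seed, {
    n <- n_breakpoints
    classes <- c("deletion", "tandem-duplication", "head-to-head", "tail-to-tail")
    pos1 <- sort(floor(runif(n, 8e7, 8e7 + 5e7)))
    pos2 <- floor(runif(n, 1e8, 1.5e8))
    chrom1 <- rep("3", n)
    chrom2 <- sample(c("3", "5"), n, replace = TRUE)
    if (kind == "chromothripsis") {
      orientation <- sample(classes, n, replace = TRUE)
      cn <- rep_len(c(2L, 3L), n + 1L)
    } else {
      orientation <- sample(classes, n, replace = TRUE,
                            prob = c(0.85, 0.05, 0.05, 0.05))
      steps <- rep(seq_len(ceiling((n + 1L) / 2L)), each = 2L)[seq_len(n + 1L)]
      cn <- 1L + steps
    }
    out <- list(breakpoints = data.frame(chrom1 = chrom1, pos1 = pos1,
                                         chrom2 = chrom2, pos2 = pos2,
                                         orientation = orientation,
                                         stringsAsFactors = FALSE),
                cn_track = cn, kind = kind)
    class(out) <- "rearrangement_cluster"
    out
  })
}
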