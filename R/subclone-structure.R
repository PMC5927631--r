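## Dirichlet-process clustering of mutations by cancer cell fraction,
## pigeonhole ordering of clusters into a clone tree, and per-branch
## cumulative mutation burdens.
##
## The fraction of cancer cells carrying each mutation is modelled by a
## truncated stick-breaking Dirichlet-process mixture with Binomial
## read-count emission across samples, with an adjustment for the reduced
## sensitivity to call mutations at low tumor fractions: the prior mass of
## a cluster is down-weighted by the probability that a mutation at that
## CCF yields at least `min_alt_reads` alt reads at the observed depth.

#' Cluster mutations by cancer cell fraction across samples
#'
#' @param mutations long-format mutation table (columns sample, mutation_id,
#'   chrom, pos, alt_reads, total_reads).
#' @param cn_segments copy-number segments with per-sample purity.
#' @param max_clusters truncation level of the stick-breaking approximation.
#' @param iterations Gibbs sweeps.
#' @param seed integer seed; fixed seed gives identical assignments.
#' @param alpha Dirichlet-process concentration.
#' @param min_alt_reads calling threshold used in the sensitivity
#'   adjustment.
#' @param grid_step CCF grid resolution for the cluster-centre update.
#' @param merge_tol occupied clusters whose centres agree within this CCF
#'   distance in every sample are merged after the final sweep (truncated
#'   stick-breaking otherwise leaves near-duplicate components).
#' @return object of class `subclone_clusters`: `centers` (cluster x sample
#'   CCF matrix), `assignment` (named integer vector, maximum-posterior),
#'   `sizes`, `samples`, and `n_dropped` (zero-depth mutations removed).
#' @export
fit_subclone_clusters <- function(mutations, cn_segments,
                                  max_clusters = 10L, iterations = 300L,
                                  seed = 1L, alpha = 0.05,
                                  min_alt_reads = 3L, grid_step = 0.01,
                                  merge_tol = 0.1) {
  samples <- sort(unique(mutations$sample))
  ids <- unique(mutations$mutation_id)
  if (length(ids) < 2L) stopf("need at least 2 mutations to cluster")
  n <- length(ids); S <- length(samples)
  alt <- depth <- cc <- matrix(NA_real_, n, S,
                               dimnames = list(ids, samples))
  for (s in seq_along(samples)) {
    ms <- mutations[mutations$sample == samples[s], , drop = FALSE]
    j <- match(ms$mutation_id, ids)
    alt[j, s] <- ms$alt_reads
    depth[j, s] <- ms$total_reads
    seg <- cn_segments[cn_segments$sample == samples[s], , drop = FALSE]
    if (nrow(seg) == 0L) stopf("no copy-number segments for sample %s",
                               samples[s])
    si <- match_segment(ms$chrom, ms$pos, seg)
    if (anyNA(si)) stopf("mutation outside any segment in %s", samples[s])
    pur <- seg$purity[1]
    cnt <- seg$major_cn[si] + seg$minor_cn[si]
    ## per-unit-CCF expected VAF assuming multiplicity 1
    cc[j, s] <- pur / (pur * cnt + (1 - pur) * 2)
  }
  if (anyNA(alt)) stopf("samples do not share the mutation set")
  zero <- rowSums(depth) == 0
  n_dropped <- sum(zero)
  if (n_dropped > 0) {
    message(sprintf("dropping %d zero-depth mutation(s)", n_dropped))
    alt <- alt[!zero, , drop = FALSE]; depth <- depth[!zero, , drop = FALSE]
    cc <- cc[!zero, , drop = FALSE]; ids <- ids[!zero]; n <- length(ids)
  }

  K <- max_clusters
  grid <- seq(0, 1, by = grid_step)
  loglik_mut_cluster <- function(centers) {
    ## n x K matrix of summed Binomial log-likelihoods
    ll <- matrix(0, n, K)
    for (s in seq_len(S)) {
      p <- pmin(pmax(outer(cc[, s], centers[, s]), 1e-9), 1 - 1e-9)
      ll <- ll + dbinom(alt[, s], depth[, s], p, log = TRUE)
    }
    ll
  }
  detect_prob <- function(centers) {
    ## P(called in >= 1 sample) for a mutation at each cluster's CCF,
    ## evaluated at the median per-sample depth and VAF scaling
    pr_miss <- matrix(1, n, K)
    for (s in seq_len(S)) {
      p <- pmin(pmax(outer(cc[, s], centers[, s]), 1e-9), 1 - 1e-9)
      pr_miss <- pr_miss * pbinom(min_alt_reads - 1L, depth[, s], p)
    }
    pmax(1 - pr_miss, 1e-12)
  }

  with_seed(seed, {
    ## initialise centres from quantiles of the naive per-mutation CCF
    ccf_hat <- rowMeans(pmin(alt / pmax(depth, 1) / cc, 1.2))
    init_q <- quantile(ccf_hat, probs = seq(0.05, 0.95, length.out = K))
    centers <- matrix(pmin(pmax(rep(init_q, S), 0), 1), K, S)
    w <- rep(1 / K, K)
    z <- integer(n)
    for (it in seq_len(iterations)) {
      ll <- loglik_mut_cluster(centers)
      lw <- sweep(ll + log(detect_prob(centers)), 2, log(w), "+")
      lw <- lw - apply(lw, 1, max)
      pr <- exp(lw); pr <- pr / rowSums(pr)
      z <- apply(pr, 1, function(p) sample.int(K, 1L, prob = p))
      nk <- tabulate(z, K)
      ## stick-breaking weights: v_k ~ Beta(1 + n_k, alpha + n_{k+1..K})
      v <- rbeta(K, 1 + nk, alpha + c(rev(cumsum(rev(nk)))[-1], 0))
      v[K] <- 1
      w <- v * cumprod(c(1, 1 - v[-K]))
      w <- pmax(w, 1e-12); w <- w / sum(w)
      ## grid Gibbs update of each occupied cluster centre, per sample
      for (k in which(nk > 0)) {
        rows <- which(z == k)
        for (s in seq_len(S)) {
          p <- pmin(pmax(outer(cc[rows, s], grid), 1e-9), 1 - 1e-9)
          lg <- colSums(matrix(dbinom(alt[rows, s], depth[rows, s], p,
                                      log = TRUE), nrow = length(rows)))
          lg <- lg - max(lg)
          centers[k, s] <- grid[sample.int(length(grid), 1L,
                                           prob = exp(lg))]
        }
      }
      ## empty clusters: resample centres from the prior (uniform CCF)
      for (k in which(nk == 0)) centers[k, ] <- runif(S)
    }
    ## maximum-posterior hard assignment at the final state
    ll <- loglik_mut_cluster(centers)
    lw <- sweep(ll + log(detect_prob(centers)), 2, log(w), "+")
    z <- apply(lw, 1, which.max)
    ## merge occupied clusters indistinguishable at the CCF resolution of
    ## the data (within merge_tol in every sample); truncated
    ## stick-breaking otherwise leaves near-duplicate components
    repeat {
      occ <- sort(unique(z))
      if (length(occ) < 2L) break
      merged <- FALSE
      for (i in seq_along(occ)[-1]) {
        for (j in seq_len(i - 1L)) {
          a <- occ[i]; b <- occ[j]
          if (all(abs(centers[a, ] - centers[b, ]) < merge_tol)) {
            na <- sum(z == a); nb <- sum(z == b)
            centers[b, ] <- (na * centers[a, ] + nb * centers[b, ]) /
              (na + nb)
            z[z == a] <- b
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    keep <- sort(unique(z))
    ## relabel occupied clusters by decreasing total CCF
    ord <- keep[order(-rowSums(centers[keep, , drop = FALSE]))]
    relabel <- match(z, ord)
    centers <- centers[ord, , drop = FALSE]
    rownames(centers) <- paste0("C", seq_along(ord))
    colnames(centers) <- samples
    out <- list(centers = centers,
                assignment = setNames(relabel, ids),
                sizes = tabulate(relabel, length(ord)),
                samples = samples, n_dropped = n_dropped)
    class(out) <- "subclone_clusters"
    out
  })
}

#' Order subclone clusters into a clone tree by the pigeonhole principle
#'
#' Cluster A may parent cluster B only if A's CCF is at least B's in every
#' sample (within tolerance), and siblings must have CCFs summing to no
#' more than their parent's in every sample. Among admissible parents the
#' one with the largest CCF is chosen: clusters attach as shallowly as
#' possible and are nested deeper only when the sibling-sum constraint
#' forces it.
#'
#' @param clusters a `subclone_clusters` object.
#' @param tolerance CCF slack for the comparisons.
#' @return object of class `clone_tree`: `parent` (integer vector, NA at
#'   the root), `centers`, `sizes`.
#' @export
order_clusters_pigeonhole <- function(clusters, tolerance = 0.05) {
  centers <- clusters$centers
  K <- nrow(centers)
  root <- which.max(rowSums(centers))
  if (any(centers[root, ] < 1 - 2 * tolerance))
    stopf("no clonal root cluster: cluster %d has CCF %s", root,
          paste(round(centers[root, ], 2), collapse = ", "))
  parent <- rep(NA_integer_, K)
  placed <- root
  for (b in setdiff(order(-rowSums(centers)), root)) {
    valid <- character()
    best <- NA_integer_; best_ccf <- -Inf
    for (a in placed) {
      if (any(centers[a, ] < centers[b, ] - tolerance)) {
        valid <- c(valid, sprintf("C%d cannot parent C%d (CCF order)", a, b))
        next
      }
      sibs <- which(!is.na(parent) & parent == a)
      kid_sum <- colSums(centers[c(sibs, b), , drop = FALSE])
      if (any(kid_sum > centers[a, ] + tolerance)) {
        valid <- c(valid, sprintf("C%d + siblings exceed C%d (pigeonhole)",
                                  b, a))
        next
      }
      if (sum(centers[a, ]) > best_ccf) {
        best <- a; best_ccf <- sum(centers[a, ])
      }
    }
    if (is.na(best))
      stopf("no valid clone tree; violated constraints:\n  %s",
            paste(valid, collapse = "\n  "))
    parent[b] <- best
    placed <- c(placed, b)
  }
  out <- list(parent = parent, centers = centers, sizes = clusters$sizes)
  class(out) <- "clone_tree"
  out
}

#' Cumulative mutation burden along each root-to-leaf branch
#'
#' @param tree a `clone_tree`.
#' @param clusters the `subclone_clusters` the tree was built from.
#' @param ages named numeric vector mapping patient id to age at surgery.
#' @param patient patient id for these clusters.
#' @return data.frame with columns patient, branch (terminal cluster),
#'   burden (mutations from root to leaf) and age.
#' @export
branch_burdens <- function(tree, clusters, ages, patient = "P1") {
  if (!patient %in% names(ages)) stopf("no age for patient %s", patient)
  K <- length(tree$parent)
  leaves <- setdiff(seq_len(K), tree$parent[!is.na(tree$parent)])
  burden <- vapply(leaves, function(k) {
    total <- 0
    while (!is.na(k)) {
      total <- total + clusters$sizes[k]
      k <- tree$parent[k]
    }
    total
  }, numeric(1))
  data.frame(patient = patient, branch = paste0("C", leaves),
             burden = burden, age = unname(ages[patient]),
             stringsAsFactors = FALSE)
}
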