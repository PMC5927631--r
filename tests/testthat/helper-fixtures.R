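# Shared fixtures: every dataset is generated in code under a fixed seed.

# two-sample tumor with a clonal (CCF 1.0) and a subclonal (CCF 0.4) clone,
# no arm gain, subsampled to ~n mutations
make_two_cluster_sim <- function(n = 200L, depth = 100L, seed = 5L) {
  tree <- list(parent = c(NA, 1L), ccf = rbind(c(1, 1), c(0.4, 0.4)),
               duration = c(30, 30))
  tr <- synthetic_truth(rate = 87, age = 60, t_dup = NA, t_mrca = 30,
                        purity = 1, depth = depth, tree = tree)
  sim <- simulate_mutation_table(tr, seed = seed)
  ids <- unique(sim$mutations$mutation_id)
  keep <- ids[round(seq(1, length(ids), length.out = n))]
  sim$mutations <- sim$mutations[sim$mutations$mutation_id %in% keep, ]
  sim
}

# default gained-region truth used in the timing tests
make_gain_sim <- function(seed = 2L, depth = 200L, purity = 0.8) {
  tr <- synthetic_truth(rate = 87, age = 60, t_dup = 10, t_mrca = 40,
                        purity = purity, depth = depth)
  list(truth = tr, sim = simulate_mutation_table(tr, seed = seed))
}

gain_region <- function(truth) {
  list(chrom = "5", start = 1e6, end = 1e6 + truth$L)
}

# cohort of patients with known per-patient slopes for the rate model
make_rate_cohort <- function(n_patients = 33L, beta = 87, sigma_u = 17,
                             seed = 11L, noise = "poisson") {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_patients), function(i) {
      age <- runif(1, 40, 75)
      slope <- max(rnorm(1, beta, sigma_u), 5)
      burden <- switch(noise,
        poisson = rpois(2L, slope * age),
        none = rep(slope * age, 2L))
      data.frame(patient = sprintf("K%03d", i),
                 branch = c("C2", "C3"), burden = burden, age = age)
    })
    do.call(rbind, rows)
  })
}

# manual subclone_clusters object for tree-building tests
manual_clusters <- function(ccf_matrix, sizes) {
  structure(list(centers = ccf_matrix,
                 assignment = setNames(
                   rep(seq_len(nrow(ccf_matrix)), sizes),
                   paste0("m", seq_len(sum(sizes)))),
                 sizes = sizes,
                 samples = colnames(ccf_matrix) %||%
                   paste0("S", seq_len(ncol(ccf_matrix))),
                 n_dropped = 0L),
            class = "subclone_clusters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
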