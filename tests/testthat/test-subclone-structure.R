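test_that("DP clustering recovers planted clusters and is deterministic", {
  sim <- make_two_cluster_sim(n = 200L, depth = 100L, seed = 5)
  cl <- fit_subclone_clusters(sim$mutations, sim$cn_segments,
                              iterations = 200L, seed = 1)
  expect_identical(nrow(cl$centers), 2L)
  truth <- rbind(c(1, 1), c(0.4, 0.4))
  expect_true(all(abs(cl$centers - truth) < 0.05))
  # conservation: sizes account for every assigned mutation
  expect_identical(sum(cl$sizes), length(cl$assignment))

  cl2 <- fit_subclone_clusters(sim$mutations, sim$cn_segments,
                               iterations = 200L, seed = 1)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("a single clonal cluster is recovered near CCF 1", {
  tree <- list(parent = NA_integer_, ccf = matrix(1, 1, 2), duration = 40)
  tr <- synthetic_truth(rate = 87, age = 40, t_dup = NA, t_mrca = 40,
                        purity = 0.9, depth = 150L, tree = tree)
  sim <- simulate_mutation_table(tr, seed = 13)
  ids <- unique(sim$mutations$mutation_id)[1:150]
  muts <- sim$mutations[sim$mutations$mutation_id %in% ids, ]
  cl <- fit_subclone_clusters(muts, sim$cn_segments,
                              iterations = 200L, seed = 4)
  expect_identical(nrow(cl$centers), 1L)
  expect_true(all(abs(cl$centers - 1) < 0.03))
})

test_that("pigeonhole ordering nests or branches clusters correctly", {
  # 0.6 + 0.5 > 1.0: siblings excluded, linear chain forced
  chain <- manual_clusters(matrix(c(1, 0.6, 0.5), 3, 1), c(100, 50, 40))
  t1 <- order_clusters_pigeonhole(chain)
  expect_identical(t1$parent, c(NA_integer_, 1L, 2L))

  # 0.4 + 0.3 <= 1.0: both admissible as children of the root
  branch <- manual_clusters(matrix(c(1, 0.4, 0.3), 3, 1), c(100, 40, 30))
  t2 <- order_clusters_pigeonhole(branch)
  expect_identical(t2$parent, c(NA_integer_, 1L, 1L))

  # a second sample separating the subclones forces branching
  sep <- manual_clusters(rbind(c(1, 1), c(0.6, 0.05), c(0.3, 0.9)),
                         c(100, 50, 40))
  t3 <- order_clusters_pigeonhole(sep)
  expect_identical(t3$parent[2:3], c(1L, 1L))

  solo <- manual_clusters(matrix(1, 1, 1), 400L)
  expect_identical(order_clusters_pigeonhole(solo)$parent, NA_integer_)

  no_root <- manual_clusters(matrix(c(0.7, 0.4), 2, 1), c(10, 10))
  expect_error(order_clusters_pigeonhole(no_root), "root")

  impossible <- manual_clusters(rbind(c(1, 1), c(0.9, 0.2), c(0.2, 0.9),
                                      c(0.6, 0.6)),
                                c(100, 30, 30, 30))
  expect_error(order_clusters_pigeonhole(impossible), "constraints")
})

test_that("branch burdens are root-to-leaf path sums", {
  cl <- manual_clusters(matrix(c(1, 0.4, 0.3), 3, 1), c(500, 250, 250))
  tree <- order_clusters_pigeonhole(cl)
  bb <- branch_burdens(tree, cl, ages = c(P1 = 60))
  expect_identical(sort(bb$burden), c(750, 750))
  expect_error(branch_burdens(tree, cl, ages = c(P9 = 60)), "age")

  solo <- manual_clusters(matrix(1, 1, 1), 400L)
  bb1 <- branch_burdens(order_clusters_pigeonhole(solo), solo,
                        ages = c(P1 = 50))
  expect_identical(bb1$burden, 400)
})

test_that("phylogeny-aware burdens place the MRCA at 50% molecular time", {
  # a tumor whose two subclones diverged at half of molecular time: trunk
  # n mutations, each lineage another n. Lineage-resolved burdens put the
  # MRCA at n / 2n = 50%; the naive clonal-vs-subclonal ratio says 33%.
  n <- 600
  cl <- manual_clusters(matrix(c(1, 0.5, 0.5), 3, 1), c(n, n, n))
  # branching allowed (0.5 + 0.5 <= 1)
  tree <- order_clusters_pigeonhole(cl)
  bb <- branch_burdens(tree, cl, ages = c(P1 = 60))
  rate <- 87
  mrca_frac <- mrca_age(n, rate) / (bb$burden[1] / rate)
  expect_equal(mrca_frac, 0.5)
  naive_frac <- n / sum(cl$sizes)
  expect_equal(naive_frac, 1 / 3, tolerance = 1e-12)
})

test_that("tree ordering is invariant to cluster relabelling", {
  perm_tree <- function(ord) {
    cl <- manual_clusters(matrix(c(1, 0.6, 0.5)[ord], 3, 1),
                          c(100L, 50L, 40L)[ord])
    tr <- order_clusters_pigeonhole(cl)
    # canonical form: each cluster's CCF paired with its parent's CCF
    data.frame(ccf = tr$centers[, 1],
               parent_ccf = ifelse(is.na(tr$parent), NA,
                                   tr$centers[tr$parent, 1]))
  }
  base <- perm_tree(1:3)
  for (ord in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    got <- perm_tree(ord)
    expect_identical(got[order(got$ccf), ], base[order(base$ccf), ],
                     ignore_attr = TRUE)
  }
})
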