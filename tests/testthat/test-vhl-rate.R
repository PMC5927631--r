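# independent enumeration oracle: brute-force every substitution through
# the codon table, no shared code with the package implementation
oracle_consequences <- function(cds) {
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- strsplit(cds, "")[[1]]
  out <- character()
  for (i in seq_along(bases)) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[i])) {
      mut <- bases; mut[i] <- alt
      codon_i <- (i - 1) %/% 3 + 1
      ref_cod <- paste(bases[(codon_i - 1) * 3 + 1:3], collapse = "")
      alt_cod <- paste(mut[(codon_i - 1) * 3 + 1:3], collapse = "")
      ra <- gc_tab[[ref_cod]]; aa <- gc_tab[[alt_cod]]
      out <- c(out, if (codon_i == 1) "start_lost"
               else if (ra == "*" && aa != "*") "stop_lost"
               else if (ra != "*" && aa == "*") "stop_gained"
               else if (ra == aa) "synonymous" else "missense")
    }
  }
  table(factor(out, levels = c("start_lost", "stop_lost", "stop_gained",
                               "synonymous", "missense")))
}

random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    gc_tab <- Biostrings::GENETIC_CODE
    coding <- names(gc_tab)[gc_tab != "*"]
    repeat {
      mid <- sample(coding, n_codons, replace = TRUE)
      cds <- paste(c("ATG", mid, "TGA"), collapse = "")
      if (!is.na(cds)) return(cds)
    }
  })
}

test_that("spectrum-context rates conserve the genome-wide rate", {
  classes <- substitution_classes()
  ctx <- unique(paste0(substr(classes, 1, 1), substr(classes, 3, 3),
                       substr(classes, 7, 7)))
  spectrum <- withr::with_seed(41, setNames(rpois(96, 20), classes))
  sites <- withr::with_seed(42,
    setNames(round(runif(length(ctx), 1e6, 1e8)), ctx))
  rates <- spectrum_context_rates(spectrum, sites, total_rate = 87)
  got_ctx <- paste0(substr(names(rates), 1, 1), substr(names(rates), 3, 3),
                    substr(names(rates), 7, 7))
  expect_equal(sum(rates * sites[got_ctx]), 87, tolerance = 1e-9)

  # single active class: per-site rate R/N
  one <- setNames(numeric(96), classes); one["A[C>A]A"] <- 5
  r1 <- spectrum_context_rates(one, setNames(1e6, "ACA"), total_rate = 87)
  expect_equal(unname(r1["A[C>A]A"]), 87 / 1e6)

  # class observed without genome sites is an error
  expect_error(spectrum_context_rates(one, setNames(1e6, "TCT"), 87),
               "missing")
})

test_that("CDS enumeration is complete and matches the codon-table oracle", {
  s <- enumerate_cds_substitutions("ATGTGGTGA")
  expect_identical(nrow(s), 27L)
  counts <- table(factor(s$consequence,
                         levels = c("start_lost", "stop_lost", "stop_gained",
                                    "synonymous", "missense")))
  expect_identical(as.integer(counts),
                   as.integer(oracle_consequences("ATGTGGTGA")))
  expect_identical(unname(counts["stop_gained"]), 2L)
  expect_identical(unname(counts["start_lost"]), 9L)

  for (seed in 1:5) {
    cds <- random_cds(n_codons = 10 + seed, seed = seed)
    got <- enumerate_cds_substitutions(cds)
    expect_identical(nrow(got), 3L * nchar(cds))
    expect_identical(
      as.integer(table(factor(got$consequence,
        levels = c("start_lost", "stop_lost", "stop_gained", "synonymous",
                   "missense")))),
      as.integer(oracle_consequences(cds)))
  }

  expect_error(enumerate_cds_substitutions("ATGTG"), "divisible")
  expect_error(enumerate_cds_substitutions("CTGTGGTGA"), "ATG")
  expect_error(enumerate_cds_substitutions("ATGTGGAAA"), "stop codon")
  expect_error(enumerate_cds_substitutions("ATGTGACCCTGA"), "internal stop")
})

test_that("driver substitution rate sums the right class rates", {
  subs <- enumerate_cds_substitutions("ATGTGGTGA")
  none <- driver_consequence_set(FALSE, FALSE, FALSE)
  expect_equal(driver_substitution_rate(subs, none, 1e-7), 0)

  sg_only <- driver_consequence_set(FALSE, FALSE, TRUE)
  expect_equal(driver_substitution_rate(subs, sg_only, 1e-7), 2e-7)

  # monotone non-decreasing as the driver set grows
  r0 <- driver_substitution_rate(subs, sg_only, 1e-7)
  r1 <- driver_substitution_rate(
    subs, driver_consequence_set(TRUE, FALSE, TRUE), 1e-7)
  r2 <- driver_substitution_rate(
    subs, driver_consequence_set(TRUE, TRUE, TRUE), 1e-7)
  expect_true(r0 <= r1 && r1 <= r2)

  # hotspot missense set: codon 2 tryptophan -> specific residues
  hs <- driver_consequence_set(FALSE, FALSE, FALSE,
    aa_subs = data.frame(position = 2, alt_residue = c("C", "R")))
  n_hits <- sum(subs$consequence == "missense" & subs$codon == 2 &
                  subs$alt_aa %in% c("C", "R"))
  expect_equal(driver_substitution_rate(subs, hs, 1e-7), n_hits * 1e-7)
  expect_gt(n_hits, 0)
})

test_that("indel driver rate uses the zero-intercept slope", {
  subs <- c(4000, 8000, 12000)
  expect_equal(indel_driver_rate(subs, 0.15 * subs, 87, 642, 5.32e9),
               0.15 * 87 * 642 / 5.32e9)
  expect_equal(indel_driver_rate(c(5000, 9000), c(0, 0), 87, 642, 5.32e9),
               0)
  expect_error(indel_driver_rate(c(0, 0), c(1, 2), 87, 642), "zero")
  # worked example: s = 0.155, 87/yr, CDS 642 bp
  expect_equal(indel_driver_rate(c(1000, 2000), 0.155 * c(1000, 2000),
                                 87, 642, 5.32e9),
               87 * 0.155 * 642 / 5.32e9)
})

test_that("component rates combine to the published-style total", {
  v <- total_vhl_rate(8.5e-7, 1.2e-6)
  expect_equal(v$total, 2.05e-6)
  # half-away-from-zero rounding to 2 significant figures gives 2.1e-6
  signif_half_up <- function(x, sig) {
    m <- 10^(sig - 1 - floor(log10(abs(x))))
    floor(x * m + 0.5 + 1e-9) / m
  }
  expect_equal(signif_half_up(v$total, 2), 2.1e-6)
  expect_equal(total_vhl_rate(1.2e-6, 8.5e-7)$total, v$total)
  expect_equal(total_vhl_rate(0, 0)$total, 0)
})
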