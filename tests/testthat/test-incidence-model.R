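make_state <- function(cohort, mu = 2.1e-6, alpha1 = 1, beta1 = 0.1,
                       alpha3 = 1, beta3 = 0.1, lambda = 0.01) {
  st <- init_sampler_state(cohort, mu)
  st$alpha1 <- alpha1; st$beta1 <- beta1
  st$alpha3 <- alpha3; st$beta3 <- beta3
  st$lambda <- lambda
  st
}

test_that("lambda update is the exact conjugate draw", {
  # z2 = (5, 10, 15): posterior Gamma(3.01, 30.01), mean 0.10033...
  draws <- withr::with_seed(1, {
    replicate(20000, lambda_update(c(5, 10, 15)))
  })
  expect_equal(mean(draws), 3.01 / 30.01, tolerance = 0.02)
  expect_equal(var(draws), 3.01 / 30.01^2, tolerance = 0.05)

  # no sporadic data: the prior is returned unchanged
  d0 <- withr::with_seed(2, replicate(20000, lambda_update(numeric(0))))
  expect_equal(mean(d0), 1, tolerance = 0.1)

  expect_identical(lambda_update(c(5, 10), seed = 3),
                   lambda_update(c(5, 10), seed = 3))
})

test_that("split kernel preserves the latent sum exactly", {
  coh <- data.frame(group = c("inherited", "sporadic"),
                    age = c(40, 55), censored = FALSE)
  st <- make_state(coh, alpha1 = 2, beta1 = 0.2, alpha3 = 3, beta3 = 0.3,
                   lambda = 0.02)
  withr::with_seed(5, {
    for (i in 1:200) {
      st <- dirichlet_split_update(st, 1, kappa = 10)
      st <- dirichlet_split_update(st, 2, kappa = 10)
      expect_equal(st$z1[1] + st$z3[1], 40, tolerance = 1e-9)
      expect_equal(st$z1[2] + st$z2[2] + st$z3[2], 55, tolerance = 1e-9)
    }
  })
  expect_error(dirichlet_split_update(st, 1, kappa = -1), "kappa")
})

test_that("split kernel targets the uniform split in the exponential case", {
  # alpha = beta equal for both stages: the conditional of z1 given
  # z1 + z3 = y is uniform on (0, y); grid/closed-form oracle
  coh <- data.frame(group = "inherited", age = 1, censored = FALSE)
  st <- make_state(coh, alpha1 = 1, beta1 = 1, alpha3 = 1, beta3 = 1)
  zs <- withr::with_seed(6, {
    out <- numeric(20000)
    for (i in seq_along(out)) {
      st <- dirichlet_split_update(st, 1, kappa = 3)
      out[i] <- st$z1[1]
    }
    out
  })
  keep <- zs[seq(5001, 20000, by = 10)]
  expect_equal(mean(keep), 0.5, tolerance = 0.04)
  ks <- suppressWarnings(ks.test(keep, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("censored rejection matches the truncated-sum distribution", {
  coh <- data.frame(group = "inherited", age = 30, censored = TRUE)
  st <- make_state(coh, alpha1 = 1, beta1 = 1 / 12, alpha3 = 1,
                   beta3 = 1 / 18)
  sums <- withr::with_seed(7, {
    vapply(1:4000, function(i) {
      s <- censored_rejection_update(st, 1)
      s$z1[1] + s$z3[1]
    }, numeric(1))
  })
  expect_true(all(sums > 30))

  # inverse-CDF oracle: hypoexponential (rates b1 != b3) truncated at c
  b1 <- 1 / 12; b3 <- 1 / 18; cc <- 30
  Fx <- function(x) 1 - (b3 * exp(-b1 * x) - b1 * exp(-b3 * x)) / (b3 - b1)
  Fc <- Fx(cc)
  oracle <- withr::with_seed(8, {
    u <- runif(4000)
    vapply(u, function(ui) {
      target <- Fc + ui * (1 - Fc)
      uniroot(function(x) Fx(x) - target, c(cc, 2000))$root
    }, numeric(1))
  })
  ks <- suppressWarnings(ks.test(sums, oracle))
  expect_gt(ks$p.value, 0.001)

  # the exact-conditional fallback targets the same distribution
  exact <- withr::with_seed(77, {
    vapply(1:4000, function(i) {
      s <- censored_rejection_update(st, 1, fallback_after = 0L)
      s$z1[1] + s$z3[1]
    }, numeric(1))
  })
  ks2 <- suppressWarnings(ks.test(exact, oracle))
  expect_gt(ks2$p.value, 0.001)

  # censoring age ~0: the first draw is always accepted
  coh0 <- data.frame(group = "sporadic", age = 1e-9, censored = TRUE)
  st0 <- make_state(coh0)
  s0 <- censored_rejection_update(st0, 1, seed = 9)
  expect_gt(s0$z1[1] + s0$z2[1] + s0$z3[1], 0)

  # pathological parameters hit the attempt cap with a clear error
  st_bad <- make_state(coh, alpha1 = 100, beta1 = 100, alpha3 = 100,
                       beta3 = 100)
  expect_error(
    withr::with_seed(10, censored_rejection_update(st_bad, 1,
                                                   max_attempts = 50)),
    "attempts")
})

test_that("shape-rate kernel matches a 2-D grid-integration oracle", {
  z <- withr::with_seed(11, rgamma(6, 2, 0.1))
  pri <- waiting_time_priors(numeric(0)) # uninformative p=q=r=s=1
  # grid oracle for the posterior mean of beta
  alphas <- seq(0.05, 12, length.out = 240)
  betas <- seq(0.001, 1.2, length.out = 240)
  lp <- outer(alphas, betas, function(a, b)
    (a - 1) * sum(log(z)) - b * (1 + sum(z)) -
      (1 + length(z)) * lgamma(a) + a * (1 + length(z)) * log(b))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle_beta <- sum(w * rep(betas, each = length(alphas)))
  oracle_alpha <- sum(w * rep(alphas, times = length(betas)))

  coh <- data.frame(group = "inherited", age = 40, censored = FALSE)
  st <- make_state(coh, alpha1 = 2, beta1 = 0.1)
  st$z1 <- z # hold the latent data fixed; update only (alpha1, beta1)
  chain <- withr::with_seed(12, {
    out <- matrix(NA_real_, 30000, 2)
    for (i in seq_len(nrow(out))) {
      st <- shape_rate_update(st, 1, pri, gamma_scale = 30)
      out[i, ] <- c(st$alpha1, st$beta1)
    }
    out
  })
  keep <- chain[seq(5001, 30000, by = 5), ]
  expect_equal(mean(keep[, 2]), oracle_beta, tolerance = 0.05)
  expect_equal(mean(keep[, 1]), oracle_alpha, tolerance = 0.05)
})

test_that("shape-rate kernel concentrates on the truth and degenerates", {
  z <- withr::with_seed(13, rgamma(20000, 2, 0.1))
  pri <- waiting_time_priors(numeric(0))
  coh <- data.frame(group = "inherited", age = 40, censored = FALSE)
  st <- make_state(coh, alpha1 = 1.5, beta1 = 0.05)
  st$z1 <- z
  chain <- withr::with_seed(14, {
    out <- matrix(NA_real_, 4000, 2)
    for (i in seq_len(nrow(out))) {
      st <- shape_rate_update(st, 1, pri, gamma_scale = 3000)
      out[i, ] <- c(st$alpha1, st$beta1)
    }
    out
  })
  keep <- chain[2001:4000, ]
  expect_equal(mean(keep[, 1]), 2, tolerance = 0.05)
  expect_equal(mean(keep[, 2]), 0.1, tolerance = 0.05)

  # vanishing proposal step: acceptance rate -> 1
  st2 <- make_state(coh, alpha1 = 2, beta1 = 0.1)
  st2$z1 <- z[1:50]
  acc <- withr::with_seed(15, {
    vapply(1:100, function(i) {
      st2 <<- shape_rate_update(st2, 1, pri, gamma_scale = 1e9)
      st2$last_accepted
    }, logical(1))
  })
  expect_gte(mean(acc), 0.99)
})

test_that("informative 3p prior stays finite in log space", {
  pri <- waiting_time_priors(rep(100, 50))
  expect_true(is.finite(pri$comp1$log_p))
  expect_equal(pri$comp1$log_p, 50 * log(100))
  expect_identical(pri$comp1$r, 50L)
})

test_that("full sampler marginal for lambda matches a brute-force oracle", {
  # a cohort with only uncensored events leaves the lambda posterior
  # heavy-tailed (lambda -> Inf degenerates to the inherited model, which
  # event ages alone cannot rule out), so the well-posed check includes
  # censored individuals, as every realistic sporadic cohort does
  a1 <- 2; b1 <- 0.2; a3 <- 3; b3 <- 0.3
  ys <- c(30, 45, 60); ncen <- 30L; cage <- 85
  coh <- data.frame(group = "sporadic", age = c(ys, rep(cage, ncen)),
                    censored = rep(c(FALSE, TRUE), c(length(ys), ncen)))

  # brute-force oracle: marginalise Z1 + Z3 by simulation at large n, then
  # integrate the lambda posterior on a log grid
  oracle_mean <- withr::with_seed(1, {
    z1 <- rgamma(4e5, a1, b1); z3 <- rgamma(4e5, a3, b3); s <- z1 + z3
    py <- function(lam, y) mean(ifelse(s < y, lam * exp(-lam * (y - s)), 0))
    pcen <- function(lam) mean(ifelse(s >= cage, 1,
                                      exp(-lam * (cage - s))))
    lgrid <- exp(seq(log(1e-5), log(5), length.out = 500))
    lpost <- vapply(lgrid, function(l)
      dgamma(l, 0.01, 0.01, log = TRUE) +
        sum(log(vapply(ys, function(y) py(l, y), numeric(1)))) +
        ncen * log(pcen(l)), numeric(1))
    w <- exp(lpost - max(lpost)) * lgrid # log-spaced grid measure
    w <- w / sum(w)
    sum(w * lgrid)
  })

  cfg <- sampler_config(iterations = 20000, burnin = 4000, thin = 4,
                        seed = 16, update_shapes = FALSE, kappa = 10)
  dr <- run_gibbs(coh, waiting_time_priors(numeric(0)), mu = 2.1e-6, cfg,
                  init_shapes = c(a1, b1, a3, b3))
  expect_equal(unique(dr$alpha1), a1) # shapes really were held fixed
  expect_equal(mean(dr$lambda), oracle_mean, tolerance = 0.05)
})

test_that("run_gibbs is seeded, and inherited-only cohorts leave lambda at its prior", {
  coh <- simulate_incidence_cohort(300, 2.1e-6, n_sporadic = 30L,
                                   n_inherited = 30L, seed = 18)
  pri <- waiting_time_priors(withr::with_seed(18, rgamma(10, 2.5, 0.17)))
  cfg <- sampler_config(iterations = 400, burnin = 100, thin = 2, seed = 3)
  d1 <- run_gibbs(coh, pri, 2.1e-6, cfg)
  d2 <- run_gibbs(coh, pri, 2.1e-6, cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(nrow(d1), length(seq(102, 400, by = 2)))

  inh <- coh[coh$group == "inherited", ]
  cfg2 <- sampler_config(iterations = 3000, burnin = 500, thin = 1,
                         seed = 4)
  d3 <- run_gibbs(inh, pri, 2.1e-6, cfg2)
  # prior Gamma(0.01, 0.01) draws: compare on the probability scale
  ks <- suppressWarnings(ks.test(d3$lambda, function(q)
    pgamma(q, 0.01, 0.01)))
  expect_gt(ks$p.value, 0.001)
})

test_that("cohorts can be drawn from incidence tables and survival curves", {
  tb <- data.frame(age_lo = seq(0, 80, 5), age_hi = seq(5, 85, 5),
                   rate = 0)
  c0 <- sample_cohort_from_curves(incidence_table = tb, n = 50, seed = 5)
  expect_true(all(c0$censored))
  expect_true(all(c0$age == 85))

  tb$rate <- c(rep(0, 8), seq(5, 45, 5))
  c1 <- sample_cohort_from_curves(incidence_table = tb, n = 2000, seed = 6)
  expect_identical(c1, sample_cohort_from_curves(incidence_table = tb,
                                                 n = 2000, seed = 6))
  expect_true(any(!c1$censored))
  expect_true(all(c1$age[!c1$censored] >= 40))

  sc <- data.frame(age = seq(10, 60, 10),
                   surv = c(1, 0.8, 0.5, 0.2, 0.05, 0))
  c2 <- sample_cohort_from_curves(survival_curve = sc, n = 500, seed = 7)
  expect_true(all(!c2$censored)) # survival reaches 0: everyone has an event
  expect_true(all(c2$age <= 60))

  bad <- data.frame(age = c(10, 20), surv = c(0.5, 0.9))
  expect_error(sample_cohort_from_curves(survival_curve = bad, n = 10),
               "non-increasing")
  expect_error(sample_cohort_from_curves(n = 10), "exactly one")
})

test_that("interventions scale the VHL-hit waiting time and incidence", {
  coh <- simulate_incidence_cohort(300, 2.1e-6, n_sporadic = 150L,
                                   n_inherited = 80L, seed = 20)
  pri <- waiting_time_priors(withr::with_seed(20, rgamma(10, 2.5, 0.17)))
  cfg <- sampler_config(iterations = 1500, burnin = 500, thin = 5,
                        seed = 21)
  dr <- run_gibbs(coh, pri, 2.1e-6, cfg)

  full <- intervention_curves(dr, rho = 1, seed = 22)
  half <- intervention_curves(dr, rho = 0.5, seed = 22)
  quarter <- intervention_curves(dr, rho = 0.25, seed = 22)
  expect_equal(mean(half$z2_mean) / mean(full$z2_mean), 2,
               tolerance = 0.05)
  expect_true(all(half$curves$mean <= full$curves$mean + 1e-12))
  expect_true(all(quarter$curves$mean <= half$curves$mean + 1e-12))
  expect_error(intervention_curves(dr, rho = 0), "rho")
  expect_error(intervention_curves(dr, rho = 1.5), "rho")
})
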