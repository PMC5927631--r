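## Bayesian three-stage waiting-time model of ccRCC age incidence.
##
## The age of incidence of sporadic disease is Y = Z1 + Z2 + Z3 and of
## inherited (VHL-carrier) disease Y = Z1 + Z3, with
##   Z1 ~ Gamma(alpha1, beta1)   time to 3p loss
##   Z2 ~ Exponential(lambda)    time to the somatic VHL hit, lambda = nu*mu
##   Z3 ~ Gamma(alpha3, beta3)   time from biallelic VHL loss to diagnosis.
## Censored individuals contribute only a lower bound on the sum, handled
## by data augmentation. The sampler cycles: Metropolis-Hastings Dirichlet
## split proposals for the latent waiting times of uncensored individuals;
## rejection sampling for censored individuals; Metropolis-Hastings with
## independent gamma proposals for the two (shape, rate) pairs under their
## conjugate priors; and an exact conjugate gamma draw for lambda. The
## quantity of interest is nu = lambda / mu, the number of 3p-loss cells
## capable of initiating a tumor.

#' Priors for the waiting-time model
#'
#' The (alpha, beta) pairs take the conjugate prior
#' `f(alpha, beta) propto p^(alpha-1) exp(-beta q) Gamma(alpha)^(-r)
#' beta^(alpha s)`. For the time to 3p loss the prior is informative,
#' distilled from molecular-timing estimates of the ages at which 3p was
#' lost: `p1 = prod(x)`, `q1 = sum(x)`, `r1 = s1 = n` (held in log space so
#' the product never overflows). The diagnosis-stage prior is
#' uninformative (p = q = r = s = 1), as is the lambda prior
#' Gamma(0.01, 0.01).
#'
#' @param ages_3p estimated ages of chromosome 3p loss (years).
#' @param lambda_shape,lambda_rate gamma prior for lambda.
#' @return a `wt_priors` list with components `comp1`, `comp3` (each
#'   log_p, q, r, s) and `lambda` (shape, rate).
#' @export
waiting_time_priors <- function(ages_3p, lambda_shape = 0.01,
                                lambda_rate = 0.01) {
  assert_positive(c(lambda_shape, lambda_rate), "lambda prior")
  if (length(ages_3p) > 0) assert_positive(ages_3p, "ages_3p")
  n <- length(ages_3p)
  comp1 <- if (n > 0)
    list(log_p = sum(log(ages_3p)), q = sum(ages_3p), r = n, s = n)
  else list(log_p = 0, q = 1, r = 1, s = 1)
  structure(list(comp1 = comp1,
                 comp3 = list(log_p = 0, q = 1, r = 1, s = 1),
                 lambda = c(shape = lambda_shape, rate = lambda_rate)),
            class = "wt_priors")
}

## log conjugate-prior/posterior density for a gamma (shape, rate) pair
log_shape_rate_density <- function(alpha, beta, log_p, q, r, s) {
  if (alpha <= 0 || beta <= 0) return(-Inf)
  (alpha - 1) * log_p - beta * q - r * lgamma(alpha) + alpha * s * log(beta)
}

#' Sampler configuration
#' @param iterations total Gibbs iterations.
#' @param burnin iterations discarded as burn-in.
#' @param kappa Dirichlet-proposal concentration for the latent splits.
#' @param gamma_scale gamma-proposal scale for the (shape, rate) updates
#'   (proposal mean = current value, variance = current / gamma_scale).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed.
#' @param max_attempts cap on rejection-sampling attempts per censored
#'   individual per sweep.
#' @param update_shapes set FALSE to hold (alpha, beta) pairs fixed (used
#'   for oracle checks of the lambda marginal).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(iterations = 50000L, burnin = 10000L,
                           kappa = 10, gamma_scale = 1000, thin = 10L,
                           seed = 1L, max_attempts = 1e5,
                           update_shapes = TRUE) {
  if (burnin >= iterations) stopf("burnin must be smaller than iterations")
  assert_positive(c(kappa, gamma_scale, thin), "kappa/gamma_scale/thin")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), kappa = kappa,
                 gamma_scale = gamma_scale, thin = as.integer(thin),
                 seed = seed, max_attempts = max_attempts,
                 update_shapes = update_shapes),
            class = "sampler_config")
}

#' Initialise the sampler state from an incidence cohort
#'
#' Uncensored individuals have their observed age split evenly across the
#' relevant waiting times; censored individuals start 20% above their
#' censoring age so the latent-sum constraint holds from the first sweep.
#' Shape/rate pairs start at method-of-moments values from the initial
#' latent times.
#'
#' @param cohort data.frame with columns group, age, censored (see
#'   [simulate_incidence_cohort()]).
#' @param mu VHL driver mutation rate per cell per year.
#' @return a `sampler_state` list.
#' @export
init_sampler_state <- function(cohort, mu) {
  stopifnot(all(c("group", "age", "censored") %in% names(cohort)))
  if (nrow(cohort) == 0L) stopf("empty cohort")
  if (!all(cohort$group %in% c("sporadic", "inherited")))
    stopf("group must be sporadic or inherited")
  assert_positive(cohort$age, "ages")
  assert_positive(mu, "mu")
  spor <- cohort$group == "sporadic"
  d <- ifelse(spor, 3, 2)
  target <- ifelse(cohort$censored, cohort$age * 1.2, cohort$age)
  z1 <- target / d
  z3 <- target / d
  z2 <- ifelse(spor, target / d, NA_real_)
  mom <- function(z) {
    m <- mean(z); v <- var(z)
    if (!is.finite(v) || v <= 0) c(1, 1 / m) else c(m^2 / v, m / v)
  }
  p1 <- mom(z1); p3 <- mom(z3)
  lam <- if (any(spor)) 1 / mean(z2[spor]) else 1
  structure(list(y = cohort$age, group = cohort$group,
                 censored = cohort$censored,
                 z1 = z1, z2 = z2, z3 = z3,
                 alpha1 = p1[1], beta1 = p1[2],
                 alpha3 = p3[1], beta3 = p3[2],
                 lambda = lam, mu = mu, iter = 0L),
            class = "sampler_state")
}

## --- latent-split kernel (vectorised over individuals) -------------------

## one MH Dirichlet-split sweep for a set of uncensored individuals;
## returns updated z columns and the acceptance indicator
split_step <- function(y, z, alphas, betas, lambda, kappa) {
  n <- nrow(z); d <- ncol(z)
  a_cur <- kappa * z / rowSums(z)
  g <- matrix(rgamma(n * d, shape = a_cur, rate = 1), n, d)
  ok <- rowSums(g) > 0 & apply(g > 0, 1, all)
  w <- g / rowSums(g)
  zs <- y * w
  a_new <- kappa * w

  ## target log ratio: gamma terms for components with a shape parameter,
  ## exponential term (shape 1, rate lambda) for the middle of a 3-split
  lr <- (alphas[1] - 1) * log(zs[, 1] / z[, 1]) -
    betas[1] * (zs[, 1] - z[, 1]) +
    (alphas[2] - 1) * log(zs[, d] / z[, d]) -
    betas[2] * (zs[, d] - z[, d])
  if (d == 3L) lr <- lr - lambda * (zs[, 2] - z[, 2])

  ## Hastings correction f(z_old | z*) / f(z* | z_old); the scale Jacobians
  ## cancel in the ratio
  x_cur <- z / y
  lq_fwd <- rowSums((a_cur - 1) * log(w)) - rowSums(lgamma(a_cur)) +
    lgamma(rowSums(a_cur))
  lq_rev <- rowSums((a_new - 1) * log(x_cur)) - rowSums(lgamma(a_new)) +
    lgamma(rowSums(a_new))
  lr <- lr + lq_rev - lq_fwd
  lr[!ok] <- -Inf
  if (any(is.nan(lr)))
    stopf("NaN in split-kernel log density (alpha1=%g beta1=%g)",
          alphas[1], betas[1])
  acc <- log(runif(n)) < lr
  z[acc, ] <- zs[acc, , drop = FALSE]
  list(z = z, accepted = acc)
}

#' Metropolis-Hastings Dirichlet split update for uncensored individuals
#'
#' Proposes new latent waiting times as the observed age times a Dirichlet
#' draw concentrated at the current split (`kappa` controls the spread),
#' preserving the latent sum exactly, and accepts with the product of the
#' gamma/exponential density ratios and the Hastings correction for the
#' asymmetric proposal.
#'
#' @param state a `sampler_state`.
#' @param individual index of an uncensored individual.
#' @param kappa Dirichlet concentration.
#' @param seed optional integer seed.
#' @return updated state; `state$last_accepted` records the MH decision.
#' @export
dirichlet_split_update <- function(state, individual, kappa = 10,
                                   seed = NULL) {
  if (state$censored[individual]) stopf("individual %d is censored",
                                        individual)
  assert_positive(kappa, "kappa")
  with_seed(seed, {
    i <- individual
    if (state$group[i] == "sporadic") {
      st <- split_step(state$y[i],
                       cbind(state$z1[i], state$z2[i], state$z3[i]),
                       c(state$alpha1, state$alpha3),
                       c(state$beta1, state$beta3), state$lambda, kappa)
      state$z1[i] <- st$z[, 1]; state$z2[i] <- st$z[, 2]
      state$z3[i] <- st$z[, 3]
    } else {
      st <- split_step(state$y[i], cbind(state$z1[i], state$z3[i]),
                       c(state$alpha1, state$alpha3),
                       c(state$beta1, state$beta3), state$lambda, kappa)
      state$z1[i] <- st$z[, 1]; state$z3[i] <- st$z[, 2]
    }
    state$last_accepted <- st$accepted
    state
  })
}

## --- censored rejection kernel -------------------------------------------

## exact draw of (z1, z3) ~ f1 x f3 conditioned on z1 + z3 > c, by
## inverse-CDF sampling of the z1 marginal on a fine grid plus the exact
## truncated-gamma conditional for z3; used when plain rejection would
## stall because the current parameters place almost no mass past c
sample_gamma_pair_tail <- function(cc, a1, b1, a3, b3, ngrid = 512L) {
  p1_tail <- pgamma(cc, a1, b1, lower.tail = FALSE)
  grid <- seq(0, cc, length.out = ngrid + 1L)
  dens <- dgamma(grid, a1, b1) * pgamma(cc - grid, a3, b3,
                                        lower.tail = FALSE)
  wmid <- (dens[-1] + dens[-length(dens)]) / 2 * diff(grid)
  mass_in <- sum(wmid)
  total <- mass_in + p1_tail
  if (total <= 0 || runif(1L) < p1_tail / total) {
    z1 <- qgamma(runif(1L) * max(p1_tail, 1e-300), a1, b1,
                 lower.tail = FALSE)
    z3 <- rgamma(1L, a3, b3)
  } else {
    cdf <- cumsum(wmid)
    u <- runif(1L) * mass_in
    cell <- findInterval(u, cdf) + 1L
    z1 <- runif(1L, grid[cell], grid[cell + 1L])
    p3_tail <- pgamma(cc - z1, a3, b3, lower.tail = FALSE)
    z3 <- qgamma(runif(1L) * max(p3_tail, 1e-300), a3, b3,
                 lower.tail = FALSE)
  }
  c(z1, z3)
}

## redraw latent times from their priors until the sum exceeds the
## censoring age, vectorised over individuals. Inherited individuals whose
## acceptance probability is so small that `fallback_after` attempts all
## fail are drawn exactly from the conditional instead (same target
## distribution); sporadic individuals keep the exponential component,
## whose memorylessness keeps rejection efficient whenever lambda is small.
censored_step <- function(cens_age, sporadic, alphas, betas, lambda,
                          max_attempts, fallback_after = 2000L) {
  n <- length(cens_age)
  z1 <- z3 <- rep(NA_real_, n)
  z2 <- ifelse(sporadic, NA_real_, 0)
  todo <- seq_len(n)
  attempts <- 0L
  while (length(todo) > 0) {
    attempts <- attempts + 1L
    if (attempts > fallback_after && any(!sporadic[todo])) {
      for (i in todo[!sporadic[todo]]) {
        z <- sample_gamma_pair_tail(cens_age[i], alphas[1], betas[1],
                                    alphas[2], betas[2])
        z1[i] <- z[1]; z3[i] <- z[2]
      }
      todo <- todo[sporadic[todo]]
      if (length(todo) == 0L) break
    }
    if (attempts > max_attempts)
      stopf(paste0("rejection sampling exceeded %d attempts for a censored",
                   " individual (alpha1=%.3g beta1=%.3g alpha3=%.3g",
                   " beta3=%.3g lambda=%.3g): parameters place almost no",
                   " mass beyond the censoring age"),
            max_attempts, alphas[1], betas[1], alphas[2], betas[2], lambda)
    m <- length(todo)
    t1 <- rgamma(m, alphas[1], betas[1])
    t3 <- rgamma(m, alphas[2], betas[2])
    t2 <- ifelse(sporadic[todo], rexp(m, lambda), 0)
    keep <- t1 + t2 + t3 > cens_age[todo]
    idx <- todo[keep]
    z1[idx] <- t1[keep]; z3[idx] <- t3[keep]
    z2[idx] <- ifelse(sporadic[idx], t2[keep], NA_real_)
    todo <- todo[!keep]
  }
  list(z1 = z1, z2 = z2, z3 = z3)
}

#' Rejection-sampling update of latent times for a censored individual
#'
#' Draws each waiting time afresh from its current prior (gamma for the
#' 3p-loss and diagnosis stages, exponential for the VHL-hit stage of
#' sporadic individuals) until their sum exceeds the censoring age.
#'
#' @param state a `sampler_state`.
#' @param individual index of a censored individual.
#' @param seed optional integer seed.
#' @param max_attempts attempt cap; exceeding it signals pathological
#'   parameters and raises an error.
#' @param fallback_after rejection attempts after which an inherited
#'   individual is drawn exactly from the conditional distribution
#'   instead of by further rejection.
#' @return updated state.
#' @export
censored_rejection_update <- function(state, individual, seed = NULL,
                                      max_attempts = 1e5,
                                      fallback_after = 2000L) {
  if (!state$censored[individual]) stopf("individual %d is not censored",
                                         individual)
  with_seed(seed, {
    i <- individual
    st <- censored_step(state$y[i], state$group[i] == "sporadic",
                        c(state$alpha1, state$alpha3),
                        c(state$beta1, state$beta3), state$lambda,
                        max_attempts, fallback_after)
    state$z1[i] <- st$z1; state$z2[i] <- st$z2; state$z3[i] <- st$z3
    state
  })
}

## --- (shape, rate) kernel -------------------------------------------------

shape_rate_step <- function(alpha, beta, z, prior, gamma_scale) {
  log_p <- prior$log_p + sum(log(z))
  q <- prior$q + sum(z)
  r <- prior$r + length(z)
  s <- prior$s + length(z)
  a_star <- rgamma(1L, shape = gamma_scale * alpha, rate = gamma_scale)
  b_star <- rgamma(1L, shape = gamma_scale * beta, rate = gamma_scale)
  lr <- log_shape_rate_density(a_star, b_star, log_p, q, r, s) -
    log_shape_rate_density(alpha, beta, log_p, q, r, s) +
    dgamma(alpha, gamma_scale * a_star, gamma_scale, log = TRUE) +
    dgamma(beta, gamma_scale * b_star, gamma_scale, log = TRUE) -
    dgamma(a_star, gamma_scale * alpha, gamma_scale, log = TRUE) -
    dgamma(b_star, gamma_scale * beta, gamma_scale, log = TRUE)
  if (is.nan(lr)) stopf("NaN in shape-rate log density")
  if (is.finite(lr) && log(runif(1L)) < lr)
    list(alpha = a_star, beta = b_star, accepted = TRUE)
  else list(alpha = alpha, beta = beta, accepted = FALSE)
}

#' Metropolis-Hastings update of a gamma (shape, rate) pair
#'
#' The target is the gamma likelihood of the current latent times for the
#' chosen component times its conjugate prior, evaluated in log space.
#' Proposals are independent gammas centred at the current values
#' (shape = gamma_scale x current, rate = gamma_scale), with the Hastings
#' correction for the asymmetry.
#'
#' @param state a `sampler_state`.
#' @param which 1 (time to 3p loss) or 3 (time to diagnosis).
#' @param priors a [waiting_time_priors()] object.
#' @param gamma_scale proposal scale.
#' @param seed optional integer seed.
#' @return updated state; `state$last_accepted` records the MH decision.
#' @export
shape_rate_update <- function(state, which, priors, gamma_scale = 1000,
                              seed = NULL) {
  if (!which %in% c(1, 3)) stopf("which must be 1 or 3")
  assert_positive(gamma_scale, "gamma_scale")
  with_seed(seed, {
    z <- if (which == 1) state$z1 else state$z3
    prior <- if (which == 1) priors$comp1 else priors$comp3
    cur <- if (which == 1) c(state$alpha1, state$beta1)
           else c(state$alpha3, state$beta3)
    st <- shape_rate_step(cur[1], cur[2], z, prior, gamma_scale)
    if (which == 1) {
      state$alpha1 <- st$alpha; state$beta1 <- st$beta
    } else {
      state$alpha3 <- st$alpha; state$beta3 <- st$beta
    }
    state$last_accepted <- st$accepted
    state
  })
}

#' Exact conjugate update of lambda
#'
#' With prior Gamma(shape, rate) and exponential latent times z2, the
#' posterior is Gamma(shape + n, rate + sum(z2)) and is sampled directly.
#'
#' @param z2 latent VHL-hit waiting times of the sporadic individuals.
#' @param prior numeric `(shape, rate)`, default the Gamma(0.01, 0.01)
#'   prior.
#' @param seed optional integer seed.
#' @return a single lambda draw.
#' @export
lambda_update <- function(z2, prior = c(shape = 0.01, rate = 0.01),
                          seed = NULL) {
  z2 <- z2[!is.na(z2)]
  with_seed(seed,
    rgamma(1L, shape = prior[[1]] + length(z2),
           rate = prior[[2]] + sum(z2)))
}

## --- full sampler ----------------------------------------------------------

#' Run the Gibbs sampler for the three-stage waiting-time model
#'
#' @param cohort incidence cohort (columns group, age, censored).
#' @param priors a [waiting_time_priors()] object.
#' @param mu VHL driver mutation rate per cell per year; the clone size is
#'   reported as `nu = lambda / mu`.
#' @param config a [sampler_config()].
#' @param init_shapes optional numeric `(alpha1, beta1, alpha3, beta3)`
#'   overriding the method-of-moments initialisation (and held fixed when
#'   `config$update_shapes` is FALSE).
#' @return object of class `posterior_draws`: data.frame of retained draws
#'   (alpha1, beta1, alpha3, beta3, lambda, nu) with acceptance rates and
#'   the config as attributes.
#' @export
run_gibbs <- function(cohort, priors, mu, config = sampler_config(),
                      init_shapes = NULL) {
  stopifnot(inherits(priors, "wt_priors"), inherits(config, "sampler_config"))
  state <- init_sampler_state(cohort, mu)
  if (!is.null(init_shapes)) {
    assert_positive(init_shapes, "init_shapes")
    state$alpha1 <- init_shapes[[1]]; state$beta1 <- init_shapes[[2]]
    state$alpha3 <- init_shapes[[3]]; state$beta3 <- init_shapes[[4]]
  }
  spor <- state$group == "sporadic"
  unc_spor <- which(spor & !state$censored)
  unc_inh <- which(!spor & !state$censored)
  cen <- which(state$censored)
  keep_at <- seq(config$burnin + config$thin, config$iterations,
                 by = config$thin)
  keep_flag <- logical(config$iterations)
  keep_flag[keep_at] <- TRUE
  draws <- matrix(NA_real_, length(keep_at), 5L,
                  dimnames = list(NULL, c("alpha1", "beta1", "alpha3",
                                          "beta3", "lambda")))
  acc <- c(split_sporadic = 0, split_inherited = 0,
           shape1 = 0, shape3 = 0)
  n_acc <- c(split_sporadic = 0, split_inherited = 0,
             shape1 = 0, shape3 = 0)
  with_seed(config$seed, {
    row <- 0L
    for (it in seq_len(config$iterations)) {
      if (length(unc_inh)) {
        st <- split_step(state$y[unc_inh],
                         cbind(state$z1[unc_inh], state$z3[unc_inh]),
                         c(state$alpha1, state$alpha3),
                         c(state$beta1, state$beta3), state$lambda,
                         config$kappa)
        state$z1[unc_inh] <- st$z[, 1]; state$z3[unc_inh] <- st$z[, 2]
        acc["split_inherited"] <- acc["split_inherited"] + sum(st$accepted)
        n_acc["split_inherited"] <- n_acc["split_inherited"] +
          length(unc_inh)
      }
      if (length(unc_spor)) {
        st <- split_step(state$y[unc_spor],
                         cbind(state$z1[unc_spor], state$z2[unc_spor],
                               state$z3[unc_spor]),
                         c(state$alpha1, state$alpha3),
                         c(state$beta1, state$beta3), state$lambda,
                         config$kappa)
        state$z1[unc_spor] <- st$z[, 1]; state$z2[unc_spor] <- st$z[, 2]
        state$z3[unc_spor] <- st$z[, 3]
        acc["split_sporadic"] <- acc["split_sporadic"] + sum(st$accepted)
        n_acc["split_sporadic"] <- n_acc["split_sporadic"] +
          length(unc_spor)
      }
      if (length(cen)) {
        st <- censored_step(state$y[cen], spor[cen],
                            c(state$alpha1, state$alpha3),
                            c(state$beta1, state$beta3), state$lambda,
                            config$max_attempts)
        state$z1[cen] <- st$z1; state$z2[cen] <- st$z2
        state$z3[cen] <- st$z3
      }
      if (config$update_shapes) {
        st <- shape_rate_step(state$alpha1, state$beta1, state$z1,
                              priors$comp1, config$gamma_scale)
        state$alpha1 <- st$alpha; state$beta1 <- st$beta
        acc["shape1"] <- acc["shape1"] + st$accepted
        n_acc["shape1"] <- n_acc["shape1"] + 1
        st <- shape_rate_step(state$alpha3, state$beta3, state$z3,
                              priors$comp3, config$gamma_scale)
        state$alpha3 <- st$alpha; state$beta3 <- st$beta
        acc["shape3"] <- acc["shape3"] + st$accepted
        n_acc["shape3"] <- n_acc["shape3"] + 1
      }
      if (any(spor))
        state$lambda <- rgamma(1L,
          shape = priors$lambda[["shape"]] + sum(spor),
          rate = priors$lambda[["rate"]] + sum(state$z2[spor]))
      else
        state$lambda <- rgamma(1L, priors$lambda[["shape"]],
                               priors$lambda[["rate"]])
      if (keep_flag[it]) {
        row <- row + 1L
        draws[row, ] <- c(state$alpha1, state$beta1, state$alpha3,
                          state$beta3, state$lambda)
      }
    }
  })
  out <- as.data.frame(draws)
  out$nu <- out$lambda / mu
  attr(out, "acceptance") <- ifelse(n_acc > 0, acc / n_acc, NA_real_)
  attr(out, "config") <- config
  attr(out, "mu") <- mu
  class(out) <- c("posterior_draws", "data.frame")
  out
}

#' Sample an incidence cohort from published-style curves
#'
#' Sporadic individuals are drawn from an age-specific annual incidence
#' table (rates per 100,000, 5-year bands) treated as a piecewise-constant
#' hazard; individuals without an event are censored at the table's upper
#' age. Inherited individuals are drawn by inverse-CDF sampling of a
#' Kaplan-Meier-style survival curve, censored at its last age.
#'
#' @param incidence_table data.frame with columns age_lo, age_hi, rate
#'   (per 100,000/year), for the sporadic group.
#' @param survival_curve data.frame with columns age, surv (non-increasing
#'   from 1), for the inherited group.
#' @param n individuals to draw.
#' @param seed integer seed.
#' @return incidence cohort data.frame (group, age, censored).
#' @export
sample_cohort_from_curves <- function(incidence_table = NULL,
                                      survival_curve = NULL, n, seed = 1L) {
  if (is.null(incidence_table) == is.null(survival_curve))
    stopf("supply exactly one of incidence_table or survival_curve")
  with_seed(seed, {
    if (!is.null(incidence_table)) {
      tb <- incidence_table
      stopifnot(all(c("age_lo", "age_hi", "rate") %in% names(tb)))
      if (any(tb$rate < 0)) stopf("negative incidence rates")
      h <- tb$rate / 1e5
      width <- tb$age_hi - tb$age_lo
      age <- rep(max(tb$age_hi), n)
      censored <- rep(TRUE, n)
      alive <- rep(TRUE, n)
      for (b in seq_len(nrow(tb))) {
        p_event <- 1 - exp(-h[b] * width[b])
        hit <- alive & runif(n) < p_event
        age[hit] <- runif(sum(hit), tb$age_lo[b], tb$age_hi[b])
        censored[hit] <- FALSE
        alive <- alive & !hit
      }
      data.frame(group = "sporadic", age = age, censored = censored,
                 stringsAsFactors = FALSE)
    } else {
      sc <- survival_curve
      stopifnot(all(c("age", "surv") %in% names(sc)))
      if (is.unsorted(sc$age)) stopf("survival curve ages must increase")
      if (any(diff(sc$surv) > 1e-12)) stopf("survival curve must be non-increasing")
      F <- 1 - sc$surv
      u <- runif(n)
      event <- u <= max(F)
      age <- rep(max(sc$age), n)
      if (any(event))
        age[event] <- stats::approx(c(0, F), c(min(sc$age) - 1e-9, sc$age),
                                    xout = u[event], ties = "ordered",
                                    rule = 2)$y
      data.frame(group = "inherited", age = pmax(age, 1e-6),
                 censored = !event, stringsAsFactors = FALSE)
    }
  })
}

#' Posterior-predictive incidence curves under clone-size interventions
#'
#' For each retained posterior draw, simulates sporadic ages with the
#' VHL-hit waiting time drawn as Exponential(rho x lambda) — a clone
#' reduced to a fraction `rho` of its fitted size — added to fresh draws of
#' the other two waiting times, and summarises the cumulative incidence by
#' age with pointwise 95% posterior bands.
#'
#' @param draws a `posterior_draws` object.
#' @param rho clone-size fraction in (0, 1]; 1 reproduces the fitted model.
#' @param ages age grid (years).
#' @param n_per_draw simulated individuals per posterior draw.
#' @param max_draws subsample at most this many posterior draws.
#' @param seed integer seed.
#' @return list with `curves` (data.frame age, mean, lo95, hi95),
#'   `z2_mean` (mean VHL-hit waiting time per draw) and `rho`.
#' @export
intervention_curves <- function(draws, rho, ages = seq(0, 100, by = 5),
                                n_per_draw = 200L, max_draws = 500L,
                                seed = 1L) {
  if (rho <= 0 || rho > 1) stopf("rho must lie in (0, 1]")
  stopifnot(inherits(draws, "posterior_draws"))
  with_seed(seed, {
    idx <- if (nrow(draws) > max_draws)
      round(seq(1L, nrow(draws), length.out = max_draws)) else seq_len(nrow(draws))
    cum <- matrix(NA_real_, length(idx), length(ages))
    z2m <- numeric(length(idx))
    for (j in seq_along(idx)) {
      d <- draws[idx[j], ]
      z1 <- rgamma(n_per_draw, d$alpha1, d$beta1)
      z2 <- rexp(n_per_draw, rho * d$lambda)
      z3 <- rgamma(n_per_draw, d$alpha3, d$beta3)
      y <- z1 + z2 + z3
      z2m[j] <- mean(z2)
      cum[j, ] <- vapply(ages, function(a) mean(y <= a), numeric(1))
    }
    curves <- data.frame(age = ages,
                         mean = colMeans(cum),
                         lo95 = apply(cum, 2, quantile, 0.025),
                         hi95 = apply(cum, 2, quantile, 0.975))
    list(curves = curves, z2_mean = z2m, rho = rho)
  })
}

#' Posterior summary of the clone-size model
#' @param draws a `posterior_draws` object.
#' @return data.frame of posterior medians and 95% intervals per parameter.
#' @export
summarize_posterior <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  pars <- c("alpha1", "beta1", "alpha3", "beta3", "lambda", "nu")
  do.call(rbind, lapply(pars, function(p) {
    q <- quantile(draws[[p]], c(0.025, 0.5, 0.975))
    data.frame(parameter = p, lo95 = q[1], median = q[2], hi95 = q[3],
               row.names = NULL)
  }))
}
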