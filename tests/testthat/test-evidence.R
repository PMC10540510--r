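## Stepping-stone marginal-likelihood estimator, built here only as an
## independent cross-check of the Wang-Landau route.
stepping_stone <- function(locus, st, model_id, config, seed,
                           K = 12L, n_per = 120L) {
  set.seed(seed)
  betas <- (seq(0, K) / K)^3
  state <- coalacc:::.init_state(locus, st, model_id, config, "gt")
  state <- coalacc:::.prior_state_draw(state)
  full_ll <- function(s) {
    locus_loglik_pruning(s$locus, s$G, s$st, s$Z, c(1, s$r1, s$r2),
                         s$model, cmap = s$cmap)
  }
  ## power-posterior sweeps: reuse the Gibbs machinery on a site subset
  ## approximation of the power likelihood via random site subsampling
  total <- 0
  l <- locus$length
  for (k in seq_len(K)) {
    b0 <- betas[k]; b1 <- betas[k + 1]
    n_sites <- max(0L, round(b0 * l))
    state$sites <- if (n_sites == 0L) NULL else seq_len(n_sites)
    lls <- numeric(n_per)
    for (i in seq_len(n_per)) {
      state <- if (is.null(state$sites)) coalacc:::.prior_sweep(state) else
        coalacc:::.gibbs_sweep(state)
      lls[i] <- full_ll(state)
    }
    m <- max((b1 - b0) * lls)
    total <- total + m + log(mean(exp((b1 - b0) * lls - m)))
  }
  total
}

test_that("an empty locus has marginal likelihood exactly 1", {
  st <- tree3()
  lc <- structure(list(length = 0L), class = "locus_alignment")
  ml <- marginal_likelihood_wl(lc, st, "M0", test_config(), seed = 1)
  expect_identical(ml$logml, 0)
})

test_that("Wang-Landau estimate matches a prior Monte Carlo oracle", {
  set.seed(11)
  st <- tree4()
  Z <- scenario_truth(st, list())
  sim <- simulate_locus(st, Z, length = 30, rates = c(0.2, 2))
  cfg <- chain_config(wl_max_iter = 1500, k_spr = 1, wl_check = 30)
  ## oracle: log mean over prior draws of the pruning likelihood
  n_mc <- 3000
  lls <- numeric(n_mc)
  state <- coalacc:::.init_state(sim$locus, st, "M0", cfg, "gt")
  for (i in seq_len(n_mc)) {
    state <- coalacc:::.prior_state_draw(state)
    lls[i] <- locus_loglik_pruning(sim$locus, state$G, st, state$Z,
                                   c(1, state$r1, state$r2), state$model,
                                   cmap = state$cmap)
  }
  m <- max(lls)
  or <- m + log(mean(exp(lls - m)))
  w <- exp(lls - m); w <- w / sum(w)
  se_mc <- sqrt(sum(w^2))            # effective-sample-size based
  ml <- marginal_likelihood_wl(sim$locus, st, "M0", cfg, seed = 5)
  tol <- 3 * sqrt(ml$se^2 + se_mc^2) + 0.35
  expect_lt(abs(ml$logml - or), tol)
})

test_that("Wang-Landau agrees with a stepping-stone cross-check", {
  set.seed(23)
  st <- tree4()
  Z <- scenario_truth(st, list())
  sim <- simulate_locus(st, Z, length = 30, rates = c(0.25, 2))
  cfg <- chain_config(wl_max_iter = 1200, k_spr = 1, wl_check = 30)
  ml <- marginal_likelihood_wl(sim$locus, st, "M0", cfg, seed = 3)
  ss <- stepping_stone(sim$locus, st, "M0", cfg, seed = 4)
  expect_lt(abs(ml$logml - ss), 3)
})

test_that("the estimate is invariant to the block partition", {
  set.seed(42)
  st <- tree4()
  Z <- scenario_truth(st, list())
  sim <- simulate_locus(st, Z, length = 60, rates = c(0.2, 2))
  cfg1 <- chain_config(block_size = 60, wl_max_iter = 1200, k_spr = 1,
                       wl_check = 30)
  cfg2 <- chain_config(block_size = 20, wl_max_iter = 1200, k_spr = 1,
                       wl_check = 30)
  m1 <- marginal_likelihood_wl(sim$locus, st, "M0", cfg1, seed = 9)
  m2 <- marginal_likelihood_wl(sim$locus, st, "M0", cfg2, seed = 9)
  expect_equal(length(m2$block_ratios), 3L)
  expect_lt(abs(m1$logml - m2$logml),
            3 * sqrt(m1$se^2 + m2$se^2) + 1.0)
})

test_that("Bayes factors satisfy their algebraic identities and selection", {
  ev <- bayes_factors(c(M0 = -100, M1 = -90, M2 = -95),
                      cutoffs = c(9.5, 0, 0), has_targets = TRUE)
  expect_equal(ev$logBF1, 10)
  expect_equal(ev$logBF2, 5)
  expect_equal(ev$logBF3, 5)
  expect_equal(ev$logBF3, ev$logBF1 - ev$logBF2)
  expect_equal(ev$selected, "M1")
  ## below the BF1 cutoff the argmax fallback decides
  ev2 <- bayes_factors(c(M0 = -90.5, M1 = -92, M2 = -95),
                       cutoffs = c(10, 0, 0))
  expect_equal(ev2$selected, "M0")
  ev3 <- bayes_factors(c(M0 = -10, M2 = -30), has_targets = FALSE,
                       cutoffs = c(10, 0, 0))
  expect_equal(ev3$selected, "M0")
  expect_true(is.na(ev3$logBF1))
  expect_error(bayes_factors(c(M0 = -1), has_targets = TRUE), "missing")
})
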