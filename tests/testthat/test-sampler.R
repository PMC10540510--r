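test_that("ancestral imputation matches the enumeration posterior", {
  set.seed(14)
  st <- tree3()
  mod <- build_q(jc_model(), 0.3)
  rates <- c(1, 0.25, 2)
  Z <- c(1L, 1L, 1L, 1L, 0L)
  G <- sample_gene_tree(st)
  cm <- map_gene_tree(G, st)
  chm <- matrix(c("a", "g", "a"), 3, 1, dimnames = list(c("A", "B", "C")))
  lc <- locus_alignment(chm)
  ## enumeration posterior of the gene-root base
  Ms <- vector("list", cm$n_aug)
  for (i in seq_len(cm$n_aug)) {
    if (i == cm$root) next
    Ms[[i]] <- expm_oracle(mod$Q, rates[Z[cm$sbranch[i]] + 1] * cm$len[i])
  }
  internal <- setdiff(seq_len(cm$n_aug), 1:3)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  obs <- lc$mat[1, c("A", "B", "C")]
  post <- numeric(4)
  for (r in seq_len(nrow(grid))) {
    x <- integer(cm$n_aug)
    x[internal] <- grid[r, ]
    x[1:3] <- obs
    pr <- mod$pi[x[cm$root]]
    for (i in seq_len(cm$n_aug)) {
      if (i == cm$root) next
      pr <- pr * Ms[[i]][x[cm$parent[i]], x[i]]
    }
    post[x[cm$root]] <- post[x[cm$root]] + pr
  }
  post <- post / sum(post)
  n <- 30000
  cnt <- numeric(4)
  for (i in seq_len(n)) {
    H <- impute_H(lc, st, cm, Z, rates, mod)
    cnt[H[1, cm$root]] <- cnt[H[1, cm$root]] + 1
  }
  expect_lt(max(abs(cnt / n - post)), 0.015)
})

test_that("imputation respects deterministic limits", {
  st <- tree3(theta = 1e-9)
  mod <- build_q(jc_model(), 0.25)
  G <- concordant_gene_tree(st, eps = 1e-12)
  cm <- map_gene_tree(G, st)
  ## all tips share one base and all rates ~ 0: every node gets that base
  chm <- matrix("c", 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  lc <- locus_alignment(chm)
  H <- impute_H(lc, st, cm, rep(1L, 5), c(1e-12, 1e-12, 1e-12), mod)
  expect_true(all(H == 2L))
})

test_that("rate updates obey constraints and sample the prior without data", {
  set.seed(31)
  st <- tree3()
  lc <- empty_locus(c("A", "B", "C"), 8L)
  cfg <- chain_config(n_burn = 200, n_iter = 2200, thin = 1, k_spr = 1)
  ch <- run_chain(lc, st, "M2", cfg, seed = 7)
  expect_true(all(ch$draws$r1 < 1))
  expect_true(all(ch$draws$r2 > ch$draws$r1))
  ## Gamma(5, 0.04) has mean 0.2; truncation at 1 is negligible
  expect_lt(abs(mean(ch$draws$r1) - 0.2), 0.02)
  expect_lt(abs(mean(ch$draws$r2) - 2), 0.15)
  ## 2*piA ~ Beta(10, 10)
  expect_lt(abs(mean(2 * ch$draws$piA) - 0.5), 0.02)
  expect_lt(abs(sd(2 * ch$draws$piA) - sqrt(0.25 / 21)), 0.02)
})

test_that("data-free chain reproduces the MSC topology distribution", {
  st <- tree3(theta = 0.02)
  lc <- empty_locus(c("A", "B", "C"), 6L)
  ch <- run_chain(lc, st, "M0",
                  chain_config(n_burn = 300, n_iter = 4500, thin = 1,
                               k_spr = 2),
                  seed = 21)
  conc <- mean(ch$draws$topology == "1,2|1,2,3")
  p_theory <- 1 - (2 / 3) * exp(-2 * 0.01 / 0.02)
  ## MCMC draws are autocorrelated; allow a generous Monte Carlo band
  expect_lt(abs(conc - p_theory), 0.035)
})

test_that("gene-tree moves never violate height or species constraints", {
  set.seed(44)
  st <- tree4()
  Z <- scenario_truth(st, list())
  sim <- simulate_locus(st, Z, length = 20, rates = c(0.3, 2))
  cfg <- chain_config(n_burn = 0, n_iter = 1, thin = 1)
  state <- coalacc:::.init_state(sim$locus, st, "M2", cfg, "gt")
  for (i in 1:300) {
    state <- coalacc:::.gibbs_sweep(state)
    G <- state$G
    nr <- which(G$parent > 0)
    expect_true(all(G$height[nr] <= G$height[G$parent[nr]] + 1e-9))
    ## mapping must stay valid (errors would throw here)
    expect_silent(map_gene_tree(G, st))
  }
})

test_that("posterior recovers simulation truth on a 9-taxon locus", {
  set.seed(77)
  st <- tree9(target = c("T1", "T2"))
  Z <- scenario_truth(st, list(c("T1", "T2")))
  sim <- simulate_locus(st, Z, length = 150, rates = c(0.2, 2.5),
                        piA = 0.25)
  ch <- run_chain(sim$locus, st, "M1",
                  chain_config(n_burn = 150, n_iter = 250, thin = 2,
                               k_spr = 1), seed = 5)
  ## accelerated tips called, conserved background not
  expect_gt(ch$pp_accel[["T1"]], 0.5)
  expect_gt(ch$pp_accel[["T2"]], 0.5)
  expect_lt(max(ch$pp_accel[c("T6", "T7", "O1", "O2")]), 0.5)
  expect_lt(abs(ch$post_mean[["r1"]] - 0.2), 0.12)
  expect_lt(abs(ch$post_mean[["r2"]] - 2.5), 1.2)
})

test_that("null-simulated data yields no acceleration calls", {
  set.seed(90)
  st <- tree9(target = c("T4", "T5"))
  Z <- scenario_truth(st, list())
  sim <- simulate_locus(st, Z, length = 150, rates = c(0.2, 2))
  ch <- run_chain(sim$locus, st, "M2",
                  chain_config(n_burn = 150, n_iter = 250, thin = 2,
                               k_spr = 1), seed = 6)
  expect_true(all(ch$pp_accel < 0.5))
})

test_that("species-tree mode runs without gene-tree machinery", {
  set.seed(15)
  st <- tree9(target = c("T1", "T2"))
  Z <- scenario_truth(st, list(c("T1", "T2")))
  sim <- simulate_locus(st, Z, length = 120, rates = c(0.2, 2.5))
  ch <- run_chain(sim$locus, st, "M1", test_config(), seed = 4,
                  method = "st")
  expect_gt(ch$pp_accel[["T1"]], 0.5)
  expect_true(all(ch$draws$topology == "species"))
})
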