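test_that("conservation prior matrix is row-stochastic with Dollo absorption", {
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1); b <- runif(1)
    phi <- build_phi(a, b, dollo = TRUE)
    expect_equal(rowSums(phi), rep(1, 3), tolerance = 1e-12)
    expect_equal(phi[3, ], c(0, 0, 1))
  }
  phi <- build_phi(0.3, 0.4, dollo = FALSE, reversion = 0.2)
  expect_equal(phi[3, ], c(0, 0.2, 0.8))
  expect_error(build_phi(1.2, 0.5), "probabilities")
})

test_that("model restrictions confine the accelerated state correctly", {
  st <- tree9(target = c("T1", "T2"), outgroup = c("O1", "O2"))
  a0 <- model_spec(st, "M0")
  a1 <- model_spec(st, "M1")
  a2 <- model_spec(st, "M2")
  expect_false(any(a0[, 3]))
  ## M1: only branches with all-target descendants (T1, T2, their mrca)
  lab_ok <- which(a1[, 3])
  t1 <- which(st$labels == "T1")
  expect_setequal(st$labels[lab_ok],
                  c("T1", "T2", st$labels[st$parent[t1]]))
  ## outgroup branches never accelerate even under M2
  og_nodes <- which(vapply(coalacc:::.tip_descendants(st), function(d) {
    all(st$labels[d] %in% c("O1", "O2"))
  }, TRUE))
  expect_false(any(a2[og_nodes, 3]))
  expect_true(all(a2[setdiff(seq_len(st$n_nodes), og_nodes), 3]))
})

test_that("emissions match direct per-segment recomputation", {
  set.seed(6)
  st <- tree4()
  G <- sample_gene_tree(st)
  cm <- map_gene_tree(G, st)
  mod <- build_q(jc_model(), 0.3)
  rates <- c(1, 0.2, 2)
  Z <- c(1L, 1L, 1L, 1L, 1L, 2L, 0L)
  lc <- empty_locus(c("A", "B", "C", "D"), l = 15L)
  H <- impute_H(lc, st, cm, Z, rates, mod)
  be <- branch_emission(H, cm, mod, rates, st)
  ## direct recomputation with single transition_matrix calls
  emis2 <- matrix(0, st$n_nodes, 3L)
  for (i in seq_len(cm$n_aug)) {
    if (i == cm$root) next
    for (z in 0:2) {
      M <- transition_matrix(mod, rates[z + 1], cm$len[i])
      lp <- sum(log(M[cbind(H[, cm$parent[i]], H[, i])]))
      emis2[cm$sbranch[i], z + 1] <- emis2[cm$sbranch[i], z + 1] + lp
    }
  }
  expect_equal(be$emis, emis2, tolerance = 1e-9)
  expect_equal(be$root_ll, sum(log(mod$pi[H[, cm$root]])), tolerance = 1e-12)
  ## zero-length segments contribute equally (zero) to every state
  zl <- which(cm$len == 0)
  for (i in zl) expect_equal(be$emis[cm$sbranch[i], 1],
                             be$emis[cm$sbranch[i], 1])
})

test_that("forward-backward Z sampling matches exhaustive enumeration", {
  set.seed(12)
  st <- tree3()
  N <- st$n_nodes
  phi <- build_phi(0.4, 0.3, dollo = TRUE)
  emis <- matrix(rnorm(N * 3, sd = 1.5), N, 3)
  allowed <- model_spec(st, "M2")
  ## exhaustive posterior over 3^(N-1) configurations with root fixed at 0
  grid <- as.matrix(expand.grid(rep(list(0:2), N - 1)))
  logp <- apply(grid, 1, function(zz) {
    Z <- c(zz, 0L)
    if (any(!allowed[cbind(seq_len(N), Z + 1L)])) return(-Inf)
    lp <- sum(emis[cbind(seq_len(N), Z + 1L)])
    for (s in seq_len(N - 1)) {
      lp <- lp + log(phi[Z[st$parent[s]] + 1L, Z[s] + 1L])
    }
    lp
  })
  p_exact <- exp(logp - max(logp))
  p_exact <- p_exact / sum(p_exact)
  ## marginal P(Z_s = 2) from enumeration vs sampling
  marg2 <- vapply(seq_len(N - 1), function(s) {
    sum(p_exact[grid[, s] == 2L])
  }, 0)
  n <- 40000
  cnt <- numeric(N - 1)
  logZs <- numeric(5)
  for (i in seq_len(n)) {
    zs <- sample_Z(emis, phi, allowed, st)
    cnt <- cnt + (zs$Z[seq_len(N - 1)] == 2L)
    if (i <= 5) logZs[i] <- zs$logZ
  }
  expect_lt(max(abs(cnt / n - marg2)), 0.015)
  ## the FB normalizer equals the enumeration normalizer
  expect_equal(logZs[1], max(logp) + log(sum(exp(logp - max(logp)))),
               tolerance = 1e-9)
})

test_that("flat emissions reproduce the prior transition law", {
  set.seed(3)
  st <- tree3()
  phi <- build_phi(0.5, 0.4, dollo = TRUE)
  allowed <- model_spec(st, "M2")
  emis <- matrix(0, st$n_nodes, 3)
  n <- 30000
  cnt <- matrix(0, st$n_nodes, 3)
  for (i in seq_len(n)) {
    Z <- sample_Z(emis, phi, allowed, st)$Z
    cnt[cbind(seq_len(st$n_nodes), Z + 1L)] <-
      cnt[cbind(seq_len(st$n_nodes), Z + 1L)] + 1
  }
  ## matrix-power marginal along the root-to-branch path
  p_int <- c(1, 0, 0) %*% phi         # internal node 4 (child of root)
  p_tip1 <- p_int %*% phi             # tips A, B (children of node 4)
  expect_lt(max(abs(cnt[4, ] / n - p_int)), 0.015)
  expect_lt(max(abs(cnt[1, ] / n - p_tip1)), 0.015)
  ## under M0 state 2 never appears
  a0 <- model_spec(st, "M0")
  for (i in 1:200) {
    expect_false(any(sample_Z(emis, phi, a0, st)$Z == 2L))
  }
  ## Dollo: an accelerated parent forces accelerated children
  for (i in 1:500) {
    Z <- sample_Z(emis, build_phi(0.9, 0.9, TRUE), allowed, st)$Z
    for (s in seq_len(st$n_nodes - 1L)) {
      if (Z[st$parent[s]] == 2L) expect_equal(Z[s], 2L)
    }
  }
})

test_that("alpha/beta Gibbs draws follow the conjugate Beta posteriors", {
  st <- tree9()
  ## all branches background: beta is drawn from its Beta(1,1) prior
  set.seed(2)
  Z <- rep(0L, st$n_nodes)
  draws <- replicate(4000, gibbs_alpha_beta(Z, st)$beta)
  expect_equal(mean(draws), 0.5, tolerance = 0.03)
  expect_equal(stats::var(draws), 1 / 12, tolerance = 0.01)
  ## alpha sees n01 = 0, n00 = 16 edges
  draws_a <- replicate(4000, gibbs_alpha_beta(Z, st)$alpha)
  expect_equal(mean(draws_a), 1 / (2 + 16), tolerance = 0.01)
  ## posterior mean approaches the empirical transition fraction
  Z2 <- rep(0L, st$n_nodes)
  Z2[c(1, 2, 3)] <- 1L                # three 0 -> 1 transitions
  draws_a2 <- replicate(4000, gibbs_alpha_beta(Z2, st)$alpha)
  n01 <- 3; n00 <- st$n_nodes - 1 - 3
  expect_equal(mean(draws_a2), (1 + n01) / (2 + n01 + n00), tolerance = 0.01)
})

test_that("acceleration calling counts independent events", {
  st <- tree9()
  pp <- setNames(numeric(st$n_nodes), st$labels)
  ## two sibling tips accelerated, parent not: 2 events
  pp[c("T1", "T2")] <- 0.9
  res <- call_acceleration(pp, st)
  expect_setequal(res$accelerated, c("T1", "T2"))
  expect_equal(res$n_events, 2L)
  ## parent and both children: 1 event
  pp[st$labels[st$parent[which(st$labels == "T1")]]] <- 0.8
  res2 <- call_acceleration(pp, st)
  expect_equal(res2$n_events, 1L)
  ## nothing above threshold
  expect_equal(call_acceleration(pp * 0, st)$n_events, 0L)
})
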