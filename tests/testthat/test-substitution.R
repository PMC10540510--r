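test_that("build_q reproduces JC at piA = 0.25 and is stationary", {
  mod <- build_q(jc_model(), 0.25)
  expect_equal(unname(mod$Q[1, 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(mod$Q)), rep(-1, 4), tolerance = 1e-12)
  expect_lt(max(abs(mod$pi %*% mod$Q)), 1e-10)
  ## eigendecomposition reconstructs Q
  expect_lt(max(abs(mod$P %*% diag(mod$lambda) %*% mod$Pinv - mod$Q)), 1e-10)
  expect_error(build_q(jc_model(), 0.5), "piA")
  expect_error(build_q(jc_model(), 0), "piA")
})

test_that("transition matrices match an independent expm oracle", {
  nm <- read_neutral_model(paste(
    "BACKGROUND: 0.3 0.2 0.2 0.3", "RATE_MAT:",
    " -1 0.3 0.4 0.3", " 0.45 -1.2 0.3 0.45",
    " 0.6 0.3 -1.5 0.6", " 0.3 0.3 0.4 -1", sep = "\n"))
  mod <- build_q(nm, 0.32)
  set.seed(1)
  for (i in 1:10) {
    r <- runif(1, 0, 3); t <- runif(1, 0, 0.5)
    M <- transition_matrix(mod, r, t)
    expect_lt(max(abs(M - expm_oracle(mod$Q, r * t))), 1e-10)
    expect_equal(rowSums(M), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(transition_matrix(mod, 1, 0), diag(4), tolerance = 1e-12)
  ## ergodic limit: long branches forget the starting base
  Mlong <- transition_matrix(mod, 1, 50)
  for (i in 1:4) expect_equal(unname(Mlong[i, ]), mod$pi, tolerance = 1e-8)
  ## Chapman-Kolmogorov
  M1 <- transition_matrix(mod, 0.7, 0.1)
  M2 <- transition_matrix(mod, 0.7, 0.25)
  expect_lt(max(abs(M1 %*% M2 - transition_matrix(mod, 0.7, 0.35))), 1e-9)
})

test_that("transition matrices commute with the strand-symmetry swap", {
  mod <- build_q(jc_model(), 0.31)
  swap <- matrix(0, 4, 4)
  swap[cbind(1:4, c(4, 3, 2, 1))] <- 1   # A<->T, C<->G
  M <- transition_matrix(mod, 1.3, 0.2)
  expect_lt(max(abs(swap %*% M - M %*% swap)), 1e-10)
})

test_that("pruning equals brute-force enumeration on small gene trees", {
  set.seed(21)
  st <- tree3()
  mod <- build_q(jc_model(), 0.3)
  Z <- c(1L, 1L, 1L, 2L, 0L)
  rates <- c(1, 0.3, 2.5)
  for (rep in 1:5) {
    G <- sample_gene_tree(st)
    chm <- matrix(sample(c("a", "c", "g", "t"), 6, replace = TRUE), 3, 2)
    rownames(chm) <- c("A", "B", "C")
    lc <- locus_alignment(chm)
    expect_equal(locus_loglik_pruning(lc, G, st, Z, rates, mod),
                 enum_loglik(lc, G, st, Z, rates, mod),
                 tolerance = 1e-8)
  }
  ## missing data marginalizes correctly
  chm <- matrix(c("a", "-", "g", "n", "c", "t"), 3, 2)
  rownames(chm) <- c("A", "B", "C")
  lc <- locus_alignment(chm)
  G <- sample_gene_tree(st)
  expect_equal(locus_loglik_pruning(lc, G, st, Z, rates, mod),
               enum_loglik(lc, G, st, Z, rates, mod), tolerance = 1e-8)
})

test_that("likelihood is invariant to time/rate rescaling", {
  set.seed(5)
  st <- tree4()
  mod <- build_q(jc_model(), 0.27)
  G <- sample_gene_tree(st)
  Z <- rep(1L, 7); Z[7] <- 0L
  chm <- matrix(sample(c("a", "c", "g", "t"), 4 * 20, replace = TRUE), 4)
  rownames(chm) <- c("A", "B", "C", "D")
  lc <- locus_alignment(chm)
  rates <- c(1, 0.2, 2)
  ll1 <- locus_loglik_pruning(lc, G, st, Z, rates, mod)
  c_scale <- 3.7
  st2 <- st
  st2$blen <- st$blen * c_scale
  st2$tlen <- st$tlen * c_scale
  st2$height <- st$height * c_scale
  G2 <- G
  G2$height <- G$height * c_scale
  ll2 <- locus_loglik_pruning(lc, G2, st2, Z, rates / c_scale, mod)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("species-tree pruning matches the JC pairwise closed form", {
  ## two taxa, one site each pattern: P(diff) = 3/4 (1 - exp(-4/3 r t))
  st <- read_species_tree("(A:0.15,B:0.1);")
  mod <- build_q(jc_model(), 0.25)
  r <- 0.7
  t_tot <- 0.25
  p_diff <- 3 / 4 * (1 - exp(-4 / 3 * r * t_tot))
  same <- locus_alignment(matrix(c("a", "a"), 2, 1,
                                 dimnames = list(c("A", "B"), NULL)))
  diff <- locus_alignment(matrix(c("a", "g"), 2, 1,
                                 dimnames = list(c("A", "B"), NULL)))
  Z <- c(1L, 1L, 0L)
  ll_same <- species_tree_loglik(same, st, Z, c(1, r, 2), mod)
  ll_diff <- species_tree_loglik(diff, st, Z, c(1, r, 2), mod)
  expect_equal(exp(ll_diff) * 3, 0.25 * p_diff, tolerance = 1e-10)
  expect_equal(exp(ll_same), 0.25 * (1 - p_diff), tolerance = 1e-10)
})

test_that("gene-tree pruning nests the species-tree model", {
  ## concordant gene tree with coalescences at speciation times
  st <- tree9(theta = 1e-9)
  set.seed(9)
  G <- concordant_gene_tree(st, eps = 1e-12)
  Z <- rep(1L, st$n_nodes); Z[st$n_nodes] <- 0L
  mod <- build_q(jc_model(), 0.3)
  chm <- matrix(sample(c("a", "c", "g", "t"), 9 * 30, replace = TRUE), 9)
  rownames(chm) <- st$labels[1:9]
  lc <- locus_alignment(chm)
  ll_gene <- locus_loglik_pruning(lc, G, st, Z, c(1, 0.2, 2), mod)
  ll_spec <- species_tree_loglik(lc, st, Z, c(1, 0.2, 2), mod,
                                 use_tlen = TRUE)
  expect_equal(ll_gene, ll_spec, tolerance = 1e-6)
})
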