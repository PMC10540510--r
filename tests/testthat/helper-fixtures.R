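## Shared fixtures: small trees with known geometry, built in code.

## 3 taxa: ((A,B),C); internal branch t = 0.01, clock-like
tree3 <- function(theta = 0.02) {
  st <- read_species_tree("((A:0.02,B:0.02):0.01,C:0.03);")
  st$theta[4:5] <- theta
  st
}

## 4 taxa with an outgroup
tree4 <- function(theta = 0.03) {
  st <- read_species_tree("(((A:0.05,B:0.05):0.03,C:0.08):0.04,D:0.12);",
                          outgroup = "D")
  st$theta[5:7] <- theta
  st
}

## 9 taxa, clock-like, two clades usable as targets
tree9 <- function(theta = 0.02, target = character(),
                  outgroup = c("O1", "O2")) {
  nwk <- paste0("(((((T1:0.02,T2:0.02):0.02,T3:0.04):0.02,",
                "(T4:0.03,T5:0.03):0.03):0.04,(T6:0.05,T7:0.05):0.05)",
                ":0.05,(O1:0.08,O2:0.08):0.07);")
  st <- read_species_tree(nwk, target = target, outgroup = outgroup)
  st$theta[(st$n_tips + 1L):st$n_nodes] <- theta
  st
}

## alignment of all-ambiguous characters: likelihood 1 for every state
empty_locus <- function(taxa, l = 10L) {
  m <- matrix("n", length(taxa), l)
  rownames(m) <- taxa
  locus_alignment(m, id = "empty")
}

## short chain settings for tests
test_config <- function(...) {
  chain_config(n_burn = 100L, n_iter = 200L, thin = 2L, k_spr = 1L,
               wl_max_iter = 800L, wl_check = 30L, wl_step_min = 5e-3, ...)
}

## deterministic gene tree matching the species tree with coalescences
## just above each speciation time
concordant_gene_tree <- function(st, eps = 1e-9) {
  S <- st$n_tips
  parent <- integer(2L * S - 1L)
  height <- numeric(2L * S - 1L)
  ## species internal node s (post-order) -> gene node S + (s - S)
  for (s in (S + 1L):st$n_nodes) {
    g <- s
    height[g] <- st$height[s] + eps
    for (c in st$children[[s]]) parent[c] <- g
  }
  gene_tree(parent, height, S)
}

## independent matrix exponential oracle
expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

## brute-force pruning oracle: enumerate all internal-node states of an
## augmented gene tree, transition matrices from the expm oracle
enum_loglik <- function(locus, G, st, Z, rates, model) {
  cmap <- map_gene_tree(G, st)
  n <- cmap$n_aug
  Ms <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == cmap$root) next
    r <- rates[Z[cmap$sbranch[i]] + 1L]
    Ms[[i]] <- expm_oracle(model$Q, r * cmap$len[i])
  }
  S <- st$n_tips
  internal <- setdiff(seq_len(n), seq_len(S))
  total <- 0
  for (j in seq_len(locus$length)) {
    obs <- locus$mat[j, st$labels[seq_len(S)]]
    p_site <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
    for (r in seq_len(nrow(grid))) {
      x <- integer(n)
      x[internal] <- grid[r, ]
      pr <- model$pi[x[cmap$root]]
      ok <- TRUE
      for (i in seq_len(n)) {
        if (i == cmap$root) next
        xi <- if (i <= S) obs[i] else x[i]
        if (is.na(xi)) next      # missing tip: marginalizes to 1
        pr <- pr * Ms[[i]][x[cmap$parent[i]], xi]
      }
      p_site <- p_site + pr
    }
    total <- total + log(p_site)
  }
  total
}
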