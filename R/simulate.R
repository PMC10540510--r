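## Sequence simulation under the multispecies coalescent with three-state
## rate control, scenario builders, and the bundled surrogate tree.

#' Conservation-state truth for an acceleration scenario
#'
#' Every non-root branch starts conserved (state 1); branches inside the
#' given clades (all extant descendants within one clade's tip set) are
#' switched to accelerated (state 2), which automatically respects Dollo
#' irreversibility.  The root is background (state 0).
#'
#' @param st a \code{spectree}.
#' @param clades list of character vectors of tip labels; each vector is
#'   one independently accelerated monophyletic clade (empty list = null).
#' @return integer state vector over nodes.
#' @export
scenario_truth <- function(st, clades = list()) {
  N <- st$n_nodes
  desc <- .tip_descendants(st)
  tips <- st$labels[seq_len(st$n_tips)]
  Z <- rep(1L, N)
  Z[N] <- 0L
  for (cl in clades) {
    idx <- which(tips %in% cl)
    if (length(idx) != length(cl)) stop("unknown tips in clade")
    inside <- vapply(desc, function(d) all(d %in% idx), TRUE)
    Z[inside & seq_len(N) != N] <- 2L
  }
  Z
}

#' Simulate one locus
#'
#' Draws a gene tree from the multispecies coalescent, a root sequence
#' i.i.d. from the stationary distribution (2*piA ~ Beta(10,10) unless
#' given), then evolves the sequence segment-by-segment down the
#' augmented gene tree, each segment at the rate multiplier of its
#' enclosing species branch's conservation state; only extant-species
#' sequences are emitted.
#'
#' @param st a \code{spectree}.
#' @param Z integer conservation states (see \code{\link{scenario_truth}}).
#' @param length locus length in bp.
#' @param rates optional c(r1, r2); drawn from the Gamma(5, 0.04) and
#'   Gamma(10, 0.2) priors (means 0.2 and 2) when NULL.
#' @param piA optional stationary composition parameter.
#' @param neutral a \code{neutral_model} (default Jukes-Cantor).
#' @param id locus identifier.
#' @return list with \code{locus} (a \code{locus_alignment}) and
#'   \code{truth} (G, Z, r1, r2, piA).
#' @export
simulate_locus <- function(st, Z, length = 100L, rates = NULL, piA = NULL,
                           neutral = jc_model(), id = "sim") {
  if (is.null(rates)) {
    repeat {
      r1 <- stats::rgamma(1L, 5, scale = 0.04)
      if (r1 < 1) break
    }
    repeat {
      r2 <- stats::rgamma(1L, 10, scale = 0.2)
      if (r2 > r1) break
    }
    rates <- c(r1, r2)
  }
  if (is.null(piA)) piA <- stats::rbeta(1L, 10, 10) / 2
  piA <- min(max(piA, 1e-3), 0.5 - 1e-3)
  model <- build_q(neutral, piA)
  rmult <- c(1, rates)
  G <- sample_gene_tree(st)
  cmap <- map_gene_tree(G, st)
  l <- as.integer(length)
  seqs <- matrix(NA_integer_, l, cmap$n_aug)
  seqs[, cmap$root] <- .sample_rows(matrix(model$pi, l, 4L, byrow = TRUE))
  ord <- rev(.topo_order(cmap$parent, cmap$root))   # parents first
  for (i in ord) {
    if (i == cmap$root) next
    r <- rmult[Z[cmap$sbranch[i]] + 1L]
    M <- transition_matrix(model, r, cmap$len[i])
    seqs[, i] <- .sample_rows(M[seqs[, cmap$parent[i]], , drop = FALSE])
  }
  tips <- st$labels[seq_len(st$n_tips)]
  ch <- matrix(c("a", "c", "g", "t")[seqs[, seq_len(st$n_tips)]],
               nrow = l)
  chm <- t(ch)
  rownames(chm) <- tips
  locus <- locus_alignment(chm, id = id)
  list(locus = locus,
       truth = list(G = G, Z = Z, r1 = rates[1L], r2 = rates[2L],
                    piA = piA))
}

#' Build a benchmark locus set
#'
#' Simulates \code{n_null} loci conserved on every lineage plus
#' \code{n_accel} loci accelerated in the scenario clades (defaults 400
#' and 100), optionally scaling all internal population sizes by a common
#' factor.
#'
#' @param st a \code{spectree}.
#' @param clades list of accelerated clades (tip-label vectors).
#' @param n_null,n_accel locus counts.
#' @param length locus length (bp).
#' @param theta_scale multiplicative scaling of internal theta values.
#' @param seed integer seed.
#' @param neutral a \code{neutral_model}.
#' @return list with \code{loci} (list of \code{locus_alignment}),
#'   \code{truth} (data frame: id, accelerated, r1, r2, piA),
#'   \code{Z_null}, \code{Z_accel}, \code{tree} (the theta-scaled tree).
#' @export
build_benchmark <- function(st, clades, n_null = 400L, n_accel = 100L,
                            length = 100L, theta_scale = 1,
                            seed = 1L, neutral = jc_model()) {
  set.seed(seed)
  st2 <- st
  internal <- (st$n_tips + 1L):st$n_nodes
  st2$theta[internal] <- st2$theta[internal] * theta_scale
  Z_null <- scenario_truth(st2, list())
  Z_accel <- scenario_truth(st2, clades)
  loci <- vector("list", n_null + n_accel)
  rows <- vector("list", n_null + n_accel)
  for (i in seq_len(n_null + n_accel)) {
    accel <- i > n_null
    Z <- if (accel) Z_accel else Z_null
    id <- sprintf("%s%04d", if (accel) "accel" else "null", i)
    sim <- simulate_locus(st2, Z, length = length, neutral = neutral,
                          id = id)
    loci[[i]] <- sim$locus
    rows[[i]] <- data.frame(id = id, accelerated = accel,
                            r1 = sim$truth$r1, r2 = sim$truth$r2,
                            piA = sim$truth$piA, stringsAsFactors = FALSE)
  }
  list(loci = loci, truth = do.call(rbind, rows), Z_null = Z_null,
       Z_accel = Z_accel, tree = st2)
}

#' Bundled synthetic surrogate species tree
#'
#' A self-contained 20-taxon clock-like species tree (17 ingroup taxa in
#' clades A-G plus outgroups O1-O3) with branch lengths in expected
#' neutral substitutions per site, used by examples and simulation
#' studies when no user tree is supplied.  It is a synthetic stand-in
#' with realistic magnitudes (tree height 0.36 substitutions/site;
#' internal theta defaulting to 0.02), not an empirical phylogeny.
#'
#' @param theta population-size parameter applied to all internal
#'   branches (tips are 0).
#' @param target,outgroup taxon sets (defaults: no targets; O1-O3).
#' @return a \code{spectree}.
#' @export
surrogate_tree <- function(theta = 0.02, target = character(),
                           outgroup = c("O1", "O2", "O3")) {
  nwk <- paste0(
    "(((((((A1:0.01,A2:0.01):0.04,((B1:0.012,B2:0.012):0.018,B3:0.03)",
    ":0.02):0.03,((C1:0.015,C2:0.015):0.03,((D1:0.01,D2:0.01):0.015,",
    "(D3:0.012,D4:0.012):0.013):0.02):0.035):0.04,(((E1:0.02,E2:0.02)",
    ":0.02,((F1:0.01,F2:0.01):0.012,F3:0.022):0.018):0.03,G1:0.07):0.05)",
    ":0.08,O1:0.2):0.08,O2:0.28):0.08,O3:0.36);")
  st <- read_species_tree(nwk, target = target, outgroup = outgroup)
  st$theta[(st$n_tips + 1L):st$n_nodes] <- theta
  st
}

#' Acceleration scenarios on the surrogate tree
#'
#' The three benchmark scenarios: one, two, or three independently
#' accelerated monophyletic clades.
#'
#' @return named list of clade lists (\code{single}, \code{double},
#'   \code{triple}).
#' @export
surrogate_scenarios <- function() {
  B <- c("B1", "B2", "B3")
  E <- c("E1", "E2")
  C <- c("C1", "C2")
  list(single = list(B), double = list(B, E), triple = list(B, E, C))
}
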