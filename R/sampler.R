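## Collapsed Gibbs sampler for one locus under one model specification.
##
## Sweep order: impute H -> sample Z -> MH on (r1, r2) -> MH on piA ->
## guided SPR (x k) -> node-height moves -> Gibbs on (alpha, beta).
## Every update conditions on the imputed complete data: Z, r and piA use
## the per-segment emissions of H, and the two gene-tree moves keep the
## gene-node bases of H fixed in the state (their ids persist across
## moves) while marginalizing the boundary bases analytically, so the
## H-guided SPR proposal is a valid Metropolis-Hastings kernel for the
## joint (G, H) conditional.  H is redrawn from its exact conditional at
## the start of each sweep.

#' Default chain configuration
#'
#' @param n_burn burn-in sweeps.
#' @param n_iter kept sweeps after burn-in.
#' @param thin record every \code{thin}-th kept sweep.
#' @param k_spr guided SPR attempts per sweep.
#' @param r1_shape,r1_scale,r2_shape,r2_scale Gamma priors (shape-scale) on
#'   the conserved and accelerated rates; defaults have means 0.2 and 2.
#' @param gamma Beta(gamma, gamma) prior hyperparameter on 2*piA.
#' @param dollo Dollo irreversibility of acceleration.
#' @param root_state conservation state fixed at the root.
#' @param n_height number of internal gene nodes receiving a height move
#'   per sweep (NULL = all).
#' @param block_size Wang-Landau data-block size in sites.
#' @param wl_max_iter,wl_check,wl_flat,wl_step0,wl_step_min Wang-Landau
#'   schedule: iteration budget per block step, flatness check interval,
#'   occupancy flatness tolerance, initial and terminal log-weight steps.
#' @param adapt adapt MH proposal scales during burn-in (target ~0.3).
#' @return a named list of settings.
#' @export
chain_config <- function(n_burn = 2000L, n_iter = 3000L, thin = 2L,
                         k_spr = 2L,
                         r1_shape = 5, r1_scale = 0.04,
                         r2_shape = 10, r2_scale = 0.2,
                         gamma = 10, dollo = TRUE, root_state = 0L,
                         n_height = NULL,
                         block_size = 50L, wl_max_iter = 2000L,
                         wl_check = 40L, wl_flat = 0.2, wl_step0 = 1,
                         wl_step_min = 1e-3, adapt = TRUE) {
  list(n_burn = n_burn, n_iter = n_iter, thin = thin, k_spr = k_spr,
       r1_shape = r1_shape, r1_scale = r1_scale,
       r2_shape = r2_shape, r2_scale = r2_scale,
       gamma = gamma, dollo = dollo, root_state = root_state,
       n_height = n_height,
       block_size = block_size, wl_max_iter = wl_max_iter,
       wl_check = wl_check, wl_flat = wl_flat, wl_step0 = wl_step0,
       wl_step_min = wl_step_min, adapt = adapt)
}

## species-tree "map": the species tree itself viewed as an augmented tree
## (one segment per branch, rate of branch s governed by Z_s); used by the
## concordant species-tree mode and for nesting tests.
species_cmap <- function(st, use_tlen = FALSE) {
  N <- st$n_nodes
  len <- if (use_tlen) st$tlen else st$blen
  trav <- .aug_traversal(st$parent, N, N)
  structure(list(parent = st$parent, len = c(len[seq_len(N - 1L)], 0),
                 sbranch = seq_len(N), height = st$height, n_gene = N,
                 n_aug = N, root = N, m = integer(N), n = integer(N),
                 tau = vector("list", N), sp_node = seq_len(N),
                 kids = trav$kids, ord = trav$ord),
            class = "coalmap")
}

## categorical row sampling: W is l x 4 (unnormalized, non-negative)
.sample_rows <- function(W) {
  c1 <- W[, 1L]; c2 <- c1 + W[, 2L]; c3 <- c2 + W[, 3L]
  tot <- c3 + W[, 4L]
  u <- stats::runif(nrow(W)) * tot
  1L + (u > c1) + (u > c2) + (u > c3)
}

#' Impute ancestral sequences on the augmented gene tree
#'
#' Per site, an upward pruning pass over the augmented tree (boundary
#' points are degree-2 nodes using the enclosing species branch's rate)
#' followed by a root-to-tips ancestral draw; exact conditional sampling
#' given (Y, G, Z, r, pi).  Ambiguous or gapped tip sites are sampled from
#' their compatible bases as well, so the returned matrix is complete.
#'
#' @param locus a \code{locus_alignment}.
#' @param st a \code{spectree}.
#' @param cmap a \code{coalmap}.
#' @param Z integer states per species node.
#' @param rates c(r0, r1, r2).
#' @param model a \code{subst_model}.
#' @param sites optional site subset.
#' @return l x n_aug integer matrix of bases (1..4).
#' @export
impute_H <- function(locus, st, cmap, Z, rates, model, sites = NULL) {
  Ms <- .edge_matrices(cmap, Z, rates, model)
  tip_ids <- seq_len(st$n_tips)
  tipmask <- lapply(st$labels[tip_ids], function(tx) {
    m <- locus$mask[[tx]]
    if (is.null(m)) matrix(1, 4L, locus$length) else m
  })
  if (!is.null(sites)) {
    tipmask <- lapply(tipmask, function(m) m[, sites, drop = FALSE])
  }
  pr <- .prune_loglik(cmap, Ms, tipmask, model$pi, return_partials = TRUE)
  l <- length(pr$site)
  H <- matrix(NA_integer_, l, cmap$n_aug)
  ## root draw
  Wr <- t(pr$L[[cmap$root]]) * rep(model$pi, each = l)
  H[, cmap$root] <- .sample_rows(Wr)
  for (i in rev(cmap$ord)) {       # parents before children
    if (i == cmap$root) next
    p <- cmap$parent[i]
    Lc <- if (i %in% tip_ids) tipmask[[i]] else pr$L[[i]]
    W <- Ms[[i]][H[, p], , drop = FALSE] * t(Lc)
    H[, i] <- .sample_rows(W)
  }
  H
}

## complete-data log-likelihood given H (per-segment counts), for MH steps
.complete_ll <- function(counts, cmap, Z, rates, model, rootH) {
  idx <- seq_len(cmap$n_aug)[-cmap$root]
  rt <- rates[Z[cmap$sbranch[idx]] + 1L] * cmap$len[idx]
  M <- .batch_tpm(model, rt)
  lM <- matrix(log(pmax(as.vector(M), 1e-300)), nrow = 16L)
  cmat <- matrix(unlist(counts[idx]), nrow = 16L)
  sum(cmat * lM) + sum(log(model$pi[rootH]))
}

## log-likelihood restricted to segments whose species branch has state z
.state_ll <- function(counts, cmap, Z, rate, z, model) {
  idx <- seq_len(cmap$n_aug)[-cmap$root]
  idx <- idx[Z[cmap$sbranch[idx]] == z]
  if (!length(idx)) return(0)
  M <- .batch_tpm(model, rate * cmap$len[idx])
  lM <- matrix(log(pmax(as.vector(M), 1e-300)), nrow = 16L)
  cmat <- matrix(unlist(counts[idx]), nrow = 16L)
  sum(cmat * lM)
}

#' Metropolis-Hastings update of the conserved and accelerated rates
#'
#' Multiplicative log-normal random-walk proposals; acceptance combines
#' the complete-data likelihood ratio over segments in the matching state,
#' the Gamma prior ratio and the proposal Jacobian.  Proposals violating
#' r1 < 1 or r2 > r1 are rejected outright.
#'
#' @param state sampler state (see \code{\link{run_chain}}).
#' @return updated state (fields \code{r1}, \code{r2}, acceptance flags in
#'   \code{acc}).
#' @export
mh_update_rates <- function(state) {
  cfg <- state$config
  counts <- state$counts
  ## r1
  r1p <- state$r1 * exp(state$scales$r1 * stats::rnorm(1L))
  state$acc$r1_try <- state$acc$r1_try + 1L
  if (r1p < 1 && r1p < state$r2) {
    d <- .state_ll(counts, state$cmap, state$Z, r1p, 1L, state$model) -
      .state_ll(counts, state$cmap, state$Z, state$r1, 1L, state$model) +
      stats::dgamma(r1p, cfg$r1_shape, scale = cfg$r1_scale, log = TRUE) -
      stats::dgamma(state$r1, cfg$r1_shape, scale = cfg$r1_scale, log = TRUE) +
      log(r1p / state$r1)
    if (log(stats::runif(1L)) < d) {
      state$r1 <- r1p
      state$acc$r1 <- state$acc$r1 + 1L
    }
  }
  ## r2
  r2p <- state$r2 * exp(state$scales$r2 * stats::rnorm(1L))
  state$acc$r2_try <- state$acc$r2_try + 1L
  if (r2p > state$r1) {
    d <- .state_ll(counts, state$cmap, state$Z, r2p, 2L, state$model) -
      .state_ll(counts, state$cmap, state$Z, state$r2, 2L, state$model) +
      stats::dgamma(r2p, cfg$r2_shape, scale = cfg$r2_scale, log = TRUE) -
      stats::dgamma(state$r2, cfg$r2_shape, scale = cfg$r2_scale, log = TRUE) +
      log(r2p / state$r2)
    if (log(stats::runif(1L)) < d) {
      state$r2 <- r2p
      state$acc$r2 <- state$acc$r2 + 1L
    }
  }
  state
}

## reflect a value into (lo, hi)
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Metropolis-Hastings update of the stationary composition parameter
#'
#' Reflected Gaussian random walk on piA in (0, 1/2); acceptance combines
#' the complete-data likelihood under the rebuilt rate matrix and the
#' Beta(gamma, gamma) prior on 2*piA.  The eigendecomposition is
#' refreshed on acceptance.
#'
#' @param state sampler state.
#' @return updated state.
#' @export
mh_update_pi <- function(state) {
  cfg <- state$config
  piAp <- .reflect(state$piA + state$scales$piA * stats::rnorm(1L), 0, 0.5)
  piAp <- min(max(piAp, 1e-6), 0.5 - 1e-6)
  modp <- build_q(state$neutral, piAp, cfg$gamma)
  rates <- c(1, state$r1, state$r2)
  rootH <- state$H[, state$cmap$root]
  state$acc$pi_try <- state$acc$pi_try + 1L
  d <- .complete_ll(state$counts, state$cmap, state$Z, rates, modp, rootH) -
    .complete_ll(state$counts, state$cmap, state$Z, rates, state$model,
                 rootH) +
    stats::dbeta(2 * piAp, cfg$gamma, cfg$gamma, log = TRUE) -
    stats::dbeta(2 * state$piA, cfg$gamma, cfg$gamma, log = TRUE)
  if (log(stats::runif(1L)) < d) {
    state$piA <- piAp
    state$model <- modp
    state$acc$pi <- state$acc$pi + 1L
  }
  state
}

## marginal (H integrated out) pruning log-likelihood of the current state
.state_pruning_ll <- function(state, G = NULL, cmap = NULL) {
  if (is.null(G)) G <- state$G
  if (is.null(cmap)) cmap <- map_gene_tree(G, state$st)
  locus_loglik_pruning(state$locus, G, state$st, state$Z,
                       c(1, state$r1, state$r2), state$model,
                       cmap = cmap, sites = state$sites)
}

## complete-data log-likelihood of the gene-node bases Hg (l x n_gene),
## with boundary (speciation-crossing) bases marginalized analytically:
## each gene edge's transition matrix is the ordered product of its
## segment matrices.  This is the target used by the gene-tree moves,
## which keep Hg fixed while G changes (Hg is indexed by gene-node ids,
## which persist across SPR and height moves).
.gene_complete_ll <- function(Gparent, root, cmap, Hg, Z, rates, model) {
  ng <- cmap$n_gene
  idx <- seq_len(cmap$n_aug)[-cmap$root]
  rt <- rates[Z[cmap$sbranch[idx]] + 1L] * cmap$len[idx]
  Mseg <- .batch_tpm(model, rt)
  pos <- integer(cmap$n_aug)      # aug node -> column offset in Mseg
  pos[idx] <- seq_along(idx)
  ll <- 0
  for (i in seq_len(ng)) {
    p <- Gparent[i]
    if (p == 0L) next
    ## walk the aug chain child -> ... -> parent, collecting segments
    M <- Mseg[, (4L * pos[i] - 3L):(4L * pos[i]), drop = FALSE]
    a <- cmap$parent[i]
    while (a > ng) {               # boundary nodes have ids > n_gene
      k <- pos[a]
      M <- Mseg[, (4L * k - 3L):(4L * k), drop = FALSE] %*% M
      a <- cmap$parent[a]
    }
    cnt <- tabulate((Hg[, i] - 1L) * 4L + Hg[, p], nbins = 16L)
    ll <- ll + sum(cnt * log(pmax(as.vector(M), 1e-300)))
  }
  ll + sum(log(model$pi[Hg[, root]]))
}

## convenience wrapper for the current or a proposed gene tree
.state_gene_ll <- function(state, G, cmap) {
  .gene_complete_ll(G$parent, G$root, cmap,
                    state$H[, seq_len(cmap$n_gene), drop = FALSE],
                    state$Z, c(1, state$r1, state$r2), state$model)
}

## log guidance weight: transition probability of the moving subtree's
## sequence from a candidate node's imputed sequence over the height gap
.guide_weight <- function(state, Hc, Hg, dt) {
  M <- transition_matrix(state$model, 1, max(dt, 1e-8))
  cnt <- tabulate((Hg - 1L) * 4L + Hc, nbins = 16L)
  sum(cnt * as.vector(log(pmax(M, 1e-300))))
}

#' Guided subtree-prune-regraft move on the gene tree
#'
#' Detaches a uniformly chosen non-root gene subtree, enumerates candidate
#' regraft edges whose time span can legally host the new parent (the
#' species branch at the regraft height must be ancestral to both joining
#' lineages), weights candidates by the transition probability of the
#' subtree's imputed root sequence from each candidate's imputed sequence,
#' draws a candidate softmax-proportionally and a height uniformly in the
#' legal interval (exponentially above the root), and accepts by a
#' Metropolis-Hastings ratio combining the coalescent prior, the
#' complete-data likelihood of the imputed gene-node bases (boundary
#' bases marginalized analytically) and the forward/reverse proposal
#' probabilities.  Because the proposal is guided by H, the acceptance
#' must condition on H as well; the gene-node bases are held fixed in
#' the state across the move.
#'
#' @param state sampler state.
#' @return updated state (fields \code{G}, \code{cmap} on acceptance;
#'   counters in \code{acc}).
#' @export
guided_spr_move <- function(state) {
  G <- state$G; st <- state$st
  S <- G$n_tips; ng <- 2L * S - 1L
  if (S < 3L) return(state)
  state$acc$spr_try <- state$acc$spr_try + 1L
  sets <- .lineage_sets(G, st)
  nonroot <- setdiff(seq_len(ng), G$root)
  g <- nonroot[sample.int(length(nonroot), 1L)]
  p <- G$parent[g]
  ch <- .g_children(G)
  sib <- setdiff(ch[[p]], g)
  q <- G$parent[p]
  ## remaining tree = everything outside subtree(g) and p
  in_sub <- logical(ng)
  stack <- g
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    in_sub[x] <- TRUE
    stack <- c(stack, ch[[x]])
  }
  remain <- which(!in_sub & seq_len(ng) != p)
  rem_parent <- G$parent
  rem_parent[sib] <- q               # splice out p
  rem_root <- if (q == 0L) sib else G$root
  ## candidate edges: (c, rem_parent[c]) for c in remain with parent in
  ## remain; plus the virtual edge above the remaining root
  h_g <- G$height[g]
  theta_N <- st$theta[st$n_nodes]
  cand <- integer(0); lo <- numeric(0); hi <- numeric(0); lw <- numeric(0)
  Hg <- state$H[, g]
  for (c0 in remain) {
    pa <- rem_parent[c0]
    lo_c <- max(h_g, G$height[c0], .mrca_height2(st, sets, g, c0))
    hi_c <- if (c0 == rem_root) Inf else G$height[pa]
    if (lo_c >= hi_c) next
    cand <- c(cand, c0); lo <- c(lo, lo_c); hi <- c(hi, hi_c)
    lw <- c(lw, .guide_weight(state, state$H[, c0], Hg,
                              abs(G$height[c0] - h_g)))
  }
  if (!length(cand)) {
    state$acc$spr_skip <- state$acc$spr_skip + 1L
    return(state)
  }
  ## reverse-candidate: p currently sits on the edge above sib
  c_old <- sib
  io <- match(c_old, cand)
  if (is.na(io)) {                     # current position must be re-reachable
    state$acc$spr_skip <- state$acc$spr_skip + 1L
    return(state)
  }
  w <- exp(lw - max(lw))
  i_new <- sample.int(length(cand), 1L, prob = w)
  c_new <- cand[i_new]
  lsel_fwd <- log(w[i_new] / sum(w))
  lsel_rev <- log(w[io] / sum(w))
  ## height proposal
  if (is.finite(hi[i_new])) {
    h_new <- stats::runif(1L, lo[i_new], hi[i_new])
    ldens_fwd <- -log(hi[i_new] - lo[i_new])
  } else {
    rate <- if (theta_N > 0) 2 / theta_N else 1
    h_new <- lo[i_new] + stats::rexp(1L, rate)
    ldens_fwd <- log(rate) - rate * (h_new - lo[i_new])
  }
  h_old <- G$height[p]
  if (is.finite(hi[io])) {
    ldens_rev <- -log(hi[io] - lo[io])
    if (h_old <= lo[io] || h_old >= hi[io]) {
      ## numerically outside its own legal interval: skip defensively
      state$acc$spr_skip <- state$acc$spr_skip + 1L
      return(state)
    }
  } else {
    rate <- if (theta_N > 0) 2 / theta_N else 1
    ldens_rev <- log(rate) - rate * (h_old - lo[io])
  }
  ## build proposed tree: reattach p onto edge above c_new at h_new
  newp <- rem_parent
  newp[c_new] <- p
  newp[p] <- if (c_new == rem_root) 0L else rem_parent[c_new]
  newp[g] <- p
  newh <- G$height
  newh[p] <- h_new
  Gp <- tryCatch(gene_tree(newp, newh, S), error = function(e) NULL)
  if (is.null(Gp)) {
    state$acc$spr_skip <- state$acc$spr_skip + 1L
    return(state)
  }
  cmapp <- tryCatch(map_gene_tree(Gp, st), error = function(e) NULL)
  if (is.null(cmapp)) {
    state$acc$spr_skip <- state$acc$spr_skip + 1L
    return(state)
  }
  if (is.null(state$cur_gll)) {
    state$cur_gll <- .state_gene_ll(state, G, state$cmap)
    state$cur_prior <- msc_log_density(G, st, state$cmap)
  }
  prior_p <- msc_log_density(Gp, st, cmapp)
  gll_p <- .state_gene_ll(state, Gp, cmapp)
  la <- prior_p + gll_p - state$cur_prior - state$cur_gll +
    (lsel_rev + ldens_rev) - (lsel_fwd + ldens_fwd)
  if (is.finite(la) && log(stats::runif(1L)) < la) {
    state$G <- Gp
    state$cmap <- cmapp
    state$cur_gll <- gll_p
    state$cur_prior <- prior_p
    state$acc$spr <- state$acc$spr + 1L
  }
  state
}

#' Local node-height moves on the gene tree
#'
#' For each internal gene node, proposes a height uniformly in a window
#' centred at the current height, truncated to the legal interval (above
#' the children's heights and the species MRCA of the clade; below the
#' parent), and accepts by Metropolis-Hastings with the coalescent prior
#' and complete-data (gene-node H) likelihood ratios, including the truncation
#' correction of the uniform proposal.
#'
#' @param state sampler state.
#' @param window proposal window width (substitution units); default half
#'   the species-tree height.
#' @return updated state.
#' @export
node_height_move <- function(state, window = NULL) {
  G <- state$G; st <- state$st
  S <- G$n_tips
  if (is.null(window)) window <- 0.5 * st$height[st$n_nodes]
  sets <- .lineage_sets(G, st)
  ch <- sets$ch
  if (!is.null(state$cur_gll)) {
    cur_ll <- state$cur_gll
    cur_prior <- state$cur_prior
  } else {
    cur_ll <- .state_gene_ll(state, G, state$cmap)
    cur_prior <- msc_log_density(G, st, state$cmap)
  }
  nodes <- (S + 1L):(2L * S - 1L)
  n_h <- state$config$n_height
  if (!is.null(n_h) && n_h < length(nodes)) {
    nodes <- sort(sample(nodes, n_h))
  }
  for (v in nodes) {
    h <- G$height[v]
    kids <- ch[[v]]
    lo <- max(G$height[kids], .mrca_height2(st, sets, kids[1L], kids[2L]))
    hi <- if (G$parent[v] == 0L) Inf else G$height[G$parent[v]]
    I_fwd <- c(max(lo, h - window / 2), min(hi, h + window / 2))
    hp <- stats::runif(1L, I_fwd[1L], I_fwd[2L])
    I_rev <- c(max(lo, hp - window / 2), min(hi, hp + window / 2))
    state$acc$hgt_try <- state$acc$hgt_try + 1L
    Gp <- G
    Gp$height[v] <- hp
    cmapp <- tryCatch(map_gene_tree(Gp, st, sets),
                      error = function(e) NULL)
    if (is.null(cmapp)) next
    prp <- tryCatch(msc_log_density(Gp, st, cmapp), error = function(e) NULL)
    if (is.null(prp)) next
    llp <- .state_gene_ll(state, Gp, cmapp)
    la <- (prp + llp) - (cur_prior + cur_ll) +
      log(I_fwd[2L] - I_fwd[1L]) - log(I_rev[2L] - I_rev[1L])
    if (is.finite(la) && log(stats::runif(1L)) < la) {
      G <- Gp
      state$cmap <- cmapp
      cur_ll <- llp
      cur_prior <- prp
      state$acc$hgt <- state$acc$hgt + 1L
    }
  }
  state$G <- G
  state$cur_gll <- cur_ll
  state$cur_prior <- cur_prior
  state
}

## draw (r1, r2) from their (constrained) priors by rejection
.prior_rates <- function(cfg) {
  repeat {
    r1 <- stats::rgamma(1L, cfg$r1_shape, scale = cfg$r1_scale)
    if (r1 < 1) break
  }
  repeat {
    r2 <- stats::rgamma(1L, cfg$r2_shape, scale = cfg$r2_scale)
    if (r2 > r1) break
  }
  c(r1, r2)
}

## fresh draw from the joint prior (used as the Wang-Landau surrogate at
## the first block step and for chain initialization)
.prior_state_draw <- function(state) {
  cfg <- state$config
  st <- state$st
  r <- .prior_rates(cfg)
  state$r1 <- r[1L]; state$r2 <- r[2L]
  state$piA <- min(max(stats::rbeta(1L, cfg$gamma, cfg$gamma) / 2, 1e-4),
                   0.5 - 1e-4)
  state$model <- build_q(state$neutral, state$piA, cfg$gamma)
  state$alpha <- stats::runif(1L)
  state$beta <- stats::runif(1L)
  state$reversion <- if (cfg$dollo) 0 else stats::runif(1L)
  phi <- build_phi(state$alpha, state$beta, cfg$dollo, state$reversion)
  zs <- sample_Z(matrix(0, st$n_nodes, 3L), phi, state$allowed, st,
                 cfg$root_state)
  state$Z <- zs$Z
  if (state$method == "gt") {
    state$G <- sample_gene_tree(st)
    state$cmap <- map_gene_tree(state$G, st)
  }
  state
}

## one full Gibbs sweep over the active site subset
.gibbs_sweep <- function(state) {
  cfg <- state$config
  rates <- c(1, state$r1, state$r2)
  state$H <- impute_H(state$locus, state$st, state$cmap, state$Z, rates,
                      state$model, state$sites)
  state$counts <- .segment_counts(state$cmap, state$H)
  be <- branch_emission(state$H, state$cmap, state$model, rates, state$st)
  phi <- build_phi(state$alpha, state$beta, cfg$dollo, state$reversion)
  zs <- sample_Z(be$emis, phi, state$allowed, state$st, cfg$root_state)
  state$Z <- zs$Z
  state <- mh_update_rates(state)
  state <- mh_update_pi(state)
  if (state$method == "gt") {
    ## conditioning variables changed: invalidate the move-block cache
    state$cur_gll <- NULL
    state$cur_prior <- NULL
    for (k in seq_len(cfg$k_spr)) state <- guided_spr_move(state)
    state <- node_height_move(state)
  }
  ab <- gibbs_alpha_beta(state$Z, state$st, cfg$dollo)
  state$alpha <- ab$alpha
  state$beta <- ab$beta
  state$reversion <- ab$reversion
  state
}

## sweep with no data: exact independent draw from the prior
.prior_sweep <- function(state) .prior_state_draw(state)

.init_state <- function(locus, st, model_id, config, method) {
  st <- with_desc_cache(st)
  allowed <- model_spec(st, model_id)
  neutral <- attr(config, "neutral")
  if (is.null(neutral)) neutral <- jc_model()
  at_frac <- mean(locus$char %in% c("a", "t"))
  piA <- min(max(at_frac / 2, 0.05), 0.45)
  state <- list(
    locus = locus, st = st, method = method, config = config,
    allowed = allowed, neutral = neutral, sites = NULL,
    r1 = 0.2, r2 = 2, piA = piA,
    model = build_q(neutral, piA, config$gamma),
    alpha = 0.5, beta = 0.2, reversion = 0,
    Z = rep(1L, st$n_nodes),
    scales = list(r1 = 0.4, r2 = 0.4, piA = 0.05),
    acc = list(r1 = 0L, r1_try = 0L, r2 = 0L, r2_try = 0L,
               pi = 0L, pi_try = 0L, spr = 0L, spr_try = 0L,
               spr_skip = 0L, hgt = 0L, hgt_try = 0L)
  )
  state$Z[st$n_nodes] <- config$root_state
  ## states must respect the model restriction
  for (s in seq_len(st$n_nodes)) {
    if (!allowed[s, state$Z[s] + 1L]) {
      state$Z[s] <- which(allowed[s, ])[1L] - 1L
    }
  }
  if (method == "gt") {
    state$G <- sample_gene_tree(st)
    state$cmap <- map_gene_tree(state$G, st)
  } else {
    state$G <- NULL
    state$cmap <- species_cmap(st)
  }
  state
}

## burn-in adaptation of proposal scales toward ~0.3 acceptance
.adapt_scales <- function(state, prev) {
  for (nm in c("r1", "r2", "pi")) {
    tries <- state$acc[[paste0(nm, "_try")]] - prev[[paste0(nm, "_try")]]
    if (tries < 10L) next
    rate <- (state$acc[[nm]] - prev[[nm]]) / tries
    key <- if (nm == "pi") "piA" else nm
    state$scales[[key]] <- state$scales[[key]] * exp(rate - 0.3)
    state$scales[[key]] <- min(max(state$scales[[key]], 1e-3), 5)
  }
  state
}

#' Run the collapsed Gibbs sampler for one locus
#'
#' @param locus a \code{locus_alignment}.
#' @param st a \code{spectree} with theta and target/outgroup sets.
#' @param model_id "M0", "M1" or "M2".
#' @param config a \code{\link{chain_config}} list; attach a
#'   \code{neutral_model} as \code{attr(config, "neutral")} (default
#'   Jukes-Cantor).
#' @param seed integer seed (all randomness flows from it).
#' @param method "gt" (gene-tree model) or "st" (species-tree model).
#' @return list with \code{draws} (data frame of thinned posterior draws:
#'   iter, loglik, r1, r2, piA, alpha, beta, n_accel, topology),
#'   \code{pp_accel} (named per-branch posterior P(Z_s = 2 | Y)),
#'   \code{post_mean} (posterior means), \code{acceptance} (MH rates),
#'   \code{model_id}, \code{method}.
#' @export
run_chain <- function(locus, st, model_id = "M2", config = chain_config(),
                      seed = 1L, method = c("gt", "st")) {
  method <- match.arg(method)
  set.seed(seed)
  state <- .init_state(locus, st, model_id, config, method)
  n_total <- config$n_burn + config$n_iter
  keep <- integer(0)
  N <- st$n_nodes
  z2 <- numeric(N)
  nz <- 0L
  rows <- list()
  prev_acc <- state$acc
  for (it in seq_len(n_total)) {
    state <- .gibbs_sweep(state)
    if (config$adapt && it <= config$n_burn && it %% 50L == 0L) {
      state <- .adapt_scales(state, prev_acc)
      prev_acc <- state$acc
    }
    if (it > config$n_burn && (it - config$n_burn) %% config$thin == 0L) {
      nz <- nz + 1L
      z2 <- z2 + (state$Z == 2L)
      ll <- if (method == "gt") {
        .state_pruning_ll(state, state$G, state$cmap)
      } else {
        species_tree_loglik(locus, st, state$Z, c(1, state$r1, state$r2),
                            state$model)
      }
      rows[[nz]] <- data.frame(
        iter = it, loglik = ll, r1 = state$r1, r2 = state$r2,
        piA = state$piA, alpha = state$alpha, beta = state$beta,
        n_accel = sum(state$Z == 2L),
        topology = if (method == "gt") .topology_id(state$G) else "species",
        stringsAsFactors = FALSE)
    }
  }
  draws <- do.call(rbind, rows)
  pp <- z2 / max(nz, 1L)
  names(pp) <- st$labels
  acc <- state$acc
  rate <- function(a, b) if (b > 0L) a / b else NA_real_
  list(draws = draws,
       pp_accel = pp,
       post_mean = c(r1 = mean(draws$r1), r2 = mean(draws$r2),
                     piA = mean(draws$piA)),
       acceptance = c(r1 = rate(acc$r1, acc$r1_try),
                      r2 = rate(acc$r2, acc$r2_try),
                      piA = rate(acc$pi, acc$pi_try),
                      spr = rate(acc$spr, acc$spr_try),
                      height = rate(acc$hgt, acc$hgt_try)),
       model_id = model_id, method = method)
}
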