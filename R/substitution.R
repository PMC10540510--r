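## Strand-symmetric GTR substitution model and Felsenstein pruning.
##
## The stationary distribution has a single free parameter piA with
## pi = (piA, 1/2 - piA, 1/2 - piA, piA) (A,C,G,T); exchangeabilities come
## from the neutral model.  The generator is eigendecomposed through its
## symmetrization diag(sqrt(pi)) Q diag(1/sqrt(pi)), which has a real
## spectrum for any reversible model.

#' Build the locus substitution model
#'
#' \code{Q[i,j] = s[i,j] * pi[j]} off-diagonal with exchangeabilities
#' \code{s} from the neutral model, diagonal chosen so rows sum to zero,
#' rescaled to an expected rate of 1 substitution/site per unit branch
#' length at rate multiplier 1.
#'
#' @param neutral a \code{neutral_model} (see \code{\link{read_neutral_model}}).
#' @param piA stationary frequency of A (equals that of T); in (0, 0.5).
#' @param gamma hyperparameter of the \code{Beta(gamma, gamma)} prior on
#'   \code{2*piA} (carried along for the sampler).
#' @return a \code{subst_model}: list with \code{Q}, \code{pi},
#'   \code{piA}, \code{gamma}, and eigendecomposition \code{P},
#'   \code{Pinv}, \code{lambda} with \code{Q = P diag(lambda) Pinv}.
#' @export
build_q <- function(neutral, piA, gamma = 10) {
  if (!is.finite(piA) || piA <= 0 || piA >= 0.5) {
    stop("piA must lie strictly inside (0, 0.5)")
  }
  pi <- c(piA, 0.5 - piA, 0.5 - piA, piA)
  Q <- sweep(neutral$exch, 2L, pi, "*")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))          # symmetric for reversible Q
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- e$vectors / sp                  # rows scaled: diag(1/sp) %*% U
  Pinv <- t(e$vectors) * rep(sp, each = 4L)  # t(U) %*% diag(sp)
  structure(list(Q = Q, pi = pi, piA = piA, gamma = gamma,
                 P = P, Pinv = Pinv, lambda = e$values),
            class = "subst_model")
}

#' Transition probability matrix
#'
#' \code{exp(r * t * Q)} via the cached eigendecomposition.  Small negative
#' entries from round-off (above -1e-12) are clipped to zero.
#'
#' @param model a \code{subst_model}.
#' @param r rate multiplier (>= 0).
#' @param t elapsed branch length (>= 0).
#' @return 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(model, r, t) {
  if (r < 0 || t < 0) stop("r and t must be non-negative")
  M <- model$P %*% (exp(r * t * model$lambda) * model$Pinv)
  if (any(!is.finite(M))) stop("non-finite transition matrix")
  if (any(M < -1e-12)) stop("transition matrix entry below -1e-12")
  M[M < 0] <- 0
  M
}

## tip likelihood mask for encoded bases (integers with NA = missing)
.tip_mask_from_codes <- function(codes) {
  l <- length(codes)
  m <- matrix(0, 4L, l)
  ok <- !is.na(codes)
  m[cbind(codes[ok], which(ok))] <- 1
  m[, !ok] <- 1
  m
}

## batched transition matrices: one matrix per (rate*t) value, computed in
## a single BLAS multiply P %*% [exp(rt L) * Pinv]_stacked
.batch_tpm <- function(model, rt) {
  n <- length(rt)
  E <- exp(model$lambda %o% rt)                    # 4 x n
  B <- model$Pinv[, rep.int(seq_len(4L), n)] *
    E[, rep(seq_len(n), each = 4L), drop = FALSE]
  M <- model$P %*% B                               # 4 x 4n
  M[M < 0] <- 0
  M
}

## per-segment transition matrices of an augmented tree as a list
.edge_matrices <- function(cmap, Z, rates, model) {
  n <- cmap$n_aug
  idx <- seq_len(n)[-cmap$root]
  rt <- rates[Z[cmap$sbranch[idx]] + 1L] * cmap$len[idx]
  M <- .batch_tpm(model, rt)
  out <- vector("list", n)
  for (k in seq_along(idx)) {
    out[[idx[k]]] <- M[, (4L * k - 3L):(4L * k), drop = FALSE]
  }
  out
}

## generic pruning over an augmented (or plain) tree description.
## cm: list with n_aug, parent, root, and cached kids/ord (children before
## parents); Ms[[i]] is the transition matrix above node i; tipmask is a
## list over tips 1..S of 4 x l masks.  Partial likelihood vectors are
## rescaled per site only when underflow threatens.
.prune_loglik <- function(cm, Ms, tipmask, pi, return_partials = FALSE) {
  l <- ncol(tipmask[[1L]])
  n_tips <- length(tipmask)
  L <- vector("list", cm$n_aug)
  logscale <- numeric(l)
  kids <- cm$kids
  ord <- cm$ord
  nint <- 0L
  for (i in ord) {
    if (i <= n_tips) {
      L[[i]] <- tipmask[[i]]
    } else {
      ks <- kids[[i]]
      acc <- Ms[[ks[1L]]] %*% L[[ks[1L]]]
      for (c in ks[-1L]) acc <- acc * (Ms[[c]] %*% L[[c]])
      nint <- nint + 1L
      if (nint %% 8L == 0L) {       # periodic underflow guard
        mx <- pmax(acc[1L, ], acc[2L, ], acc[3L, ], acc[4L, ])
        if (any(mx < 1e-60)) {
          mx[mx <= 0] <- 1
          logscale <- logscale + log(mx)
          acc <- acc * rep(1 / mx, each = 4L)
        }
      }
      L[[i]] <- acc
    }
  }
  site_ll <- log(colSums(pi * L[[cm$root]])) + logscale
  if (return_partials) list(loglik = sum(site_ll), site = site_ll, L = L)
  else sum(site_ll)
}

## children lists and children-before-parents order for an aug tree
.aug_traversal <- function(parent, root, n) {
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  list(kids = kids, ord = .topo_order(parent, root))
}

## children-before-parent ordering from a parent map (memoized depth walk)
.topo_order <- function(parent, root) {
  n <- length(parent)
  depth <- rep.int(-1L, n)
  depth[root] <- 0L
  for (i in seq_len(n)) {
    if (depth[i] >= 0L) next
    chain <- i; j <- i
    while (depth[j] < 0L) {
      j <- parent[j]
      chain <- c(chain, j)
    }
    base <- depth[j]
    k <- length(chain) - 1L
    depth[chain[-length(chain)]] <- base + seq.int(k, 1L)
  }
  order(depth, decreasing = TRUE)
}

#' Locus log-likelihood on a gene tree (ancestral states marginalized)
#'
#' Felsenstein pruning over the augmented gene tree in which each segment
#' inside species branch s evolves at rate multiplier \code{rates[Z_s+1]};
#' the stationary distribution is applied at the gene-tree root and
#' missing bases are marginalized.
#'
#' @param locus a \code{locus_alignment}.
#' @param G a \code{genetree}.
#' @param st a \code{spectree}.
#' @param Z integer conservation states (0/1/2) per species node.
#' @param rates numeric c(r0, r1, r2) rate multipliers.
#' @param model a \code{subst_model}.
#' @param cmap optional precomputed map.
#' @param sites optional site (column) subset.
#' @return total log-likelihood.
#' @export
locus_loglik_pruning <- function(locus, G, st, Z, rates, model,
                                 cmap = NULL, sites = NULL) {
  if (is.null(cmap)) cmap <- map_gene_tree(G, st)
  Ms <- .edge_matrices(cmap, Z, rates, model)
  tip_ids <- seq_len(st$n_tips)
  tipmask <- lapply(st$labels[tip_ids], function(tx) {
    m <- locus$mask[[tx]]
    if (is.null(m)) matrix(1, 4L, locus$length) else m
  })
  if (!is.null(sites)) {
    tipmask <- lapply(tipmask, function(m) m[, sites, drop = FALSE])
  }
  .prune_loglik(cmap, Ms, tipmask, model$pi)
}

#' Locus log-likelihood directly on the species tree
#'
#' The concordant-tree special case: pruning on the species tree itself
#' with per-branch rate multipliers \code{rates[Z_s+1]} and the given
#' branch lengths (no coalescent variation).
#'
#' @inheritParams locus_loglik_pruning
#' @param use_tlen use height-consistent branch spans instead of the input
#'   branch lengths (default FALSE).
#' @return total log-likelihood.
#' @export
species_tree_loglik <- function(locus, st, Z, rates, model, sites = NULL,
                                use_tlen = FALSE) {
  N <- st$n_nodes
  bl <- if (use_tlen) st$tlen else st$blen
  Ms <- vector("list", N)
  for (i in seq_len(N - 1L)) {
    Ms[[i]] <- transition_matrix(model, rates[Z[i] + 1L], bl[i])
  }
  tip_ids <- seq_len(st$n_tips)
  tipmask <- lapply(st$labels[tip_ids], function(tx) {
    m <- locus$mask[[tx]]
    if (is.null(m)) matrix(1, 4L, locus$length) else m
  })
  if (!is.null(sites)) {
    tipmask <- lapply(tipmask, function(m) m[, sites, drop = FALSE])
  }
  cm <- list(n_aug = N, parent = st$parent, root = N)
  cm <- c(cm, .aug_traversal(st$parent, N, N))
  .prune_loglik(cm, Ms, tipmask, model$pi)
}
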