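## Three-state conservation process on the species tree.
##
## Z_s = 0 (background, rate 1), 1 (conserved, r1 < 1), 2 (accelerated,
## r2 > r1).  Transitions along species-tree edges follow the prior matrix
## Phi(alpha, beta); under Dollo irreversibility state 2 is absorbing.

#' Prior transition matrix over conservation states
#'
#' @param alpha prior probability of gaining conservation (0 -> 1).
#' @param beta prior probability of losing conservation (1 -> 2).
#' @param dollo if TRUE the accelerated state is absorbing.
#' @param reversion probability of reverting 2 -> 1 (non-Dollo only).
#' @return 3x3 row-stochastic matrix, rows/cols in state order 0,1,2.
#' @export
build_phi <- function(alpha, beta, dollo = TRUE, reversion = 0) {
  for (p in c(alpha, beta, reversion)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("probabilities must be in [0,1]")
  }
  rbind(c(1 - alpha, alpha, 0),
        c(0, 1 - beta, beta),
        if (dollo) c(0, 0, 1) else c(0, reversion, 1 - reversion))
}

#' Allowed conservation states per branch for a model specification
#'
#' M0 allows states {0,1} everywhere; M1 additionally allows the
#' accelerated state on branches leading to target species only (branches
#' whose extant descendants are all targets); M2 allows acceleration on
#' every non-outgroup branch.  Branches whose extant descendants are all
#' outgroup taxa are restricted to {0,1} under every model.
#'
#' @param st a \code{spectree} (with \code{target}/\code{outgroup} sets).
#' @param model "M0", "M1" or "M2".
#' @return N x 3 logical matrix; \code{[s, z+1]} says state z is allowed
#'   on branch s.
#' @export
model_spec <- function(st, model = c("M0", "M1", "M2")) {
  model <- match.arg(model)
  N <- st$n_nodes
  desc <- .tip_descendants(st)
  tips <- st$labels[seq_len(st$n_tips)]
  tgt <- tips %in% st$target
  out <- tips %in% st$outgroup
  all_target <- vapply(desc, function(d) all(tgt[d]), TRUE)
  all_out <- vapply(desc, function(d) all(out[d]), TRUE)
  allowed <- matrix(TRUE, N, 3L)
  allowed[, 3L] <- switch(model,
    M0 = FALSE,
    M1 = all_target & !all_out,
    M2 = !all_out)
  allowed
}

## per-segment 16-cell pattern counts; index (child-1)*4 + parent so that
## sum(counts * as.vector(M)) gives sum over sites of M[parent, child]
.segment_counts <- function(cmap, H) {
  n <- cmap$n_aug
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == cmap$root) next
    p <- cmap$parent[i]
    counts[[i]] <- tabulate((H[, i] - 1L) * 4L + H[, p], nbins = 16L)
  }
  counts
}

#' Per-branch, per-state log emissions given imputed sequences
#'
#' For species branch s and state z, sums \code{log M(r_z, t_seg)[parent
#' base, child base]} over every gene-branch segment lying inside s and
#' every site.  The stationary density of the gene-tree root base is
#' returned separately (it does not depend on Z).
#'
#' @param H l x n_aug integer matrix of bases at every augmented node.
#' @param cmap a \code{coalmap}.
#' @param model a \code{subst_model}.
#' @param rates c(r0, r1, r2).
#' @param st a \code{spectree}.
#' @return list with \code{emis} (N x 3 matrix of log emissions) and
#'   \code{root_ll} (log stationary density of root bases).
#' @export
branch_emission <- function(H, cmap, model, rates, st) {
  if (anyNA(H)) stop("H must be fully imputed")
  counts <- .segment_counts(cmap, H)
  N <- st$n_nodes
  emis <- matrix(0, N, 3L)
  idx <- seq_len(cmap$n_aug)[-cmap$root]
  cmat <- matrix(unlist(counts[idx]), nrow = 16L)
  grp <- cmap$sbranch[idx]
  for (z in 0:2) {
    M <- .batch_tpm(model, rates[z + 1L] * cmap$len[idx])
    lM <- matrix(log(pmax(as.vector(M), 1e-300)), nrow = 16L)
    contrib <- colSums(cmat * lM)
    agg <- rowsum(contrib, grp)
    emis[as.integer(rownames(agg)), z + 1L] <- agg[, 1L]
  }
  root_ll <- sum(log(model$pi[H[, cmap$root]]))
  list(emis = emis, root_ll = root_ll)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Sample conservation states by forward-backward on the species tree
#'
#' Exact conditional draw of Z given per-branch log emissions, the prior
#' transition matrix and the allowed-state restriction: an upward pass of
#' partial log-sums followed by a root-to-tips ancestral draw.
#'
#' @param emis N x 3 matrix of per-branch log emissions.
#' @param phi 3x3 prior transition matrix (\code{\link{build_phi}}).
#' @param allowed N x 3 logical restriction (\code{\link{model_spec}}).
#' @param st a \code{spectree}.
#' @param root_state state fixed at the root (default 0, background).
#' @return list with \code{Z} (integer states) and \code{logZ} (the log
#'   normalizer, i.e. log sum over allowed Z of prior x emission).
#' @export
sample_Z <- function(emis, phi, allowed, st, root_state = 0L) {
  N <- st$n_nodes
  lphi <- log(phi)
  up <- matrix(-Inf, N, 3L)
  ## post-order: canonical internal ordering is already post-order
  for (s in seq_len(N)) {
    for (z in 0:2) {
      if (!allowed[s, z + 1L]) next
      v <- emis[s, z + 1L]
      if (s > st$n_tips) {
        for (c in st$children[[s]]) {
          v <- v + .logsumexp(lphi[z + 1L, ] + up[c, ])
        }
      }
      up[s, z + 1L] <- v
    }
  }
  if (!allowed[N, root_state + 1L] || !is.finite(up[N, root_state + 1L])) {
    stop("no allowed state at the root")
  }
  Z <- integer(N)
  Z[N] <- root_state
  for (s in rev(seq_len(N - 1L))) {   # parents come after children
    zp <- Z[st$parent[s]]
    lw <- lphi[zp + 1L, ] + up[s, ]
    if (all(!is.finite(lw))) stop("no allowed state on branch ", st$labels[s])
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(lw)] <- 0
    Z[s] <- sample.int(3L, 1L, prob = w) - 1L
  }
  list(Z = Z, logZ = up[N, root_state + 1L])
}

#' Gibbs update of the conservation-gain/loss hyperparameters
#'
#' With uniform priors, the conditional posteriors given the current state
#' configuration are \code{alpha ~ Beta(1 + n01, 1 + n00)} and
#' \code{beta ~ Beta(1 + n12, 1 + n11)} where \code{nxy} counts
#' parent-to-child transitions x -> y over species-tree edges; the
#' non-Dollo reversion probability is updated analogously from
#' \code{n21, n22}.
#'
#' @param Z integer state vector.
#' @param st a \code{spectree}.
#' @param dollo logical.
#' @return list \code{alpha}, \code{beta}, \code{reversion}.
#' @export
gibbs_alpha_beta <- function(Z, st, dollo = TRUE) {
  N <- st$n_nodes
  zp <- Z[st$parent[seq_len(N - 1L)]]
  zc <- Z[seq_len(N - 1L)]
  n <- function(a, b) sum(zp == a & zc == b)
  list(alpha = stats::rbeta(1L, 1 + n(0L, 1L), 1 + n(0L, 0L)),
       beta = stats::rbeta(1L, 1 + n(1L, 2L), 1 + n(1L, 1L)),
       reversion = if (dollo) 0 else
         stats::rbeta(1L, 1 + n(2L, 1L), 1 + n(2L, 2L)))
}

#' Call accelerated branches and count independent acceleration events
#'
#' Branches whose posterior probability of the accelerated state reaches
#' the threshold are called accelerated; independent events are maximal
#' accelerated subtrees whose parent branch is not accelerated.
#'
#' @param pp numeric vector of per-branch P(Z_s = 2 | Y), length N.
#' @param st a \code{spectree}.
#' @param threshold calling threshold (default 0.5).
#' @return list with \code{accelerated} (branch labels), \code{n_events},
#'   and \code{pattern} (a compact "label:+" string).
#' @export
call_acceleration <- function(pp, st, threshold = 0.5) {
  N <- st$n_nodes
  acc <- !is.na(pp) & pp >= threshold
  roots <- which(acc & (st$parent == 0L | !acc[pmax(st$parent, 1L)]))
  list(accelerated = st$labels[acc], n_events = length(roots),
       pattern = paste(st$labels[roots], collapse = "+"))
}
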