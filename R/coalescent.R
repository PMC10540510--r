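## Multispecies-coalescent prior over gene trees.
##
## A gene tree holds one lineage per extant species (tips 1..S share ids
## with the species-tree tips).  Node heights are measured in the species
## tree's substitution-length units, so the pairwise coalescence rate
## within species branch s is 2/theta_s.

#' Construct a gene tree
#'
#' @param parent integer parent map over 2S-1 nodes (0 at the root).
#' @param height node heights (tips at 0) in substitution units.
#' @param n_tips number of tips S; tips are nodes 1..S and map to the
#'   species-tree tips with the same ids.
#' @return a \code{genetree} object.
#' @export
gene_tree <- function(parent, height, n_tips) {
  stopifnot(length(parent) == length(height),
            length(parent) == 2L * n_tips - 1L)
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("gene tree must have exactly one root")
  nr <- seq_along(parent)[-root]
  if (any(height[nr] > height[parent[nr]] + 1e-9)) {
    stop("child above parent")
  }
  structure(list(parent = as.integer(parent), height = as.numeric(height),
                 n_tips = as.integer(n_tips), root = root),
            class = "genetree")
}

## children list for a gene tree
.g_children <- function(G) {
  n <- length(G$parent)
  ch <- vector("list", n)
  for (i in seq_len(n)) {
    p <- G$parent[i]
    if (p > 0L) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

## gene nodes in increasing-height (post) order, tips first
.g_order <- function(G) order(G$height, seq_along(G$height))

## descendant species-tip sets per gene node
.g_tipsets <- function(G) {
  n <- length(G$parent)
  out <- vector("list", n)
  for (i in seq_len(G$n_tips)) out[[i]] <- i
  ch <- .g_children(G)
  for (i in .g_order(G)) {
    if (i > G$n_tips) out[[i]] <- unlist(out[ch[[i]]])
  }
  out
}

## lineage descriptors per gene node: bitmask fast path (<= 30 tips) or
## tip-set lists; both expose the species-location and MRCA-height queries
.lineage_sets <- function(G, st) {
  st <- with_desc_cache(st)
  smask <- attr(st, "mask")
  ch <- .g_children(G)
  ord <- .topo_order(G$parent, G$root)
  S <- G$n_tips
  ng <- length(G$parent)
  if (!is.null(smask)) {
    mask <- integer(ng)
    ftip <- integer(ng)
    mask[seq_len(S)] <- bitwShiftL(1L, seq_len(S) - 1L)
    ftip[seq_len(S)] <- seq_len(S)
    for (i in ord) {
      if (i > S) {
        ks <- ch[[i]]
        mask[i] <- bitwOr(mask[ks[1L]], mask[ks[2L]])
        ftip[i] <- ftip[ks[1L]]
      }
    }
    list(kind = "mask", mask = mask, ftip = ftip, smask = smask, ch = ch,
         ord = ord)
  } else {
    list(kind = "list", tipsets = .g_tipsets(G), ch = ch, ord = ord)
  }
}

## species branch containing gene node g at height h
.locate_sp <- function(st, sets, g, h) {
  if (sets$kind == "mask") {
    .sp_locate(st, sets$smask, sets$mask[g], sets$ftip[g], h)
  } else {
    tips <- sets$tipsets[[g]]
    base <- if (length(tips) == 1L) tips else .species_mrca(st, tips)
    if (h < st$height[base] - 1e-9) {
      stop("incompatible coalescence placement (node below species MRCA)")
    }
    .sp_at(st, base, h)
  }
}

## height of the species MRCA of the union of two gene lineages' tip sets
.mrca_height2 <- function(st, sets, g1, g2) {
  if (sets$kind == "mask") {
    m <- bitwOr(sets$mask[g1], sets$mask[g2])
    s <- sets$ftip[g1]
    smask <- sets$smask
    while (bitwAnd(smask[s], m) != m) s <- st$parent[s]
    st$height[s]
  } else {
    s <- .species_mrca(st, unique(c(sets$tipsets[[g1]], sets$tipsets[[g2]])))
    st$height[s]
  }
}

## species branch containing gene node g at height h
.sp_at <- function(st, base, h) {
  s <- base
  while (st$parent[s] != 0L && h >= st$height[st$parent[s]] - 1e-12) {
    s <- st$parent[s]
  }
  s
}

#' Map a gene tree into species-tree branches
#'
#' Cuts every gene-tree branch at each speciation time it crosses, giving
#' the segment decomposition used by the likelihood (each segment lies in
#' exactly one species branch and evolves at that branch's conservation
#' rate), plus the per-branch lineage counts (m_s, n_s) and ordered
#' coalescent waiting times of the multispecies-coalescent density.
#'
#' @param G a \code{genetree}.
#' @param st a \code{spectree}.
#' @param sets optional precomputed lineage descriptors (internal).
#' @return a \code{coalmap}: list with the augmented tree (gene nodes
#'   followed by degree-2 boundary nodes; fields \code{parent}, \code{len},
#'   \code{sbranch}, \code{height}, \code{n_gene}, \code{n_aug},
#'   \code{root}), per-branch counts \code{m}, \code{n}, event waiting
#'   times \code{tau} (with the residual last for non-root branches), and
#'   \code{sp_node} (containing species branch per gene node).
#' @export
map_gene_tree <- function(G, st, sets = NULL) {
  st <- with_desc_cache(st)
  S <- G$n_tips
  if (S != st$n_tips) stop("tip count mismatch")
  ng <- 2L * S - 1L
  if (is.null(sets)) sets <- .lineage_sets(G, st)
  sp_node <- integer(ng)
  for (g in seq_len(ng)) {
    sp_node[g] <- .locate_sp(st, sets, g, G$height[g])
  }
  ## segments: walk each non-root gene edge upward through species branches.
  ## Gene nodes occupy aug ids 1..ng; boundary nodes are appended.  Upper
  ## bound on boundary nodes: (#gene edges) x (#internal species nodes).
  cap <- ng + (ng - 1L) * (st$n_nodes - st$n_tips)
  aparent <- integer(cap); alen <- numeric(cap); abranch <- integer(cap)
  aheight <- numeric(cap)
  aheight[seq_len(ng)] <- G$height
  nxt <- ng
  for (g in seq_len(ng)) {
    p <- G$parent[g]
    if (p == 0L) next
    s <- sp_node[g]
    low <- G$height[g]
    hp <- G$height[p]
    cur <- g
    while (st$parent[s] != 0L && st$height[st$parent[s]] < hp - 1e-12) {
      b <- st$height[st$parent[s]]
      nxt <- nxt + 1L
      aheight[nxt] <- b
      aparent[cur] <- nxt; alen[cur] <- b - low; abranch[cur] <- s
      cur <- nxt; low <- b; s <- st$parent[s]
    }
    aparent[cur] <- p; alen[cur] <- hp - low; abranch[cur] <- s
  }
  aparent <- aparent[seq_len(nxt)]; alen <- alen[seq_len(nxt)]
  abranch <- abranch[seq_len(nxt)]; aheight <- aheight[seq_len(nxt)]
  ## per-branch event bookkeeping
  N <- st$n_nodes
  m <- integer(N); n <- integer(N)
  ev <- vector("list", N)
  for (g in (S + 1L):ng) ev[[sp_node[g]]] <- c(ev[[sp_node[g]]], G$height[g])
  for (s in seq_len(S)) { m[s] <- 1L; n[s] <- 1L }
  tau <- vector("list", N)
  for (s in (S + 1L):N) {
    m[s] <- sum(n[st$children[[s]]])
    k_ev <- length(ev[[s]])
    n[s] <- m[s] - k_ev
    hs <- sort(ev[[s]])
    prev <- st$height[s]
    w <- numeric(0)
    for (h in hs) { w <- c(w, h - prev); prev <- h }
    if (st$parent[s] != 0L) w <- c(w, st$height[st$parent[s]] - prev)
    tau[[s]] <- w
  }
  if (n[N] != 1L) stop("gene tree does not fully coalesce in the root branch")
  trav <- .aug_traversal(aparent, G$root, nxt)
  structure(list(parent = aparent, len = alen, sbranch = abranch,
                 height = aheight, n_gene = ng, n_aug = nxt,
                 root = G$root, m = m, n = n, tau = tau,
                 sp_node = sp_node, kids = trav$kids, ord = trav$ord),
            class = "coalmap")
}

#' Multispecies-coalescent log prior density of a gene tree
#'
#' Sums, over ancestral species branches, the coalescence log-rates
#' \code{log(2/theta_s)} and exponential waiting terms
#' \code{-k(k-1) tau / theta_s} for each coalescence, plus the survival
#' term for the residual interval before the next speciation; the root
#' branch absorbs all remaining lineages (no survival term).
#'
#' @param G a \code{genetree}.
#' @param st a \code{spectree}.
#' @param cmap optional precomputed \code{\link{map_gene_tree}} result.
#' @return log density (base e).
#' @export
msc_log_density <- function(G, st, cmap = NULL) {
  if (is.null(cmap)) cmap <- map_gene_tree(G, st)
  S <- st$n_tips; N <- st$n_nodes
  ll <- 0
  for (s in (S + 1L):N) {
    m_s <- cmap$m[s]; n_s <- cmap$n[s]
    if (m_s <= 1L) next
    th <- st$theta[s]
    if (th <= 0) {
      stop(sprintf("theta is 0 on branch %s with %d lineages",
                   st$labels[s], m_s))
    }
    w <- cmap$tau[[s]]
    nev <- m_s - n_s
    ks <- if (nev > 0L) seq(m_s, n_s + 1L) else integer(0)
    if (nev > 0L) {
      ll <- ll + sum(log(2 / th) - ks * (ks - 1L) / th * w[seq_len(nev)])
    }
    if (st$parent[s] != 0L && n_s > 1L) {
      ll <- ll - n_s * (n_s - 1L) / th * w[nev + 1L]
    }
  }
  ll
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Draws exponential waiting times with rate \code{k(k-1)/theta_s} between
#' coalescences within each species branch (working from the tips to the
#' root in post-order), merging uniformly chosen lineage pairs; lineages
#' surviving to the top of a branch enter the parent branch, and the root
#' branch absorbs everything.  A branch with \code{theta == 0} coalesces
#' its lineages immediately at its base (the zero-ILS limit).
#'
#' Uses R's global RNG; seed with \code{set.seed} for reproducibility.
#'
#' @param st a \code{spectree}.
#' @return a \code{genetree}.
#' @export
sample_gene_tree <- function(st) {
  S <- st$n_tips; N <- st$n_nodes
  parent <- integer(2L * S - 1L)
  height <- numeric(2L * S - 1L)
  nxt <- S
  live <- vector("list", N)   # lineages leaving each species node
  for (s in seq_len(N)) {
    lin <- if (s <= S) s else unlist(live[st$children[[s]]])
    t0 <- st$height[s]
    top <- if (st$parent[s] == 0L) Inf else st$height[st$parent[s]]
    th <- st$theta[s]
    t <- t0
    while (length(lin) > 1L) {
      k <- length(lin)
      if (th <= 0) {
        dt <- 0
      } else {
        dt <- stats::rexp(1L, rate = k * (k - 1L) / th)
      }
      if (t + dt >= top) break
      t <- t + dt
      pair <- sample.int(k, 2L)
      nxt <- nxt + 1L
      parent[lin[pair]] <- nxt
      height[nxt] <- t
      lin <- c(lin[-pair], nxt)
    }
    live[[s]] <- lin
  }
  gene_tree(parent, height, S)
}

#' Serialize a gene tree to newick
#' @param G a \code{genetree}.
#' @param st a \code{spectree} providing tip labels.
#' @return newick string with branch lengths in substitution-time units.
#' @export
gene_tree_newick <- function(G, st) {
  ch <- .g_children(G)
  rec <- function(i) {
    bl <- if (G$parent[i] > 0L) G$height[G$parent[i]] - G$height[i] else NULL
    lab <- if (i <= G$n_tips) st$labels[i] else ""
    body <- if (i <= G$n_tips) lab else {
      paste0("(", paste(vapply(ch[[i]], rec, ""), collapse = ","), ")")
    }
    if (is.null(bl)) paste0(body, ";") else
      paste0(body, ":", formatC(bl, digits = 10, format = "g"))
  }
  rec(G$root)
}

## canonical topology identifier: sorted clade strings
.topology_id <- function(G) {
  ts <- .g_tipsets(G)
  ints <- ts[(G$n_tips + 1L):length(ts)]
  paste(sort(vapply(ints, function(x) paste(sort(x), collapse = ","), "")),
        collapse = "|")
}
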