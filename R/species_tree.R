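## Canonical species-tree container
##
## Nodes are indexed 1..N with tips 1..S (sorted lexicographically by label)
## and internal nodes S+1..N in post-order, so the root is always node N.
## Branch "s" means the branch above node s; the root has no branch.

#' Construct a species tree object
#'
#' Builds the canonical rooted, strictly bifurcating species-tree container
#' used throughout the package from an \code{ape} \code{phylo} object.
#' Branch lengths are interpreted as expected neutral substitutions per
#' site.  Node heights (speciation times on the same scale) are computed
#' bottom-up as \code{max(child height + child branch length)}; for
#' clock-like input these reproduce the input lengths exactly.
#'
#' @param phy a rooted, bifurcating \code{phylo} with branch lengths.
#' @param theta numeric vector of per-node population-size parameters
#'   (4*Ne*mu), in canonical node order, or \code{NULL} (all zero).
#' @param target,outgroup character vectors of tip labels.
#' @return an object of class \code{spectree}: a list with elements
#'   \code{n_tips}, \code{n_nodes}, \code{labels}, \code{parent} (0 at the
#'   root), \code{children}, \code{blen} (NA at the root), \code{tlen}
#'   (height-consistent branch spans), \code{height}, \code{theta},
#'   \code{target}, \code{outgroup}.
#' @export
species_tree <- function(phy, theta = NULL, target = character(),
                         outgroup = character()) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (is.null(phy$edge.length)) stop("species tree must have branch lengths")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (!ape::is.binary(phy)) stop("non-bifurcating species tree")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  S <- length(phy$tip.label)
  N <- 2L * S - 1L
  if (phy$Nnode != S - 1L) stop("unexpected node count")

  ## map ape ids -> canonical ids
  ord <- order(phy$tip.label)
  tip_map <- integer(S)          # ape tip id -> canonical id
  tip_map[ord] <- seq_len(S)
  ## internal nodes in post-order: use ape postorder edge traversal
  phy2 <- ape::reorder.phylo(phy, "postorder")
  post_int <- unique(phy2$edge[, 1L])   # parents in postorder; root last
  int_map <- integer(S - 1L)
  int_map[post_int - S] <- S + seq_along(post_int)
  node_map <- c(tip_map, int_map)       # ape id -> canonical id

  parent <- integer(N)
  blen <- rep(NA_real_, N)
  for (i in seq_len(nrow(phy$edge))) {
    child <- node_map[phy$edge[i, 2L]]
    parent[child] <- node_map[phy$edge[i, 1L]]
    blen[child] <- phy$edge.length[i]
  }
  labels <- character(N)
  labels[seq_len(S)] <- sort(phy$tip.label)
  if (!is.null(phy$node.label) && length(phy$node.label) == S - 1L) {
    labels[node_map[S + seq_len(S - 1L)]] <- phy$node.label
  }

  children <- vector("list", N)
  for (i in seq_len(N - 1L)) {
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  if (any(lengths(children[(S + 1L):N]) != 2L)) {
    stop("non-bifurcating species tree")
  }
  ## canonicalize internal ids: post-order with children visited in order
  ## of their smallest descendant tip, so the numbering is independent of
  ## the newick's child ordering (read/write becomes a bijection)
  mintip <- integer(N)
  mintip[seq_len(S)] <- seq_len(S)
  for (s in (S + 1L):N) mintip[s] <- min(mintip[children[[s]]])
  new_id <- integer(N)
  new_id[seq_len(S)] <- seq_len(S)
  ctr <- S
  visit <- function(s) {
    if (s > S) {
      for (c in children[[s]][order(mintip[children[[s]]])]) visit(c)
      ctr <<- ctr + 1L
      new_id[s] <<- ctr
    }
  }
  visit(N)
  if (any(new_id[(S + 1L):N] != (S + 1L):N)) {
    inv <- order(new_id)
    parent2 <- integer(N)
    for (i in seq_len(N)) {
      parent2[new_id[i]] <- if (parent[i] == 0L) 0L else new_id[parent[i]]
    }
    parent <- parent2
    blen <- blen[inv]
    labels <- labels[inv]
    children <- vector("list", N)
    for (i in seq_len(N - 1L)) {
      children[[parent[i]]] <- c(children[[parent[i]]], i)
    }
  }
  empty <- !nzchar(labels)
  labels[empty] <- paste0("n", which(empty))
  height <- numeric(N)
  for (s in (S + 1L):N) {
    kids <- children[[s]]
    height[s] <- max(height[kids] + blen[kids])
  }
  if (any(height[(S + 1L):N] <= vapply(children[(S + 1L):N], function(k) {
    max(height[k])
  }, 0))) stop("node heights must increase tipward to rootward")
  tlen <- c(height[parent[seq_len(N - 1L)]] - height[seq_len(N - 1L)],
            NA_real_)
  if (any(tlen[seq_len(N - 1L)] <= 0)) stop("non-positive branch span")

  if (is.null(theta)) theta <- numeric(N)
  if (length(theta) != N) stop("theta must have one entry per node")
  if (any(theta < 0)) stop("theta must be non-negative")
  theta[seq_len(S)] <- 0   # one allele per extant species
  bad <- setdiff(c(target, outgroup), labels[seq_len(S)])
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  if (length(intersect(target, outgroup))) {
    stop("target and outgroup sets overlap")
  }
  structure(list(
    n_tips = S, n_nodes = N, labels = labels, parent = parent,
    children = children, blen = blen, tlen = tlen, height = height,
    theta = theta, target = sort(unique(target)),
    outgroup = sort(unique(outgroup))
  ), class = "spectree")
}

#' Read a species tree with population sizes
#'
#' Parses a rooted bifurcating newick species tree whose branch lengths are
#' expected neutral substitutions per site, and attaches per-branch theta
#' (4*Ne*mu) values either from an explicit table or from a second newick
#' tree of identical topology with branch lengths in coalescent units
#' (theta = 2 * l1 / l2; see \code{\link{estimate_theta}}).
#'
#' @param newick newick string or path for the substitution-unit tree.
#' @param theta_source one of: a numeric vector in canonical node order; a
#'   data frame with columns \code{label}, \code{theta}; a newick
#'   string/path for the coalescent-unit tree; or \code{NULL}.
#' @param target,outgroup tip-label sets.
#' @return a \code{spectree}.
#' @export
read_species_tree <- function(newick, theta_source = NULL,
                              target = character(), outgroup = character()) {
  phy <- .read_newick(newick)
  st <- species_tree(phy, NULL, target, outgroup)
  if (is.null(theta_source)) return(st)
  if (is.numeric(theta_source)) {
    th <- theta_source
  } else if (is.data.frame(theta_source)) {
    th <- numeric(st$n_nodes)
    idx <- match(theta_source$label, st$labels)
    if (anyNA(idx)) stop("theta table labels not in tree")
    th[idx] <- theta_source$theta
  } else {
    coal <- species_tree(.read_newick(theta_source))
    est <- estimate_theta(st, coal)
    th <- est$theta
  }
  st$theta <- th
  st$theta[seq_len(st$n_tips)] <- 0
  if (any(th < 0)) stop("theta must be non-negative")
  st
}

.read_newick <- function(x) {
  if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x) else
    ape::read.tree(x)
}

#' Write a species tree to newick
#'
#' @param st a \code{spectree}.
#' @param file optional path; if \code{NULL} the newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return newick string (invisibly when writing to file).
#' @export
write_species_tree <- function(st, file = NULL, digits = 12) {
  phy <- as_phylo(st)
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Convert a spectree to ape phylo
#' @param st a \code{spectree}.
#' @return a \code{phylo} object.
#' @export
as_phylo <- function(st) {
  S <- st$n_tips; N <- st$n_nodes
  ## ape wants tips 1..S, root S+1, other internals following
  amap <- integer(N)
  amap[seq_len(S)] <- seq_len(S)
  ints <- (S + 1L):N
  amap[N] <- S + 1L
  rest <- setdiff(ints, N)
  amap[rest] <- S + 1L + seq_along(rest)
  edge <- cbind(amap[st$parent[seq_len(N - 1L)]], amap[seq_len(N - 1L)])
  phy <- list(edge = edge, tip.label = st$labels[seq_len(S)],
              edge.length = st$blen[seq_len(N - 1L)], Nnode = S - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

## tip descendants (canonical ids) of each node, as a list of integer sets
.tip_descendants <- function(st) {
  S <- st$n_tips; N <- st$n_nodes
  out <- vector("list", N)
  for (i in seq_len(S)) out[[i]] <- i
  for (s in (S + 1L):N) {
    out[[s]] <- sort(unlist(out[st$children[[s]]], use.names = FALSE))
  }
  out
}

## lowest node whose tip set contains all of 'tips' (integer tip ids)
.species_mrca <- function(st, tips) {
  s <- tips[1L]
  tips <- unique(tips)
  repeat {
    desc <- .desc_cache(st)[[s]]
    if (all(tips %in% desc)) return(s)
    s <- st$parent[s]
    if (s == 0L) stop("mrca walk escaped the root")
  }
}

## memoized descendant cache stored on the object environment-free way:
## recompute on demand (trees are small); kept as a function for clarity.
.desc_cache <- function(st) {
  if (!is.null(attr(st, "desc"))) return(attr(st, "desc"))
  .tip_descendants(st)
}

## attach the descendant cache (call once after construction in hot paths);
## for trees with <= 30 tips a bitmask representation of each node's tip
## set is attached as well, used by the gene-tree mapping fast path
with_desc_cache <- function(st) {
  if (is.null(attr(st, "desc"))) {
    desc <- .tip_descendants(st)
    attr(st, "desc") <- desc
    if (st$n_tips <= 30L) {
      attr(st, "mask") <- vapply(desc, function(d) {
        m <- 0L
        for (i in d) m <- bitwOr(m, bitwShiftL(1L, i - 1L))
        m
      }, 0L)
    }
  }
  st
}

## species branch containing a lineage with tip-set mask m at height h;
## walks up from a starting tip until the branch both contains the tip
## set and spans h.  Errors when h is below the species MRCA.
.sp_locate <- function(st, smask, m, start, h) {
  s <- start
  par <- st$parent
  hts <- st$height
  while (par[s] != 0L &&
         (bitwAnd(smask[s], m) != m || h >= hts[par[s]] - 1e-12)) {
    s <- par[s]
  }
  if (bitwAnd(smask[s], m) != m || hts[s] > h + 1e-9) {
    stop("incompatible coalescence placement (node below species MRCA)")
  }
  s
}

#' @export
print.spectree <- function(x, ...) {
  cat(sprintf("Species tree: %d tips, %d nodes\n", x$n_tips, x$n_nodes))
  cat(sprintf("  tree height: %.4f subst/site; mean internal theta: %.4g\n",
              x$height[x$n_nodes],
              mean(x$theta[(x$n_tips + 1L):x$n_nodes])))
  if (length(x$target)) cat("  targets:", paste(x$target, collapse = " "), "\n")
  if (length(x$outgroup)) cat("  outgroup:", paste(x$outgroup, collapse = " "), "\n")
  invisible(x)
}
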