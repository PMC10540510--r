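## Population-size estimation from dual branch-length trees, per-locus
## site concordance factors, and adaptive method routing.

#' Estimate per-branch population sizes from two branch-length scales
#'
#' Given the same rooted topology with branch lengths in expected
#' substitutions/site (l1) and in coalescent units (l2), the
#' population-size parameter of a branch is \code{theta = 2 * l1 / l2}.
#' Extant (tip) branches are set to 0 (a single allele per species is
#' sampled) and the root receives the average of the internal-branch
#' estimates.
#'
#' @param subst_tree a \code{spectree} with substitution-unit lengths.
#' @param coal_tree a \code{spectree} with coalescent-unit lengths and the
#'   identical topology.
#' @return a \code{theta_estimate}: list with \code{table} (data frame:
#'   label, l1, l2, theta, source) and \code{theta} (vector in the
#'   canonical node order of \code{subst_tree}).
#' @export
estimate_theta <- function(subst_tree, coal_tree) {
  if (subst_tree$n_tips != coal_tree$n_tips) stop("topology mismatch")
  d1 <- .tip_descendants(subst_tree)
  d2 <- .tip_descendants(coal_tree)
  key <- function(st, d) {
    vapply(d, function(i) paste(st$labels[i], collapse = ","), "")
  }
  k1 <- key(subst_tree, d1)
  k2 <- key(coal_tree, d2)
  map <- match(k1, k2)
  if (anyNA(map)) stop("topology mismatch between the two trees")
  N <- subst_tree$n_nodes
  S <- subst_tree$n_tips
  theta <- numeric(N)
  src <- character(N)
  for (s in seq_len(N)) {
    if (s <= S) {
      theta[s] <- 0
      src[s] <- "tip-zeroed"
    } else if (subst_tree$parent[s] == 0L) {
      src[s] <- "root-averaged"     # filled below
    } else {
      l2 <- coal_tree$blen[map[s]]
      if (!is.finite(l2) || l2 <= 0) {
        stop("coalescent-unit length is 0 on internal branch ",
             subst_tree$labels[s])
      }
      theta[s] <- 2 * subst_tree$blen[s] / l2
      src[s] <- "ratio"
    }
  }
  internal <- which(src == "ratio")
  theta[subst_tree$parent == 0L] <- mean(theta[internal])
  tab <- data.frame(
    label = subst_tree$labels,
    l1 = subst_tree$blen,
    l2 = coal_tree$blen[map],
    theta = theta,
    source = src,
    stringsAsFactors = FALSE)
  structure(list(table = tab, theta = theta), class = "theta_estimate")
}

## quartet side subtrees for the branch above internal node u:
## children of u (2 sides), plus sibling subtree and the rest of the tree
## (or the sibling's two children when u's parent is the root).
.branch_sides <- function(st, u, desc) {
  p <- st$parent[u]
  if (p == 0L || u <= st$n_tips) return(NULL)
  kids <- st$children[[u]]
  sib <- setdiff(st$children[[p]], u)
  s1 <- desc[[kids[1L]]]
  s2 <- desc[[kids[2L]]]
  rest <- setdiff(seq_len(st$n_tips), desc[[p]])
  if (length(rest)) {
    list(s1, s2, desc[[sib]], rest)
  } else if (sib > st$n_tips) {
    sk <- st$children[[sib]]
    list(s1, s2, desc[[sk[1L]]], desc[[sk[2L]]])
  } else {
    NULL
  }
}

#' Per-locus site concordance factors
#'
#' For each internal species-tree branch, samples up to \code{n_quartets}
#' quartets (one taxon from each of the four surrounding subtrees).  A
#' site is decisive for a quartet when its four bases are unambiguous and
#' show exactly two states in a 2+2 split, and concordant when the split
#' groups the two taxa on each side of the branch together (the
#' ((A,A),(G,G)) pattern).  CFq = concordant/decisive; the branch sCF is
#' the mean CFq over quartets with decisive sites.
#'
#' @param locus a \code{locus_alignment}.
#' @param st a \code{spectree}.
#' @param n_quartets quartets sampled per branch (all, if fewer exist).
#' @param seed integer seed for quartet sampling.
#' @return a \code{concordance_report}: list with \code{table} (branch,
#'   scf, n_quartets, mean decisive sites), \code{mean_scf}, and
#'   \code{locus}.
#' @export
site_cf <- function(locus, st, n_quartets = 100L, seed = 1L) {
  set.seed(seed)
  desc <- .tip_descendants(st)
  S <- st$n_tips
  have <- st$labels[seq_len(S)] %in% locus$taxa
  rows <- list()
  for (u in (S + 1L):st$n_nodes) {
    sides <- .branch_sides(st, u, desc)
    if (is.null(sides)) next
    sides <- lapply(sides, function(x) x[have[x]])
    if (any(lengths(sides) == 0L)) next
    n_all <- prod(lengths(sides))
    idx <- if (n_all <= n_quartets) {
      seq_len(n_all)
    } else {
      sample.int(n_all, n_quartets)
    }
    cf <- numeric(0)
    nd <- integer(0)
    dims <- lengths(sides)
    for (q in idx) {
      sub <- arrayInd(q, dims)
      taxa <- vapply(1:4, function(k) st$labels[sides[[k]][sub[k]]], "")
      chs <- locus$char[, taxa, drop = FALSE]
      ok <- rowSums(matrix(chs %in% c("a", "c", "g", "t"), ncol = 4L)) == 4L
      if (!any(ok)) { nd <- c(nd, 0L); next }
      m <- chs[ok, , drop = FALSE]
      ab <- m[, 1L] == m[, 2L]
      cd <- m[, 3L] == m[, 4L]
      ac <- m[, 1L] == m[, 3L]
      ad <- m[, 1L] == m[, 4L]
      bc <- m[, 2L] == m[, 3L]
      bd <- m[, 2L] == m[, 4L]
      two_states <- apply(m, 1L, function(r) length(unique(r))) == 2L
      split22 <- two_states & ((ab & cd) | (ac & bd) | (ad & bc))
      decisive <- sum(split22)
      conc <- sum(split22 & ab & cd)
      nd <- c(nd, decisive)
      if (decisive > 0L) cf <- c(cf, conc / decisive)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      branch = st$labels[u],
      scf = if (length(cf)) mean(cf) else NA_real_,
      n_quartets = length(idx),
      mean_decisive = if (length(nd)) mean(nd) else 0,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 mean_scf = if (!is.null(tab) && any(!is.na(tab$scf)))
                   mean(tab$scf, na.rm = TRUE) else NA_real_,
                 locus = locus$id),
            class = "concordance_report")
}

#' Route loci between the gene-tree and species-tree methods
#'
#' Deterministic routing from site-concordance reports: under the
#' \code{mean} rule a locus goes to the gene-tree method when its mean sCF
#' falls below the cutoff; under the \code{fraction} rule, when the
#' fraction of branches with sCF below \code{thresholds[1]} exceeds
#' \code{thresholds[2]}.  Branches with undefined sCF are excluded; a
#' locus with no defined branch routes to the (cheaper) species-tree
#' method.
#'
#' @param reports list of \code{concordance_report}.
#' @param rule "mean" or "fraction".
#' @param thresholds numeric: cutoff for "mean"; \code{c(scf_cutoff,
#'   fraction_cutoff)} for "fraction".
#' @return character vector ("gt" or "st") named by locus id.
#' @export
route_loci <- function(reports, rule = c("mean", "fraction"),
                       thresholds = 0.5) {
  rule <- match.arg(rule)
  out <- vapply(reports, function(rep) {
    scf <- rep$table$scf
    scf <- scf[!is.na(scf)]
    if (!length(scf)) return("st")
    if (rule == "mean") {
      if (mean(scf) < thresholds[1L]) "gt" else "st"
    } else {
      if (mean(scf < thresholds[1L]) > thresholds[2L]) "gt" else "st"
    }
  }, "")
  names(out) <- vapply(reports, `[[`, "", "locus")
  out
}
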