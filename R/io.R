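## Alignment and neutral-model IO.
##
## Bases are encoded 1..4 = A,C,G,T internally; gaps and IUPAC ambiguity
## codes become partial-likelihood masks (missing data) during pruning.

IUPAC <- list(
  a = "A", c = "C", g = "G", t = "T", u = "T",
  r = c("A", "G"), y = c("C", "T"), s = c("C", "G"), w = c("A", "T"),
  k = c("G", "T"), m = c("A", "C"), b = c("C", "G", "T"),
  d = c("A", "G", "T"), h = c("A", "C", "T"), v = c("A", "C", "G"),
  n = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
  "?" = c("A", "C", "G", "T"), "." = c("A", "C", "G", "T")
)

## 4 x 16ish lookup: per character, the 0/1 compatibility vector over ACGT
.iupac_mask <- local({
  m <- sapply(IUPAC, function(b) as.numeric(c("A", "C", "G", "T") %in% b))
  colnames(m) <- names(IUPAC)
  m
})

#' Create a locus alignment
#'
#' @param seqs character matrix (taxa in rows, sites in columns) or a
#'   named character vector of equal-length sequences.
#' @param id locus identifier.
#' @param interval optional 0-based half-open genomic interval
#'   \code{c(start, end)}.
#' @return a \code{locus_alignment}: list with \code{taxa}, \code{mat}
#'   (l x S integer matrix, NA = missing/ambiguous), \code{mask} (list of
#'   4 x l tip likelihood masks), \code{length}, \code{id},
#'   \code{interval}, \code{char} (l x S character matrix).
#' @export
locus_alignment <- function(seqs, id = "locus", interval = NULL) {
  if (is.matrix(seqs)) {
    ch <- seqs
  } else {
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) stop("sequences differ in length")
    ch <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(ch) <- names(seqs)
  }
  if (is.null(rownames(ch))) stop("sequences must be named by taxon")
  ch <- tolower(ch)
  bad <- setdiff(unique(as.vector(ch)), names(IUPAC))
  if (length(bad)) stop("unknown characters: ", paste(bad, collapse = ""))
  l <- ncol(ch)
  if (l < 1L) stop("alignment must have length >= 1")
  base_idx <- match(ch, c("a", "c", "g", "t"))
  dim(base_idx) <- dim(ch)
  mat <- t(base_idx)               # l x S
  colnames(mat) <- rownames(ch)
  mask <- lapply(seq_len(nrow(ch)), function(i) {
    .iupac_mask[, ch[i, ], drop = FALSE]   # 4 x l
  })
  names(mask) <- rownames(ch)
  structure(list(taxa = rownames(ch), mat = mat, mask = mask, length = l,
                 id = id, interval = interval, char = t(ch)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Locus '%s': %d taxa x %d sites\n", x$id, length(x$taxa),
              x$length))
  invisible(x)
}

#' Read loci from FASTA (optionally split by BED intervals)
#'
#' Reads a (possibly concatenated) FASTA alignment and returns one
#' \code{locus_alignment} per BED row, or the whole alignment as a single
#' locus when no BED is supplied.  BED intervals are 0-based, half-open.
#'
#' @param fasta_path FASTA file path.
#' @param bed_path optional BED path (chrom, start, end, [name]).
#' @param tree optional \code{spectree}; taxa are checked against its tips.
#' @return list of \code{locus_alignment}.
#' @export
read_loci <- function(fasta_path, bed_path = NULL, tree = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  ch <- do.call(rbind, lapply(as.character(dna), identity))
  rownames(ch) <- names(dna)
  if (!is.null(tree)) {
    bad <- setdiff(rownames(ch), tree$labels[seq_len(tree$n_tips)])
    if (length(bad)) stop("unknown taxon: ", paste(bad, collapse = ", "))
  }
  if (is.null(bed_path)) {
    return(list(locus_alignment(ch, id = basename(fasta_path))))
  }
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns")
  lapply(seq_len(nrow(bed)), function(i) {
    a <- bed[i, 2L]; b <- bed[i, 3L]
    if (a < 0 || b > ncol(ch) || a >= b) {
      stop(sprintf("BED interval [%d,%d) out of range for length %d",
                   a, b, ncol(ch)))
    }
    id <- if (ncol(bed) >= 4L) as.character(bed[i, 4L]) else
      sprintf("%s:%d-%d", bed[i, 1L], a, b)
    locus_alignment(ch[, (a + 1L):b, drop = FALSE], id = id,
                    interval = c(a, b))
  })
}

#' Write loci to FASTA
#' @param loci list of \code{locus_alignment} (concatenated in order).
#' @param path output file.
#' @export
write_loci <- function(loci, path) {
  taxa <- loci[[1L]]$taxa
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(loci, function(lc) paste(lc$char[, tx], collapse = ""), ""),
          collapse = "")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in taxa) {
    writeLines(c(paste0(">", tx), toupper(seqs[[tx]])), con)
  }
  invisible(path)
}

#' Read a PHAST-style neutral substitution model
#'
#' Parses the \code{BACKGROUND} and \code{RATE_MAT} blocks of a PHAST
#' \code{.mod} file and rescales the rate matrix so the expected rate is 1
#' substitution per site per unit branch length
#' (\code{-sum(pi * diag(Q)) == 1}).
#'
#' @param mod text of, or path to, a \code{.mod} file.
#' @return a \code{neutral_model}: list with \code{Q} (normalized 4x4 rate
#'   matrix, ACGT order), \code{freq} (stationary frequencies), \code{exch}
#'   (symmetric exchangeabilities \code{Q[i,j]/freq[j]}).
#' @export
read_neutral_model <- function(mod) {
  lines <- if (length(mod) == 1L && file.exists(mod)) readLines(mod) else
    strsplit(mod, "\n")[[1L]]
  bg_i <- grep("^BACKGROUND:", lines)
  rm_i <- grep("^RATE_MAT:", lines)
  if (!length(bg_i) || !length(rm_i)) {
    stop("need BACKGROUND and RATE_MAT blocks")
  }
  freq <- as.numeric(strsplit(trimws(sub("^BACKGROUND:", "", lines[bg_i])),
                              "\\s+")[[1L]])
  if (length(freq) != 4L) stop("BACKGROUND must list 4 frequencies")
  if (abs(sum(freq) - 1) > 1e-6) stop("frequencies must sum to 1")
  rows <- lines[(rm_i + 1L):(rm_i + 4L)]
  Q <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
  }, numeric(4)))
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  if (any(Q[row(Q) != col(Q)] < 0)) stop("negative off-diagonal rates")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix")
  Q <- Q / scale
  exch <- sweep(Q, 2L, freq, "/")
  diag(exch) <- 0
  structure(list(Q = Q, freq = freq, exch = exch), class = "neutral_model")
}

#' Write a neutral model in PHAST .mod dialect
#' @param nm a \code{neutral_model}.
#' @param path output file.
#' @export
write_neutral_model <- function(nm, path) {
  lines <- c(
    "ORDER: 1",
    "SUBST_MOD: REV",
    paste("BACKGROUND:", paste(formatC(nm$freq, digits = 12, format = "g"),
                               collapse = " ")),
    "RATE_MAT:",
    apply(nm$Q, 1L, function(r) {
      paste(" ", paste(formatC(r, digits = 12, format = "g"),
                       collapse = " "))
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' Jukes-Cantor neutral model
#' @return a \code{neutral_model} with equal frequencies and rates.
#' @export
jc_model <- function() {
  Q <- matrix(1 / 3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  diag(Q) <- -1
  structure(list(Q = Q, freq = rep(0.25, 4),
                 exch = {
                   e <- matrix(4 / 3, 4, 4); diag(e) <- 0; e
                 }),
            class = "neutral_model")
}
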