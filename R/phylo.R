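# Clade-level conservation metrics on externally built trees and alignments:
# mean root-to-tip path length per clade and mean pairwise percent
# identity/similarity.

#' Midpoint-root a tree
#'
#' Thin wrapper around `phangorn::midpoint` for use before
#' [mean_root_to_tip()] on unrooted trees.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return a rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Mean root-to-tip path length of a clade
#'
#' Arithmetic mean, over the leaves carrying `label`, of the sum of branch
#' lengths from the root to the leaf (substitutions/site) -- a simple proxy
#' for per-clade substitution rate.
#'
#' @param tree rooted `phylo` tree with branch lengths on every edge.
#' @param clades named character vector or 2-column `data.frame`
#'   (`leaf`, `clade`) mapping leaf names to clade labels.
#' @param label clade label to summarise.
#' @return mean path length (numeric scalar).
#' @export
mean_root_to_tip <- function(tree, clades, label) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; midpoint-root it first (see midpoint_root())")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must carry branch lengths on every edge")
  if (is.data.frame(clades))
    clades <- stats::setNames(as.character(clades[[2]]),
                              as.character(clades[[1]]))
  leaves <- names(clades)[clades == label]
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) stop("leaves not in tree: ", paste(miss, collapse = ", "))
  if (!length(leaves)) stop("no leaves labelled ", label)
  depths <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  mean(depths[match(leaves, tree$tip.label)])
}

#' Mean pairwise identity and similarity within a clade alignment
#'
#' For every unordered pair of members, identity is the fraction of columns
#' where both are non-gap and identical, over columns where both are non-gap;
#' similarity additionally counts substitution-matrix-positive residue pairs
#' (default BLOSUM62). Means are taken over all pairs.
#'
#' @param alignment `AAStringSet` (or named character vector) of aligned,
#'   equal-length sequences.
#' @param members names to include (>= 2); default all.
#' @param matrix substitution matrix name (data set in Biostrings).
#' @param gap_mode `"pairwise"` (default: columns gapped in either member of
#'   a pair are excluded from that pair's denominator) or `"all"` (all
#'   alignment columns in the denominator).
#' @return one-row `data.frame`: `n_pairs`, `mean_identity`,
#'   `mean_similarity` (percent), `matrix`.
#' @export
pairwise_similarity <- function(alignment, members = NULL,
                                matrix = "BLOSUM62",
                                gap_mode = c("pairwise", "all")) {
  gap_mode <- match.arg(gap_mode)
  if (methods::is(alignment, "XStringSet"))
    seqs <- stats::setNames(as.character(alignment), names(alignment))
  else seqs <- alignment
  if (is.null(members)) members <- names(seqs)
  miss <- setdiff(members, names(seqs))
  if (length(miss))
    stop("members absent from alignment: ", paste(miss, collapse = ", "))
  if (length(members) < 2L) stop("at least 2 members required")
  if (length(unique(nchar(seqs[members]))) != 1L)
    stop("aligned sequences must have equal length")
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  sm <- get(matrix, envir = e)
  chars <- lapply(seqs[members], function(s) strsplit(s, "")[[1]])
  pairs <- utils::combn(length(members), 2)
  ident <- simil <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- chars[[pairs[1, p]]]; b <- chars[[pairs[2, p]]]
    both <- a != "-" & b != "-"
    denom <- if (gap_mode == "pairwise") sum(both) else length(a)
    if (denom == 0) { ident[p] <- simil[p] <- NA_real_; next }
    eq <- both & a == b
    pos <- both
    pos[both] <- sm[cbind(a[both], b[both])] > 0
    ident[p] <- 100 * sum(eq) / denom
    simil[p] <- 100 * sum(pos) / denom
  }
  data.frame(n_pairs = ncol(pairs),
             mean_identity = mean(ident, na.rm = TRUE),
             mean_similarity = mean(simil, na.rm = TRUE),
             matrix = matrix, stringsAsFactors = FALSE)
}
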