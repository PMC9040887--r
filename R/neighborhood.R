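# Gene-neighborhood extraction (five nearest ORFs on each side, by gene rank
# order on the scaffold) and inside-vs-outside functional-category ratios.

CATEGORIES <- c("metabolism", "signaling_cell_function",
                "genetic_information_processing", "unknown")

#' Nearest neighbors of a focal gene
#'
#' Up to `k` genes per side of the focal gene, by genomic rank order on the
#' same scaffold (not bp distance); fewer are returned near scaffold ends.
#'
#' @param focal_id gene id present in the annotation.
#' @param annotation a [genome_annotation()].
#' @param k neighbors per side (default 5).
#' @return list with `focal_id`, `upstream` and `downstream` gene feature
#'   `data.frame`s, each ordered by increasing distance from the focal gene
#'   (upstream = lower-coordinate side).
#' @export
nearest_neighbors <- function(focal_id, annotation, k = 5L) {
  g <- annotation$genes
  i <- which(g$gene_id == focal_id)
  if (length(i) != 1L) stop("focal gene not in annotation: ", focal_id)
  same <- g[g$scaffold_id == g$scaffold_id[i], , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  j <- which(same$gene_id == focal_id)
  up <- same[rev(seq_len(j - 1L))[seq_len(min(k, j - 1L))], , drop = FALSE]
  dn_idx <- (j + 1L):nrow(same)
  dn <- if (j < nrow(same))
    same[dn_idx[seq_len(min(k, length(dn_idx)))], , drop = FALSE]
  else same[0, , drop = FALSE]
  rownames(up) <- rownames(dn) <- NULL
  list(focal_id = focal_id, upstream = up, downstream = dn)
}

#' Built-in keyword-to-category map
#'
#' The rule table shipped with the package (first-matching keyword wins;
#' keywords are matched case-insensitively against gene product annotations).
#' Users can supply their own table of the same shape to
#' [assign_categories()].
#'
#' @return `data.frame` with columns `keyword`, `category`, `subcategory`,
#'   in rule priority order.
#' @export
default_category_map <- function() {
  path <- system.file("extdata", "category_keywords.tsv",
                      package = "glycomine", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assign functional categories to genes by annotation keywords
#'
#' @param genes gene feature `data.frame` (uses `gene_id` and `annotation`).
#' @param category_map rule table (see [default_category_map()]).
#' @param multi if `FALSE` (default) the first matching rule wins, so each
#'   gene gets exactly one category and counts conserve; if `TRUE` a gene is
#'   counted once per matching category (one row per match), replicating
#'   Venn-style multi-term counting.
#' @return `data.frame` with columns `gene_id`, `category`, `subcategory`
#'   and the counting `mode` used; genes with no matching keyword are
#'   `unknown`.
#' @export
assign_categories <- function(genes, category_map = default_category_map(),
                              multi = FALSE) {
  mode <- if (multi) "multi" else "single"
  one <- function(i) {
    ann <- genes$annotation[i]
    hit <- which(vapply(category_map$keyword, function(kw)
      grepl(kw, ann, ignore.case = TRUE, fixed = FALSE), logical(1)))
    if (!length(hit))
      return(data.frame(gene_id = genes$gene_id[i], category = "unknown",
                        subcategory = "", mode = mode,
                        stringsAsFactors = FALSE))
    if (!multi) hit <- hit[1]
    else hit <- hit[!duplicated(category_map$category[hit])]
    data.frame(gene_id = genes$gene_id[i],
               category = category_map$category[hit],
               subcategory = category_map$subcategory[hit], mode = mode,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), one))
  rownames(out) <- NULL
  out
}

#' Inside/outside functional-category ratios
#'
#' Per-category neighbor counts for genes found inside versus outside
#' clusters and their ratio. Categories absent from both sides are omitted;
#' a ratio with zero outside-count is reported as `NA` (undefined), not
#' infinity.
#'
#' @param assignments_inside,assignments_outside outputs of
#'   [assign_categories()] for the two neighbor sets; both nonempty.
#' @return `data.frame` with columns `category`, `count_inside`,
#'   `count_outside`, `ratio`.
#' @export
inside_outside_ratio <- function(assignments_inside, assignments_outside) {
  if (nrow(assignments_inside) == 0 || nrow(assignments_outside) == 0)
    stop("both inside and outside assignment sets must be nonempty")
  lev <- union(unique(assignments_inside$category),
               unique(assignments_outside$category))
  lev <- lev[order(match(lev, CATEGORIES))]
  ci <- table(factor(assignments_inside$category, levels = lev))
  co <- table(factor(assignments_outside$category, levels = lev))
  out <- data.frame(category = lev, count_inside = as.integer(ci),
                    count_outside = as.integer(co),
                    stringsAsFactors = FALSE)
  out <- out[out$count_inside + out$count_outside > 0, , drop = FALSE]
  out$ratio <- ifelse(out$count_outside == 0, NA_real_,
                      out$count_inside / out$count_outside)
  rownames(out) <- NULL
  out
}
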