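# Signed shortest gene-to-BGC distances and the inside-cluster rule.
#
# Distance is the gap between the closest interval boundaries, 0 for any
# overlap (touching half-open intervals also have gap 0). Sign: positive when
# the gene lies on the lower-coordinate (5') side of the cluster in scaffold
# orientation, negative on the 3' side. A homolog counts as inside a cluster
# when it overlaps it, lies within 2 kb, or has at most 5 annotated genes
# strictly between it and the facing cluster boundary.

#' Signed shortest distance between a gene and a BGC
#'
#' @param gene one-row gene feature (list or `data.frame` row with `start`,
#'   `end`, `scaffold_id`), 0-based half-open.
#' @param bgc one-row BGC interval, same conventions.
#' @return distance in bp: 0 on overlap; `bgc$start - gene$end` (positive)
#'   when the gene is 5' of the cluster; `-(gene$start - bgc$end)` (negative)
#'   when 3' of it.
#' @export
signed_distance <- function(gene, bgc) {
  if (!identical(as.character(gene$scaffold_id), as.character(bgc$scaffold_id)))
    stop("gene and BGC are on different scaffolds")
  if (gene$start < bgc$end && bgc$start < gene$end) return(0)
  if (gene$end <= bgc$start) return(as.numeric(bgc$start - gene$end))
  -as.numeric(gene$start - bgc$end)
}

# annotated genes lying strictly within the open gap between the facing
# boundaries (fully contained; the focal gene itself excluded)
count_intervening <- function(gene, bgc, annotation) {
  d <- signed_distance(gene, bgc)
  if (d == 0) return(0L)
  if (d > 0) { lo <- gene$end; hi <- bgc$start } else { lo <- bgc$end; hi <- gene$start }
  g <- annotation$genes
  sum(g$scaffold_id == gene$scaffold_id & g$gene_id != gene$gene_id &
        g$start >= lo & g$end <= hi)
}

#' Inside-cluster rule
#'
#' A gene is inside a BGC when it overlaps it (`signed_distance` 0), lies
#' within `inside_bp` of it, or has at most `inside_genes` annotated genes
#' strictly between it and the facing cluster boundary (disjunction of
#' sufficient conditions; "within 5 genes or 2 kb").
#'
#' @param signed_distance signed bp distance from [signed_distance()].
#' @param intervening_genes count of genes strictly between the facing
#'   boundaries.
#' @param inside_bp bp threshold (default 2000).
#' @param inside_genes gene-rank threshold (default 5).
#' @return logical.
#' @export
is_inside <- function(signed_distance, intervening_genes, inside_bp = 2000,
                      inside_genes = 5) {
  signed_distance == 0 | abs(signed_distance) <= inside_bp |
    intervening_genes <= inside_genes
}

#' Nearest BGC to a gene on the same scaffold
#'
#' Among same-scaffold BGCs strictly closer than `max_distance`, returns the
#' one minimising `|signed_distance|`; ties break toward the 5' (positive)
#' side, then lexicographic `bgc_id`. When none qualifies the gene is reported
#' unassigned (`nearest_bgc_id` `NA`, `inside` `FALSE`) rather than dropped.
#'
#' @param gene one-row gene feature.
#' @param bgcs BGC interval table (may be empty).
#' @param annotation the gene's [genome_annotation()] (for intervening-gene
#'   counts).
#' @param max_distance maximum |distance| considered, exclusive (default
#'   2 Mbp).
#' @param inside_bp,inside_genes thresholds passed to [is_inside()].
#' @return one-row `data.frame`: `gene_id`, `genome_id`, `scaffold_id`,
#'   `nearest_bgc_id`, `signed_distance`, `intervening_genes`, `inside`.
#' @export
nearest_bgc <- function(gene, bgcs, annotation, max_distance = 2e6,
                        inside_bp = 2000, inside_genes = 5) {
  empty <- data.frame(
    gene_id = gene$gene_id, genome_id = gene$genome_id,
    scaffold_id = gene$scaffold_id, nearest_bgc_id = NA_character_,
    signed_distance = NA_real_, intervening_genes = NA_integer_,
    inside = FALSE, stringsAsFactors = FALSE)
  if (is.null(bgcs) || nrow(bgcs) == 0) return(empty)
  cand <- bgcs[bgcs$scaffold_id == gene$scaffold_id, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  d <- vapply(seq_len(nrow(cand)), function(i)
    signed_distance(gene, cand[i, ]), numeric(1))
  ok <- abs(d) < max_distance
  if (!any(ok)) return(empty)
  cand <- cand[ok, , drop = FALSE]; d <- d[ok]
  ord <- order(abs(d), -sign(d), cand$bgc_id)
  best <- ord[1]
  iv <- count_intervening(gene, cand[best, ], annotation)
  data.frame(
    gene_id = gene$gene_id, genome_id = gene$genome_id,
    scaffold_id = gene$scaffold_id, nearest_bgc_id = cand$bgc_id[best],
    signed_distance = d[best], intervening_genes = as.integer(iv),
    inside = is_inside(d[best], iv, inside_bp, inside_genes),
    stringsAsFactors = FALSE)
}

#' Proximity of a set of focal genes to their nearest BGCs
#'
#' Vectorised driver over [nearest_bgc()].
#'
#' @param annotation a [genome_annotation()].
#' @param bgcs BGC interval table for the same genome.
#' @param gene_ids focal gene ids (must exist in the annotation).
#' @inheritParams nearest_bgc
#' @return `data.frame` with one row per focal gene (see [nearest_bgc()]).
#' @export
bgc_proximity <- function(annotation, bgcs, gene_ids, max_distance = 2e6,
                          inside_bp = 2000, inside_genes = 5) {
  g <- annotation$genes
  miss <- setdiff(gene_ids, g$gene_id)
  if (length(miss))
    stop("focal gene(s) absent from annotation: ", paste(miss, collapse = ", "))
  rows <- lapply(gene_ids, function(id)
    nearest_bgc(g[g$gene_id == id, ], bgcs, annotation, max_distance,
                inside_bp, inside_genes))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics of gene-to-BGC distances for one subfamily
#'
#' Genes without an assigned nearest BGC are excluded from the statistics and
#' counted separately.
#'
#' @param results proximity `data.frame` (rows for one subfamily).
#' @param subfamily label stored in the output.
#' @return one-row `data.frame`: `subfamily`, `n`, `n_unassigned`, mean /
#'   median / lower and upper quartile of the signed distance and of
#'   |distance| (bp). All statistics `NA` when every gene is unassigned.
#' @export
distance_summary <- function(results, subfamily) {
  if (nrow(results) == 0) stop("no proximity results supplied")
  keep <- !is.na(results$nearest_bgc_id)
  d <- results$signed_distance[keep]
  q <- function(x, p) unname(stats::quantile(x, p))
  if (!length(d))
    return(data.frame(subfamily = subfamily, n = 0L,
                      n_unassigned = sum(!keep),
                      mean = NA_real_, median = NA_real_, q25 = NA_real_,
                      q75 = NA_real_, mean_abs = NA_real_,
                      median_abs = NA_real_, q25_abs = NA_real_,
                      q75_abs = NA_real_))
  data.frame(
    subfamily = subfamily, n = length(d), n_unassigned = sum(!keep),
    mean = mean(d), median = stats::median(d), q25 = q(d, 0.25),
    q75 = q(d, 0.75),
    mean_abs = mean(abs(d)), median_abs = stats::median(abs(d)),
    q25_abs = q(abs(d), 0.25), q75_abs = q(abs(d), 0.75),
    stringsAsFactors = FALSE)
}

#' Default |distance| bin edges for distribution comparison
#'
#' Landmark thresholds of the analysis: inside (0), the 2 kb inside rule,
#' the 20 kb exclusion zone and a 100 kb display window, with an open-ended
#' outer bin.
#' @return numeric vector of edges.
#' @export
default_distance_bins <- function() c(0, 2000, 20000, 100000, Inf)

.bin_distances <- function(x, edges) {
  # bin |distance|: exactly-0 is its own (inside) bin, then (edges half-open]
  a <- abs(x)
  labs <- c("0", paste0("(", utils::head(edges, -1), ",", utils::tail(edges, -1), "]"))
  idx <- ifelse(a == 0, 1L,
                1L + as.integer(cut(a, breaks = edges, right = TRUE,
                                    include.lowest = FALSE)))
  factor(labs[idx], levels = labs)
}

#' Chi-square comparison of two distance distributions
#'
#' Bins both samples of |distance| into shared edges ({0} is its own bin),
#' forms a 2 x k contingency table, drops all-zero columns and computes the
#' classical (uncorrected) chi-square statistic with its upper-tail P value.
#'
#' @param a,b numeric vectors of signed distances (bp), nonempty.
#' @param bin_edges shared bin edges covering all |distances| (default
#'   [default_distance_bins()]).
#' @return list with `statistic`, `df`, `p_value`, `table` (the contingency
#'   table used) and `bin_edges`.
#' @export
compare_distance_distributions <- function(a, b,
                                           bin_edges = default_distance_bins()) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (max(abs(c(a, b))) > max(bin_edges))
    stop("bin edges do not cover all observations")
  tab <- rbind(a = table(.bin_distances(a, bin_edges)),
               b = table(.bin_distances(b, bin_edges)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)
    stop("fewer than 2 non-empty bins; chi-square test undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab, bin_edges = bin_edges)
}
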