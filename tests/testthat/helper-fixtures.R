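# Shared in-code fixtures and independent oracles.

# memoised small synthetic genome set reused across test files
.fixture_env <- new.env(parent = emptyenv())
small_genome_set <- function() {
  if (is.null(.fixture_env$gs))
    .fixture_env$gs <- generate_genome_set(
      simulation_config(n_genomes = 8, seed = 7))
  .fixture_env$gs
}

as_genome_list <- function(gs) {
  out <- lapply(names(gs$annotations), function(g)
    list(annotation = gs$annotations[[g]], bgcs = gs$bgcs[[g]]))
  stats::setNames(out, names(gs$annotations))
}

# hand-built annotation: genes laid out left to right on one scaffold
toy_annotation <- function(starts, ends, scaffold = "s1", genome = "G",
                           ids = NULL, annotation = "") {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_along(starts))
  genome_annotation(genome,
    gene_features(ids, genome, scaffold, starts, ends,
                  annotation = annotation))
}

toy_bgcs <- function(starts, ends, scaffold = "s1", genome = "G",
                     ids = NULL) {
  if (is.null(ids)) ids <- sprintf("b%02d", seq_along(starts))
  bgc_intervals(ids, genome, scaffold, starts, ends)
}

# independent exhaustive scan used against nearest_bgc()
oracle_nearest <- function(gene, bgcs, max_distance = 2e6) {
  best <- NULL
  for (i in seq_len(nrow(bgcs))) {
    b <- bgcs[i, ]
    if (b$scaffold_id != gene$scaffold_id) next
    d <- if (gene$start < b$end && b$start < gene$end) 0
    else if (gene$end <= b$start) b$start - gene$end
    else -(gene$start - b$end)
    if (abs(d) >= max_distance) next
    better <- is.null(best) || abs(d) < abs(best$d) ||
      (abs(d) == abs(best$d) && sign(d) > sign(best$d)) ||
      (abs(d) == abs(best$d) && sign(d) == sign(best$d) &&
         b$bgc_id < best$id)
    if (better) best <- list(d = d, id = b$bgc_id)
  }
  best
}

# manual type-7 quantile (independent of stats::quantile)
manual_quantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# mirror a toy annotation/bgc table through scaffold length L
mirror_genes <- function(ann, L) {
  g <- ann$genes
  genome_annotation(ann$genome_id,
    gene_features(g$gene_id, g$genome_id, g$scaffold_id,
                  L - g$end, L - g$start, g$strand, g$annotation))
}
mirror_bgcs <- function(bgcs, L) {
  bgc_intervals(bgcs$bgc_id, bgcs$genome_id, bgcs$scaffold_id,
                L - bgcs$end, L - bgcs$start, bgcs$predicted_type)
}
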