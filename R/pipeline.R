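# End-to-end orchestration: filter -> classify -> proximity -> census ->
# neighborhood, with deterministic "#"-commented TSV outputs.

#' Run the resistance-guided mining pipeline
#'
#' Runs the stages in order on a set of genomes: optional homology-hit
#' filtering, motif classification of the candidate proteome, gene-to-BGC
#' proximity for every classified gene, per-genome census and coincidence,
#' per-subfamily distance summaries with a YQL-vs-AZL chi-square comparison,
#' and inside-vs-outside neighborhood category ratios for AZL genes. Reruns
#' with the same inputs and thresholds are byte-identical.
#'
#' @param genomes named list (by genome id); each element a list with
#'   `annotation` (a [genome_annotation()]) and `bgcs` (a [bgc_intervals()]
#'   table).
#' @param proteins named character vector (or `AAStringSet`) of candidate
#'   protein sequences; names must be gene ids present in the annotations.
#' @param references list of [reference_anchor()]s for window location.
#' @param hits optional hit table from [read_blast_hits()]; when given,
#'   proteins are restricted to queries surviving [filter_hits()].
#' @param evalue_max,identity_min,coverage_min hit-filter thresholds.
#' @param max_distance,inside_bp,inside_genes proximity thresholds.
#' @param bin_edges chi-square bin edges
#'   (default [default_distance_bins()]).
#' @param category_map keyword rules for [assign_categories()].
#' @param out_dir optional directory for TSV outputs.
#' @return list of class `glycomine_run` with elements `calls`, `summary`,
#'   `proximity`, `census`, `coincidence`, `distance_summaries`,
#'   `distance_test` (or `NULL` when either subfamily is empty),
#'   `neighborhood_ratio` (or `NULL`), `thresholds`.
#' @export
run_pipeline <- function(genomes, proteins, references, hits = NULL,
                         evalue_max = 1e-4, identity_min = 25,
                         coverage_min = 0.75, max_distance = 2e6,
                         inside_bp = 2000, inside_genes = 5,
                         bin_edges = default_distance_bins(),
                         category_map = default_category_map(),
                         out_dir = NULL) {
  if (methods::is(proteins, "XStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  for (g in names(genomes)) {
    if (!inherits(genomes[[g]]$annotation, "genome_annotation"))
      stop("genome ", g, " lacks a genome_annotation")
  }
  if (!is.null(hits)) {
    kept <- filter_hits(hits, evalue_max, identity_min, coverage_min)
    proteins <- proteins[names(proteins) %in% kept$query_id]
  }
  # map gene id -> genome id
  gene2genome <- do.call(rbind, lapply(names(genomes), function(g)
    data.frame(gene_id = genomes[[g]]$annotation$genes$gene_id, genome_id = g,
               stringsAsFactors = FALSE)))

  cls <- classify_proteome(proteins, references)
  calls <- cls$calls
  calls$genome_id <- gene2genome$genome_id[match(calls$protein_id,
                                                 gene2genome$gene_id)]
  unmapped <- calls$protein_id[is.na(calls$genome_id)]
  if (length(unmapped))
    warning("protein(s) not matching any annotated gene: ",
            paste(utils::head(unmapped, 5), collapse = ", "))

  classified <- calls[calls$subfamily %in% SUBFAMILIES &
                        !is.na(calls$genome_id), , drop = FALSE]
  prox <- do.call(rbind, lapply(split(classified, classified$genome_id),
    function(cc) {
      g <- genomes[[cc$genome_id[1]]]
      bgc_proximity(g$annotation, g$bgcs, cc$protein_id, max_distance,
                    inside_bp, inside_genes)
    }))
  if (!is.null(prox)) {
    rownames(prox) <- NULL
    prox$subfamily <- classified$subfamily[match(prox$gene_id,
                                                 classified$protein_id)]
  }

  cens <- census(classified)
  coin <- coincidence(cens)

  dsum <- do.call(rbind, lapply(SUBFAMILIES, function(sf) {
    rows <- prox[prox$subfamily == sf, , drop = FALSE]
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    distance_summary(rows, sf)
  }))
  dtest <- NULL
  dy <- prox$signed_distance[prox$subfamily == "YQL" &
                               !is.na(prox$nearest_bgc_id)]
  da <- prox$signed_distance[prox$subfamily == "AZL" &
                               !is.na(prox$nearest_bgc_id)]
  if (length(dy) && length(da))
    dtest <- tryCatch(compare_distance_distributions(dy, da, bin_edges),
                      error = function(e) NULL)

  nratio <- NULL
  azl <- prox[prox$subfamily == "AZL" & !is.na(prox$nearest_bgc_id), ,
              drop = FALSE]
  if (!is.null(azl) && nrow(azl) && any(azl$inside) && any(!azl$inside)) {
    grab <- function(rows) do.call(rbind, lapply(seq_len(nrow(rows)),
      function(i) {
        ann <- genomes[[rows$genome_id[i]]]$annotation
        nb <- nearest_neighbors(rows$gene_id[i], ann, k = 5L)
        rbind(nb$upstream, nb$downstream)
      }))
    ins <- assign_categories(grab(azl[azl$inside, , drop = FALSE]),
                             category_map)
    outs <- assign_categories(grab(azl[!azl$inside, , drop = FALSE]),
                              category_map)
    nratio <- inside_outside_ratio(ins, outs)
  }

  thresholds <- list(evalue_max = evalue_max, identity_min = identity_min,
                     coverage_min = coverage_min, max_distance = max_distance,
                     inside_bp = inside_bp, inside_genes = inside_genes,
                     bin_edges = bin_edges)
  res <- structure(list(calls = calls, summary = cls$summary,
                        proximity = prox, census = cens, coincidence = coin,
                        distance_summaries = dsum, distance_test = dtest,
                        neighborhood_ratio = nratio,
                        thresholds = thresholds),
                   class = "glycomine_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.glycomine_run <- function(x, ...) {
  cat("glycomine pipeline run\n")
  cat("  proteins classified:", nrow(x$calls), "\n")
  s <- x$summary
  cat(sprintf("  %s: %d (%.1f%%)\n", s$subfamily, s$n, s$percent), sep = "")
  if (!is.null(x$proximity))
    cat("  genes with a nearest BGC:",
        sum(!is.na(x$proximity$nearest_bgc_id)),
        "(inside:", sum(x$proximity$inside), ")\n")
  invisible(x)
}

#' Write pipeline outputs as commented TSV files
#'
#' Every file carries "#" header lines with the package version and the
#' thresholds used, so a rerun with the same inputs and configuration is
#' byte-identical.
#'
#' @param run a `glycomine_run` object.
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- run$thresholds
  comments <- c(
    paste0("glycomine ",
           as.character(utils::packageVersion("glycomine"))),
    paste0("thresholds: evalue_max=", th$evalue_max,
           " identity_min=", th$identity_min,
           " coverage_min=", th$coverage_min,
           " max_distance=", th$max_distance,
           " inside_bp=", th$inside_bp, " inside_genes=", th$inside_genes),
    paste0("distance_bins: ", paste(th$bin_edges, collapse = ",")))
  paths <- c(calls = "subfamily_calls.tsv", summary = "subfamily_summary.tsv",
             proximity = "bgc_proximity.tsv", census = "census.tsv",
             distance_summaries = "distance_summaries.tsv")
  written <- character()
  for (nm in names(paths)) {
    obj <- run[[nm]]
    if (is.null(obj)) next
    p <- file.path(out_dir, paths[[nm]])
    write_tsv_commented(obj, p, comments)
    written[nm] <- p
  }
  p <- file.path(out_dir, "coincidence.tsv")
  write_tsv_commented(run$coincidence$cells, p,
                      c(comments,
                        paste0("totals: both=", run$coincidence$totals["both"],
                               " either_only=",
                               run$coincidence$totals["either_only"],
                               " neither=", run$coincidence$totals["neither"])))
  written["coincidence"] <- p
  if (!is.null(run$neighborhood_ratio)) {
    p <- file.path(out_dir, "neighborhood_ratio.tsv")
    write_tsv_commented(run$neighborhood_ratio, p, comments)
    written["neighborhood_ratio"] <- p
  }
  invisible(written)
}
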