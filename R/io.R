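# File readers and writers. All coordinates inside the package are 0-based
# half-open [start, end); GFF3 is read/written as 1-based inclusive, BED as
# 0-based half-open.

STRANDS <- c("+", "-", "?")

#' Construct a gene feature table
#'
#' A gene feature table is a plain `data.frame` with one row per gene and
#' columns `gene_id`, `genome_id`, `scaffold_id`, `start`, `end`, `strand`,
#' `annotation`. Coordinates are 0-based half-open.
#'
#' @param gene_id,genome_id,scaffold_id character vectors.
#' @param start,end integer coordinates, 0-based half-open; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"?"` per gene (`"?"` = unstranded).
#' @param annotation free-text product description; may be empty.
#' @return a `data.frame` of gene features.
#' @export
gene_features <- function(gene_id, genome_id, scaffold_id, start, end,
                          strand = "?", annotation = "") {
  df <- data.frame(
    gene_id = as.character(gene_id),
    genome_id = as.character(genome_id),
    scaffold_id = as.character(scaffold_id),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(gene_id)),
    annotation = rep_len(as.character(annotation), length(gene_id)),
    stringsAsFactors = FALSE
  )
  validate_gene_features(df)
  df
}

validate_gene_features <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene_id", "genome_id", "scaffold_id", "start", "end", "strand",
            "annotation")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("gene feature table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$start >= df$end))
      stop("gene features must satisfy 0 <= start < end")
    if (!all(df$strand %in% STRANDS))
      stop("strand must be one of ", paste(STRANDS, collapse = " "))
  }
  invisible(df)
}

#' Bundle gene features into a genome annotation
#'
#' @param genome_id genome identifier.
#' @param genes gene feature table (see [gene_features()]); sorted on return
#'   by `(scaffold_id, start)`.
#' @param scaffolds optional `data.frame` with columns `scaffold_id`,
#'   `length` (bp, `NA` when unknown). Scaffolds absent from it are added
#'   with unknown length.
#' @return an object of class `genome_annotation`: a list with elements
#'   `genome_id`, `scaffolds`, `genes`.
#' @export
genome_annotation <- function(genome_id, genes, scaffolds = NULL) {
  validate_gene_features(genes)
  if (nrow(genes) && any(duplicated(genes$gene_id)))
    stop("duplicate gene_id within genome: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  genes$genome_id <- rep(genome_id, nrow(genes))
  genes <- genes[order(genes$scaffold_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(scaffolds))
    scaffolds <- data.frame(scaffold_id = character(), length = numeric())
  extra <- setdiff(unique(genes$scaffold_id), scaffolds$scaffold_id)
  if (length(extra))
    scaffolds <- rbind(scaffolds,
                       data.frame(scaffold_id = extra, length = NA_real_))
  known <- !is.na(scaffolds$length)
  if (any(known)) {
    lim <- stats::setNames(scaffolds$length, scaffolds$scaffold_id)
    bad <- genes$end > lim[genes$scaffold_id] & !is.na(lim[genes$scaffold_id])
    if (any(bad))
      stop("gene(s) extend past known scaffold length: ",
           paste(genes$gene_id[bad], collapse = ", "))
  }
  structure(list(genome_id = genome_id, scaffolds = scaffolds, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation", x$genome_id, "--", nrow(x$genes), "genes on",
      nrow(x$scaffolds), "scaffold(s)\n")
  invisible(x)
}

# deterministic synthetic id for features lacking locus_tag/ID/protein_id
.synthetic_id <- function(scaffold_id, ordinal) {
  sprintf("%s_feat%04d", scaffold_id, ordinal)
}

.precheck_lines <- function(path, min_fields, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment) & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  bad <- which(nf < min_fields)
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    stop("parse error at line ", lineno, " of ", basename(path),
         ": expected at least ", min_fields, " tab-separated fields, found ",
         nf[bad[1]])
  }
  invisible(sum(keep))
}

#' Read gene features from GFF3 or flat TSV
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. Gene identity is taken from `locus_tag`, else `ID`,
#' else `protein_id`, else a deterministic synthetic id (scaffold + ordinal).
#' A flat TSV must carry a header with columns `gene_id`, `scaffold_id`,
#' `start`, `end` (already 0-based half-open) and optionally `strand`,
#' `annotation`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @param genome_id genome identifier for the returned annotation.
#' @return a [genome_annotation()] object.
#' @export
read_gene_features <- function(path, genome_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    n <- .precheck_lines(path, 9L)
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    # prefer gene records when the file mixes feature types
    if ("type" %in% names(df) && any(tolower(as.character(df$type)) == "gene"))
      df <- df[tolower(as.character(df$type)) == "gene", , drop = FALSE]
    if (nrow(df) == 0) {
      warning("no gene records in ", basename(path), " for genome ", genome_id)
      return(genome_annotation(genome_id, gene_features(character(0),
        character(0), character(0), numeric(0), numeric(0))))
    }
    pick <- function(col) if (col %in% names(df)) as.character(df[[col]]) else
      rep(NA_character_, nrow(df))
    id <- pick("locus_tag")
    id <- ifelse(is.na(id), pick("ID"), id)
    id <- ifelse(is.na(id), pick("protein_id"), id)
    scaf <- as.character(df$seqnames)
    miss <- is.na(id)
    if (any(miss)) {
      ord <- stats::ave(seq_len(nrow(df)), scaf, FUN = seq_along)
      id[miss] <- .synthetic_id(scaf[miss], ord[miss])
    }
    ann <- pick("product")
    ann[is.na(ann)] <- ""
    strand <- as.character(df$strand)
    strand[!strand %in% c("+", "-")] <- "?"
    genes <- gene_features(id, genome_id, scaf,
                           start = df$start - 1, end = df$end,
                           strand = strand, annotation = ann)
    # scaffold lengths from ##sequence-region pragmas when present
    hdr <- grep("^##sequence-region", readLines(path, warn = FALSE),
                value = TRUE)
    scaffolds <- NULL
    if (length(hdr)) {
      parts <- strsplit(trimws(hdr), "\\s+")
      scaffolds <- data.frame(
        scaffold_id = vapply(parts, `[`, "", 2L),
        length = as.numeric(vapply(parts, `[`, "", 4L)))
    }
    return(genome_annotation(genome_id, genes, scaffolds))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("no gene records in ", basename(path), " for genome ", genome_id)
    return(genome_annotation(genome_id, gene_features(character(0),
      character(0), character(0), numeric(0), numeric(0))))
  }
  need <- c("gene_id", "scaffold_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene TSV must have columns ", paste(need, collapse = ", "))
  genes <- gene_features(df$gene_id, genome_id, df$scaffold_id, df$start,
                         df$end,
                         strand = if ("strand" %in% names(df)) df$strand else "?",
                         annotation = if ("annotation" %in% names(df))
                           df$annotation else "")
  genome_annotation(genome_id, genes)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gene_features()]: internal 0-based half-open coordinates
#' are written 1-based inclusive; known scaffold lengths become
#' `##sequence-region` pragmas; gene ids are written as both `ID` and
#' `locus_tag` and annotations as `product`.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_features <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  sc <- annotation$scaffolds
  head <- "##gff-version 3"
  known <- !is.na(sc$length)
  if (any(known))
    head <- c(head, sprintf("##sequence-region %s 1 %d",
                            sc$scaffold_id[known], as.integer(sc$length[known])))
  attrs <- sprintf("ID=%s;locus_tag=%s%s", g$gene_id, g$gene_id,
                   ifelse(nzchar(g$annotation),
                          paste0(";product=", gsub("[;=\t]", " ", g$annotation)),
                          ""))
  body <- sprintf("%s\tglycomine\tgene\t%d\t%d\t.\t%s\t.\t%s",
                  g$scaffold_id, as.integer(g$start) + 1L, as.integer(g$end),
                  ifelse(g$strand %in% c("+", "-"), g$strand, "."), attrs)
  writeLines(c(head, body), path)
  invisible(path)
}

#' Construct a BGC interval table
#'
#' One row per biosynthetic gene cluster interval; coordinates 0-based
#' half-open.
#'
#' @param bgc_id,genome_id,scaffold_id character vectors.
#' @param start,end 0-based half-open coordinates; `start < end`.
#' @param predicted_type free-text product class (e.g. a PKS/NRPS class).
#' @param similar_cluster,similar_pct optional most-similar known cluster name
#'   and its percent gene similarity.
#' @return a `data.frame` of BGC intervals.
#' @export
bgc_intervals <- function(bgc_id, genome_id, scaffold_id, start, end,
                          predicted_type = "", similar_cluster = NA_character_,
                          similar_pct = NA_real_) {
  df <- data.frame(
    bgc_id = as.character(bgc_id),
    genome_id = as.character(genome_id),
    scaffold_id = as.character(scaffold_id),
    start = as.numeric(start), end = as.numeric(end),
    predicted_type = rep_len(as.character(predicted_type), length(bgc_id)),
    similar_cluster = rep_len(as.character(similar_cluster), length(bgc_id)),
    similar_pct = rep_len(as.numeric(similar_pct), length(bgc_id)),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$start < 0)) stop("negative BGC coordinate")
    if (any(df$start >= df$end)) stop("BGC intervals must satisfy start < end")
  }
  df
}

#' Read BGC intervals from BED or TSV
#'
#' BED coordinates are 0-based half-open and pass through unchanged. A TSV
#' must carry a header with `bgc_id`, `scaffold_id`, `start`, `end` and
#' optionally `predicted_type`, `similar_cluster`, `similar_pct`. Duplicate
#' intervals (same scaffold, start, end) are collapsed with a warning.
#'
#' @param path BED (`.bed`) or TSV file.
#' @param genome_id genome identifier.
#' @return a [bgc_intervals()] `data.frame` (possibly empty).
#' @export
read_bgc_intervals <- function(path, genome_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)) & !startsWith(lines, "#")))
    return(bgc_intervals(character(0), character(0), character(0),
                         numeric(0), numeric(0)))
  if (is_bed) {
    .precheck_lines(path, 3L)
    gr <- rtracklayer::import(path, format = "bed")
    df <- as.data.frame(gr)
    out <- bgc_intervals(
      bgc_id = if ("name" %in% names(df) && !all(is.na(df$name)))
        as.character(df$name) else sprintf("bgc%03d", seq_len(nrow(df))),
      genome_id = genome_id,
      scaffold_id = as.character(df$seqnames),
      start = df$start - 1, end = df$end)  # GRanges is 1-based inclusive
  } else {
    df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("bgc_id", "scaffold_id", "start", "end")
    if (!all(need %in% names(df)))
      stop("BGC TSV must have columns ", paste(need, collapse = ", "))
    grab <- function(col, default) if (col %in% names(df)) df[[col]] else default
    out <- bgc_intervals(df$bgc_id, genome_id, df$scaffold_id, df$start,
                         df$end,
                         predicted_type = grab("predicted_type", ""),
                         similar_cluster = grab("similar_cluster", NA),
                         similar_pct = grab("similar_pct", NA))
  }
  key <- paste(out$scaffold_id, out$start, out$end)
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicate BGC interval(s) in ",
            basename(path))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write BGC intervals as BED4
#'
#' @param bgcs a [bgc_intervals()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bgc_intervals <- function(bgcs, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", bgcs$scaffold_id,
                     as.integer(bgcs$start), as.integer(bgcs$end), bgcs$bgc_id),
             path)
  invisible(path)
}

#' Read BLAST tabular hits (12-column outfmt 6)
#'
#' Columns: query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Coverage is computed as the aligned subject
#' span divided by the subject length supplied through `subject_lengths`.
#'
#' @param path 12-column tab-separated file, no header.
#' @param subject_lengths named numeric vector, or a 2-column TSV path
#'   (`subject_id`, `length`), giving subject sequence lengths in residues.
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `evalue`, `coverage`, `bitscore`.
#' @export
read_blast_hits <- function(path, subject_lengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  if (!any(keep))
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), evalue = numeric(),
                      coverage = numeric(), bitscore = numeric()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(keep)[which(nf != 12L)[1]]
    stop("parse error at line ", bad, " of ", basename(path),
         ": expected 12 tab-separated columns, found ", nf[nf != 12L][1])
  }
  m <- do.call(rbind, fields)
  if (is.character(subject_lengths)) {
    lt <- utils::read.delim(subject_lengths, stringsAsFactors = FALSE)
    subject_lengths <- stats::setNames(lt[[2]], lt[[1]])
  }
  subj <- m[, 2]
  unknown <- setdiff(unique(subj), names(subject_lengths))
  if (length(unknown))
    stop("no subject length supplied for: ", paste(unknown, collapse = ", "))
  sstart <- as.numeric(m[, 9]); send <- as.numeric(m[, 10])
  span <- abs(send - sstart) + 1
  out <- data.frame(
    query_id = m[, 1], subject_id = subj,
    percent_identity = as.numeric(m[, 3]),
    evalue = as.numeric(m[, 11]),
    coverage = span / as.numeric(subject_lengths[subj]),
    bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (any(out$percent_identity < 0 | out$percent_identity > 100))
    stop("percent identity outside [0, 100]")
  if (any(out$evalue < 0)) stop("negative e-value")
  if (any(out$coverage < 0 | out$coverage > 1 + 1e-9))
    stop("coverage outside [0, 1]; check subject lengths")
  out
}

# "#"-commented TSV writer used by every stage for its outputs
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
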