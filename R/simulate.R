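# Synthetic genomes, proteomes and assay data with a known ground-truth
# manifest. The generator's defaults emulate the study conditions of the
# Streptomyces HTH_42 survey: ~49/43/8% YQL/AZL/AZL2 subfamily mix,
# YQL/AZL2 mostly single copy and >20 kb from any cluster (mean 25 kb),
# AZL multi-copy and inside or near clusters (mean |distance| 2.3 kb),
# and kinetic/dose-response curves generated from the package's fitted
# functional forms.

SAFE_RESIDUES <- c("G", "P", "W", "F", "Y", "C", "R", "N", "K")

#' Simulation configuration
#'
#' Defaults encode the study conditions; every field can be overridden.
#' Per-genome copy-number spectra give an expected subfamily mix of about
#' 49% YQL / 43% AZL / 8% AZL2. AZL placements split into inside
#' (distance 0), edge (gap <= 2 kb) and mid (gap with >= 6 intervening
#' genes) classes whose realized mean |distance| is calibrated to
#' `azl_mean_abs_distance`; YQL and AZL2 genes are planted far from clusters
#' (gaps rescaled to mean `far_mean_abs_distance`, all > 20 kb, >= 6
#' intervening genes).
#'
#' @param n_genomes number of genomes.
#' @param yql_copy_probs,azl_copy_probs,azl2_copy_probs named probability
#'   vectors over per-genome copy numbers (names are copy counts). Copy
#'   numbers are allocated to genomes by exact largest-remainder quota and
#'   shuffled, so the planted mix is realized for every seed.
#' @param azl_present_prob,azl2_present_prob probability a genome carries the
#'   subfamily at all.
#' @param azl_inside_frac,azl_edge_frac fractions of AZL plants placed inside
#'   a cluster / at the cluster edge (remainder are mid-range).
#' @param azl_edge_gap_range,azl_mid_gap_range uniform gap ranges (bp).
#' @param azl_mean_abs_distance target mean |distance| over all AZL plants
#'   (bp).
#' @param far_gap_range,far_mean_abs_distance gap range and target mean for
#'   YQL/AZL2 plants (bp).
#' @param far_min_intervening minimum intervening genes for far plants.
#' @param protein_length planted protein length (residues, before the random
#'   0-8 residue N-terminal extension).
#' @param window_offset 0-based catalytic window offset in the base
#'   sequences.
#' @param mutation_rates per-subfamily substitution rates applied to the base
#'   sequences (YQL conserved, AZL diverse).
#' @param decoy_frac fraction of extra motif-free decoy proteins (manifest
#'   label UNCLASSIFIED).
#' @param bgc_genes_range genes per synthetic cluster.
#' @param seed integer master seed; expanded into per-entity child seeds by a
#'   fixed counter scheme so adding entities never reshuffles existing ones.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 100,
                              yql_copy_probs = c("0" = 0.06, "1" = 0.86,
                                                 "2" = 0.08),
                              azl_present_prob = 0.45,
                              azl_copy_probs = c("1" = 0.35, "2" = 0.40,
                                                 "3" = 0.18, "4" = 0.05,
                                                 "5" = 0.02),
                              azl2_present_prob = 0.155,
                              azl2_copy_probs = c("1" = 0.93, "2" = 0.07),
                              azl_inside_frac = 0.40, azl_edge_frac = 0.35,
                              azl_edge_gap_range = c(200, 2000),
                              azl_mid_gap_range = c(3800, 11500),
                              azl_mean_abs_distance = 2300,
                              far_gap_range = c(21000, 29000),
                              far_mean_abs_distance = 25000,
                              far_min_intervening = 6,
                              protein_length = 360, window_offset = 45,
                              mutation_rates = c(YQL = 0.20, AZL = 0.50,
                                                 AZL2 = 0.35),
                              decoy_frac = 0,
                              bgc_genes_range = c(8, 12),
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genomes >= 1, protein_length > window_offset + 10,
            azl_inside_frac + azl_edge_frac <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

# fixed counter scheme for child seeds (kept below 2^31)
.child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 69621) %% 2147483563) + 1L
}

.mutate_seq <- function(res, rate, protect) {
  hit <- which(stats::runif(length(res)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) res[i] <- sample(setdiff(AA20, res[i]), 1)
  res
}

# replace residues so no motif occurs outside the planted slot
.scrub_motifs <- function(res, slot_start, slot_len) {
  slot <- if (slot_len > 0) slot_start + seq_len(slot_len) - 1L else integer()
  for (pass in 1:50) {
    sc <- scan_motif_windows(paste(res, collapse = ""))
    if (nrow(sc)) {
      keep <- sc$window_start + 1L != slot_start | slot_len == 0L
      sc <- sc[keep, , drop = FALSE]
    }
    if (nrow(sc) == 0) return(res)
    span <- sc$window_start[1] + seq_len(nchar(sc$window[1]))  # 1-based
    fix <- setdiff(span, slot)
    if (!length(fix)) stop("cannot scrub motif overlapping planted window")
    res[fix[1]] <- sample(SAFE_RESIDUES, 1)
  }
  stop("motif scrub did not converge")
}

.sample_window <- function(subfamily, variant = NULL) {
  pat <- motif_patterns()
  pick <- function(cls) if (length(cls) == 1) cls else sample(cls, 1)
  if (subfamily == "YQL") {
    w <- c("Q", pick(DEFAULT_ALIPHATIC), "D")
  } else if (subfamily == "AZL") {
    first <- if (is.null(variant)) pick(c("Q", "H")) else
      if (variant == "QxQ") "Q" else "H"
    w <- c(first, pick(DEFAULT_ALIPHATIC), "Q")
  } else if (subfamily == "AZL2") {
    w <- c("H", pick(DEFAULT_ALIPHATIC), pick(c("S", "T")), pick(c("D", "E")))
  } else stop("unknown subfamily ", subfamily)
  w
}

# family base sequences share a common ancestor so that anchored alignment is
# meaningful for every query/anchor combination
.make_bases <- function(length, window_offset, seed) {
  set.seed(seed)
  anc <- sample(AA20, length, replace = TRUE)
  anc <- .scrub_motifs(anc, 1L, 0L)  # slot is overwritten by derive()
  slot <- window_offset + 1:4
  derive <- function(window4) {
    b <- .mutate_seq(anc, 0.15, protect = slot)
    b[slot] <- window4
    .scrub_motifs(b, window_offset + 1L, 4L)
  }
  list(
    YQL  = derive(c("Q", "L", "D", sample(SAFE_RESIDUES, 1))),
    AZL  = derive(c("Q", "V", "Q", sample(SAFE_RESIDUES, 1))),
    AZL2 = derive(c("H", "I", "T", "D")),
    DECOY = derive(sample(SAFE_RESIDUES, 4, replace = TRUE))
  )
}

#' Generate one synthetic motif protein
#'
#' Mutates the subfamily's base sequence at the configured per-subfamily
#' rate (substitutions only, catalytic slot protected), resamples the
#' catalytic window from the subfamily's motif pattern, prepends a random
#' 0-8 residue extension, and vetoes accidental motifs outside the planted
#' window by targeted residue replacement. `subfamily = "UNCLASSIFIED"`
#' yields a motif-free decoy.
#'
#' @param subfamily `"YQL"`, `"AZL"`, `"AZL2"` or `"UNCLASSIFIED"`.
#' @param bases base-sequence set from the generator (or `NULL` to build one
#'   from `seed`).
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param variant AZL variant (`"QxQ"`/`"HxQ"`), or `NULL` to sample.
#' @return list with `sequence`, `window` (`NA` for decoys), `window_start`
#'   (0-based), `variant`.
#' @export
generate_motif_protein <- function(subfamily, config = simulation_config(),
                                   bases = NULL, seed = 1, variant = NULL) {
  if (is.null(bases))
    bases <- .make_bases(config$protein_length, config$window_offset, seed)
  set.seed(seed)
  w0 <- config$window_offset
  slot <- w0 + 1:4
  if (subfamily == "UNCLASSIFIED") {
    res <- .mutate_seq(bases$DECOY, config$mutation_rates[["AZL"]],
                       protect = slot)
    res[slot] <- sample(SAFE_RESIDUES, 4, replace = TRUE)
    res <- .scrub_motifs(res, 0L, 0L)
    ext <- sample(0:8, 1)
    if (ext) res <- c(sample(SAFE_RESIDUES, ext, replace = TRUE), res)
    return(list(sequence = paste(res, collapse = ""), window = NA_character_,
                window_start = NA_integer_, variant = NA_character_))
  }
  rate <- config$mutation_rates[[subfamily]]
  res <- .mutate_seq(bases[[subfamily]], rate, protect = slot)
  win <- .sample_window(subfamily, variant)
  res[slot[seq_along(win)]] <- win
  if (length(win) == 3L && res[slot[4]] %in% c("D", "E", "S", "T", "Q", "H"))
    res[slot[4]] <- sample(SAFE_RESIDUES, 1)  # keep 4-window motif-free
  res <- .scrub_motifs(res, w0 + 1L, 4L)
  ext <- sample(0:8, 1)
  if (ext) {
    pre <- sample(SAFE_RESIDUES, ext, replace = TRUE)
    res <- c(pre, res)
  }
  list(sequence = paste(res, collapse = ""),
       window = paste(win, collapse = ""),
       window_start = w0 + ext,
       variant = if (subfamily == "AZL") {
         if (win[1] == "Q") "QxQ" else "HxQ"
       } else NA_character_)
}

# annotation vocabularies
.BGC_PRODUCTS <- c("type 1 polyketide synthase", "nonribosomal peptide synthetase",
                   "ABC transporter permease", "cytochrome P450 monooxygenase",
                   "O-methyltransferase", "glycosyltransferase",
                   "DinB family DNA-damage inducible protein",
                   "drug resistance efflux pump", "terpene cyclase")
.HOUSEKEEPING <- c("ribosomal protein L3", "two-component histidine kinase",
                   "response regulator", "cell wall hydrolase",
                   "N-acetyltransferase", "ComF family DNA helicase",
                   "alcohol dehydrogenase", "sigma factor",
                   "hypothetical protein", "tRNA ligase",
                   "cell division protein FtsZ", "sensor kinase")

# cursor-based scaffold builder ------------------------------------------

.new_builder <- function(scaffold_id) {
  env <- new.env(parent = emptyenv())
  env$scaffold_id <- scaffold_id
  env$cursor <- 100
  env$genes <- list()
  env
}

.add_gene <- function(b, id, len, annotation, strand = "+", at = NULL) {
  start <- if (is.null(at)) b$cursor else at
  g <- list(gene_id = id, scaffold_id = b$scaffold_id, start = start,
            end = start + len, strand = strand, annotation = annotation)
  b$genes[[length(b$genes) + 1L]] <- g
  b$cursor <- max(b$cursor, g$end) + round(stats::runif(1, 100, 300))
  g
}

.builder_genes <- function(b) {
  do.call(rbind, lapply(b$genes, function(g)
    data.frame(g, stringsAsFactors = FALSE)))
}

#' Generate a synthetic genome set with ground truth
#'
#' Builds `n_genomes` multi-scaffold genomes, each carrying planted YQL, AZL
#' and AZL2 genes at exactly the manifest distances and gene ranks relative
#' to their own biosynthetic gene cluster, filler genes, cluster-only and
#' plain scaffolds, and one planted protein sequence per homolog gene.
#' Byte-identical for a fixed seed. When `out_dir` is given, one GFF3 and one
#' BED file per genome and a combined protein FASTA are written.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `annotations` (named list of [genome_annotation()]),
#'   `bgcs` (named list of [bgc_intervals()] tables), `proteins` (named
#'   character vector), `references` (list of [reference_anchor()]: AZL and
#'   YQL), `truth` (manifest: `plants`, `census`, per-genome ids), `files`
#'   (paths, when written).
#' @export
generate_genome_set <- function(config = simulation_config(), out_dir = NULL) {
  seed <- config$seed
  bases <- .make_bases(config$protein_length, config$window_offset,
                       .child_seed(seed, 1))
  references <- list(
    reference_anchor("AZL", paste(bases$AZL, collapse = ""),
                     config$window_offset),
    reference_anchor("YQL", paste(bases$YQL, collapse = ""),
                     config$window_offset))

  # ---- plan copy numbers per genome (exact quota allocation, shuffled) --
  set.seed(.child_seed(seed, 2))
  gid <- sprintf("G%03d", seq_len(config$n_genomes))
  ng <- config$n_genomes
  quota <- function(n, probs) {
    # largest-remainder apportionment of n genomes over copy classes
    k <- floor(n * probs)
    frac <- n * probs - k
    rem <- n - sum(k)
    if (rem > 0) {
      up <- order(frac, decreasing = TRUE)[seq_len(rem)]
      k[up] <- k[up] + 1L
    }
    rep(as.integer(names(probs)), k)
  }
  with_absent <- function(present_prob, probs) {
    npres <- round(present_prob * ng)
    sample(c(quota(npres, probs), rep(0L, ng - npres)))
  }
  yql_counts <- sample(quota(ng, config$yql_copy_probs))
  azl_counts <- with_absent(config$azl_present_prob, config$azl_copy_probs)
  azl2_counts <- with_absent(config$azl2_present_prob, config$azl2_copy_probs)
  plan <- lapply(seq_len(ng), function(i)
    c(YQL = yql_counts[i], AZL = azl_counts[i], AZL2 = azl2_counts[i]))
  census_true <- data.frame(genome_id = gid,
                            do.call(rbind, plan), row.names = NULL,
                            stringsAsFactors = FALSE)
  n_decoys <- round(config$decoy_frac * sum(unlist(plan)))

  # ---- plan AZL placements globally (exact class quotas, calibrated mean)
  n_azl <- sum(census_true$AZL)
  n_inside <- round(config$azl_inside_frac * n_azl)
  n_edge <- round(config$azl_edge_frac * n_azl)
  n_mid <- n_azl - n_inside - n_edge
  azl_class <- character(n_azl)
  if (n_azl) {
    pool <- c(rep("inside", n_inside), rep("edge", n_edge), rep("mid", n_mid))
    azl_class <- pool[order(stats::runif(n_azl))]
    edge_gaps <- round(stats::runif(sum(azl_class == "edge"),
                                    config$azl_edge_gap_range[1],
                                    config$azl_edge_gap_range[2]))
    mid_gaps <- stats::runif(sum(azl_class == "mid"),
                             config$azl_mid_gap_range[1],
                             config$azl_mid_gap_range[2])
    # calibrate realized mean |distance| to the configured target
    if (length(mid_gaps)) {
      target_sum <- config$azl_mean_abs_distance * n_azl - sum(edge_gaps)
      if (target_sum > 0) mid_gaps <- mid_gaps * target_sum / sum(mid_gaps)
      mid_gaps <- round(pmax(mid_gaps, config$azl_edge_gap_range[2] + 1000))
    }
  } else edge_gaps <- mid_gaps <- numeric(0)

  n_far <- sum(census_true$YQL) + sum(census_true$AZL2)
  far_gaps <- stats::runif(n_far, config$far_gap_range[1],
                           config$far_gap_range[2])
  if (n_far) {
    far_gaps <- far_gaps * config$far_mean_abs_distance / mean(far_gaps)
    far_gaps <- round(pmax(far_gaps, 20001))
  }

  idx <- list(edge = 1L, mid = 1L, far = 1L, azl = 1L, variant = 0L)

  annotations <- list(); bgc_list <- list()
  proteins <- character(); plants <- list()

  for (i in seq_len(config$n_genomes)) {
    g_seed <- .child_seed(seed, 100 + i)
    set.seed(g_seed)
    counts <- plan[[i]]
    gene_n <- 0L; scaf_n <- 0L; bgc_n <- 0L
    next_gene <- function() { gene_n <<- gene_n + 1L
      sprintf("%s_g%04d", gid[i], gene_n) }
    next_scaf <- function() { scaf_n <<- scaf_n + 1L
      sprintf("%s_s%02d", gid[i], scaf_n) }
    next_bgc <- function() { bgc_n <<- bgc_n + 1L
      sprintf("%s_bgc%02d", gid[i], bgc_n) }
    genes_acc <- list(); bgc_acc <- list()

    add_fillers <- function(b, n, products = .HOUSEKEEPING,
                            len_range = c(600, 1500)) {
      for (k in seq_len(n))
        .add_gene(b, next_gene(), round(stats::runif(1, len_range[1],
                                                     len_range[2])),
                  sample(products, 1),
                  strand = sample(c("+", "-"), 1))
    }
    add_bgc <- function(b, plant_inside = FALSE, plant_id = NULL) {
      nb <- sample(seq(config$bgc_genes_range[1], config$bgc_genes_range[2]), 1)
      plant_at <- if (plant_inside) sample(2:(nb - 1), 1) else -1L
      first_start <- b$cursor
      plant_gene <- NULL
      for (k in seq_len(nb)) {
        if (k == plant_at) {
          plant_gene <- .add_gene(b, plant_id, 1100,
                                  "HTH_42 family DNA glycosylase")
        } else {
          .add_gene(b, next_gene(), round(stats::runif(1, 800, 1600)),
                    sample(.BGC_PRODUCTS, 1), strand = sample(c("+", "-"), 1))
        }
      }
      last_end <- max(vapply(b$genes, function(g) g$end, numeric(1)))
      bgc <- list(bgc_id = next_bgc(), scaffold_id = b$scaffold_id,
                  start = first_start, end = last_end,
                  predicted_type = sample(c("T1PKS", "NRPS", "terpene",
                                            "T2PKS"), 1))
      bgc_acc[[length(bgc_acc) + 1L]] <<- bgc
      list(bgc = bgc, plant_gene = plant_gene)
    }
    fill_gap <- function(b, gap_lo, gap_hi, n_fill, len_range = c(240, 330)) {
      # n_fill genes fully inside the open interval (gap_lo, gap_hi)
      avail <- gap_hi - gap_lo - 100
      lens <- round(stats::runif(n_fill, len_range[1], len_range[2]))
      while (sum(lens) + (n_fill - 1) * 20 > avail && n_fill > 0) {
        n_fill <- n_fill - 1L; lens <- lens[seq_len(n_fill)]
      }
      if (!n_fill) return(0L)
      spare <- avail - sum(lens)
      gapspace <- floor(spare / (n_fill + 1))
      at <- gap_lo + 50
      for (k in seq_len(n_fill)) {
        at <- at + gapspace
        .add_gene(b, next_gene(), lens[k], sample(.HOUSEKEEPING, 1),
                  at = at)
        at <- at + lens[k]
      }
      n_fill
    }

    plant_scaffold <- function(subfamily, class, gap, side, plant_id,
                               n_fill) {
      b <- .new_builder(next_scaf())
      add_fillers(b, sample(2:4, 1))
      if (class == "inside") {
        res <- add_bgc(b, plant_inside = TRUE, plant_id = plant_id)
        pg <- res$plant_gene
        info <- list(signed_distance = 0, intervening = 0L, inside = TRUE,
                     nearest_bgc_id = res$bgc$bgc_id)
      } else if (side == "3prime") {   # gene after (higher coords): sign -
        res <- add_bgc(b)
        gap_lo <- res$bgc$end
        gene_start <- gap_lo + gap
        nf <- if (n_fill > 0) fill_gap(b, gap_lo, gene_start, n_fill) else 0L
        pg <- .add_gene(b, plant_id, 1100, "HTH_42 family DNA glycosylase",
                        at = gene_start)
        add_fillers(b, sample(2:3, 1))
        info <- list(signed_distance = -gap, intervening = nf,
                     inside = is_inside(-gap, nf),
                     nearest_bgc_id = res$bgc$bgc_id)
      } else {                         # gene before (lower coords): sign +
        pg <- .add_gene(b, plant_id, 1100, "HTH_42 family DNA glycosylase")
        bgc_start <- pg$end + gap
        nf <- if (n_fill > 0) fill_gap(b, pg$end, bgc_start, n_fill) else 0L
        b$cursor <- bgc_start
        res <- add_bgc(b)
        add_fillers(b, sample(2:3, 1))
        info <- list(signed_distance = gap, intervening = nf,
                     inside = is_inside(gap, nf),
                     nearest_bgc_id = res$bgc$bgc_id)
      }
      genes_acc[[length(genes_acc) + 1L]] <<- .builder_genes(b)
      info$scaffold_id <- b$scaffold_id
      info
    }

    plant_one <- function(subfamily, k) {
      plant_id <- next_gene()
      if (subfamily == "AZL") {
        class <- azl_class[idx$azl]
        gap <- switch(class, inside = 0,
                      edge = { v <- edge_gaps[idx$edge]
                               idx$edge <<- idx$edge + 1L; v },
                      mid = { v <- mid_gaps[idx$mid]
                              idx$mid <<- idx$mid + 1L; v })
        idx$azl <<- idx$azl + 1L
        n_fill <- if (class == "mid")
          config$far_min_intervening + sample(0:2, 1) else 0L
        idx$variant <<- idx$variant + 1L
        variant <- if (idx$variant %% 2L) "QxQ" else "HxQ"
      } else {
        class <- "far"
        gap <- far_gaps[idx$far]; idx$far <<- idx$far + 1L
        n_fill <- config$far_min_intervening + sample(0:4, 1)
        variant <- NULL
      }
      side <- if ((idx$azl + idx$far + k) %% 2L) "3prime" else "5prime"
      info <- plant_scaffold(subfamily, class, gap, side, plant_id, n_fill)
      prot <- generate_motif_protein(subfamily, config, bases,
                                     seed = .child_seed(seed,
                                       10000 + 1000 * i + gene_n),
                                     variant = variant)
      proteins[[plant_id]] <<- prot$sequence
      plants[[length(plants) + 1L]] <<- data.frame(
        genome_id = gid[i], gene_id = plant_id,
        scaffold_id = info$scaffold_id, subfamily = subfamily,
        azl_variant = if (is.null(variant)) NA_character_ else variant,
        placement = class, signed_distance = info$signed_distance,
        intervening_genes = info$intervening, inside = info$inside,
        nearest_bgc_id = info$nearest_bgc_id, window = prot$window,
        window_start = prot$window_start, stringsAsFactors = FALSE)
    }

    # plain scaffold + cluster-only scaffold for realism
    b0 <- .new_builder(next_scaf()); add_fillers(b0, sample(4:8, 1))
    genes_acc[[length(genes_acc) + 1L]] <- .builder_genes(b0)
    b1 <- .new_builder(next_scaf()); add_fillers(b1, 2); add_bgc(b1)
    add_fillers(b1, 2)
    genes_acc[[length(genes_acc) + 1L]] <- .builder_genes(b1)

    for (sf in c("YQL", "AZL", "AZL2"))
      for (k in seq_len(counts[[sf]])) plant_one(sf, k)

    genes <- do.call(rbind, genes_acc)
    ann <- genome_annotation(gid[i],
      gene_features(genes$gene_id, gid[i], genes$scaffold_id, genes$start,
                    genes$end, genes$strand, genes$annotation))
    annotations[[gid[i]]] <- ann
    bgc_list[[gid[i]]] <- if (length(bgc_acc)) bgc_intervals(
      vapply(bgc_acc, `[[`, "", "bgc_id"), gid[i],
      vapply(bgc_acc, `[[`, "", "scaffold_id"),
      vapply(bgc_acc, `[[`, 0, "start"), vapply(bgc_acc, `[[`, 0, "end"),
      vapply(bgc_acc, `[[`, "", "predicted_type"))
    else bgc_intervals(character(0), character(0), character(0),
                       numeric(0), numeric(0))
  }

  # decoy proteins (not tied to genes; motif-free)
  if (n_decoys > 0) {
    for (k in seq_len(n_decoys)) {
      prot <- generate_motif_protein("UNCLASSIFIED", config, bases,
                                     seed = .child_seed(seed, 900000 + k))
      proteins[[sprintf("decoy_%03d", k)]] <- prot$sequence
    }
  }

  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(genome_id = character(), gene_id = character(),
               subfamily = character())
  truth <- list(plants = plants, census = census_true,
                genome_ids = gid, config = config)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gff <- bed <- character(length(gid))
    for (i in seq_along(gid)) {
      gff[i] <- file.path(out_dir, paste0(gid[i], ".gff3"))
      bed[i] <- file.path(out_dir, paste0(gid[i], ".bed"))
      write_gene_features(annotations[[gid[i]]], gff[i])
      write_bgc_intervals(bgc_list[[gid[i]]], bed[i])
    }
    fasta <- file.path(out_dir, "proteins.fasta")
    writeLines(as.vector(rbind(paste0(">", names(proteins)),
                               unlist(proteins))), fasta)
    manifest <- file.path(out_dir, "truth_plants.tsv")
    write_tsv_commented(plants, manifest,
                        comments = c("synthetic ground-truth manifest",
                                     paste("seed", seed)))
    files <- list(gff3 = gff, bed = bed, fasta = fasta, manifest = manifest)
  }

  list(annotations = annotations, bgcs = bgc_list,
       proteins = unlist(proteins), references = references, truth = truth,
       files = files)
}

# ---- assay data ---------------------------------------------------------

#' Generate synthetic assay data from the kinetic functional forms
#'
#' Produces noiseless or Gaussian-noise kinetics inputs: single-turnover time
#' courses `A (1 - exp(-k t))`, growth curves with a planted lag (lagged
#' exponential capped at a carrying capacity), lag-time and percent-survival
#' dose-response series from the four-parameter Hill form. Defaults use the
#' reported enzymology values (kcat 7.8, 0.8 and 0.04 min^-1; lag-IC50 5.9
#' and 3.9 uM; survival IC50 48.1 and 11.1 uM).
#'
#' @param block list of generation blocks; see defaults in the function. Each
#'   time-course block has `k`, `A`, `times`; each dose-response block has
#'   `doses`, `ic50`, `h` and (for lag) `min_lag`, `max_lag`.
#' @param sigma Gaussian noise SD added independently per technical
#'   replicate and point (0 = noiseless).
#' @param replicates technical replicates averaged per reported point
#'   (default 3; assays are performed in triplicate and means are plotted).
#' @param seed integer seed.
#' @param out_dir optional directory for CSV output.
#' @return list with `time_courses`, `lag_curves`, `survival_curves` (each a
#'   named list of `data.frame`s) and `truth` (generating parameters).
#' @export
generate_assay_data <- function(block = default_assay_block(), sigma = 0,
                                replicates = 3, seed = 1, out_dir = NULL) {
  stopifnot(sigma >= 0, replicates >= 1)
  set.seed(.child_seed(seed, 7))
  noise <- function(n, scale = 1) if (sigma > 0)
    rowMeans(matrix(stats::rnorm(n * replicates, 0, sigma * scale),
                    nrow = n)) else rep(0, n)
  tcs <- lapply(block$time_courses, function(bl) {
    y <- bl$A * (1 - exp(-bl$k * bl$times)) + noise(length(bl$times))
    data.frame(time = bl$times, fraction_product = y)
  })
  lags <- lapply(block$lag_series, function(bl) {
    y <- .hill_response(bl$doses, bl$min_lag, bl$max_lag, bl$ic50, bl$h,
                        "increasing") +
      noise(length(bl$doses), scale = bl$max_lag - bl$min_lag)
    data.frame(dose = bl$doses, lag = y)
  })
  survs <- lapply(block$survival_series, function(bl) {
    y <- .hill_response(bl$doses, 0, 100, bl$ic50, bl$h, "decreasing") +
      noise(length(bl$doses), scale = 100)
    data.frame(dose = bl$doses, survival = y)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(lst, prefix) for (nm in names(lst))
      utils::write.csv(lst[[nm]],
                       file.path(out_dir, paste0(prefix, "_", nm, ".csv")),
                       row.names = FALSE)
    wr(tcs, "timecourse"); wr(lags, "lag"); wr(survs, "survival")
  }
  list(time_courses = tcs, lag_curves = lags, survival_curves = survs,
       truth = block, sigma = sigma, seed = seed)
}

#' Default assay generation block (reported enzymology values)
#'
#' @return nested list of generation parameters used by
#'   [generate_assay_data()].
#' @export
default_assay_block <- function() {
  doses <- c(0, 0.5, 1, 2, 5, 10, 25, 50, 100)
  # colony-survival series extends to saturation of the less sensitive strain
  doses_surv <- c(0, 2, 5, 10, 20, 50, 100, 200, 400)
  tgrid <- function(k) log(2) / k * c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
  list(
    time_courses = list(
      wildtype = list(k = 7.8, A = 1, times = tgrid(7.8)),
      q43a = list(k = 0.8, A = 1, times = tgrid(0.8)),
      q41a = list(k = 0.04, A = 1, times = tgrid(0.04))),
    lag_series = list(
      hedh4 = list(doses = doses, ic50 = 5.9, h = 2, min_lag = 2,
                   max_lag = 12),
      vector = list(doses = doses, ic50 = 3.9, h = 2, min_lag = 2,
                    max_lag = 12)),
    survival_series = list(
      hedh4 = list(doses = doses_surv, ic50 = 48.1, h = 1.5),
      vector = list(doses = doses_surv, ic50 = 11.1, h = 1.5))
  )
}

#' Generate a growth curve with a planted lag
#'
#' Lagged exponential capped at a carrying capacity:
#' `OD(t) = min(OD0 * exp(r * max(0, t - lag)), K)`, with optional
#' multiplicative Gaussian noise.
#'
#' @param lag planted lag (h).
#' @param rate exponential growth rate (per h).
#' @param times time grid (h).
#' @param od0 baseline OD600.
#' @param K carrying capacity.
#' @param sigma noise SD on log-OD.
#' @param seed integer seed.
#' @return `data.frame` with `time`, `od`.
#' @export
generate_growth_curve <- function(lag, rate, times, od0 = 0.01, K = 1,
                                  sigma = 0, seed = 1) {
  set.seed(.child_seed(seed, 11))
  od <- pmin(od0 * exp(rate * pmax(0, times - lag)), K)
  if (sigma > 0) od <- od * exp(stats::rnorm(length(od), 0, sigma))
  data.frame(time = times, od = od)
}
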