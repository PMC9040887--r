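# Catalytic-motif classification of HTH_42 proteins into the YQL, AZL and
# AZL2 subfamilies. Subfamilies are defined by short catalytic motifs:
#   YQL   Q-Phi-D          (3 residues)
#   AZL   (Q/H)-Phi-Q      (3 residues; variants QxQ and HxQ)
#   AZL2  H-Phi-(S/T)-(D/E) (4 residues)
# where Phi is an aliphatic residue. Position-3 classes {D}, {Q}, {S,T} are
# disjoint, so no window can match two patterns.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

DEFAULT_ALIPHATIC <- c("A", "V", "L", "I", "M")

SUBFAMILIES <- c("YQL", "AZL", "AZL2")

#' Catalytic motif patterns
#'
#' Returns the per-position residue classes defining the three subfamily
#' motifs. The aliphatic set Phi is configurable; the default is the
#' conservative set A/V/L/I/M.
#'
#' @param aliphatic residue set used for the Phi position.
#' @return named list of patterns; each pattern is a list of per-position
#'   allowed-residue character vectors.
#' @export
motif_patterns <- function(aliphatic = DEFAULT_ALIPHATIC) {
  list(
    YQL  = list("Q", aliphatic, "D"),
    AZL  = list(c("Q", "H"), aliphatic, "Q"),
    AZL2 = list("H", aliphatic, c("S", "T"), c("D", "E"))
  )
}

.match_pattern <- function(res, pattern) {
  length(res) == length(pattern) &&
    all(mapply(function(r, cls) r %in% cls, res, pattern))
}

#' Classify a catalytic window into a subfamily
#'
#' A 4-residue window is tested against the AZL2 pattern; a 3-residue window
#' against YQL then AZL. AZL calls carry the variant (`QxQ` or `HxQ`, `x`
#' standing for the aliphatic position) read from position 1.
#'
#' @param window residue string of length 3 or 4, uppercase amino-acid
#'   alphabet.
#' @inheritParams motif_patterns
#' @return list with elements `subfamily` (one of `YQL`, `AZL`, `AZL2`,
#'   `UNCLASSIFIED`) and `azl_variant` (`NA` unless subfamily is `AZL`).
#' @examples
#' classify_motif("QID")$subfamily   # YQL
#' classify_motif("HVQ")             # AZL, variant HxQ
#' classify_motif("HLTD")$subfamily  # AZL2
#' @export
classify_motif <- function(window, aliphatic = DEFAULT_ALIPHATIC) {
  stopifnot(is.character(window), length(window) == 1L)
  res <- strsplit(window, "")[[1]]
  if (!length(res) %in% c(3L, 4L))
    stop("window must be 3 or 4 residues, got ", length(res))
  if (!all(res %in% AA20))
    stop("non-amino-acid character in window: ",
         paste(setdiff(res, AA20), collapse = ""))
  pat <- motif_patterns(aliphatic)
  if (length(res) == 4L) {
    if (.match_pattern(res, pat$AZL2))
      return(list(subfamily = "AZL2", azl_variant = NA_character_))
    return(list(subfamily = "UNCLASSIFIED", azl_variant = NA_character_))
  }
  if (.match_pattern(res, pat$YQL))
    return(list(subfamily = "YQL", azl_variant = NA_character_))
  if (.match_pattern(res, pat$AZL))
    return(list(subfamily = "AZL",
                azl_variant = if (res[1] == "Q") "QxQ" else "HxQ"))
  list(subfamily = "UNCLASSIFIED", azl_variant = NA_character_)
}

#' Filter homology-search hits by e-value, identity and coverage
#'
#' Keeps hits with `evalue <= evalue_max`, `percent_identity >= identity_min`
#' and `coverage > coverage_min` (coverage strictly greater, matching the
#' ">75% coverage" convention). Input order is preserved.
#'
#' @param hits `data.frame` from [read_blast_hits()].
#' @param evalue_max e-value cutoff (inclusive), default `1e-4`.
#' @param identity_min percent-identity cutoff (inclusive), default 25.
#' @param coverage_min coverage fraction cutoff (exclusive), default 0.75.
#' @return the filtered `data.frame`.
#' @export
filter_hits <- function(hits, evalue_max = 1e-4, identity_min = 25,
                        coverage_min = 0.75) {
  stopifnot(evalue_max > 0, identity_min > 0, coverage_min > 0)
  keep <- hits$evalue <= evalue_max &
    hits$percent_identity >= identity_min &
    hits$coverage > coverage_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the catalytic window of a query by anchored pairwise alignment
#'
#' Globally aligns the query to a reference whose catalytic window position is
#' known (affine gaps, BLOSUM62) and reads off the query residues aligned to
#' the reference's catalytic columns. Returns `NULL` when any catalytic column
#' aligns to a gap in the query.
#'
#' @param query,reference protein sequences (character or `AAString`).
#' @param reference_window_start 0-based residue index of the window in the
#'   reference.
#' @param window_length 3 or 4.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return list with `window_start` (0-based index in the query), `window`
#'   (residue string) and `score` (alignment score), or `NULL` if not found.
#' @export
locate_catalytic_window <- function(query, reference, reference_window_start,
                                    window_length = 3L, gap_opening = 10,
                                    gap_extension = 0.5) {
  query <- as.character(query); reference <- as.character(reference)
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  if (reference_window_start < 0 ||
      reference_window_start + window_length > nchar(reference))
    stop("reference window does not fit in the reference sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  qa <- as.character(Biostrings::alignedPattern(pa))
  ra <- as.character(Biostrings::alignedSubject(pa))
  out <- .window_from_alignment(qa, ra, reference_window_start, window_length)
  if (is.null(out)) return(NULL)
  out$score <- Biostrings::score(pa)
  out
}

# classify the query window at an anchored position, tolerating a small
# alignment jitter: offsets 0, +/-1, +/-2 are examined and the first
# classifying window (3-residue patterns first, then the 4-residue AZL2
# pattern) is accepted; otherwise the window at the anchored position is
# reported UNCLASSIFIED
.probe_window <- function(seq, anchored_start, aliphatic) {
  n <- nchar(seq)
  for (off in c(0L, -1L, 1L, -2L, 2L)) {
    p <- anchored_start + off
    if (p < 0L) next
    w3 <- if (p + 3L <= n) substr(seq, p + 1L, p + 3L) else NULL
    if (!is.null(w3)) {
      cl <- classify_motif(w3, aliphatic)
      if (cl$subfamily != "UNCLASSIFIED")
        return(list(cl = cl, window = w3, window_start = p))
    }
    w4 <- if (p + 4L <= n) substr(seq, p + 1L, p + 4L) else NULL
    if (!is.null(w4)) {
      cl4 <- classify_motif(w4, aliphatic)
      if (cl4$subfamily != "UNCLASSIFIED")
        return(list(cl = cl4, window = w4, window_start = p))
    }
  }
  w3 <- substr(seq, anchored_start + 1L, min(anchored_start + 3L, n))
  list(cl = list(subfamily = "UNCLASSIFIED", azl_variant = NA_character_),
       window = w3, window_start = anchored_start)
}

# read the query residues aligned to the reference's catalytic columns out of
# one gapped alignment pair
.window_from_alignment <- function(qa, ra, reference_window_start,
                                   window_length) {
  qa <- strsplit(qa, "")[[1]]
  ra <- strsplit(ra, "")[[1]]
  ref_pos <- cumsum(ra != "-")
  cols <- match(reference_window_start + seq_len(window_length), ref_pos)
  if (anyNA(cols)) return(NULL)
  qres <- qa[cols]
  if (any(qres == "-")) return(NULL)
  q_pos <- cumsum(qa != "-")
  list(window_start = q_pos[cols[1]] - 1L,
       window = paste(qres, collapse = ""))
}

#' Regex-scan a sequence for motif windows (anchor-free fallback)
#'
#' Scans every 3- and 4-residue window of the raw sequence against the motif
#' patterns. Because short motifs occur by chance, anchored alignment
#' ([locate_catalytic_window()]) is the default window-location mechanism;
#' this scan is the explicit anchor-free fallback and is also used by the
#' synthetic generator to veto accidental motifs.
#'
#' @param sequence protein sequence (character).
#' @inheritParams motif_patterns
#' @return `data.frame` with columns `window_start` (0-based), `window`,
#'   `subfamily`; zero rows when no window matches.
#' @export
scan_motif_windows <- function(sequence, aliphatic = DEFAULT_ALIPHATIC) {
  res <- strsplit(as.character(sequence), "")[[1]]
  n <- length(res)
  pat <- motif_patterns(aliphatic)
  hits <- list()
  for (w in c(3L, 4L)) {
    if (n < w) next
    for (i in seq_len(n - w + 1L)) {
      win <- res[i:(i + w - 1L)]
      if (!all(win %in% AA20)) next
      for (nm in names(pat)) {
        if (length(pat[[nm]]) == w && .match_pattern(win, pat[[nm]]))
          hits[[length(hits) + 1L]] <- data.frame(
            window_start = i - 1L, window = paste(win, collapse = ""),
            subfamily = nm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(window_start = integer(), window = character(),
                      subfamily = character()))
  do.call(rbind, hits)
}

#' Reference anchor constructor
#'
#' @param name anchor label (e.g. `"AZL"`, `"YQL"`).
#' @param sequence anchor protein sequence.
#' @param window_start 0-based index of the catalytic window in the anchor.
#' @return list usable in the `references` argument of [classify_proteome()].
#' @export
reference_anchor <- function(name, sequence, window_start) {
  list(name = name, sequence = as.character(sequence),
       window_start = as.integer(window_start))
}

#' Classify a set of proteins into glycosylase subfamilies
#'
#' Each protein's catalytic window is located by anchored alignment against
#' every supplied reference and the motif is then verified at the anchored
#' position (tolerating up to two columns of alignment jitter around the
#' catalytic site): 3-residue windows are classified YQL/AZL first, then the
#' 4-residue AZL2 pattern. A classified call is preferred over UNCLASSIFIED;
#' among classified calls from different anchors the higher alignment score
#' wins, ties breaking toward the AZL anchor.
#'
#' @param proteins named character vector or `AAStringSet` of protein
#'   sequences; names are protein ids.
#' @param references list of [reference_anchor()] objects (at least one);
#'   typically an AZL anchor and a YQL anchor.
#' @param aliphatic Phi residue set.
#' @param mode `"anchor"` (alignment to references, default) or `"scan"`
#'   (regex scan, anchor-free fallback).
#' @return list with `calls` (`data.frame`: `protein_id`, `subfamily`,
#'   `azl_variant`, `window`, `window_start`, `anchor`) and `summary`
#'   (`data.frame`: `subfamily`, `n`, `percent`; percentages over all input
#'   proteins and summing to 100).
#' @export
classify_proteome <- function(proteins, references,
                              aliphatic = DEFAULT_ALIPHATIC,
                              mode = c("anchor", "scan")) {
  mode <- match.arg(mode)
  if (methods::is(proteins, "XStringSet")) {
    seqs <- stats::setNames(as.character(proteins), names(proteins))
  } else seqs <- proteins
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("proteins must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (mode == "anchor" && length(references) < 1L)
    stop("at least one reference anchor required")
  if (mode == "anchor") {
    # one vectorised alignment pass per anchor
    aln <- lapply(references, function(ref) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(unname(seqs)),
        Biostrings::AAString(ref$sequence), type = "global",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
      list(qa = as.character(Biostrings::alignedPattern(pa)),
           ra = as.character(Biostrings::alignedSubject(pa)),
           score = Biostrings::score(pa))
    })
  }
  call_one <- function(id) {
    seq <- seqs[[id]]
    if (mode == "scan") {
      sc <- scan_motif_windows(seq, aliphatic)
      if (nrow(sc) == 0)
        return(data.frame(protein_id = id, subfamily = "UNCLASSIFIED",
                          azl_variant = NA_character_, window = NA_character_,
                          window_start = NA_integer_, anchor = "scan"))
      # first match in sequence order
      cl <- classify_motif(sc$window[1], aliphatic)
      return(data.frame(protein_id = id, subfamily = cl$subfamily,
                        azl_variant = cl$azl_variant, window = sc$window[1],
                        window_start = sc$window_start[1], anchor = "scan"))
    }
    i <- match(id, names(seqs))
    best <- NULL
    for (r in seq_along(references)) {
      ref <- references[[r]]
      qa <- aln[[r]]$qa[i]; ra <- aln[[r]]$ra[i]
      loc3 <- .window_from_alignment(qa, ra, ref$window_start, 3L)
      cand <- NULL
      if (!is.null(loc3)) {
        # verify the motif at the anchored position, tolerating a one- or
        # two-column misalignment around the catalytic site
        probe <- .probe_window(seq, loc3$window_start, aliphatic)
        cand <- list(cl = probe$cl,
                     loc = list(window_start = probe$window_start,
                                window = probe$window,
                                score = aln[[r]]$score[i]),
                     anchor = ref$name)
      }
      if (is.null(cand)) next
      if (is.null(best)) { best <- cand; next }
      best_cls <- best$cl$subfamily != "UNCLASSIFIED"
      cand_cls <- cand$cl$subfamily != "UNCLASSIFIED"
      take <- (cand_cls && !best_cls) ||
        (cand_cls == best_cls && cand$loc$score > best$loc$score) ||
        (cand_cls == best_cls && cand$loc$score == best$loc$score &&
           cand$anchor == "AZL" && best$anchor != "AZL")
      if (take) best <- cand
    }
    if (is.null(best))
      return(data.frame(protein_id = id, subfamily = "UNCLASSIFIED",
                        azl_variant = NA_character_, window = NA_character_,
                        window_start = NA_integer_, anchor = NA_character_))
    data.frame(protein_id = id, subfamily = best$cl$subfamily,
               azl_variant = best$cl$azl_variant, window = best$loc$window,
               window_start = best$loc$window_start, anchor = best$anchor,
               stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, lapply(names(seqs), call_one))
  rownames(calls) <- NULL
  lev <- c(SUBFAMILIES, "UNCLASSIFIED")
  n <- table(factor(calls$subfamily, levels = lev))
  summary <- data.frame(subfamily = lev, n = as.integer(n),
                        percent = if (sum(n)) 100 * as.integer(n) / sum(n)
                                  else rep(0, length(lev)))
  list(calls = calls, summary = summary)
}

#' Position frequency matrix of catalytic windows
#'
#' Per-column residue probabilities over the 20 amino acids for a set of
#' equal-length windows (the data behind a sequence logo).
#'
#' @param windows character vector of windows, all the same length.
#' @return 20 x L numeric matrix; rows are amino acids, columns sum to 1.
#' @export
motif_frequency_matrix <- function(windows) {
  windows <- windows[!is.na(windows)]
  if (!length(windows)) stop("at least one window required")
  lens <- unique(nchar(windows))
  if (length(lens) != 1L)
    stop("mixed window lengths: ", paste(lens, collapse = ", "))
  m <- do.call(rbind, strsplit(windows, ""))
  pfm <- vapply(seq_len(lens), function(j) {
    tab <- table(factor(m[, j], levels = AA20))
    as.numeric(tab) / length(windows)
  }, numeric(length(AA20)))
  dimnames(pfm) <- list(AA20, paste0("pos", seq_len(lens)))
  pfm
}
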