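test_that("catalytic windows classify into the right subfamilies", {
  expect_equal(classify_motif("QID")$subfamily, "YQL")
  expect_equal(classify_motif("QVQ"),
               list(subfamily = "AZL", azl_variant = "QxQ"))
  expect_equal(classify_motif("HVQ"),
               list(subfamily = "AZL", azl_variant = "HxQ"))
  expect_equal(classify_motif("HLTD")$subfamily, "AZL2")
  expect_equal(classify_motif("HLSE")$subfamily, "AZL2")
  expect_equal(classify_motif("KGE")$subfamily, "UNCLASSIFIED")
  expect_equal(classify_motif("QIDA")$subfamily, "UNCLASSIFIED") # 4-mer: AZL2 only
  expect_error(classify_motif("QXZ"), "non-amino-acid")
  expect_error(classify_motif("QV"), "3 or 4")
})

test_that("no trigram is accepted by two motif patterns (exhaustive)", {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  grid <- expand.grid(a = aa, b = aa, c = aa, stringsAsFactors = FALSE)
  pat <- motif_patterns()
  yql <- grid$a %in% pat$YQL[[1]] & grid$b %in% pat$YQL[[2]] &
    grid$c %in% pat$YQL[[3]]
  azl <- grid$a %in% pat$AZL[[1]] & grid$b %in% pat$AZL[[2]] &
    grid$c %in% pat$AZL[[3]]
  expect_equal(nrow(grid), 8000)
  expect_false(any(yql & azl))
  # position-3 classes of the three patterns are pairwise disjoint
  expect_length(intersect(pat$YQL[[3]], pat$AZL[[3]]), 0)
  expect_length(intersect(pat$YQL[[3]], pat$AZL2[[3]]), 0)
  expect_length(intersect(pat$AZL[[3]], pat$AZL2[[3]]), 0)
  # classify_motif agrees with the direct pattern evaluation everywhere
  set.seed(11)
  idx <- sample(nrow(grid), 300)
  for (i in idx) {
    w <- paste0(grid$a[i], grid$b[i], grid$c[i])
    want <- if (yql[i]) "YQL" else if (azl[i]) "AZL" else "UNCLASSIFIED"
    expect_equal(classify_motif(w)$subfamily, want)
  }
})

test_that("hit filtering applies the e-value/identity/coverage cutoffs", {
  hits <- data.frame(
    query_id = sprintf("q%d", 1:6), subject_id = "ref",
    percent_identity = c(40, 30, 24.9, 25, 40, 40),
    evalue = c(1e-3, 1e-5, 1e-6, 1e-4, 1e-5, 1e-5),
    coverage = c(0.9, 0.9, 0.9, 0.9, 0.75, 0.76),
    bitscore = 100)
  kept <- filter_hits(hits)
  # q1 fails e-value; q3 fails identity; q5 fails strict coverage bound
  expect_equal(kept$query_id, c("q2", "q4", "q6"))
  expect_equal(filter_hits(hits[0, ]), hits[0, ])
})

test_that("anchored window location is exact for identity and shifted queries", {
  gs <- small_genome_set()
  ref <- gs$references[[1]]  # AZL anchor
  loc <- locate_catalytic_window(ref$sequence, ref$sequence,
                                 ref$window_start, 3L)
  expect_equal(loc$window_start, ref$window_start)
  expect_equal(loc$window,
               substr(ref$sequence, ref$window_start + 1,
                      ref$window_start + 3))
  # translation property under prefix padding
  pad <- paste0(strrep("G", 10), ref$sequence)
  locp <- locate_catalytic_window(pad, ref$sequence, ref$window_start, 3L)
  expect_equal(locp$window_start, ref$window_start + 10L)
  expect_equal(locp$window, loc$window)
  # suffix padding leaves the window untouched
  locs <- locate_catalytic_window(paste0(ref$sequence, strrep("G", 15)),
                                  ref$sequence, ref$window_start, 3L)
  expect_equal(locs$window_start, ref$window_start)
  expect_error(locate_catalytic_window("", ref$sequence, 1, 3), "empty")
})

test_that("window location reports not-found when catalytic columns are deleted", {
  gs <- small_genome_set()
  ref <- gs$references[[1]]
  w <- ref$window_start
  gapped <- paste0(substr(ref$sequence, 1, w - 2),
                   substr(ref$sequence, w + 7, nchar(ref$sequence)))
  expect_null(locate_catalytic_window(gapped, ref$sequence, w, 3L))
})

test_that("proteome classification recovers planted labels and sums to n", {
  gs <- small_genome_set()
  res <- classify_proteome(gs$proteins, gs$references)
  expect_equal(nrow(res$calls), length(gs$proteins))
  expect_equal(sum(res$summary$n), length(gs$proteins))
  expect_equal(sum(res$summary$percent), 100, tolerance = 1e-9)
  truth <- gs$truth$plants
  got <- res$calls$subfamily[match(truth$gene_id, res$calls$protein_id)]
  expect_equal(got, truth$subfamily)
  # planted windows and offsets are recovered exactly
  gotw <- res$calls$window[match(truth$gene_id, res$calls$protein_id)]
  expect_equal(gotw, truth$window)
  gots <- res$calls$window_start[match(truth$gene_id, res$calls$protein_id)]
  expect_equal(gots, truth$window_start)
})

test_that("single-protein and degenerate proteome cases behave", {
  gs <- small_genome_set()
  one <- classify_proteome(gs$proteins[1], gs$references)
  expect_equal(one$summary$percent[one$summary$subfamily ==
                                     one$calls$subfamily[1]], 100)
  expect_error(classify_proteome(stats::setNames(gs$proteins[c(1, 1)],
                                                 c("a", "a")),
                                 gs$references), "duplicate")
})

test_that("scan mode classifies planted motifs without anchors", {
  cfg <- simulation_config()
  p <- generate_motif_protein("YQL", cfg, seed = 5)
  res <- classify_proteome(c(p1 = p$sequence), references = list(),
                           mode = "scan")
  expect_equal(res$calls$subfamily, "YQL")
  expect_equal(res$calls$window_start, p$window_start)
})

test_that("position frequency matrices count residues per column", {
  pfm <- motif_frequency_matrix(rep("QVD", 7))
  expect_equal(unname(pfm["Q", 1]), 1)
  expect_equal(unname(colSums(pfm)), rep(1, 3))

  pfm2 <- motif_frequency_matrix(c("QVQ", "HVQ"))
  expect_equal(unname(pfm2["Q", 1]), 0.5)
  expect_equal(unname(pfm2["H", 1]), 0.5)

  # counting oracle on random windows
  set.seed(3)
  wins <- replicate(40, paste(sample(c("Q", "H", "V", "D", "S"), 4,
                                     replace = TRUE), collapse = ""))
  pfm3 <- motif_frequency_matrix(wins)
  chars <- do.call(rbind, strsplit(wins, ""))
  for (j in 1:4)
    expect_equal(unname(pfm3["Q", j]), sum(chars[, j] == "Q") / 40)
  expect_equal(unname(colSums(pfm3)), rep(1, 4), tolerance = 1e-9)
  expect_error(motif_frequency_matrix(c("QVD", "QVDA")), "mixed")
})
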