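test_that("genome generation is byte-identical for a fixed seed", {
  cfg <- simulation_config(n_genomes = 3, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_genome_set(cfg, out_dir = d1)
  g2 <- generate_genome_set(cfg, out_dir = d2)
  expect_identical(g1$truth$plants, g2$truth$plants)
  expect_identical(g1$proteins, g2$proteins)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed moves the random layout
  g3 <- generate_genome_set(simulation_config(n_genomes = 3, seed = 100))
  expect_false(identical(g1$truth$plants$signed_distance,
                         g3$truth$plants$signed_distance))
})

test_that("one GFF3/BED pair per genome and manifest covers every genome", {
  cfg <- simulation_config(n_genomes = 10, seed = 5)
  d <- withr::local_tempdir()
  gs <- generate_genome_set(cfg, out_dir = d)
  expect_length(list.files(d, pattern = "\\.gff3$"), 10)
  expect_length(list.files(d, pattern = "\\.bed$"), 10)
  expect_equal(gs$truth$genome_ids, sprintf("G%03d", 1:10))
  expect_setequal(unique(gs$truth$census$genome_id), gs$truth$genome_ids)
  # every planted entity appears in the manifest exactly once
  expect_false(anyDuplicated(gs$truth$plants$gene_id) > 0)
  expect_setequal(gs$truth$plants$gene_id, names(gs$proteins))
})

test_that("planted placements realize manifest distances and gene ranks", {
  gs <- small_genome_set()
  plants <- gs$truth$plants
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    ann <- gs$annotations[[p$genome_id]]
    got <- nearest_bgc(ann$genes[ann$genes$gene_id == p$gene_id, ],
                       gs$bgcs[[p$genome_id]], ann)
    expect_equal(got$signed_distance, p$signed_distance)
    expect_equal(got$intervening_genes, p$intervening_genes)
    expect_equal(got$inside, p$inside)
    expect_equal(got$nearest_bgc_id, p$nearest_bgc_id)
  }
  # far plants honour the exclusion zone and the gene-rank rule
  far <- plants[plants$placement == "far", ]
  expect_true(all(abs(far$signed_distance) > 20000))
  expect_true(all(far$intervening_genes >= 6))
  expect_true(all(!far$inside))
})

test_that("a cluster-edge AZL plant is called inside under the 2 kb rule", {
  cfg <- simulation_config(
    n_genomes = 2, seed = 3,
    yql_copy_probs = c("0" = 1), azl2_present_prob = 0,
    azl_present_prob = 1, azl_copy_probs = c("1" = 1),
    azl_inside_frac = 0, azl_edge_frac = 1,
    azl_edge_gap_range = c(1500, 1500), azl_mean_abs_distance = 1500)
  gs <- generate_genome_set(cfg)
  expect_equal(abs(gs$truth$plants$signed_distance), c(1500, 1500))
  expect_true(all(gs$truth$plants$inside))
  p <- gs$truth$plants[1, ]
  ann <- gs$annotations[[p$genome_id]]
  got <- nearest_bgc(ann$genes[ann$genes$gene_id == p$gene_id, ],
                     gs$bgcs[[p$genome_id]], ann)
  expect_true(got$inside)
})

test_that("motif proteins round-trip through the classifier", {
  cfg <- simulation_config()
  for (sf in c("YQL", "AZL", "AZL2")) {
    p <- generate_motif_protein(sf, cfg, seed = 23)
    expect_equal(classify_motif(p$window)$subfamily, sf)
    # the planted window sits at the recorded offset
    expect_equal(substr(p$sequence, p$window_start + 1,
                        p$window_start + nchar(p$window)), p$window)
    # no accidental motif elsewhere
    sc <- scan_motif_windows(p$sequence)
    expect_equal(unique(sc$window_start), p$window_start)
  }
  d <- generate_motif_protein("UNCLASSIFIED", cfg, seed = 23)
  expect_equal(nrow(scan_motif_windows(d$sequence)), 0)
  # reproducible for a fixed seed
  expect_identical(generate_motif_protein("AZL", cfg, seed = 4)$sequence,
                   generate_motif_protein("AZL", cfg, seed = 4)$sequence)
})

test_that("assay data are noiseless at sigma 0 and reproducibly noisy otherwise", {
  a0 <- generate_assay_data(sigma = 0, seed = 1)
  tc <- a0$time_courses$wildtype
  expect_equal(tc$fraction_product, 1 - exp(-7.8 * tc$time))
  expect_equal(a0$lag_curves$hedh4$lag[1], 2)     # dose 0 -> min lag

  n1 <- generate_assay_data(sigma = 0.02, seed = 6)
  n2 <- generate_assay_data(sigma = 0.02, seed = 6)
  n3 <- generate_assay_data(sigma = 0.02, seed = 7)
  expect_identical(n1$time_courses, n2$time_courses)
  expect_false(identical(n1$time_courses, n3$time_courses))
  expect_error(generate_assay_data(sigma = -1), "sigma")
})
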