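test_that("signed distance is 0 on overlap/touch and signed by scaffold side", {
  ann <- toy_annotation(c(100, 0, 5000), c(400, 100, 6000))
  g <- function(id) ann$genes[ann$genes$gene_id == id, ]
  expect_equal(signed_distance(g("g01"), toy_bgcs(200, 900)[1, ]), 0)  # overlap
  expect_equal(signed_distance(g("g02"), toy_bgcs(100, 500)[1, ]), 0)  # touching
  expect_equal(signed_distance(g("g03"), toy_bgcs(1000, 3000)[1, ]), -2000)
  expect_equal(signed_distance(g("g02"), toy_bgcs(1500, 3000)[1, ]), 1400)
  other <- toy_bgcs(10, 20, scaffold = "s2")
  expect_error(signed_distance(g("g01"), other[1, ]), "different scaffolds")
})

test_that("the inside rule is a disjunction of the 2 kb and 5-gene conditions", {
  expect_true(is_inside(1900, 8))    # close in bp, many genes between
  expect_true(is_inside(-5000, 3))   # few genes between, far in bp
  expect_false(is_inside(30000, 10))
  expect_true(is_inside(0, 99))
  # monotone: shrinking either quantity never flips inside -> outside
  set.seed(4)
  for (i in 1:50) {
    d <- sample(0:50000, 1); n <- sample(0:12, 1)
    if (is_inside(d, n)) {
      expect_true(is_inside(max(d - sample(0:d, 1), 0), n))
      expect_true(is_inside(d, max(n - 1, 0)))
    }
  }
})

test_that("nearest_bgc matches the exhaustive all-pairs oracle on random layouts", {
  set.seed(21)
  for (rep in 1:25) {
    n_genes <- 8; n_bgcs <- 6
    gstart <- sort(sample(0:500000, n_genes)) * 2
    ann <- toy_annotation(gstart, gstart + 800,
                          scaffold = sample(c("s1", "s2"), 1))
    bstart <- sample(0:900000, n_bgcs)
    bgcs <- rbind(toy_bgcs(bstart, bstart + sample(5000:20000, n_bgcs),
                           scaffold = "s1"),
                  toy_bgcs(bstart + 7, bstart + 9000, scaffold = "s2",
                           ids = sprintf("c%02d", 1:n_bgcs)))
    for (i in seq_len(n_genes)) {
      got <- nearest_bgc(ann$genes[i, ], bgcs, ann)
      want <- oracle_nearest(ann$genes[i, ], bgcs)
      if (is.null(want)) {
        expect_true(is.na(got$nearest_bgc_id))
        expect_false(got$inside)
      } else {
        expect_equal(got$nearest_bgc_id, want$id)
        expect_equal(got$signed_distance, want$d)
      }
    }
  }
})

test_that("nearest_bgc honours the strict 2 Mbp cutoff and same-scaffold rule", {
  ann <- toy_annotation(0, 1000)
  far <- toy_bgcs(1000 + 2e6, 1000 + 2e6 + 5000)          # exactly at cutoff
  expect_true(is.na(nearest_bgc(ann$genes[1, ], far, ann)$nearest_bgc_id))
  near <- toy_bgcs(1000 + 2e6 - 1, 1000 + 2e6 + 5000)
  expect_equal(nearest_bgc(ann$genes[1, ], near, ann)$signed_distance,
               2e6 - 1)
  cross <- toy_bgcs(1100, 2000, scaffold = "other")
  expect_true(is.na(nearest_bgc(ann$genes[1, ], cross, ann)$nearest_bgc_id))
  overlap <- toy_bgcs(500, 2000)
  got <- nearest_bgc(ann$genes[1, ], overlap, ann)
  expect_equal(got$signed_distance, 0)
  expect_true(got$inside)
})

test_that("mirroring a scaffold flips distance signs and keeps inside calls", {
  gs <- small_genome_set()
  gid <- names(gs$annotations)[1]
  ann <- gs$annotations[[gid]]; bgcs <- gs$bgcs[[gid]]
  plants <- gs$truth$plants[gs$truth$plants$genome_id == gid, ]
  L <- max(ann$genes$end) + 1000
  mann <- mirror_genes(ann, L); mbgcs <- mirror_bgcs(bgcs, L)
  for (id in plants$gene_id) {
    a <- nearest_bgc(ann$genes[ann$genes$gene_id == id, ], bgcs, ann)
    b <- nearest_bgc(mann$genes[mann$genes$gene_id == id, ], mbgcs, mann)
    expect_equal(b$signed_distance, -a$signed_distance)
    expect_equal(b$intervening_genes, a$intervening_genes)
    expect_equal(b$inside, a$inside)
  }
})

test_that("distance summaries match manual order statistics", {
  one <- data.frame(nearest_bgc_id = "b", signed_distance = -4000)
  s <- distance_summary(one, "AZL")
  expect_equal(s$mean, -4000)
  expect_equal(s$median, -4000)

  set.seed(9)
  d <- sample(-50000:50000, 41)
  res <- data.frame(nearest_bgc_id = "b", signed_distance = d)
  s2 <- distance_summary(res, "YQL")
  expect_equal(s2$q25, manual_quantile(d, 0.25))
  expect_equal(s2$median, manual_quantile(d, 0.5))
  expect_equal(s2$q75, manual_quantile(d, 0.75))
  expect_true(s2$q25 <= s2$median && s2$median <= s2$q75)
  expect_equal(s2$mean_abs, mean(abs(d)))

  # unassigned genes are excluded and counted separately
  res$nearest_bgc_id[1:5] <- NA
  s3 <- distance_summary(res, "YQL")
  expect_equal(s3$n, 36)
  expect_equal(s3$n_unassigned, 5)
})

test_that("chi-square distance comparison matches the closed form", {
  a <- c(0, 0, 500, 1500, 25000)
  same <- compare_distance_distributions(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # hand-built 2x2 table {10,0 / 0,10}: expected 5 everywhere, X2 = 20
  x <- rep(100, 10); y <- rep(30000, 10)
  res <- compare_distance_distributions(x, y, bin_edges = c(0, 2000, Inf))
  expect_equal(res$statistic, 20)
  expect_lt(res$p_value, 1e-4)

  # statistic symmetric in the two samples
  res2 <- compare_distance_distributions(y, x, bin_edges = c(0, 2000, Inf))
  expect_equal(res2$statistic, res$statistic)

  expect_error(compare_distance_distributions(x, x,
                                              bin_edges = c(0, 2000, Inf)),
               "non-empty bins")
  expect_error(compare_distance_distributions(numeric(0), y), "nonempty")
})
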