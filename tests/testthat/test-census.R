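test_that("census counts classified calls per genome and conserves totals", {
  calls <- data.frame(genome_id = c("g1", "g1", "g2", "g2", "g2"),
                      subfamily = c("YQL", "AZL", "AZL", "AZL",
                                    "UNCLASSIFIED"))
  cen <- census(calls)
  expect_equal(cen$YQL[cen$genome_id == "g1"], 1)
  expect_equal(cen$AZL[cen$genome_id == "g1"], 1)
  expect_equal(cen$AZL[cen$genome_id == "g2"], 2)
  expect_equal(sum(cen$YQL) + sum(cen$AZL) + sum(cen$AZL2),
               sum(calls$subfamily != "UNCLASSIFIED"))
  expect_equal(nrow(census(calls[0, ])), 0)

  # conservation on random call sets
  set.seed(13)
  rnd <- data.frame(
    genome_id = sample(sprintf("g%d", 1:12), 200, replace = TRUE),
    subfamily = sample(c("YQL", "AZL", "AZL2", "UNCLASSIFIED"), 200,
                       replace = TRUE))
  cr <- census(rnd)
  expect_equal(sum(cr[, c("YQL", "AZL", "AZL2")]),
               sum(rnd$subfamily != "UNCLASSIFIED"))
})

test_that("copy-number spectra normalise over carrier genomes", {
  cen <- data.frame(genome_id = sprintf("g%d", 1:10),
                    YQL = c(rep(1, 9), 2), AZL = 0, AZL2 = 0)
  f <- copy_number_frequency(cen, "YQL")
  expect_equal(f$percent[f$copies == "1"], 90)
  expect_equal(f$percent[f$copies == "2"], 10)
  expect_equal(sum(f$percent), 100)

  allone <- data.frame(genome_id = "g", YQL = 1, AZL = 0, AZL2 = 0)
  expect_equal(copy_number_frequency(allone, "YQL")$percent[1], 100)
  expect_equal(nrow(copy_number_frequency(allone, "AZL")), 0)

  # >=5 copies bin together; include_zero switches the denominator
  cen$YQL[1] <- 8
  f2 <- copy_number_frequency(cen, "YQL")
  expect_equal(f2$percent[f2$copies == "5+"], 10)
  f3 <- copy_number_frequency(cen, "AZL", include_zero = TRUE)
  expect_equal(f3$percent[f3$copies == "0"], 100)

  set.seed(2)
  rnd <- data.frame(genome_id = sprintf("g%d", 1:30),
                    YQL = sample(0:6, 30, replace = TRUE), AZL = 0, AZL2 = 0)
  expect_equal(sum(copy_number_frequency(rnd, "YQL")$percent), 100,
               tolerance = 1e-9)
})

test_that("coincidence cells partition the genome set", {
  cen <- data.frame(genome_id = c("a", "b", "c"),
                    YQL = c(1, 1, 0), AZL = c(1, 0, 2), AZL2 = 0)
  co <- coincidence(cen)
  expect_equal(unname(co$totals["both"]), 1L)
  expect_equal(unname(co$totals["either_only"]), 2L)
  expect_equal(unname(co$totals["neither"]), 0L)
  expect_equal(sum(co$cells$n_genomes), nrow(cen))

  empty <- data.frame(genome_id = c("a", "b"), YQL = 0, AZL = 0, AZL2 = 0)
  expect_equal(unname(coincidence(empty)$totals["neither"]), 2L)

  # brute-force tally on random censuses
  set.seed(8)
  rnd <- data.frame(genome_id = sprintf("g%d", 1:40),
                    YQL = sample(0:3, 40, replace = TRUE),
                    AZL = sample(0:4, 40, replace = TRUE), AZL2 = 0)
  co2 <- coincidence(rnd)
  expect_equal(sum(co2$cells$n_genomes), 40)
  expect_equal(sum(co2$totals), 40)
  for (i in sample(nrow(co2$cells), 5))
    expect_equal(co2$cells$n_genomes[i],
                 sum(rnd$YQL == co2$cells$yql_count[i] &
                       rnd$AZL == co2$cells$azl_count[i]))
})

test_that("two-group ANOVA matches hand-computed sums of squares and F = t^2", {
  same <- c(1, 2, 3)
  res <- anova_pairwise(same, same)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)

  # {1,1,2} vs {2,3,3}: SSB = 8/3 (df 1), SSW = 4/3 (df 4) => F = 8
  res2 <- anova_pairwise(c(1, 1, 2), c(2, 3, 3))
  expect_equal(res2$F, 8)
  expect_equal(res2$df, c(1, 4))
  expect_equal(res2$p_value, stats::pf(8, 1, 4, lower.tail = FALSE))

  # relabelling the groups leaves F and P unchanged
  res3 <- anova_pairwise(c(2, 3, 3), c(1, 1, 2))
  expect_equal(res3$F, res2$F)
  expect_equal(res3$p_value, res2$p_value)

  # F = t^2 identity on random group pairs
  set.seed(17)
  for (i in 1:20) {
    a <- rpois(sample(5:15, 1), 2); b <- rpois(sample(5:15, 1), 3)
    if (stats::var(c(a, b)) == 0) next
    got <- anova_pairwise(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
  }
  expect_error(anova_pairwise(c(2, 2, 2), c(2, 2)), "degenerate")
})
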