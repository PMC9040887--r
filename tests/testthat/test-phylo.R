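test_that("mean root-to-tip path length matches hand-summed caterpillar paths", {
  tree <- ape::read.tree(text = "((a:1.5,b:2.5):0.5,c:3);")
  clades <- c(a = "YQL", b = "YQL", c = "AZL")
  expect_equal(mean_root_to_tip(tree, clades, "YQL"), mean(c(2, 3)))
  expect_equal(mean_root_to_tip(tree, clades, "AZL"), 3)

  # linearity: scaling every branch scales the mean
  t2 <- tree; t2$edge.length <- t2$edge.length * 2.5
  expect_equal(mean_root_to_tip(t2, clades, "YQL"),
               2.5 * mean_root_to_tip(tree, clades, "YQL"))
  expect_error(mean_root_to_tip(tree, clades, "AZL2"), "no leaves")
})

test_that("unrooted trees are rejected with midpoint-rooting advice", {
  unr <- ape::read.tree(text = "(a:1,b:1,c:4);")
  expect_false(ape::is.rooted(unr))
  expect_error(mean_root_to_tip(unr, c(a = "X", b = "X", c = "X"), "X"),
               "midpoint")
  rooted <- midpoint_root(unr)
  expect_true(ape::is.rooted(rooted))
  expect_silent(mean_root_to_tip(rooted, c(a = "X", b = "X", c = "X"), "X"))
})

test_that("root-to-tip means agree with brute-force path enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    tree <- ape::rtree(20)
    clades <- stats::setNames(sample(c("YQL", "AZL"), 20, replace = TRUE),
                              tree$tip.label)
    root <- ape::Ntip(tree) + 1L
    brute <- vapply(seq_len(ape::Ntip(tree)), function(tip) {
      nodes <- ape::nodepath(tree, root, tip)
      sum(vapply(seq_len(length(nodes) - 1), function(i) {
        e <- which(tree$edge[, 1] == nodes[i] & tree$edge[, 2] == nodes[i + 1])
        tree$edge.length[e]
      }, numeric(1)))
    }, numeric(1))
    for (lab in unique(clades)) {
      expect_equal(mean_root_to_tip(tree, clades, lab),
                   mean(brute[match(names(clades)[clades == lab],
                                    tree$tip.label)]))
    }
  }
})

test_that("pairwise identity and similarity behave on constructed alignments", {
  aln <- c(s1 = "MKVLQIDAAR", s2 = "MKVLQIDAAR")
  r <- pairwise_similarity(aln)
  expect_equal(r$mean_identity, 100)
  expect_equal(r$mean_similarity, 100)

  # half the shared columns differ with substitution-negative residues
  aln2 <- c(s1 = "AAAAGGGG", s2 = "AAAADDDD")  # G vs D scores -1 in BLOSUM62
  r2 <- pairwise_similarity(aln2)
  expect_equal(r2$mean_identity, 50)
  expect_equal(r2$mean_similarity, 50)

  # conservative substitutions raise similarity above identity
  aln3 <- c(s1 = "LLLLLLLL", s2 = "IIIILLLL")  # L/I scores +2
  r3 <- pairwise_similarity(aln3)
  expect_equal(r3$mean_identity, 50)
  expect_equal(r3$mean_similarity, 100)

  # gapped columns drop out of the pair denominator
  aln4 <- c(s1 = "AA--CC", s2 = "AADDCC")
  r4 <- pairwise_similarity(aln4)
  expect_equal(r4$mean_identity, 100)
  expect_error(pairwise_similarity(aln4["s1"]), "at least 2")
  expect_error(pairwise_similarity(c(a = "AAA", b = "AAAA")), "equal length")
})

test_that("similarity dominates identity and both are symmetric", {
  set.seed(41)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  seqs <- vapply(1:4, function(i)
    paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("p", 1:4)
  r <- pairwise_similarity(seqs)
  expect_gte(r$mean_similarity, r$mean_identity)
  expect_equal(r$n_pairs, 6)
  rswap <- pairwise_similarity(seqs[c(4, 3, 2, 1)])
  expect_equal(rswap$mean_identity, r$mean_identity)
  expect_equal(rswap$mean_similarity, r$mean_similarity)
})
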