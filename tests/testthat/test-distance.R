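test_that("pairwise p-distance follows the comparable-site rule", {
  r <- p_distance_pair("ACGT", "ACGA")
  expect_equal(r$distance, 0.25)
  expect_equal(r$comparable_sites, 4)

  r <- p_distance_pair("AC-T", "ACGT")
  expect_equal(r$distance, 0)
  expect_equal(r$comparable_sites, 3)

  # ambiguity codes are excluded even when compatible
  r <- p_distance_pair("RCGT", "ACGT")
  expect_equal(r$comparable_sites, 3)
  expect_equal(r$distance, 0)

  expect_error(p_distance_pair("----", "ACGT"), "zero comparable")
  expect_error(p_distance_pair("ACG", "ACGT"), "unequal lengths")
})

test_that("p-distances match the brute-force oracle on random rows", {
  for (seed in 1:5) {
    aln <- random_alignment(2, 500, seed = seed, gap_frac = 0.04,
                            amb_frac = 0.03)
    fast <- p_distance_pair(aln[1, ], aln[2, ])
    slow <- p_dist_bruteforce(aln[1, ], aln[2, ])
    expect_equal(fast$distance, slow$distance)
    expect_equal(fast$comparable_sites, slow$comparable_sites)
  }
})

test_that("distance matrices match the oracle entry-wise", {
  aln <- random_alignment(20, 300, seed = 42, gap_frac = 0.03,
                          amb_frac = 0.02)
  dm <- p_distance_matrix(aln)
  expect_equal(dm$d, t(dm$d))
  expect_equal(diag(dm$d), setNames(rep(0, 20), dm$ids))
  for (i in 1:19) {
    for (j in (i + 1):20) {
      slow <- p_dist_bruteforce(aln[i, ], aln[j, ])
      expect_equal(dm$d[i, j], slow$distance, tolerance = 1e-12)
      expect_equal(unname(dm$m[i, j]), slow$comparable_sites)
    }
  }

  # consistency with the pair operation
  two <- p_distance_matrix(aln[1:2, ])
  expect_equal(two$d[1, 2], p_distance_pair(aln[1, ], aln[2, ])$distance)

  # identical sequences give an all-zero matrix
  same <- aligned_seqs(c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"))
  expect_true(all(p_distance_matrix(same)$d == 0))
})

test_that("distance matrices are label-invariant under permutation", {
  aln <- random_alignment(10, 200, seed = 7)
  dm <- p_distance_matrix(aln)
  perm <- withr::with_seed(8, sample(10))
  dm_p <- p_distance_matrix(aln[perm, ])
  expect_equal(dm_p$d[dm$ids, dm$ids], dm$d)
})

test_that("gap-free alignments have full comparable-site counts", {
  aln <- random_alignment(6, 150, seed = 3)
  dm <- p_distance_matrix(aln)
  expect_true(all(dm$m[upper.tri(dm$m)] == 150))
})

test_that("masking moves a distance by at most the removed site mass", {
  aln <- aligned_seqs(c(
    a = "ACGTACGTACGTACGTACGT",
    b = "ACGAACGTACGTTCGTACGA"
  ))
  full <- p_distance_pair(aln[1, ], aln[2, ])
  keep <- c(1:8, 13:20)  # drop 4 columns
  masked <- apply_mask(aln, keep)
  part <- p_distance_pair(masked[1, ], masked[2, ])
  removed <- full$comparable_sites - part$comparable_sites
  expect_lte(abs(part$distance - full$distance),
             removed / part$comparable_sites)
})

test_that("zero-comparable pairs in a matrix name the offending ids", {
  aln <- aligned_seqs(c(x = "AC--", y = "--GT", z = "ACGT"))
  expect_error(p_distance_matrix(aln), "'x' and 'y'")
})

test_that("group range tables summarise distances in percent", {
  # two groups of identical sequences at exact mutual distance 3%
  base <- strrep("A", 100)
  far <- paste0(strrep("C", 3), strrep("A", 97))
  aln <- aligned_seqs(c(g1a = base, g1b = base, g2a = far, g2b = far))
  dm <- p_distance_matrix(aln)
  tab <- subclade_range_table(dm, c(g1a = "G1", g1b = "G1",
                                    g2a = "G2", g2b = "G2"))
  cell <- tab[tab$group1 == "G1" & tab$group2 == "G2", ]
  expect_equal(cell$min_pct, 3)
  expect_equal(cell$max_pct, 3)
  within <- tab[tab$group1 == "G1" & tab$group2 == "G1", ]
  expect_equal(within$min_pct, 0)

  # one group over an all-zero matrix
  same <- aligned_seqs(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  tab <- subclade_range_table(p_distance_matrix(same),
                              c(a = "G", b = "G", c = "G"))
  expect_equal(tab$min_pct, 0)
  expect_equal(tab$max_pct, 0)

  # singleton group's within cell is NA, not 0
  tab <- subclade_range_table(p_distance_matrix(same),
                              c(a = "G", b = "G", c = "H"))
  solo <- tab[tab$group1 == "H" & tab$group2 == "H", ]
  expect_true(is.na(solo$min_pct))

  expect_error(subclade_range_table(p_distance_matrix(same), c(a = "G")),
               "ungrouped")
})

test_that("range tables bracket the divergences a survey was built with", {
  panel <- simulate_references(L = 1000, seed = 21)
  survey <- simulate_survey(panel, survey_design_default(), seed = 21)
  keep <- survey$truth$truth_label != "NON_TARGET"
  dm <- p_distance_matrix(survey$alignment[survey$truth$clone_id[keep], ])
  grouping <- setNames(survey$truth$truth_label[keep],
                       survey$truth$clone_id[keep])
  tab <- subclade_range_table(dm, grouping)
  realized <- panel$divergence_realized
  between <- tab[tab$group1 != tab$group2, ]
  # cross-subclade clone distances sit at the reference divergence plus the
  # two clones' error load (~2 x 0.5% expected), so the printed range must
  # enclose a narrow band around the panel divergence
  for (r in seq_len(nrow(between))) {
    target <- 100 * realized[between$group1[r], between$group2[r]]
    expect_gte(between$min_pct[r], target - 0.5)
    expect_lte(between$max_pct[r], target + 2.5)
  }
})

test_that("tidy and plot methods expose the distance matrix", {
  aln <- random_alignment(5, 100, seed = 2)
  dm <- p_distance_matrix(aln)
  td <- tidy(dm)
  expect_equal(nrow(td), choose(5, 2))
  expect_s3_class(autoplot(dm), "ggplot")
})
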