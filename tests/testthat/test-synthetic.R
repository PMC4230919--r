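test_that("reference panels hit their requested divergences", {
  panel <- simulate_references(L = 1000, seed = 1)
  expect_equal(panel$labels, c("I", "II", "III", "IV"))
  req <- panel$divergence_requested
  real <- panel$divergence_realized
  pos <- req > 0 & upper.tri(req)
  expect_true(all(abs(real[pos] - req[pos]) / req[pos] <= 0.20))

  # brute-force recomputation of realized divergences from the sequences
  for (pair in list(c("I", "II"), c("I", "III"), c("III", "IV"))) {
    bf <- p_dist_bruteforce(panel$references[pair[1], ],
                            panel$references[pair[2], ])
    expect_equal(real[pair[1], pair[2]], bf$distance)
  }
})

test_that("an all-zero divergence matrix gives identical references", {
  zero <- matrix(0, 4, 4, dimnames = list(c("I", "II", "III", "IV"),
                                          c("I", "II", "III", "IV")))
  panel <- simulate_references(L = 500, divergence_matrix = zero, seed = 2)
  expect_true(all(panel$references[1, ] == panel$references[2, ]))
  expect_true(all(panel$references[1, ] == panel$references[4, ]))
})

test_that("panels are byte-identical under the same seed", {
  a <- simulate_references(L = 400, seed = 7)
  b <- simulate_references(L = 400, seed = 7)
  expect_identical(a, b)
  c <- simulate_references(L = 400, seed = 8)
  expect_false(identical(a$references, c$references))
})

test_that("infeasible divergence requests fail constructively", {
  # triangle violation: A and C are near-identical yet both far from B
  bad <- matrix(c(0, 0.5, 0.01,
                  0.5, 0, 0.01,
                  0.01, 0.01, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(simulate_references(L = 1000, divergence_matrix = bad,
                                   seed = 1),
               "attainable")
  # divergences whose substitution budget exceeds the sequence length
  big <- matrix(0.7, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                           c("A", "B", "C", "D")))
  diag(big) <- 0
  expect_error(simulate_references(L = 100, divergence_matrix = big,
                                   seed = 1),
               "increase L")
  expect_error(simulate_references(L = 50, seed = 1), "at least 100")
})

test_that("capsule libraries respect the incidence parameter exactly at its bounds", {
  panel <- simulate_references(L = 300, seed = 1)
  for (s in 1:5) {
    lib <- simulate_capsule_library(panel, "A. maculatum", 30, q = 0, seed = s)
    expect_equal(sum(lib$truth$truth_label == "NON_TARGET"), 0)
  }
  lib <- simulate_capsule_library(panel, "A. maculatum", 50, q = 1, seed = 3)
  expect_equal(sum(lib$truth$truth_label == "NON_TARGET"), 50)
  expect_error(simulate_capsule_library(panel, "h", 0, q = 0.5), "n_clones")
  expect_error(
    simulate_capsule_library(panel, "h", 5, q = 0.5,
                             subclade_mixture = c(I = 0.7, II = 0.7)),
    "mixture"
  )
})

test_that("detection frequency across libraries matches the closed form", {
  panel <- simulate_references(L = 120, seed = 9)
  q <- 0.036
  n <- 126
  reps <- 1500
  hits <- vapply(seq_len(reps), function(s) {
    lib <- simulate_capsule_library(panel, "h", n, q = q, seed = s,
                                    capsule_id = paste0("r", s))
    any(lib$truth$truth_label == "NON_TARGET")
  }, logical(1))
  closed <- detection_probability(q, n)
  se <- sqrt(closed * (1 - closed) / reps)
  expect_lt(abs(mean(hits) - closed), 3 * se)
})

test_that("non-target clones stay at least 10% from every reference", {
  panel <- simulate_references(L = 400, seed = 4)
  lib <- simulate_capsule_library(panel, "h", 25, q = 1, seed = 5,
                                  error_rate = 0.05)
  for (id in lib$truth$clone_id) {
    for (g in panel$labels) {
      d <- p_distance_pair(lib$clones[id, ], panel$references[g, ])$distance
      expect_gte(d, 0.10)
    }
  }
})

test_that("within-subclade clone divergence tracks the error rate", {
  panel <- simulate_references(L = 1000, seed = 6)
  err <- 0.005
  lib <- simulate_capsule_library(panel, "h", 100, q = 0,
                                  subclade_mixture = c(I = 1),
                                  error_rate = err, seed = 11)
  d <- vapply(lib$truth$clone_id, function(id) {
    mean(lib$clones[id, ] != panel$references["I", ])
  }, double(1))
  # every substitution changes the base, so clone-to-reference distance is
  # binomial(L, error_rate)/L; check the pooled mean at 3 SE
  se <- sqrt(err * (1 - err) / (100 * 1000))
  expect_lt(abs(mean(d) - err), 3 * se)
})

test_that("pooled incidence estimates recover the true q", {
  panel <- simulate_references(L = 150, seed = 2)
  q <- 0.1
  reps <- 100
  cover <- vapply(seq_len(reps), function(s) {
    lib <- simulate_capsule_library(panel, "h", 126, q = q, seed = 1000 + s,
                                    capsule_id = paste0("r", s))
    k <- sum(lib$truth$truth_label == "NON_TARGET")
    ci <- stats::binom.test(k, 126)$conf.int
    ci[1] <= q && q <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("surveys pool capsules with a faithful truth table and manifest", {
  panel <- simulate_references(L = 300, seed = 1)

  tiny <- tibble::tibble(host = "A. maculatum", site_code = "S1",
                         n_capsules = 1L, clones_per_capsule = 4L, q = 0)
  sv <- simulate_survey(panel, tiny, seed = 1)
  expect_equal(nrow(sv$truth), 4)
  expect_equal(nrow(sv$alignment), 4)

  sv <- simulate_survey(panel, survey_design_default(), seed = 3)
  # every clone in the alignment appears exactly once in the truth table
  expect_setequal(rownames(sv$alignment), sv$truth$clone_id)
  expect_equal(anyDuplicated(sv$truth$clone_id), 0)
  # per-host totals on the generated manifest match the design
  expect_equal(count_accessions(sv$manifest, host == "A. maculatum"), 85)
  expect_equal(count_accessions(sv$manifest, host == "A. gracile"), 27)
  expect_equal(count_accessions(sv$manifest, host == "L. sylvatica"), 9)
  expect_equal(count_accessions(sv$manifest, host == "L. aurora"), 5)
  # per-host clone totals equal sums over that host's capsules
  per_capsule <- vapply(sv$capsules, function(cp) nrow(cp$truth), integer(1))
  host_of <- vapply(sv$capsules, function(cp) cp$host, character(1))
  expect_equal(sum(per_capsule[host_of == "A. maculatum"]), 85)

  expect_error(
    simulate_survey(panel, dplyr::bind_rows(tiny, tiny), seed = 1),
    "duplicate site_code"
  )
})

test_that("surveys are deterministic given the seed, including on disk", {
  panel <- simulate_references(L = 200, seed = 5)
  design <- survey_design_default()
  a <- simulate_survey(panel, design, seed = 9)
  b <- simulate_survey(panel, design, seed = 9)
  expect_identical(a$alignment, b$alignment)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_survey(a, d1)
  write_survey(b, d2)
  f1 <- file.path(d1, "survey.fasta")
  f2 <- file.path(d2, "survey.fasta")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("survey summaries expose clone accounting", {
  panel <- simulate_references(L = 200, seed = 5)
  sv <- simulate_survey(panel, survey_design_default(q = 0.05), seed = 2)
  g <- glance(sv)
  expect_equal(g$n_clones, 126L)
  expect_equal(g$n_capsules, 22L)
  expect_equal(g$n_non_target, sum(tidy(sv)$truth_label == "NON_TARGET"))
})
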