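test_that("the score is the length-normalized log-product of frequencies", {
  # all frequencies equal: score = log f regardless of string length
  for (n in c(1, 4, 9)) expect_equal(novelty_score(rep(0.2, n)), log(0.2))
  # hand-computed: (ln 0.5 + ln 0.25)/2
  expect_equal(novelty_score(c(0.5, 0.25)), (log(0.5) + log(0.25)) / 2)
  expect_equal(novelty_score(c(0.5, 0.25)), -1.0397, tolerance = 1e-4)
  expect_error(novelty_score(numeric(0)), "empty")
})

test_that("unseen bins contribute the floor and strictly lower the score", {
  lib <- make_library(c("HH.0.0.0.0" = 0.8, "EE.1.1.1.1" = 0.2))
  s_seen <- novelty_score(c("HH.0.0.0.0", "EE.1.1.1.1"), lib)
  s_with_unseen <- novelty_score(c("HH.0.0.0.0", "EE.1.1.1.1", "EH.2.2.2.2"), lib)
  expect_lt(s_with_unseen, s_seen)
  # the default floor is half the smallest nonzero frequency
  expect_equal(novelty_score("EH.2.2.2.2", lib), log(0.1))
  # monotone non-decreasing in every frequency
  expect_gte(novelty_score(c(0.3, 0.2)), novelty_score(c(0.2, 0.2)))
})

test_that("Z-scores standardize with the population sd and are shift-invariant", {
  z <- novelty_zscores(c(a = -1, b = 0, c = 1))
  expect_equal(z$z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z$z^2)), 1, tolerance = 1e-9)
  z2 <- novelty_zscores(c(a = -1, b = 0, c = 1) + 5)
  expect_equal(z2$z, z$z, tolerance = 1e-12)
  expect_error(novelty_zscores(c(a = 2, b = 2)), "degenerate population")
  expect_error(novelty_zscores(c(a = 2)), "at least 2")
})

test_that("geometry matching tests bin occupancy and guards the scheme", {
  lib <- make_library(c("HH.0.0.0.0" = 0.7, "EE.1.1.1.1" = 0.3))
  expect_true(match_geometry("HH.0.0.0.0", lib))
  expect_false(match_geometry("HH.5.1.1.1", lib))
  # a structure classified in the reference always matches itself
  tg <- sample_targets(3, seed = 15)
  sm <- classify_smotifs(smotif_string(build_synthetic_chain(tg)))
  self_lib <- build_library(sm, c(synthetic = "f1"), n_rounds = 1, seed = 1)
  expect_true(all(match_geometry(sm, self_lib)))
  # mismatched schemes are refused
  sm45 <- classify_smotifs(sm, parse_scheme("2_45_45_45"))
  expect_error(match_geometry(sm45, self_lib), "scheme mismatch")
})

test_that("strict flanking-element matching applies per-kind tolerances", {
  q_bb <- list(class = "EE", ss1_len = 10, ss2_len = 11)
  cand <- data.frame(class = "EE", ss1_len = 10, ss2_len = 11)
  expect_true(match_strict_fss(q_bb, cand))
  # strands differing by 3 (> 2) never match
  short <- data.frame(class = "EE", ss1_len = c(5, 6, 7), ss2_len = 11)
  expect_false(match_strict_fss(q_bb, short))
  # helices tolerate up to 4 residues, boundary inclusive
  q_aa <- list(class = "HH", ss1_len = 10, ss2_len = 10)
  expect_true(match_strict_fss(q_aa, data.frame(ss1_len = 14, ss2_len = 10)))
  expect_false(match_strict_fss(q_aa, data.frame(ss1_len = 15, ss2_len = 10)))
  # mixed class: strand side uses 2, helix side uses 4
  q_eh <- list(class = "EH", ss1_len = 5, ss2_len = 10)
  expect_true(match_strict_fss(q_eh, data.frame(ss1_len = 7, ss2_len = 14)))
  expect_false(match_strict_fss(q_eh, data.frame(ss1_len = 8, ss2_len = 10)))
  expect_false(match_strict_fss(q_eh, data.frame(ss1_len = 5, ss2_len = 15)))
  expect_false(match_strict_fss(q_eh, cand[0, ]))
})

test_that("reference comparison counts planted novelties exactly", {
  tg <- sample_targets(4, seed = 23)
  ref <- classify_smotifs(smotif_string(build_synthetic_chain(tg, structure_id = "ref")))
  ref_lib <- build_library(ref, c(ref = "f1"), n_rounds = 1, seed = 1)

  # query identical to the reference: nothing is new
  rep0 <- compare_to_reference(ref, ref_lib, ref)
  expect_equal(rep0$n_new_geometry, 0)
  expect_equal(rep0$n_unique_fss, 0)

  # plant one unseen bin and one same-bin length outlier
  q <- ref
  q$bin_id[1] <- "EE.9.2.2.5"            # geometry never seen
  q$ss1_len[2] <- q$ss1_len[2] + 20      # same bin, incomparable length
  rep1 <- compare_to_reference(q, ref_lib, ref)
  expect_equal(rep1$n_new_geometry, 1)
  expect_equal(rep1$n_unique_fss, 2)
  expect_lte(rep1$n_new_geometry, rep1$n_unique_fss)
  expect_false(rep1$records$geometry_known[1])
  expect_false(rep1$records$fss_known[2])
})

test_that("shared-Smotif counting is a greedy one-to-one bin matching", {
  expect_equal(shared_smotifs(c("A.1.1.1.1", "B.1.1.1.1"),
                              c("C.1.1.1.1", "D.1.1.1.1"))$n_shared, 0)
  k <- c("HH.1.1.1.1", "HE.2.2.2.2", "EE.3.3.3.3")
  expect_equal(shared_smotifs(k, k)$n_shared, 3)
  # multiset semantics: duplicates pair off one-to-one
  a <- c("X.1.1.1.1", "X.1.1.1.1", "X.1.1.1.1", "Y.1.1.1.1")
  b <- c("X.1.1.1.1", "X.1.1.1.1", "Z.1.1.1.1")
  expect_equal(shared_smotifs(a, b)$n_shared, 2)
})

test_that("planted rare-bin enrichment drives the novel mean z below the known", {
  for (seed in c(101, 202, 303)) {
    pop <- simulate_population(n_bins = 300, zipf_s = 1.5, n_known = 150,
                               n_novel = 150, lambda = 0.8, seed = seed)
    folds <- stats::setNames(names(pop$known), names(pop$known))
    lib <- build_library(pop$known, folds, scheme = NULL, n_rounds = 1, seed = 1)
    sc <- novelty_zscores(rbind(score_structures(pop$known, lib),
                                score_structures(pop$novel, lib)))
    is_novel <- grepl("^novel", sc$structure_id)
    expect_lt(mean(sc$z[is_novel]), mean(sc$z[!is_novel]))
  }
})
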