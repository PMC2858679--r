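test_that("ideal elements have the canonical construction geometry", {
  hel <- build_ideal_element("H", 10)
  ang <- acos(abs(sum(principal_axis(hel) * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  str5 <- build_ideal_element("E", 5)
  ee <- sqrt(sum((str5$ca[5, ] - str5$ca[1, ])^2))
  expect_equal(ee, 4 * 3.3, tolerance = 0.2)
  # consecutive CA spacing is physical (~3.8 A) for both kinds
  for (el in list(hel, str5)) {
    gaps <- sqrt(rowSums(diff(el$ca)^2))
    expect_true(all(gaps > 3.5 & gaps < 4.1))
  }
  expect_identical(build_ideal_element("H", 7), build_ideal_element("H", 7))
  expect_error(build_ideal_element("E", 2), "at least 3")
})

test_that("placement realizes targets and rejects infeasible ones", {
  ss1 <- build_ideal_element("H", 9)
  pl <- place_at_geometry(ss1, 12, 45, 60, 90, ss2_kind = "E", ss2_len = 6,
                          loop_len = 3)
  g <- pl$geometry
  expect_lt(abs(g$D - 12), 0.5)
  expect_lt(abs(g$delta - 45), 3)
  expect_lt(abs(g$theta - 60), 3)
  expect_lt(min(abs(g$rho - 90), 360 - abs(g$rho - 90)), 5)

  # degenerate hoist with unconstrained meridian succeeds, forward delta ~ 0
  pl0 <- place_at_geometry(ss1, 8, 0, 90, NA, ss2_kind = "H", ss2_len = 8,
                           loop_len = 2)
  expect_lt(pl0$geometry$delta, 1)
  # ... but pinning rho there is refused
  expect_error(place_at_geometry(ss1, 8, 0, 90, 120, loop_len = 2),
               "delta is degenerate")
  expect_error(place_at_geometry(ss1, 8, 45, 0, 120, loop_len = 2),
               "theta is degenerate")
  expect_error(place_at_geometry(ss1, 20, 45, 90, 120, loop_len = 1),
               "chain break")
})

test_that("loop paths keep CA spacing below the chain-break threshold", {
  ss1 <- build_ideal_element("H", 8)
  pl <- place_at_geometry(ss1, 16, 80, 70, 200, ss2_kind = "H", ss2_len = 8,
                          loop_len = 4)
  path <- rbind(pl$ss1$ca[nrow(pl$ss1$ca), ], pl$loop_ca, pl$ss2$ca[1, ])
  gaps <- sqrt(rowSums(diff(path)^2))
  expect_true(all(gaps <= 4.5))
})

test_that("a random-target sweep round-trips at the module tolerance", {
  tg <- sample_targets(100, seed = 1234)
  ok <- 0
  for (i in seq_len(100)) {
    ss1 <- build_ideal_element("H", 8)
    hit <- tryCatch({
      pl <- place_at_geometry(ss1, tg$D[i], tg$delta[i], tg$theta[i], tg$rho[i],
                              ss2_kind = tg$ss2_kind[i], ss2_len = tg$ss2_len[i],
                              loop_len = tg$loop_len[i])
      g <- pl$geometry
      abs(g$D - tg$D[i]) <= 0.5 && abs(g$delta - tg$delta[i]) <= 3 &&
        abs(g$theta - tg$theta[i]) <= 3 &&
        min(abs(g$rho - tg$rho[i]), 360 - abs(g$rho - tg$rho[i])) <= 5
    }, error = function(e) FALSE)
    ok <- ok + hit
  }
  expect_gte(ok, 95)
})

test_that("synthetic chains decompose back to their construction targets", {
  tg <- sample_targets(2, seed = 55)
  cm <- build_synthetic_chain(tg)
  expect_equal(nrow(extract_ss_elements(cm)), 3)
  sm <- smotif_string(cm)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$D, tg$D, tolerance = 0.5)
  expect_equal(sm$delta, tg$delta, tolerance = 3)
  expect_equal(sm$theta, tg$theta, tolerance = 3)
  for (i in 1:2) {
    d <- abs(sm$rho[i] - tg$rho[i]) %% 360
    expect_lt(min(d, 360 - d), 5)
  }
  expect_equal(sm$loop_len, tg$loop_len)
  # empty target list: a single element, no Smotifs
  empty <- build_synthetic_chain(data.frame())
  expect_equal(nrow(smotif_string(empty)), 0)
  expect_equal(nrow(extract_ss_elements(empty)), 1)
})

test_that("synthetic chains survive a PDB + annotation round trip", {
  tg <- sample_targets(3, seed = 66)
  cm <- build_synthetic_chain(tg)
  pdb <- tempfile(fileext = ".pdb"); ssf <- tempfile(fileext = ".ss")
  on.exit(unlink(c(pdb, ssf)))
  write_chain_pdb(cm, pdb)
  write_ss_annotation(cm, ssf)
  back <- annotate_ss(read_pdb(pdb, chain = "A"), read_ss_annotation(ssf))
  expect_equal(back$residues$ss3, cm$residues$ss3)
  sm0 <- smotif_string(cm); sm1 <- smotif_string(back)
  expect_equal(sm1$D, sm0$D, tolerance = 1e-3)     # PDB prints 3 decimals
  expect_equal(sm1$rho, sm0$rho, tolerance = 0.1)
})

test_that("population simulation is seeded, conservative and null at lambda 0", {
  pop <- simulate_population(n_bins = 100, n_known = 50, n_novel = 50,
                             string_len = c(3, 9), lambda = 0.5, seed = 8)
  expect_equal(sum(pop$base_freqs), 1, tolerance = 1e-12)
  expect_length(pop$rare_bins, 25)
  lens <- lengths(c(pop$known, pop$novel))
  expect_true(all(lens >= 3 & lens <= 9))
  pop2 <- simulate_population(n_bins = 100, n_known = 50, n_novel = 50,
                              string_len = c(3, 9), lambda = 0.5, seed = 8)
  expect_identical(pop, pop2)

  # lambda = 0: known and novel come from the same distribution
  null <- simulate_population(n_bins = 200, n_known = 200, n_novel = 200,
                              lambda = 0, seed = 99)
  folds <- stats::setNames(names(null$known), names(null$known))
  lib <- build_library(null$known, folds, scheme = NULL, n_rounds = 1, seed = 1)
  sc <- novelty_zscores(rbind(score_structures(null$known, lib),
                              score_structures(null$novel, lib)))
  is_novel <- grepl("^novel", sc$structure_id)
  dz <- mean(sc$z[is_novel]) - mean(sc$z[!is_novel])
  se <- sqrt(stats::var(sc$z[is_novel]) / sum(is_novel) +
               stats::var(sc$z[!is_novel]) / sum(!is_novel))
  expect_lt(abs(dz), 3 * se)
})

test_that("known-fold bin usage converges to the Zipf base frequencies", {
  pop <- simulate_population(n_bins = 50, zipf_s = 1.2, n_known = 1500,
                             n_novel = 0, string_len = c(5, 10), seed = 4)
  emp <- table(factor(unlist(pop$known), levels = names(pop$base_freqs)))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(max(abs(emp - pop$base_freqs)), 0.01)
  expect_gt(stats::cor(emp, pop$base_freqs), 0.999)
})
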