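test_that("a single-structure fold gives exact frequencies for any round count", {
  bins <- list(s1 = c("HH.0.0.0.0", "HH.0.0.0.0", "EE.1.1.1.1"))
  folds <- c(s1 = "f1")
  for (nr in c(1, 7, 50)) {
    lib <- build_library(bins, folds, scheme = default_scheme(), n_rounds = nr,
                         seed = 3)
    expect_equal(lib_freq(lib, "HH.0.0.0.0"), 2 / 3)
    expect_equal(lib_freq(lib, "EE.1.1.1.1"), 1 / 3)
    expect_equal(sum(lib$entries$freq), 1, tolerance = 1e-9)
  }
})

test_that("two equiprobable representatives average to the enumerated expectation", {
  # oracle: each round picks s1 or s2 with probability 1/2, so
  # E[count(A)] = E[count(B)] = 1/2 exactly
  bins <- list(s1 = "HH.0.0.0.0", s2 = "EE.1.1.1.1")
  folds <- c(s1 = "f1", s2 = "f1")
  lib <- build_library(bins, folds, scheme = default_scheme(),
                       n_rounds = 4000, seed = 21)
  cA <- lib$entries$count[lib$entries$bin == "HH.0.0.0.0"]
  cB <- lib$entries$count[lib$entries$bin == "EE.1.1.1.1"]
  expect_equal(cA + cB, 1, tolerance = 1e-9)   # one structure picked per round
  expect_lt(abs(cA - 0.5), 0.03)               # ~4 sigma at 4000 rounds
})

test_that("library builds are seed-deterministic and validate their inputs", {
  set.seed(99)
  pop <- simulate_population(n_bins = 40, n_known = 20, n_novel = 0, seed = 5)
  bins <- pop$known
  folds <- stats::setNames(rep(c("fa", "fb"), length.out = 20), names(bins))
  a <- build_library(bins, folds, scheme = NULL, n_rounds = 10, seed = 17)
  b <- build_library(bins, folds, scheme = NULL, n_rounds = 10, seed = 17)
  expect_identical(a$entries, b$entries)
  expect_equal(sum(a$entries$freq), 1, tolerance = 1e-9)
  expect_error(build_library(list(), c(a = "f")), "empty")
  expect_error(build_library(bins, folds[-1]), "no fold assignment.*known0001")
})

test_that("per-class normalization yields one simplex per class", {
  bins <- list(s1 = c("HH.0.0.0.0", "HH.1.1.1.1", "EE.1.1.1.1"))
  lib <- build_library(bins, c(s1 = "f1"), scheme = default_scheme(),
                       normalization = "per_class")
  sums <- tapply(lib$entries$freq, lib$entries$cls, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("libraries round-trip through JSON", {
  bins <- list(s1 = c("HH.0.0.0.0", "EE.1.1.1.1"), s2 = "HH.0.0.0.0")
  lib <- build_library(bins, c(s1 = "f1", s2 = "f2"), scheme = default_scheme(),
                       n_rounds = 5, seed = 2,
                       dates = c(s1 = as.Date("2001-05-01"), s2 = as.Date("1999-01-01")))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_library(lib, f)
  back <- read_library(f)
  expect_equal(back$entries$bin, lib$entries$bin)
  expect_equal(back$entries$freq, lib$entries$freq, tolerance = 1e-12)
  expect_equal(back$entries$first_seen, lib$entries$first_seen)
  expect_equal(unclass(back$scheme), unclass(lib$scheme))
  # first-seen dates come from all structures, not the sampled representatives
  expect_equal(back$entries$first_seen[back$entries$bin == "HH.0.0.0.0"],
               as.Date("1999-01-01"))
})

test_that("saturation curves equal a brute-force running-set scan", {
  set.seed(31)
  n <- 120
  d <- data.frame(
    bin_id = sample(sprintf("HH.%d.0.0.0", 0:9), n, replace = TRUE),
    class = "HH",
    date = as.Date("2000-01-01") + sample(0:3000, n, replace = TRUE))
  cv <- saturation_curve(d)
  # oracle: walk dates in order, count the growing set of seen bins
  oracle <- function(d) {
    o <- d[order(d$date), ]
    seen <- character(0); out <- integer(0)
    for (i in seq_len(nrow(o))) {
      seen <- union(seen, o$bin_id[i])
      out[i] <- length(seen)
    }
    tapply(out, o$date, max)
  }
  oc <- oracle(d)
  expect_equal(cv$n_bins, as.integer(oc[format(cv$date)]))
  expect_true(all(diff(cv$n_bins) >= 0))
  expect_equal(cv$n_bins[nrow(cv)], length(unique(d$bin_id)))
  # input order never changes the curve
  cv2 <- saturation_curve(d[sample(n), ])
  expect_equal(cv2, cv)
  # single shared date: one step to the distinct-bin count
  one <- d; one$date <- as.Date("2010-06-01")
  cv3 <- saturation_curve(one)
  expect_equal(nrow(cv3), 1)
  expect_equal(cv3$n_bins, length(unique(d$bin_id)))
})

test_that("fold-population categories partition with half-open boundaries", {
  sizes <- stats::setNames(c(1L, 2L, 9L, 10L, 50L, 99L, 100L, 400L),
                           paste0("f", 1:8))
  cats <- smotifr:::.fold_category(names(sizes), sizes, new_folds = "f8")
  expect_equal(cats, c("1", "2-10", "2-10", "10-50", "50-100", "50-100",
                       ">100", "new"))
})

test_that("novel categories built from rare bins sit left of populated folds", {
  pop <- simulate_population(n_bins = 200, zipf_s = 1.5, n_known = 150,
                             n_novel = 60, lambda = 0.9, seed = 77)
  bins <- c(pop$known, pop$novel)
  folds <- stats::setNames(names(bins), names(bins))   # one structure per fold
  lib <- build_library(pop$known, stats::setNames(names(pop$known), names(pop$known)),
                       scheme = NULL, n_rounds = 1, seed = 1)
  prof <- frequency_profile_by_category(bins, folds, lib,
                                        new_folds = names(pop$novel))
  expect_true(all(c("new", "1") %in% prof$profile$category))
  mass <- tapply(prof$profile$prop, prof$profile$category, sum)
  expect_equal(as.numeric(mass), rep(1, length(mass)), tolerance = 1e-9)
  # novel folds are enriched in low-frequency Smotifs (one-sided rank test)
  wt <- stats::wilcox.test(prof$freqs$new, prof$freqs[["1"]],
                           alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
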