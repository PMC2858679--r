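## Novelty scoring of Smotif strings and comparison against reference sets.
##
## The score of a structure is the length-normalized log of the product of
## its Smotif frequencies, S = (1/N) sum_i ln fr_i: lower S means the
## structure is built from rarer Smotifs. Scores are standardized into
## Z-scores over the scored population. The reference comparison mirrors the
## two-level question asked of a putative new fold: does any known Smotif
## share its geometry bin (geometry match), and among those, does any have
## bracing elements of comparable length (strict flanking-secondary-structure
## match, tolerance 2 residues for strands and 4 for helices)?

.auto_floor <- function(library) {
  nz <- library$entries$freq[library$entries$freq > 0]
  if (!length(nz)) stop("library has no nonzero frequencies")
  min(nz) / 2
}

#' Length-normalized log-probability score of a Smotif string
#'
#' `S = (1/N) * sum(log(max(fr_i, floor)))`. The floor keeps the score
#' finite for Smotifs in bins the library has never seen while ranking them
#' below every seen bin. With all frequencies equal to `f` the score is
#' `log(f)` regardless of string length.
#'
#' @param x either a numeric vector of frequencies, or a character vector of
#'   bin labels (then `library` must be given).
#' @param library a `smotif_library` used to look up frequencies.
#' @param floor zero-frequency floor; `NULL` uses half the smallest nonzero
#'   library frequency (requires `library`).
#' @return the score S (natural log scale).
#' @export
novelty_score <- function(x, library = NULL, floor = NULL) {
  fr <- if (is.character(x)) {
    if (is.null(library)) stop("bin labels given but no library to look them up in")
    lib_freq(library, x)
  } else as.numeric(x)
  if (length(fr) == 0) stop("cannot score an empty Smotif string")
  if (is.null(floor)) {
    if (!is.null(library)) floor <- .auto_floor(library)
    else {
      nz <- fr[fr > 0]
      if (!length(nz)) stop("all frequencies zero and no floor given")
      floor <- min(nz) / 2
    }
  }
  mean(log(pmax(fr, floor)))
}

#' Score a collection of structures against a library
#'
#' @param bins named list, structure id -> bin labels, or a classified
#'   `smotif_set` (must share the library's scheme).
#' @inheritParams novelty_score
#' @return data frame with columns `structure_id`, `N`, `score`.
#' @export
score_structures <- function(bins, library, floor = NULL) {
  if (inherits(bins, "smotif_set")) {
    .check_scheme(bins, library)
    bins <- bins_by_structure(bins)
  }
  if (is.null(floor)) floor <- .auto_floor(library)
  data.frame(structure_id = names(bins),
             N = lengths(bins),
             score = vapply(bins, novelty_score, 0, library = library, floor = floor),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert structure scores to population Z-scores
#'
#' `z_i = (S_i - mu) / sigma` with the population (not sample) standard
#' deviation of the supplied scores, so mean(z) = 0 and sd(z) = 1 by
#' construction.
#'
#' @param scores data frame from [score_structures()] (columns
#'   `structure_id`, `score`), or a named numeric vector of scores.
#' @return the data frame with a `z` column appended.
#' @export
novelty_zscores <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(structure_id = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
  if (nrow(scores) < 2) stop("need at least 2 scored structures")
  s <- scores$score
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  if (sigma < 1e-12) stop("degenerate population: all scores identical")
  scores$z <- (s - mu) / sigma
  scores
}

.check_scheme <- function(smotifs, library) {
  qs <- attr(smotifs, "scheme")
  if (!is.null(qs) && !is.null(library$scheme) && !.same_scheme(qs, library$scheme))
    stop("scheme mismatch: query classified under ", format_scheme(qs),
         " (rho_offset ", qs$rho_offset, "), library uses ",
         format_scheme(library$scheme), " (rho_offset ",
         library$scheme$rho_offset, ")")
  invisible(TRUE)
}

#' Does a Smotif's geometry bin occur in a reference library?
#'
#' @param x character vector of bin labels, or a classified `smotif_set`
#'   (scheme checked against the library).
#' @param library a `smotif_library`.
#' @return logical vector: `TRUE` where the bin has nonzero count.
#' @export
match_geometry <- function(x, library) {
  if (inherits(x, "smotif_set")) {
    .check_scheme(x, library)
    x <- x$bin_id
  }
  x %in% library$entries$bin[library$entries$count > 0]
}

.fss_tol <- function(kind) ifelse(kind == "H", 4, 2)

#' Strict flanking-secondary-structure match
#'
#' Given a query Smotif and candidate Smotifs from the same geometry bin,
#' tests whether any candidate has both bracing elements of comparable
#' length: the SS1 lengths may differ by at most 2 residues for strands and
#' 4 for helices (by the element's own kind), and likewise for SS2. The
#' boundary is inclusive.
#'
#' @param q one-row `smotif_set` slice or list with `class`, `ss1_len`,
#'   `ss2_len`.
#' @param candidates data frame of candidate Smotifs with the same columns.
#' @return `TRUE` if some candidate matches.
#' @export
match_strict_fss <- function(q, candidates) {
  if (is.null(nrow(candidates)) || nrow(candidates) == 0) return(FALSE)
  t1 <- .fss_tol(substr(q$class, 1, 1))
  t2 <- .fss_tol(substr(q$class, 2, 2))
  any(abs(candidates$ss1_len - q$ss1_len) <= t1 &
        abs(candidates$ss2_len - q$ss2_len) <= t2)
}

#' Compare a query Smotif set to a reference
#'
#' Counts the query Smotifs whose geometry bin is absent from the reference
#' library (`new geometry`) and those that additionally have no same-bin
#' reference Smotif with comparable element lengths (`unique FSS`). A new
#' geometry implies unique FSS, so `n_new_geometry <= n_unique_fss` always.
#'
#' @param query classified `smotif_set` to assess.
#' @param ref_library `smotif_library` for the geometry-level test.
#' @param ref_smotifs classified `smotif_set` (or data frame with `bin_id`,
#'   `class`, `ss1_len`, `ss2_len`) for the length-level test.
#' @return an object of class `comparison_report`: list with `n_smotifs`,
#'   `n_new_geometry`, `n_unique_fss` and the per-Smotif `records` data
#'   frame (`structure_id`, `bin_id`, `geometry_known`, `fss_known`).
#' @export
compare_to_reference <- function(query, ref_library, ref_smotifs) {
  .check_scheme(query, ref_library)
  if (inherits(ref_smotifs, "smotif_set")) .check_scheme(ref_smotifs, ref_library)
  geo <- match_geometry(query$bin_id, ref_library)
  fss <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    if (!geo[i]) { fss[i] <- FALSE; next }
    cand <- ref_smotifs[ref_smotifs$bin_id == query$bin_id[i], , drop = FALSE]
    fss[i] <- match_strict_fss(query[i, ], cand)
  }
  records <- data.frame(structure_id = query$structure_id,
                        bin_id = query$bin_id,
                        geometry_known = geo, fss_known = fss,
                        stringsAsFactors = FALSE)
  structure(list(n_smotifs = nrow(query),
                 n_new_geometry = sum(!geo),
                 n_unique_fss = sum(!fss),
                 records = records),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report:", x$n_smotifs, "Smotifs;",
      x$n_new_geometry, "with new geometry;",
      x$n_unique_fss, "with unique flanking-element lengths\n")
  invisible(x)
}

#' Count geometry-bin-equivalent Smotifs shared by two structures
#'
#' Greedy one-to-one matching on bin-label equality, i.e. the multiset
#' intersection of the two bin-label collections.
#'
#' @param a,b classified `smotif_set`s or character vectors of bin labels.
#' @return list with `n_shared` and `pairs` (data frame `bin_id`, `n`).
#' @export
shared_smotifs <- function(a, b) {
  if (inherits(a, "smotif_set")) a <- a$bin_id
  if (inherits(b, "smotif_set")) b <- b$bin_id
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  n <- if (length(common)) pmin(as.integer(ta[common]), as.integer(tb[common])) else integer(0)
  list(n_shared = sum(n),
       pairs = data.frame(bin_id = common, n = n, stringsAsFactors = FALSE,
                          row.names = NULL))
}
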