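## Smotif frequency library with fold-level redundancy removal.
##
## Fold classifications group many structures under one fold; counting every
## structure would weight popular folds by their sequence redundancy. The
## library therefore draws one representative structure per fold, repeats the
## draw over many rounds, and averages the per-bin counts across rounds.

#' Split classified Smotif bins by structure
#'
#' @param smotifs a classified `smotif_set` (see [classify_smotifs()]).
#' @return named list: per structure, the character vector of bin labels.
#' @export
bins_by_structure <- function(smotifs) {
  if (!"bin_id" %in% names(smotifs))
    stop("Smotif set is not classified; run classify_smotifs() first")
  split(smotifs$bin_id, smotifs$structure_id)
}

#' Build a Smotif frequency library
#'
#' Per round, one structure is drawn uniformly at random from each fold; the
#' bin labels of the selected structures are tallied. Counts are averaged
#' over rounds and normalized into relative frequencies. When every fold has
#' a single structure the result is exact and independent of `n_rounds`.
#'
#' @param bins named list mapping structure id to its vector of bin labels
#'   (see [bins_by_structure()]), or a classified `smotif_set`.
#' @param folds named character vector mapping structure id to fold id. Every
#'   structure in `bins` must be assigned.
#' @param scheme the `binning_scheme` the labels were produced under (taken
#'   from the set when `bins` is a `smotif_set`).
#' @param n_rounds number of random representative-selection rounds.
#' @param seed RNG seed; the build is fully reproducible given a seed.
#' @param dates optional named `Date` vector (structure id -> deposition
#'   date) used to record the earliest date each bin was seen, over all
#'   structures.
#' @param normalization `"global"` normalizes frequencies over the bins of
#'   all four classes jointly (one simplex, so frequencies of mixed-class
#'   strings can be multiplied); `"per_class"` normalizes within each class.
#' @return an object of class `smotif_library`: list with `scheme`,
#'   `normalization`, `n_rounds`, `seed` and `entries` (data frame: `bin`,
#'   `cls`, `iD`, `i_delta`, `i_theta`, `i_rho`, `count`, `freq`,
#'   `first_seen`).
#' @export
build_library <- function(bins, folds, scheme = NULL, n_rounds = 100,
                          seed = NULL, dates = NULL,
                          normalization = c("global", "per_class")) {
  normalization <- match.arg(normalization)
  if (inherits(bins, "smotif_set")) {
    if (is.null(scheme)) scheme <- attr(bins, "scheme")
    bins <- bins_by_structure(bins)
  }
  if (length(bins) == 0 || sum(lengths(bins)) == 0)
    stop("no Smotifs: cannot build an empty library")
  ids <- names(bins)
  missing_fold <- ids[!ids %in% names(folds)]
  if (length(missing_fold))
    stop("no fold assignment for structure(s): ",
         paste(missing_fold, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  by_fold <- split(ids, unname(folds[ids]))
  all_bins <- sort(unique(unlist(bins, use.names = FALSE)))
  total <- stats::setNames(numeric(length(all_bins)), all_bins)
  for (r in seq_len(n_rounds)) {
    picked <- vapply(by_fold, function(s) s[sample.int(length(s), 1)], "")
    tb <- table(unlist(bins[picked], use.names = FALSE))
    total[names(tb)] <- total[names(tb)] + as.numeric(tb)
  }
  count <- total / n_rounds
  count <- count[count > 0]

  cls <- sub("\\..*$", "", names(count))
  freq <- switch(normalization,
                 global = count / sum(count),
                 per_class = stats::ave(count, cls, FUN = function(x) x / sum(x)))

  first_seen <- rep(as.Date(NA), length(count))
  if (!is.null(dates)) {
    for (sid in ids) {
      d <- dates[sid]
      if (is.na(d)) next
      hit <- match(unique(bins[[sid]]), names(count))
      hit <- hit[!is.na(hit)]
      upd <- is.na(first_seen[hit]) | first_seen[hit] > d
      first_seen[hit[upd]] <- d
    }
  }

  ## bin labels are either cls.iD.idelta.itheta.irho or opaque (simulated)
  idx <- t(vapply(strsplit(names(count), ".", fixed = TRUE), function(p) {
    if (length(p) == 5) suppressWarnings(as.integer(p[2:5])) else rep(NA_integer_, 4)
  }, integer(4)))
  entries <- data.frame(bin = names(count), cls = cls,
                        iD = idx[, 1], i_delta = idx[, 2],
                        i_theta = idx[, 3], i_rho = idx[, 4],
                        count = as.numeric(count), freq = as.numeric(freq),
                        first_seen = first_seen,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(scheme = scheme, normalization = normalization,
                 n_rounds = n_rounds, seed = seed, entries = entries),
            class = "smotif_library")
}

#' @export
print.smotif_library <- function(x, ...) {
  cat("smotif_library:", nrow(x$entries), "occupied bins,",
      x$n_rounds, "rounds,", x$normalization, "normalization\n")
  if (!is.null(x$scheme))
    cat("  scheme:", format_scheme(x$scheme), "(rho_offset",
        x$scheme$rho_offset, ")\n")
  invisible(x)
}

#' Look up library frequencies for bin labels
#'
#' @param library a `smotif_library`.
#' @param bins character vector of bin labels.
#' @return numeric vector of relative frequencies; bins absent from the
#'   library get 0.
#' @export
lib_freq <- function(library, bins) {
  f <- stats::setNames(library$entries$freq, library$entries$bin)
  out <- unname(f[bins])
  out[is.na(out)] <- 0
  out
}

#' Serialize / load a Smotif library as JSON
#'
#' @param library a `smotif_library`.
#' @param path destination / source file.
#' @return `read_library`: the `smotif_library`.
#' @export
write_library <- function(library, path) {
  e <- library$entries
  e$first_seen <- ifelse(is.na(e$first_seen), NA, format(e$first_seen))
  obj <- list(scheme = c(unclass(library$scheme)),
              normalization = library$normalization,
              n_rounds = library$n_rounds,
              seed = library$seed,
              entries = e)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- do.call(binning_scheme, as.list(obj$scheme))
  e <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  e$first_seen <- as.Date(e$first_seen)
  structure(list(scheme = sch, normalization = obj$normalization,
                 n_rounds = obj$n_rounds, seed = obj$seed, entries = e),
            class = "smotif_library")
}

#' Saturation curve: cumulative distinct bins over deposition time
#'
#' For each Smotif class, counts how many distinct geometry bins have been
#' seen up to each date. The terminal value is the number of distinct
#' occupied bins of that class, independent of input order.
#'
#' @param smotifs a classified `smotif_set` with a `date` column, or a data
#'   frame with columns `bin_id`, `class`, `date`.
#' @return data frame with columns `class`, `date`, `n_bins` (a step
#'   function, one row per date at which the count changes).
#' @export
saturation_curve <- function(smotifs) {
  need <- c("bin_id", "class", "date")
  if (!all(need %in% names(smotifs)))
    stop("need columns bin_id, class, date (classify and date the set first)")
  d <- smotifs[!is.na(smotifs$date), need]
  if (nrow(d) == 0)
    return(data.frame(class = character(), date = as.Date(character()),
                      n_bins = integer()))
  out <- lapply(split(d, d$class), function(g) {
    first <- tapply(g$date, g$bin_id, min)
    first <- sort(as.Date(first, origin = "1970-01-01"))
    steps <- sort(unique(first))
    data.frame(class = g$class[1], date = steps,
               n_bins = vapply(steps, function(s) sum(first <= s), 1L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.fold_category <- function(fold_ids, fold_sizes, new_folds) {
  size <- fold_sizes[fold_ids]
  cat <- character(length(fold_ids))
  cat[size == 1] <- "1"
  cat[size >= 2 & size < 10] <- "2-10"
  cat[size >= 10 & size < 50] <- "10-50"
  cat[size >= 50 & size < 100] <- "50-100"
  cat[size >= 100] <- ">100"
  cat[fold_ids %in% new_folds] <- "new"
  cat
}

#' Frequency profile of Smotifs by fold-population category
#'
#' Folds are partitioned by how many structures adopt them -- `new`
#' (explicitly flagged), `1`, `2-10`, `10-50`, `50-100`, `>100` structures,
#' with half-open boundaries -- and for each category the library frequencies
#' of the member structures' Smotifs are pooled into a log-binned histogram.
#' Novel folds show up as a left-shifted profile: a larger share of rare
#' Smotifs.
#'
#' @param bins named list (structure id -> bin labels) or classified
#'   `smotif_set`.
#' @param folds named character vector, structure id -> fold id.
#' @param library a `smotif_library` supplying the frequencies.
#' @param new_folds fold ids flagged as novel (overrides the size category).
#' @param fold_sizes optional named integer vector of structures per fold;
#'   defaults to counting `folds`.
#' @param breaks log-spaced histogram breaks on the frequency axis.
#' @return list with `profile` (data frame: `category`, `bin_lo`, `bin_hi`,
#'   `prop`) and `freqs` (per-category numeric vectors of the pooled
#'   frequencies).
#' @export
frequency_profile_by_category <- function(bins, folds, library,
                                          new_folds = character(),
                                          fold_sizes = NULL,
                                          breaks = 10^seq(-6, 0, by = 0.5)) {
  if (inherits(bins, "smotif_set")) bins <- bins_by_structure(bins)
  if (is.null(fold_sizes)) {
    tb <- table(folds)
    fold_sizes <- stats::setNames(as.integer(tb), names(tb))
  }
  fr_floor <- min(breaks)
  freqs <- list()
  for (sid in names(bins)) {
    fid <- unname(folds[sid])
    if (is.na(fid)) next
    cat <- .fold_category(fid, fold_sizes, new_folds)
    fr <- pmax(lib_freq(library, bins[[sid]]), fr_floor)
    freqs[[cat]] <- c(freqs[[cat]], fr)
  }
  prof <- do.call(rbind, lapply(names(freqs), function(cat) {
    h <- graphics::hist(pmin(pmax(freqs[[cat]], min(breaks)), max(breaks)),
                        breaks = breaks, plot = FALSE)
    data.frame(category = cat, bin_lo = utils::head(breaks, -1),
               bin_hi = breaks[-1],
               prop = h$counts / max(1, sum(h$counts)),
               stringsAsFactors = FALSE)
  }))
  list(profile = prof, freqs = freqs)
}
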