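## Discretization of (D, delta, theta, rho) space and bin-quality evaluation.

#' Construct a binning scheme for Smotif geometry space
#'
#' All intervals are half-open `[lo, hi)`. Distances at or above `D_max` are
#' clamped into the last distance bin; hoist/packing angles exactly at 180
#' fold into the last angle bin. The meridian axis is shifted by `rho_offset`
#' and wrapped, so with the default scheme the interval `[330, 30)` forms a
#' single bin.
#'
#' @param dD distance bin width, Angstrom.
#' @param D_max distance cap, Angstrom; must be a multiple of `dD`.
#' @param d_delta,d_theta hoist/packing bin widths, degrees; must divide 180.
#' @param d_rho meridian bin width, degrees; must divide 360.
#' @param rho_offset meridian bin origin, degrees, in `[0, d_rho)`.
#' @return an object of class `binning_scheme`.
#' @export
binning_scheme <- function(dD = 4, D_max = 40, d_delta = 60, d_theta = 60,
                           d_rho = 60, rho_offset = 0) {
  stopifnot(dD > 0, D_max > 0, d_delta > 0, d_theta > 0, d_rho > 0)
  if (abs(D_max / dD - round(D_max / dD)) > 1e-9)
    stop("D_max must be a multiple of dD")
  if (180 %% d_delta != 0) stop("d_delta must divide 180")
  if (180 %% d_theta != 0) stop("d_theta must divide 180")
  if (360 %% d_rho != 0) stop("d_rho must divide 360")
  if (rho_offset < 0 || rho_offset >= d_rho)
    stop("rho_offset must lie in [0, d_rho)")
  structure(list(dD = dD, D_max = D_max, d_delta = d_delta, d_theta = d_theta,
                 d_rho = d_rho, rho_offset = rho_offset),
            class = "binning_scheme")
}

#' The default (tailored) binning scheme
#'
#' 4 A distance bins capped at 40 A, 60-degree hoist and packing bins
#' starting at 0, and 60-degree meridian bins starting at 30 degrees.
#'
#' @return a `binning_scheme`.
#' @export
default_scheme <- function() binning_scheme(4, 40, 60, 60, 60, rho_offset = 30)

#' @export
print.binning_scheme <- function(x, ...) {
  cat("binning_scheme ", format_scheme(x),
      "  (rho_offset ", x$rho_offset, ", D_max ", x$D_max,
      ", ", n_cells(x), " cells/class)\n", sep = "")
  invisible(x)
}

#' Number of geometric cells per Smotif class
#' @param scheme a `binning_scheme`.
#' @return integer cell count.
#' @export
n_cells <- function(scheme) {
  as.integer(round(scheme$D_max / scheme$dD) * (180 / scheme$d_delta) *
               (180 / scheme$d_theta) * (360 / scheme$d_rho))
}

#' Format / parse the compact scheme name
#'
#' Scheme names follow the `dD_ddelta_dtheta_drho` pattern (for example
#' `"4_60_60_60"`); the meridian offset and distance cap are not part of the
#' name and are supplied separately.
#'
#' @param scheme a `binning_scheme`.
#' @return `format_scheme`: the name string.
#' @export
format_scheme <- function(scheme) {
  paste(scheme$dD, scheme$d_delta, scheme$d_theta, scheme$d_rho, sep = "_")
}

#' @rdname format_scheme
#' @param name scheme name string.
#' @param rho_offset,D_max see [binning_scheme()].
#' @return `parse_scheme`: a `binning_scheme`.
#' @export
parse_scheme <- function(name, rho_offset = 0, D_max = 40) {
  p <- suppressWarnings(as.numeric(strsplit(name, "_", fixed = TRUE)[[1]]))
  if (length(p) != 4 || anyNA(p))
    stop("scheme name must look like '4_60_60_60': got '", name, "'")
  binning_scheme(p[1], D_max, p[2], p[3], p[4], rho_offset = rho_offset)
}

.same_scheme <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Assign geometry values to bin indices
#'
#' Total over all finite inputs: D is clamped to the last bin at `D_max`,
#' angles at 180 fold into the last bin, and rho is wrapped after the offset
#' shift. All indices are 0-based.
#'
#' @param D,delta,theta,rho numeric vectors of geometry values (recycled to
#'   a common length).
#' @param scheme a `binning_scheme`.
#' @return data frame with columns `iD`, `i_delta`, `i_theta`, `i_rho`.
#' @export
assign_bin <- function(D, delta, theta, rho, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "binning_scheme"))
  nD <- round(scheme$D_max / scheme$dD)
  n_del <- 180 / scheme$d_delta
  n_the <- 180 / scheme$d_theta
  iD <- pmin(floor(D / scheme$dD), nD - 1)
  i_delta <- pmin(floor(delta / scheme$d_delta), n_del - 1)
  i_theta <- pmin(floor(theta / scheme$d_theta), n_the - 1)
  i_rho <- floor(((rho - scheme$rho_offset) %% 360) / scheme$d_rho)
  data.frame(iD = as.integer(iD), i_delta = as.integer(i_delta),
             i_theta = as.integer(i_theta), i_rho = as.integer(i_rho))
}

.bin_label <- function(cls, idx) {
  paste(cls, idx$iD, idx$i_delta, idx$i_theta, idx$i_rho, sep = ".")
}

#' Classify a Smotif set under a binning scheme
#'
#' Adds the 0-based bin indices and a `bin_id` label of the form
#' `class.iD.idelta.itheta.irho`, and records the scheme on the set.
#'
#' @param smotifs a `smotif_set` with geometry columns.
#' @param scheme a `binning_scheme`.
#' @return the classified `smotif_set`.
#' @export
classify_smotifs <- function(smotifs, scheme = default_scheme()) {
  idx <- assign_bin(smotifs$D, smotifs$delta, smotifs$theta, smotifs$rho, scheme)
  for (cc in names(idx)) smotifs[[cc]] <- idx[[cc]]
  smotifs$bin_id <- if (nrow(smotifs)) .bin_label(smotifs$class, idx) else character(0)
  attr(smotifs, "scheme") <- scheme
  smotifs
}

#' Evaluate binning schemes by intra-bin structural similarity
#'
#' For each scheme, classifies the Smotifs, samples pairs that share a bin
#' and pairs (of the same class) that do not, superposes each pair and
#' collects the CA RMSD distributions. The headline summary is the fraction
#' of same-bin pairs superposing below 1 A: a good scheme makes same-bin
#' membership predict close structural similarity.
#'
#' @param smotifs a `smotif_set` with CA coordinates.
#' @param schemes list of `binning_scheme` objects (named by
#'   [format_scheme()] if unnamed).
#' @param n_pairs maximum number of pairs sampled per scheme and category.
#' @param seed RNG seed for pair sampling.
#' @param rmsd_threshold threshold for the reported fraction, Angstrom.
#' @return list per scheme: `same` and `diff` RMSD vectors, `frac_same_below`
#'   (fraction of same-bin pairs under the threshold), `n_same`, `n_diff`.
#' @export
evaluate_binning <- function(smotifs, schemes = list(default_scheme()),
                             n_pairs = 500, seed = 1, rmsd_threshold = 1.0) {
  if (is.null(nrow(smotifs)) || nrow(smotifs) < 2)
    stop("evaluate_binning needs at least 2 Smotifs")
  if (inherits(schemes, "binning_scheme")) schemes <- list(schemes)
  if (is.null(names(schemes)) || any(!nzchar(names(schemes))))
    names(schemes) <- vapply(schemes, format_scheme, "")
  set.seed(seed)
  out <- list()
  for (nm in names(schemes)) {
    cl <- classify_smotifs(smotifs, schemes[[nm]])
    same_pairs <- list()
    for (b in split(seq_len(nrow(cl)), cl$bin_id)) {
      if (length(b) < 2) next
      pr <- utils::combn(b, 2)
      same_pairs[[length(same_pairs) + 1]] <- pr
    }
    same <- if (length(same_pairs)) do.call(cbind, same_pairs) else
      matrix(integer(), nrow = 2)
    if (ncol(same) > n_pairs)
      same <- same[, sample.int(ncol(same), n_pairs), drop = FALSE]
    rs <- apply(same, 2, function(ij) superpose_rmsd(cl[ij[1], ], cl[ij[2], ]))
    rs <- as.numeric(rs)

    ## different-bin pairs, same class (so the CA pairing is like-for-like)
    diff_r <- numeric(0)
    tries <- 0
    while (length(diff_r) < min(n_pairs, length(rs) + 50) && tries < 20 * n_pairs) {
      tries <- tries + 1
      ij <- sample.int(nrow(cl), 2)
      if (cl$class[ij[1]] != cl$class[ij[2]]) next
      if (cl$bin_id[ij[1]] == cl$bin_id[ij[2]]) next
      diff_r <- c(diff_r, superpose_rmsd(cl[ij[1], ], cl[ij[2], ]))
    }
    out[[nm]] <- list(same = rs, diff = diff_r,
                      frac_same_below = if (length(rs)) mean(rs < rmsd_threshold) else NA_real_,
                      n_same = length(rs), n_diff = length(diff_r))
  }
  out
}
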