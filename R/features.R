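## Per-Smotif structural features: internal contacts and solvent exposure.

## van der Waals radii (A) for the Shrake-Rupley calculation
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20, D = 1.20)
VDW_DEFAULT <- 1.70

.smotif_res_idx <- function(smotif, chain) {
  r <- chain$residues$seq_pos
  i1s <- match(smotif$ss1_start, r); i1e <- match(smotif$ss1_end, r)
  i2s <- match(smotif$ss2_start, r); i2e <- match(smotif$ss2_end, r)
  if (anyNA(c(i1s, i1e, i2s, i2e)))
    stop("Smotif residues not found in chain ", chain$structure_id)
  list(ss1 = i1s:i1e, loop = if (i2s - i1e > 1) (i1e + 1):(i2s - 1) else integer(0),
       ss2 = i2s:i2e)
}

#' Count non-bonded heavy-atom contacts between the bracing elements
#'
#' Number of heavy-atom pairs (one atom in SS1, one in SS2) within the
#' distance cutoff. Loop atoms are excluded, and for a zero-length loop the
#' pair of sequence-adjacent junction residues is excluded so covalent
#' neighbours are not counted as contacts.
#'
#' @param smotif one-row `smotif_set` slice.
#' @param chain the `chain_model` holding the atoms.
#' @param cutoff contact distance, Angstrom.
#' @return integer contact count.
#' @export
internal_contacts <- function(smotif, chain, cutoff = 4.5) {
  idx <- .smotif_res_idx(smotif, chain)
  a1 <- chain$atoms[chain$atoms$res_idx %in% idx$ss1, , drop = FALSE]
  a2 <- chain$atoms[chain$atoms$res_idx %in% idx$ss2, , drop = FALSE]
  if (smotif$loop_len == 0) {
    if (nrow(a1) == 0 || nrow(a2) == 0) return(0L)
    ## drop only the pairs between the two sequence-adjacent junction residues
    adj1 <- a1$res_idx == max(idx$ss1); adj2 <- a2$res_idx == min(idx$ss2)
    d2 <- .cross_dist2(a1, a2)
    hit <- d2 <= cutoff^2
    hit[adj1, adj2] <- FALSE
    return(sum(hit))
  }
  if (nrow(a1) == 0 || nrow(a2) == 0) return(0L)
  sum(.cross_dist2(a1, a2) <= cutoff^2)
}

.cross_dist2 <- function(a1, a2) {
  x1 <- as.matrix(a1[, c("x", "y", "z")])
  x2 <- as.matrix(a2[, c("x", "y", "z")])
  outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
}

#' Internal-contact ratio of a Smotif
#'
#' Contacts per residue: [internal_contacts()] divided by the Smotif size.
#' Size defaults to the residues of the two bracing elements only
#' (`"braces"`); `"total"` also counts the loop.
#'
#' @inheritParams internal_contacts
#' @param size_mode `"braces"` or `"total"`.
#' @return contacts per residue.
#' @export
ic_ratio <- function(smotif, chain, cutoff = 4.5,
                     size_mode = c("braces", "total")) {
  size_mode <- match.arg(size_mode)
  size <- smotif$ss1_len + smotif$ss2_len +
    if (size_mode == "total") smotif$loop_len else 0L
  internal_contacts(smotif, chain, cutoff) / size
}

## deterministic quasi-uniform sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area per atom
#'
#' Rolls a probe sphere over each heavy atom: the atom's sphere (vdW radius
#' plus probe radius) is sampled at `n_points` quasi-uniform points and the
#' accessible fraction is the share of points not inside any neighbour's
#' expanded sphere.
#'
#' @param coords n x 3 heavy-atom coordinate matrix.
#' @param elements length-n character vector of element symbols (radii from
#'   a documented vdW set; unknown elements fall back to 1.70 A).
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points sphere sample points per atom.
#' @return numeric vector of per-atom accessible areas, Angstrom^2.
#' @export
shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 192) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  r <- VDW_RADII[toupper(elements)]
  r[is.na(r)] <- VDW_DEFAULT
  rr <- r + probe
  sp <- .sphere_points(n_points)
  asa <- numeric(n)
  ## neighbour prefilter: pairs can only occlude within r_i + r_j + 2*probe
  d2 <- .cross_dist2(data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3]),
                     data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3]))
  for (i in seq_len(n)) {
    lim <- (rr[i] + rr)^2
    nb <- which(d2[i, ] < lim & seq_len(n) != i)
    pts <- sweep(sp * rr[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(pts, 2, coords[j, ])
      acc <- acc & rowSums(dj^2) >= rr[j]^2
      if (!any(acc)) break
    }
    asa[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_points
  }
  asa
}

#' Mean per-residue solvent exposure of a Smotif
#'
#' Accessible surface area is computed for all heavy atoms of the chain
#' (Shrake-Rupley, probe 1.4 A), summed per residue, and averaged over the
#' Smotif's residues -- with the loop included or excluded. Residues without
#' atoms are skipped with a message.
#'
#' @inheritParams internal_contacts
#' @param include_loop include the connecting loop residues in the average.
#' @param asa optional precomputed per-atom ASA vector (aligned with
#'   `chain$atoms`) to avoid recomputation across Smotifs; e.g. the ACC
#'   column of a DSSP file aggregated per residue can be substituted
#'   upstream.
#' @return mean accessible area per residue, Angstrom^2.
#' @export
solvent_exposure <- function(smotif, chain, include_loop = TRUE, asa = NULL) {
  idx <- .smotif_res_idx(smotif, chain)
  res <- c(idx$ss1, if (include_loop) idx$loop, idx$ss2)
  if (is.null(asa))
    asa <- shrake_rupley(as.matrix(chain$atoms[, c("x", "y", "z")]),
                         chain$atoms$element)
  per_res <- tapply(asa, chain$atoms$res_idx, sum)
  vals <- per_res[as.character(res)]
  if (anyNA(vals)) {
    message(sum(is.na(vals)), " residue(s) without atoms skipped in ASA average")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' All features of every Smotif in a set
#'
#' @param smotifs a `smotif_set`.
#' @param chain the `chain_model` the Smotifs came from.
#' @param cutoff contact cutoff, Angstrom.
#' @param size_mode see [ic_ratio()].
#' @param with_exposure compute Shrake-Rupley exposure columns (slower).
#' @return data frame with one row per Smotif: `n_contacts`, `ic_ratio`,
#'   `size`, `loop_len`, and optionally `mean_acc`, `mean_acc_no_loop`.
#' @export
smotif_features <- function(smotifs, chain, cutoff = 4.5,
                            size_mode = c("braces", "total"),
                            with_exposure = FALSE) {
  size_mode <- match.arg(size_mode)
  n <- nrow(smotifs)
  asa <- if (with_exposure)
    shrake_rupley(as.matrix(chain$atoms[, c("x", "y", "z")]), chain$atoms$element)
  else NULL
  out <- data.frame(
    structure_id = smotifs$structure_id,
    n_contacts = vapply(seq_len(n), function(i)
      as.integer(internal_contacts(smotifs[i, ], chain, cutoff)), 1L),
    size = smotifs$ss1_len + smotifs$ss2_len +
      if (size_mode == "total") smotifs$loop_len else 0L,
    loop_len = smotifs$loop_len,
    stringsAsFactors = FALSE)
  out$ic_ratio <- out$n_contacts / out$size
  if (with_exposure) {
    out$mean_acc <- vapply(seq_len(n), function(i)
      solvent_exposure(smotifs[i, ], chain, TRUE, asa), 1.0)
    out$mean_acc_no_loop <- vapply(seq_len(n), function(i)
      solvent_exposure(smotifs[i, ], chain, FALSE, asa), 1.0)
  }
  out
}
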