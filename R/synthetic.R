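## Ground-truth generators: idealized elements placed at prescribed internal
## coordinates, whole synthetic chains, and simulated fold populations.
##
## These generators are first-class inputs for validation: a Smotif placed at
## a target (D, delta, theta, rho) must be recovered by the forward geometry
## computation within (0.5 A, 3 deg, 3 deg, 5 deg), and placement verifies
## this round trip itself rather than returning an approximation silently.

## canonical idealized backbone parameters (CA trace)
IDEAL_HELIX <- list(rise = 1.5, twist = 100, radius = 2.3)
IDEAL_STRAND <- list(rise = 3.3, zigzag = 1.0)

#' Build an idealized helix or strand CA trace
#'
#' Helix: 1.5 A rise and 100 degrees twist per residue on a 2.3 A radius.
#' Strand: 3.3 A rise with an alternating +/-1.0 A lateral zigzag. The long
#' axis lies along +z and the first CA sits near the origin. Deterministic.
#'
#' @param kind `"H"` or `"E"`.
#' @param length residue count, at least 3.
#' @return an `ss_element`: list with `kind`, `len` and the `len` x 3 CA
#'   coordinate matrix `ca`.
#' @export
build_ideal_element <- function(kind, length) {
  kind <- match.arg(kind, c("H", "E"))
  if (length < 3) stop("an element needs at least 3 residues")
  t <- seq_len(length) - 1
  ca <- if (kind == "H") {
    a <- t * IDEAL_HELIX$twist * pi / 180
    cbind(IDEAL_HELIX$radius * cos(a), IDEAL_HELIX$radius * sin(a),
          IDEAL_HELIX$rise * t)
  } else {
    cbind(IDEAL_STRAND$zigzag * (-1)^t, 0, IDEAL_STRAND$rise * t)
  }
  structure(list(kind = kind, len = as.integer(length), ca = unname(ca)),
            class = "ss_element")
}

## rotation matrix mapping unit vector a onto unit vector b (Rodrigues)
.rot_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross3(a, b)
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    ## opposite: rotate 180 degrees about any axis orthogonal to a
    h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- .unit(h - sum(h * a) * a)
    return(2 * tcrossprod(u) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

.perp_unit <- function(a) {
  h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(h - sum(h * a) * a)
}

#' Place a second element at prescribed internal coordinates
#'
#' Builds an idealized SS2 and rigidly poses it so the forward geometry of
#' the pair reproduces the target `(D, delta, theta, rho)` within
#' (0.5 A, 3 deg, 3 deg, 5 deg); the round trip is verified internally and
#' failure is an error, never a silent approximation. Loop CA positions are
#' synthesized along a gently bowed path between the junction anchors; they
#' are decorative (no geometry operation reads them) but keep CA spacing
#' below the chain-break threshold.
#'
#' @param ss1 an `ss_element` (already posed arbitrarily in space).
#' @param D,delta,theta,rho target internal coordinates (degrees; `rho` may
#'   be `NA` when `delta` or `theta` is degenerate, in which case it is
#'   unconstrained).
#' @param ss2_kind,ss2_len kind and length of the element to place.
#' @param loop_len loop residue count; must satisfy
#'   `D / (loop_len + 1) <= 4.2` so the loop can span the junction without a
#'   chain break.
#' @return list with `ss1`, `ss2` (both `ss_element`s), `loop_ca`, the
#'   `target` and the forward-computed `geometry`.
#' @export
place_at_geometry <- function(ss1, D, delta, theta, rho = NA,
                              ss2_kind = "H", ss2_len = 10, loop_len = 3) {
  stopifnot(inherits(ss1, "ss_element") || (is.list(ss1) && !is.null(ss1$ca)))
  if (D <= 0) stop("D must be positive")
  if (delta < 0 || delta > 180) stop("delta out of [0, 180]")
  if (theta < 0 || theta > 180) stop("theta out of [0, 180]")
  deg_delta <- delta < 1 || delta > 179
  deg_theta <- theta < 1 || theta > 179
  if (deg_delta && !is.na(rho))
    stop("infeasible target: delta is degenerate (plane Pi undefined), rho must be NA")
  if (deg_theta && !is.na(rho) && .circ_diff(rho, 0) > 1e-6)
    stop("infeasible target: theta is degenerate, M2 has no azimuth; rho must be NA or 0")
  if (D / (loop_len + 1) > 4.2)
    stop("loop of ", loop_len, " residues cannot span D = ", round(D, 1),
         " A without a chain break")

  M1 <- principal_axis(ss1$ca)
  P1 <- as.numeric(ss1$ca[nrow(ss1$ca), ])
  e1 <- M1
  e2 <- .perp_unit(e1)
  e3 <- .cross3(e1, e2)
  dr <- delta * pi / 180
  L_dir <- cos(dr) * e1 + sin(dr) * e2
  P2 <- P1 + D * L_dir
  tr <- theta * pi / 180
  rr <- if (is.na(rho)) 0 else rho * pi / 180
  M2 <- cos(tr) * e1 + sin(tr) * (cos(rr) * e2 + sin(rr) * e3)

  raw <- build_ideal_element(ss2_kind, ss2_len)
  a2 <- principal_axis(raw$ca)
  R <- .rot_between(a2, M2)
  ca2 <- raw$ca %*% t(R)
  ca2 <- sweep(ca2, 2, as.numeric(P2 - ca2[1, ]), "+")
  ss2 <- structure(list(kind = ss2_kind, len = as.integer(ss2_len), ca = ca2),
                   class = "ss_element")

  ## decorative loop: straight interpolation with a small perpendicular bow
  loop_ca <- NULL
  if (loop_len > 0) {
    tt <- seq_len(loop_len) / (loop_len + 1)
    w <- .unit(.cross3(L_dir, if (abs(sum(L_dir * e3)) < 0.99) e3 else e2))
    loop_ca <- t(vapply(tt, function(s)
      P1 + s * (P2 - P1) + 0.3 * sin(pi * s) * w, numeric(3)))
  }

  g <- compute_geometry(ss1$ca, ca2)
  ok <- abs(g$D - D) <= 0.5 && abs(g$delta - delta) <= 3 && abs(g$theta - theta) <= 3 &&
    (is.na(rho) || g$degenerate || .circ_diff(g$rho, rho) <= 5)
  if (!ok)
    stop(sprintf(paste0("placement verification failed: target (%.1f, %.1f, %.1f, %s) ",
                        "recovered as (%.2f, %.2f, %.2f, %.2f)"),
                 D, delta, theta, ifelse(is.na(rho), "NA", sprintf("%.1f", rho)),
                 g$D, g$delta, g$theta, g$rho))
  list(ss1 = ss1, ss2 = ss2, loop_ca = loop_ca,
       target = list(D = D, delta = delta, theta = theta, rho = rho,
                     loop_len = loop_len),
       geometry = g)
}

#' Sample random feasible placement targets
#'
#' Draws geometry targets away from the degenerate axes (hoist and packing in
#' `[10, 170]` degrees), with loop lengths long enough to span the sampled
#' distance, and element kinds/lengths typical of real structures (helices
#' 6-14, strands 4-8 residues).
#'
#' @param n number of targets.
#' @param seed optional RNG seed.
#' @return data frame usable as input to [build_synthetic_chain()].
#' @export
sample_targets <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- stats::runif(n, 4, 25)
  kinds <- sample(c("H", "E"), n, replace = TRUE)
  data.frame(
    D = D,
    delta = stats::runif(n, 10, 170),
    theta = stats::runif(n, 10, 170),
    rho = stats::runif(n, 0, 360),
    loop_len = pmax(2L, as.integer(ceiling(D / 3.8))),
    ss2_kind = kinds,
    ss2_len = ifelse(kinds == "H", sample(6:14, n, replace = TRUE),
                     sample(4:8, n, replace = TRUE)),
    stringsAsFactors = FALSE)
}

#' Build a synthetic chain realizing a sequence of placement targets
#'
#' Chains targets so the placed element of step i becomes the first element
#' of step i+1; the result is a CA-only `chain_model` with ground-truth
#' 3-state labels whose [smotif_string()] decomposition recovers
#' `nrow(targets)` Smotifs at the prescribed geometries.
#'
#' @param targets data frame with columns `D`, `delta`, `theta`, `rho`,
#'   `loop_len`, `ss2_kind`, `ss2_len` (see [sample_targets()]); zero rows
#'   give a single-element chain.
#' @param init_kind,init_len the first element.
#' @param structure_id,chain_id identifiers for the resulting model.
#' @return a `chain_model` with CA-only atoms and ss3 set by construction.
#' @export
build_synthetic_chain <- function(targets, init_kind = "H", init_len = 10,
                                  structure_id = "synthetic", chain_id = "A") {
  cur <- build_ideal_element(init_kind, init_len)
  segs <- list(list(ca = cur$ca, ss = rep(cur$kind, cur$len)))
  nt <- if (is.null(nrow(targets))) 0 else nrow(targets)
  for (i in seq_len(nt)) {
    tg <- targets[i, ]
    pl <- place_at_geometry(cur, tg$D, tg$delta, tg$theta, tg$rho,
                            ss2_kind = tg$ss2_kind, ss2_len = tg$ss2_len,
                            loop_len = tg$loop_len)
    if (!is.null(pl$loop_ca))
      segs[[length(segs) + 1]] <- list(ca = pl$loop_ca,
                                       ss = rep("C", nrow(pl$loop_ca)))
    segs[[length(segs) + 1]] <- list(ca = pl$ss2$ca, ss = rep(pl$ss2$kind, pl$ss2$len))
    cur <- pl$ss2
  }
  ca <- do.call(rbind, lapply(segs, `[[`, "ca"))
  ss <- unlist(lapply(segs, `[[`, "ss"))
  n <- nrow(ca)
  residues <- data.frame(seq_pos = as.character(seq_len(n)),
                         resno = seq_len(n), ins = "",
                         aa = "A", ss3 = ss,
                         x = ca[, 1], y = ca[, 2], z = ca[, 3],
                         stringsAsFactors = FALSE)
  atoms <- data.frame(res_idx = seq_len(n), elety = "CA", element = "C",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  structure(list(structure_id = structure_id, chain = chain_id,
                 deposition_date = NULL, residues = residues, atoms = atoms),
            class = "chain_model")
}

#' Write a chain model as a CA-trace PDB file
#'
#' Standard fixed-format ATOM records (CA only), suitable for re-reading
#' with [read_pdb()]. Pair with [write_ss_annotation()] to preserve the
#' ground-truth labels.
#'
#' @param chain a `chain_model`.
#' @param file destination path.
#' @export
write_chain_pdb <- function(chain, file) {
  r <- chain$residues
  aa3 <- vapply(r$aa, function(a) {
    x <- bio3d::aa123(a); if (is.na(x)) "ALA" else x
  }, "")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(r)), aa3, chain$chain, r$resno, ifelse(nzchar(r$ins), r$ins, " "),
    r$x, r$y, r$z)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname write_chain_pdb
#' @export
write_ss_annotation <- function(chain, file) {
  writeLines(c("chain\tseq_pos\tss",
               paste(chain$chain, chain$residues$seq_pos, chain$residues$ss3,
                     sep = "\t")), file)
  invisible(file)
}

#' Simulate fold populations over an abstract bin universe
#'
#' Emulates the statistical structure of a fold census: a heavy-tailed
#' (Zipf) distribution of Smotif-bin usage, "known" folds drawn from it, and
#' "novel" folds drawn from a mixture that shifts probability mass
#' `lambda` onto the rarest quartile of bins. With `lambda = 0` the two
#' groups are statistically identical.
#'
#' @param n_bins bin universe size.
#' @param zipf_s Zipf tail exponent of the base frequencies.
#' @param n_known,n_novel fold counts.
#' @param string_len integer range (min, max) of Smotifs per fold.
#' @param lambda probability mass shifted onto the rarest quartile for novel
#'   folds, in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return list with `known` and `novel` (named lists of bin-label vectors,
#'   one per fold), `base_freqs` (named, sums to 1), `rare_bins` (the rarest
#'   quartile labels) and `params`.
#' @export
simulate_population <- function(n_bins = 540, zipf_s = 1.5,
                                n_known = 200, n_novel = 200,
                                string_len = c(3, 12), lambda = 0.8,
                                seed = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, n_bins >= 8,
            string_len[1] >= 1, string_len[2] >= string_len[1])
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("bin%04d", seq_len(n_bins))
  base <- (seq_len(n_bins))^(-zipf_s)
  base <- base / sum(base)
  names(base) <- labels
  rare <- labels[(floor(3 * n_bins / 4) + 1):n_bins]
  rare_p <- base[rare] / sum(base[rare])

  draw_fold <- function(novel) {
    len <- sample(string_len[1]:string_len[2], 1)
    if (!novel || lambda == 0)
      return(sample(labels, len, replace = TRUE, prob = base))
    from_rare <- stats::runif(len) < lambda
    out <- character(len)
    out[from_rare] <- sample(rare, sum(from_rare), replace = TRUE, prob = rare_p)
    out[!from_rare] <- sample(labels, sum(!from_rare), replace = TRUE, prob = base)
    out
  }
  known <- stats::setNames(lapply(seq_len(n_known), function(i) draw_fold(FALSE)),
                           sprintf("known%04d", seq_len(n_known)))
  novel <- stats::setNames(lapply(seq_len(n_novel), function(i) draw_fold(TRUE)),
                           sprintf("novel%04d", seq_len(n_novel)))
  list(known = known, novel = novel, base_freqs = base, rare_bins = rare,
       params = list(n_bins = n_bins, zipf_s = zipf_s, n_known = n_known,
                     n_novel = n_novel, string_len = string_len,
                     lambda = lambda, seed = seed))
}
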