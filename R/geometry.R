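## Internal-coordinate geometry of a Smotif.
##
## Each bracing element is represented by its principal inertia axis (M1,
## M2). With P1 the CA of SS1's last residue, P2 the CA of SS2's first
## residue and L = P2 - P1, the four coordinates are
##   D     = |L|                              (A)
##   delta = angle(L, M1)   "hoist"           [0, 180] deg
##   theta = angle(M1, M2)  "packing"         [0, 180] deg
##   rho   = azimuth of M2 about M1           [0, 360) deg, "meridian"
## The azimuth is measured in the frame e1 = M1, e2 = component of L
## orthogonal to M1 (in plane Pi), e3 = e1 x e2 (normal of Pi; plane Gamma =
## span(e1, e3)): rho = atan2(M2.e3, M2.e2). Under this convention a mirror
## reflection maps rho to 360 - rho while D, delta, theta are unchanged, so
## the coordinates capture chirality.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.angle_deg <- function(a, b) {
  ca <- sum(.unit(a) * .unit(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

## absolute circular difference in degrees, result in [0, 180]
.circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Principal axis of a secondary-structure element
#'
#' The long axis of the element's CA trace: the eigenvector of the CA inertia
#' tensor (unit masses) with the smallest moment, equivalently the first
#' principal component of the coordinates. Before the tensor is formed the
#' trace is passed through a short moving average (window up to 4 residues,
#' about one helical turn): a fractional final turn otherwise tilts the raw
#' inertia axis of a short helix by several degrees, and the averaging
#' cancels the periodic wobble while leaving straight or zigzag (strand)
#' traces unchanged by symmetry. The sign is fixed so the axis points
#' N-terminus to C-terminus (positive dot product with last CA minus first
#' CA).
#'
#' @param x an n x 3 matrix of CA coordinates (n >= 3), or an `ss_element`.
#' @return a unit 3-vector.
#' @export
principal_axis <- function(x) {
  if (is.list(x) && !is.null(x$ca)) x <- x$ca
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("principal axis needs at least 3 CA positions")
  if (max(abs(sweep(x, 2, colMeans(x)))) < 1e-9)
    stop("degenerate element: all CA positions coincide")
  w <- min(4L, n - 2L)   # keep at least 3 smoothed points
  xs <- if (w >= 2) {
    apply(x, 2, function(col) stats::filter(col, rep(1 / w, w), sides = 1)[w:n])
  } else x
  cen <- sweep(xs, 2, colMeans(xs))
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  ax <- ev$vectors[, 1]   # largest spread = smallest inertia moment
  ends <- x[n, ] - x[1, ]
  s <- sum(ax * ends)
  if (abs(s) > 1e-12 && s < 0) ax <- -ax
  .unit(ax)
}

#' Internal coordinates of an element pair
#'
#' @param ca1,ca2 CA coordinate matrices of SS1 and SS2 (or `ss_element`s).
#' @param degeneracy_tol hoist angles within this many degrees of 0 or 180
#'   leave plane Pi undefined; such Smotifs get `rho = 0` and are flagged.
#' @return list with `D`, `delta`, `theta`, `rho` and logical `degenerate`.
#' @export
compute_geometry <- function(ca1, ca2, degeneracy_tol = 1) {
  if (is.list(ca1) && !is.null(ca1$ca)) ca1 <- ca1$ca
  if (is.list(ca2) && !is.null(ca2$ca)) ca2 <- ca2$ca
  M1 <- principal_axis(ca1)
  M2 <- principal_axis(ca2)
  P1 <- as.numeric(ca1[nrow(ca1), ])
  P2 <- as.numeric(ca2[1, ])
  L <- P2 - P1
  D <- .vnorm(L)
  if (D < 1e-9) stop("P1 and P2 coincide: geometry undefined")
  delta <- .angle_deg(L, M1)
  theta <- .angle_deg(M1, M2)
  degenerate <- delta < degeneracy_tol || delta > 180 - degeneracy_tol
  if (degenerate) {
    rho <- 0
  } else {
    e1 <- M1
    e2 <- .unit(L - sum(L * e1) * e1)
    e3 <- .cross3(e1, e2)
    rho <- (atan2(sum(M2 * e3), sum(M2 * e2)) * 180 / pi) %% 360
  }
  list(D = D, delta = delta, theta = theta, rho = rho, degenerate = degenerate)
}

.pair_ca <- function(a, b) {
  ## SS1 aligned anchored at its C-terminus, SS2 at its N-terminus, each
  ## trimmed to the shorter element; loop residues never enter.
  ca1a <- a$ca1[[1]]; ca2a <- a$ca2[[1]]
  ca1b <- b$ca1[[1]]; ca2b <- b$ca2[[1]]
  k1 <- min(nrow(ca1a), nrow(ca1b))
  k2 <- min(nrow(ca2a), nrow(ca2b))
  A <- rbind(ca1a[(nrow(ca1a) - k1 + 1):nrow(ca1a), , drop = FALSE],
             ca2a[seq_len(k2), , drop = FALSE])
  B <- rbind(ca1b[(nrow(ca1b) - k1 + 1):nrow(ca1b), , drop = FALSE],
             ca2b[seq_len(k2), , drop = FALSE])
  list(A = A, B = B)
}

#' Optimal-superposition CA RMSD between two Smotifs
#'
#' Pairs the bracing-element CA atoms of the two Smotifs (SS1 anchored at the
#' loop junction from the C-terminal side, SS2 from the N-terminal side, each
#' trimmed to the shorter of the two elements; loops excluded), performs a
#' least-squares rigid superposition (Kabsch, via `bio3d`) and returns the
#' minimized RMSD.
#'
#' @param a,b single-row `smotif_set` slices carrying `ca1`/`ca2` list
#'   columns, or lists with elements `ca1`, `ca2` (n x 3 matrices).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b) {
  norm_in <- function(s) {
    if (inherits(s, "data.frame")) {
      if (nrow(s) != 1) stop("superpose_rmsd expects single Smotifs")
      return(list(ca1 = s$ca1, ca2 = s$ca2))
    }
    if (is.matrix(s$ca1)) return(list(ca1 = list(s$ca1), ca2 = list(s$ca2)))
    s
  }
  p <- .pair_ca(norm_in(a), norm_in(b))
  if (nrow(p$A) < 3) stop("fewer than 3 paired CA atoms")
  va <- as.vector(t(p$A))
  vb <- as.vector(t(p$B))
  as.numeric(bio3d::rmsd(va, vb, fit = TRUE))
}
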