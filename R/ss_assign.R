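## CA-trace secondary-structure assignment (P-SEA).
##
## Assigns helix/strand/coil from CA geometry alone: the short-range
## distances d2 = |CA(i-1)CA(i+1)|, d3 = |CA(i-1)CA(i+2)|,
## d4 = |CA(i-1)CA(i+3)|, the bond angle at CA(i) and the CA dihedral,
## against the published P-SEA windows. Useful when no DSSP output is
## available (DSSP needs full backbone and an external program) and it gives
## identical criteria to every structure, so independently solved entries of
## the same protein receive consistent element boundaries.

.psea <- list(
  r_helix = c(77, 101), a_helix = c(30, 70),
  d3_helix = c(4.8, 5.8), d4_helix = c(5.8, 7.0),
  r_strand = c(110, 138), a_strand_lo = c(-180, -125), a_strand_hi = c(145, 180),
  d2_strand = c(6.1, 7.3), d3_strand = c(9.0, 10.8), d4_strand = c(11.3, 13.5)
)

.in_rng <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

.ca_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  atan2(sum(.cross3(n1, n2) * .unit(b2)), sum(n1 * n2)) * 180 / pi
}

.runs_of <- function(mask, k) {
  ## TRUE where the index lies in a run of >= k consecutive TRUEs
  n <- length(mask)
  out <- logical(n)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values & r$lengths >= k)) out[starts[j]:ends[j]] <- TRUE
  out
}

.extend_once <- function(base, cond) {
  n <- length(base)
  left <- c(base[-1], FALSE) & !base    # element just before a TRUE region
  right <- c(FALSE, base[-n]) & !base   # element just after
  base | ((left | right) & cond)
}

#' Assign secondary structure from the CA trace (P-SEA)
#'
#' Implements the P-SEA criteria on CA-only geometry: candidate residues are
#' seeded by strict distance/angle windows (runs of at least 5 for helix, 4
#' for strand, or 3 for strands making at least 5 CA contacts at sheet-pairing
#' distance 4.2-5.2 A), then extended by one residue per side where relaxed
#' windows hold. Chain breaks (CA-CA > 4.5 A) split the trace. The exact
#' element termini can differ by a residue or two from a DSSP assignment,
#' which uses hydrogen bonds on the full backbone.
#'
#' @param chain a `chain_model`.
#' @return annotation data frame (`chain`, `seq_pos`, `ss3`) suitable for
#'   [annotate_ss()].
#' @export
assign_ss_ca <- function(chain) {
  stopifnot(inherits(chain, "chain_model"))
  X <- as.matrix(chain$residues[, c("x", "y", "z")])
  n <- nrow(X)
  brk <- which(.chain_breaks(chain))   # break between residue j and j+1
  seg_id <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% brk)))
  ss <- rep("C", n)

  for (seg in split(seq_len(n), seg_id)) {
    m <- length(seg)
    if (m < 4) next
    x <- X[seg, , drop = FALSE]
    d2 <- d3 <- d4 <- r <- a <- rep(NA_real_, m)
    idx <- function(i) x[i, ]
    for (i in 2:(m - 1)) {
      d2[i] <- .vnorm(idx(i + 1) - idx(i - 1))
      r[i] <- .angle_deg(idx(i - 1) - idx(i), idx(i + 1) - idx(i))
      if (i <= m - 2) {
        d3[i] <- .vnorm(idx(i + 2) - idx(i - 1))
        a[i] <- .ca_dihedral(idx(i - 1), idx(i), idx(i + 1), idx(i + 2))
      }
      if (i <= m - 3) d4[i] <- .vnorm(idx(i + 3) - idx(i - 1))
    }
    p <- .psea
    relaxed_h <- .in_rng(d3, p$d3_helix) | .in_rng(r, p$r_helix)
    strict_h <- (.in_rng(d3, p$d3_helix) & .in_rng(d4, p$d4_helix)) |
      (.in_rng(r, p$r_helix) & .in_rng(a, p$a_helix))
    relaxed_e <- .in_rng(d3, p$d3_strand)
    strict_e <- (.in_rng(d2, p$d2_strand) & .in_rng(d3, p$d3_strand) &
                   .in_rng(d4, p$d4_strand)) |
      (.in_rng(r, p$r_strand) &
         (.in_rng(a, p$a_strand_lo) | .in_rng(a, p$a_strand_hi)))

    helix <- .extend_once(.runs_of(strict_h, 5), relaxed_h)

    strand4 <- .runs_of(strict_e, 4)
    strand3 <- .runs_of(strict_e, 3) & !strand4
    if (any(strand3)) {
      ## short strands survive only with enough sheet-pairing CA contacts
      keep <- logical(m)
      d_all <- sqrt(pmax(.cross_dist2(
        data.frame(x = x[, 1], y = x[, 2], z = x[, 3]),
        data.frame(x = X[, 1], y = X[, 2], z = X[, 3])), 0))
      contacts <- vapply(seq_len(m), function(i)
        sum(d_all[i, ] > 4.2 & d_all[i, ] <= 5.2), 0L)
      rr <- rle(strand3)
      ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1
      for (j in which(rr$values)) {
        reg <- starts[j]:ends[j]
        if (sum(contacts[reg]) >= 5) keep[reg] <- TRUE
      }
      strand3 <- keep
    }
    strand <- .extend_once(strand4 | strand3, relaxed_e)

    sseg <- rep("C", m)
    sseg[helix] <- "H"
    sseg[strand] <- "E"    # strand criteria win on overlap, as in P-SEA
    ss[seg] <- sseg
  }
  data.frame(chain = chain$chain, seq_pos = chain$residues$seq_pos, ss3 = ss,
             stringsAsFactors = FALSE)
}
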