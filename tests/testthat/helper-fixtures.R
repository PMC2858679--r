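# Fixtures are built in code: minimal PDB/DSSP texts, toy chain models and
# one-row smotif sets, and random rigid motions for invariance sweeps.

# Minimal CA-only PDB text; coords is an n x 3 matrix, resno defaults 1..n
make_pdb_text <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                          aa = "ALA", altloc = rep(" ", nrow(coords)),
                          occ = rep(1, nrow(coords))) {
  lines <- sprintf(
    "ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
    seq_len(nrow(coords)), altloc, aa, chain, resno,
    coords[, 1], coords[, 2], coords[, 3], occ)
  paste(c(lines, "END"), collapse = "\n")
}

# Classic-format DSSP text with given per-residue (resno, chain, aa, ss, acc)
make_dssp_text <- function(resno, chain = "A", aa = "A", ss = "H", acc = 100) {
  n <- length(resno)
  chain <- rep_len(chain, n); aa <- rep_len(aa, n)
  ss <- rep_len(ss, n); acc <- rep_len(acc, n)
  body <- sprintf("%5d%5d %s %s  %s%17s%4d", seq_len(n), resno, chain, aa, ss,
                  "", acc)
  paste(c("==== Secondary Structure Definition ====",
          "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC", body), collapse = "\n")
}

# chain_model straight from coordinates + labels (CA-only)
make_chain <- function(ca, ss3, id = "toy", chain = "A") {
  n <- nrow(ca)
  structure(list(
    structure_id = id, chain = chain, deposition_date = NULL,
    residues = data.frame(seq_pos = as.character(seq_len(n)), resno = seq_len(n),
                          ins = "", aa = "A", ss3 = ss3,
                          x = ca[, 1], y = ca[, 2], z = ca[, 3],
                          stringsAsFactors = FALSE),
    atoms = data.frame(res_idx = seq_len(n), elety = "CA", element = "C",
                       x = ca[, 1], y = ca[, 2], z = ca[, 3],
                       stringsAsFactors = FALSE)),
    class = "chain_model")
}

# straight CA trace along +z with standard 3.8 A spacing
line_ca <- function(n, spacing = 3.8) cbind(0, 0, spacing * (seq_len(n) - 1))

# one-row smotif_set from two CA matrices (geometry computed)
make_smotif <- function(ca1, ca2, cls = "HH", id = "s1", loop_len = 2,
                        date = as.Date(NA)) {
  g <- compute_geometry(ca1, ca2)
  d <- data.frame(structure_id = id, chain = "A", class = cls,
                  ss1_start = "1", ss1_end = as.character(nrow(ca1)),
                  ss1_len = nrow(ca1), loop_len = loop_len,
                  ss2_start = "x", ss2_end = "y", ss2_len = nrow(ca2),
                  D = g$D, delta = g$delta, theta = g$theta, rho = g$rho,
                  degenerate = g$degenerate, stringsAsFactors = FALSE)
  d$ca1 <- list(ca1); d$ca2 <- list(ca2)
  d$date <- date
  class(d) <- c("smotif_set", "data.frame")
  d
}

# uniform random rotation matrix (via QR, determinant fixed to +1)
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(ca, R, t) sweep(ca %*% t(R), 2, t, "+")

# small library over named frequencies (counts = freqs * 100)
make_library <- function(freqs, scheme = default_scheme()) {
  cls <- sub("\\..*$", "", names(freqs))
  idx <- suppressWarnings(do.call(rbind, lapply(strsplit(
    sub("^[A-Z]+\\.", "", names(freqs)), ".", fixed = TRUE),
    function(p) as.integer(rep_len(p, 4)))))
  structure(list(scheme = scheme, normalization = "global", n_rounds = 1,
                 seed = NULL,
                 entries = data.frame(bin = names(freqs), cls = cls,
                                      iD = idx[, 1], i_delta = idx[, 2],
                                      i_theta = idx[, 3], i_rho = idx[, 4],
                                      count = unname(freqs) * 100,
                                      freq = unname(freqs),
                                      first_seen = as.Date(NA),
                                      stringsAsFactors = FALSE)),
            class = "smotif_library")
}

# jittered ensemble of placed Smotifs around base geometries, for bin-quality
# evaluation tests
jittered_ensemble <- function(n_base = 6, n_var = 12, seed = 42,
                              jit_D = 2, jit_ang = 20) {
  set.seed(seed)
  base <- sample_targets(n_base)
  out <- list()
  for (i in seq_len(n_base)) {
    for (j in seq_len(n_var)) {
      tg <- base[i, ]
      D <- max(4, tg$D + stats::runif(1, -jit_D, jit_D))
      delta <- min(170, max(10, tg$delta + stats::runif(1, -jit_ang, jit_ang)))
      theta <- min(170, max(10, tg$theta + stats::runif(1, -jit_ang, jit_ang)))
      rho <- (tg$rho + stats::runif(1, -jit_ang, jit_ang)) %% 360
      ss1 <- build_ideal_element("H", 8)
      pl <- place_at_geometry(ss1, D, delta, theta, rho,
                              ss2_kind = tg$ss2_kind, ss2_len = tg$ss2_len,
                              loop_len = max(2, ceiling(D / 3.8)))
      out[[length(out) + 1]] <- make_smotif(pl$ss1$ca, pl$ss2$ca,
                                            cls = paste0("H", tg$ss2_kind),
                                            id = sprintf("b%02dv%02d", i, j))
    }
  }
  bind_smotifs(out)
}

# real chains bundled with bio3d (crystal structures), with CA-based (P-SEA)
# secondary-structure assignment so all entries get consistent criteria
real_chains <- function() {
  specs <- list(c("1hel.pdb", "A"), c("1dpx.pdb", "A"),
                c("hivp.pdb", "A"), c("hivp.pdb", "B"))
  lapply(specs, function(s) {
    f <- system.file("examples", s[1], package = "bio3d")
    ch <- read_pdb(f, chain = s[2], id = paste0(sub(".pdb", "", s[1]), "_", s[2]))
    annotate_ss(ch, assign_ss_ca(ch))
  })
}
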