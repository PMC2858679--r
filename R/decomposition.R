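## Secondary-structure element extraction and Smotif string decomposition.
##
## A Smotif is a pair of consecutive regular secondary-structure elements
## (helix or strand) plus the connecting loop. A chain with k elements yields
## k-1 overlapping Smotifs: the C-terminal element of one is the N-terminal
## element of the next, so the whole structure reads as a string of Smotifs.

## CA-CA distances beyond this are treated as chain breaks; elements and
## loops never span a break.
CHAIN_BREAK_CA <- 4.5

.chain_breaks <- function(chain) {
  xyz <- as.matrix(chain$residues[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) return(logical(0))
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  d > CHAIN_BREAK_CA
}

#' Extract helix and strand elements from an annotated chain
#'
#' Scans the 3-state labels for maximal runs of `H` or `E`. Runs shorter than
#' the per-kind minimum are demoted to coil (and thereby absorbed into the
#' loop between their neighbours); runs are split at chain breaks (CA-CA
#' distance above 4.5 A).
#'
#' @param chain a `chain_model` with `ss3` annotated.
#' @param min_helix,min_strand minimum residue counts for a run to count as
#'   an element. At least 3 CA atoms are needed for a stable principal axis.
#' @return data frame with one row per element: `kind`, `i_start`, `i_end`
#'   (row indices into `chain$residues`), `len`.
#' @export
extract_ss_elements <- function(chain, min_helix = 4, min_strand = 3) {
  stopifnot(inherits(chain, "chain_model"))
  ss <- chain$residues$ss3
  n <- length(ss)
  if (n == 0)
    return(data.frame(kind = character(), i_start = integer(),
                      i_end = integer(), len = integer()))
  brk <- .chain_breaks(chain)
  new_run <- c(TRUE, ss[-1] != ss[-n] | brk)
  run_id <- cumsum(new_run)
  out <- lapply(split(seq_len(n), run_id), function(i) {
    k <- ss[i[1]]
    if (!k %in% c("H", "E")) return(NULL)
    need <- if (k == "H") min_helix else min_strand
    if (length(i) < need) return(NULL)
    data.frame(kind = k, i_start = i[1], i_end = i[length(i)],
               len = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(kind = character(), i_start = integer(),
                      i_end = integer(), len = integer()))
  rownames(out) <- NULL
  out[order(out$i_start), , drop = FALSE]
}

.element_ca <- function(chain, i_start, i_end) {
  as.matrix(chain$residues[i_start:i_end, c("x", "y", "z")])
}

#' Decompose an element list into the string of overlapping Smotifs
#'
#' Consecutive element pairs become Smotifs; the SS2 of Smotif i is the SS1
#' of Smotif i+1. Smotifs whose connecting loop crosses a chain break are
#' dropped (with a message). Geometry is filled in via [compute_geometry()].
#'
#' @param elements element table from [extract_ss_elements()], ordered by
#'   start position.
#' @param chain the `chain_model` the elements index into.
#' @return a `smotif_set`: data frame with identification, element spans,
#'   loop length, class (`HH`/`HE`/`EH`/`EE`), the four internal coordinates
#'   `D`, `delta`, `theta`, `rho`, a `degenerate` flag, and list columns
#'   `ca1`/`ca2` holding the CA coordinates of the bracing elements.
#' @export
decompose <- function(elements, chain) {
  stopifnot(inherits(chain, "chain_model"))
  empty <- data.frame(structure_id = character(), chain = character(),
                      class = character(),
                      ss1_start = character(), ss1_end = character(), ss1_len = integer(),
                      loop_len = integer(),
                      ss2_start = character(), ss2_end = character(), ss2_len = integer(),
                      D = numeric(), delta = numeric(), theta = numeric(), rho = numeric(),
                      degenerate = logical(), stringsAsFactors = FALSE)
  k <- nrow(elements)
  if (is.null(k) || k < 2) {
    empty$ca1 <- list(); empty$ca2 <- list()
    class(empty) <- c("smotif_set", "data.frame")
    return(empty)
  }
  brk <- .chain_breaks(chain)
  rows <- list()
  for (i in seq_len(k - 1)) {
    e1 <- elements[i, ]; e2 <- elements[i + 1, ]
    ## break anywhere between the end of SS1 and the start of SS2 kills the loop
    span <- seq(e1$i_end, e2$i_start - 1)
    if (any(brk[span])) {
      message("dropping Smotif across chain break after residue ",
              chain$residues$seq_pos[e1$i_end], " in ", chain$structure_id)
      next
    }
    ca1 <- .element_ca(chain, e1$i_start, e1$i_end)
    ca2 <- .element_ca(chain, e2$i_start, e2$i_end)
    g <- compute_geometry(ca1, ca2)
    rows[[length(rows) + 1]] <- list(
      structure_id = chain$structure_id, chain = chain$chain,
      class = paste0(e1$kind, e2$kind),
      ss1_start = chain$residues$seq_pos[e1$i_start],
      ss1_end = chain$residues$seq_pos[e1$i_end],
      ss1_len = e1$len,
      loop_len = e2$i_start - e1$i_end - 1L,
      ss2_start = chain$residues$seq_pos[e2$i_start],
      ss2_end = chain$residues$seq_pos[e2$i_end],
      ss2_len = e2$len,
      D = g$D, delta = g$delta, theta = g$theta, rho = g$rho,
      degenerate = g$degenerate,
      ca1 = list(ca1), ca2 = list(ca2))
  }
  if (length(rows) == 0) {
    empty$ca1 <- list(); empty$ca2 <- list()
    class(empty) <- c("smotif_set", "data.frame")
    return(empty)
  }
  d <- do.call(rbind, lapply(rows, function(r) {
    dd <- as.data.frame(r[setdiff(names(r), c("ca1", "ca2"))], stringsAsFactors = FALSE)
    dd
  }))
  d$ca1 <- lapply(rows, function(r) r$ca1[[1]])
  d$ca2 <- lapply(rows, function(r) r$ca2[[1]])
  rownames(d) <- NULL
  d$date <- if (!is.null(chain$deposition_date)) chain$deposition_date else as.Date(NA)
  class(d) <- c("smotif_set", "data.frame")
  d
}

#' Full chain-to-Smotif-string convenience wrapper
#'
#' Composition of [extract_ss_elements()] and [decompose()]: a chain with
#' five regular secondary structures yields a string of four overlapping
#' Smotifs.
#'
#' @inheritParams extract_ss_elements
#' @return a `smotif_set` (possibly empty).
#' @export
smotif_string <- function(chain, min_helix = 4, min_strand = 3) {
  decompose(extract_ss_elements(chain, min_helix, min_strand), chain)
}

#' @export
print.smotif_set <- function(x, ...) {
  cat("smotif_set:", nrow(x), "Smotifs from",
      length(unique(x$structure_id)), "structure(s)\n")
  if (nrow(x)) {
    tb <- table(x$class)
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
    if ("bin_id" %in% names(x))
      cat("  classified under scheme",
          if (!is.null(attr(x, "scheme"))) format_scheme(attr(x, "scheme")) else "?", "\n")
  }
  invisible(x)
}

#' Combine Smotif sets
#'
#' @param ... `smotif_set` objects sharing the same columns.
#' @return a single `smotif_set`.
#' @export
bind_smotifs <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "data.frame"))
    parts <- parts[[1]]
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  if (!length(parts)) stop("no Smotifs to combine")
  schemes <- lapply(parts, attr, "scheme")
  d <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  rownames(d) <- NULL
  class(d) <- c("smotif_set", "data.frame")
  attr(d, "scheme") <- schemes[[1]]
  d
}
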