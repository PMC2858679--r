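## Chain model construction and structure/annotation I/O.
##
## The chain model is the substrate every other module works on: an ordered
## set of residues (one per author (resno, insertion) pair) carrying a CA
## coordinate and a 3-state secondary-structure label, plus the full heavy-atom
## set used by the contact and accessibility features.

STANDARD_HET <- c(MSE = "M", SEC = "U", PYL = "O", CSO = "C", HYP = "P",
                  SEP = "S", TPO = "T", PTR = "Y", MLY = "K")

#' Read a single protein chain from a PDB file or text
#'
#' Parses a PDB entry (via the `bio3d` backend) into a `chain_model`: one
#' record per residue with the CA coordinate, plus a table of all heavy atoms.
#' Alternate locations are collapsed to the highest-occupancy atom, hydrogens
#' and waters are discarded, and HETATM records are kept only for standard
#' modified residues (e.g. selenomethionine). The 3-state secondary structure
#' is initialized to coil; use [annotate_ss()] to overwrite it.
#'
#' @param input path to a PDB file, or a character scalar holding PDB text
#'   (detected by embedded newlines).
#' @param chain chain identifier. `NULL` picks the first chain in the file.
#' @param model model number for multi-model (NMR) entries, 1-based.
#' @param id structure identifier stored in the model; defaults to
#'   `<basename>_<chain>` for files and `<pdbcode>_<chain>` when a HEADER
#'   record is present.
#' @return an object of class `chain_model`: a list with elements
#'   `structure_id`, `chain`, `deposition_date` (a `Date` or `NULL`),
#'   `residues` (data frame: `seq_pos`, `resno`, `ins`, `aa`, `ss3`, `x`,
#'   `y`, `z`) and `atoms` (data frame: `res_idx`, `elety`, `element`,
#'   `x`, `y`, `z`).
#' @export
read_pdb <- function(input, chain = NULL, model = 1, id = NULL) {
  path <- .as_pdb_path(input)
  txt <- readLines(path, warn = FALSE)

  ## rm.alt=FALSE: altloc selection is occupancy-based below, not "A"-first
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atom <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models)
    stop("model ", model, " not present (file has ", n_models, ")")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]

  chains_here <- unique(atom$chain[atom$type == "ATOM"])
  if (length(chains_here) == 0) chains_here <- unique(atom$chain)
  if (is.null(chain)) chain <- chains_here[1]
  if (!chain %in% atom$chain) stop("chain not found: '", chain, "'")
  atom <- atom[atom$chain == chain, , drop = FALSE]

  keep <- atom$type == "ATOM" |
    (atom$type == "HETATM" & atom$resid %in% names(STANDARD_HET))
  atom <- atom[keep, , drop = FALSE]
  ## drop hydrogens/deuterium and waters
  atom <- atom[!(atom$elesy %in% c("H", "D")) & atom$resid != "HOH", , drop = FALSE]
  if (nrow(atom) == 0) stop("not a polypeptide chain: no heavy atoms in chain '", chain, "'")

  ## collapse altlocs: highest occupancy wins, first record breaks ties
  ins <- ifelse(is.na(atom$insert), "", atom$insert)
  akey <- paste(atom$resno, ins, atom$elety, sep = "|")
  o <- atom$o; o[is.na(o)] <- 1
  best <- tapply(seq_len(nrow(atom)), akey, function(i) i[which.max(o[i])])
  atom <- atom[sort(unlist(best)), , drop = FALSE]

  ins <- ifelse(is.na(atom$insert), "", atom$insert)
  rkey <- paste0(atom$resno, ins)
  ukey <- unique(rkey)
  ca <- atom[atom$elety == "CA", , drop = FALSE]
  ca_key <- paste0(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  ## residues must carry a CA to take part in any geometric analysis
  ukey <- ukey[ukey %in% ca_key]
  if (length(ukey) == 0) stop("not a polypeptide chain: no CA atoms in chain '", chain, "'")
  ca <- ca[match(ukey, ca_key), , drop = FALSE]

  aa1 <- bio3d::aa321(ca$resid)
  het <- ca$resid %in% names(STANDARD_HET)
  aa1[het] <- STANDARD_HET[ca$resid[het]]

  residues <- data.frame(
    seq_pos = ukey,
    resno = ca$resno,
    ins = ifelse(is.na(ca$insert), "", ca$insert),
    aa = aa1,
    ss3 = "C",
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )

  atom <- atom[rkey %in% ukey, , drop = FALSE]
  atoms <- data.frame(
    res_idx = match(paste0(atom$resno, ifelse(is.na(atom$insert), "", atom$insert)), ukey),
    elety = atom$elety,
    element = atom$elesy,
    x = atom$x, y = atom$y, z = atom$z,
    stringsAsFactors = FALSE
  )

  hdr <- grep("^HEADER", txt, value = TRUE)
  depdate <- NULL
  code <- NULL
  if (length(hdr)) {
    depdate <- .parse_pdb_date(substr(hdr[1], 51, 59))
    code <- trimws(substr(hdr[1], 63, 66))
    if (!nzchar(code)) code <- NULL
  }
  if (is.null(id)) {
    base <- if (!is.null(code)) tolower(code)
            else if (file.exists(input) || !grepl("\n", input)) sub("\\.(pdb|ent)$", "", basename(input))
            else "struct"
    id <- paste0(base, "_", chain)
  }

  structure(list(structure_id = id, chain = chain, deposition_date = depdate,
                 residues = residues, atoms = atoms),
            class = "chain_model")
}

.as_pdb_path <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) return(input)
  path <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(input, "\n", fixed = TRUE)), path)
  path
}

.parse_pdb_date <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(NULL)
  d <- tryCatch(as.Date(toupper(s), format = "%d-%b-%y"),
                error = function(e) NULL)
  if (is.null(d) || is.na(d)) return(NULL)
  ## two-digit years: PDB spans 1971+, so anything "in the future" is last century
  if (as.integer(format(d, "%Y")) > as.integer(format(Sys.Date(), "%Y")) + 1)
    d <- as.Date(format(d, "19%y-%m-%d"))
  d
}

#' @export
print.chain_model <- function(x, ...) {
  cat("chain_model:", x$structure_id, "  residues:", nrow(x$residues),
      "  atoms:", nrow(x$atoms), "\n")
  ss <- table(factor(x$residues$ss3, levels = c("H", "E", "C")))
  cat("  ss3: H=", ss["H"], " E=", ss["E"], " C=", ss["C"], "\n", sep = "")
  invisible(x)
}

#' Reduce 8-state secondary-structure codes to 3 states
#'
#' The default mapping sends the three helix states (H, G, I) to `H`, extended
#' strand (E) to `E`, and everything else -- turns, bends, isolated bridges
#' and unassigned residues -- to coil `C`. Isolated beta bridges (B) go to
#' coil because a single-residue "strand" has no extended axis. The set of
#' codes counted as helix is configurable.
#'
#' @param ss8 character vector of one-letter 8-state codes.
#' @param helix_states codes treated as helix.
#' @return character vector over `{"H","E","C"}`.
#' @export
ss8_to_ss3 <- function(ss8, helix_states = c("H", "G", "I")) {
  out <- rep("C", length(ss8))
  out[ss8 %in% helix_states] <- "H"
  out[ss8 == "E"] <- "E"
  out
}

#' Read a classic DSSP output file
#'
#' Parses the fixed-column per-residue block of classic DSSP output and
#' returns one row per residue with the 8-state code, its 3-state reduction
#' (see [ss8_to_ss3()]) and the solvent-accessibility column.
#'
#' @param input path to a DSSP file or its text content.
#' @param helix_states passed to [ss8_to_ss3()].
#' @return data frame with columns `chain`, `seq_pos`, `ss8`, `ss3`, `acc`.
#' @export
read_dssp <- function(input, helix_states = c("H", "G", "I")) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    readLines(input, warn = FALSE)
  else unlist(strsplit(input, "\n", fixed = TRUE))
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0)
    stop("malformed DSSP output: no '  #  RESIDUE' header line")
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  ## chain-break markers carry '!' in the AA column
  body <- body[substr(body, 14, 14) != "!"]
  if (length(body) == 0)
    return(data.frame(chain = character(), seq_pos = character(),
                      ss8 = character(), ss3 = character(), acc = numeric()))
  resno <- trimws(substr(body, 6, 10))
  ins <- trimws(substr(body, 11, 11))
  ch <- trimws(substr(body, 12, 12))
  ss8 <- substr(body, 17, 17)
  ss8[ss8 == " "] <- ""
  acc <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  data.frame(chain = ch, seq_pos = paste0(resno, ins), ss8 = ss8,
             ss3 = ss8_to_ss3(ss8, helix_states), acc = acc,
             stringsAsFactors = FALSE)
}

#' Read a sidecar secondary-structure annotation table
#'
#' Tab-separated file with columns `chain`, `seq_pos`, `ss` (either 8-state
#' or 3-state codes; both reduce through [ss8_to_ss3()]). This is the format
#' written by the synthetic-chain generator.
#'
#' @param path file path.
#' @inheritParams read_dssp
#' @return data frame with columns `chain`, `seq_pos`, `ss3`.
#' @export
read_ss_annotation <- function(path, helix_states = c("H", "G", "I")) {
  d <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  if (!all(c("chain", "seq_pos", "ss") %in% names(d)))
    stop("annotation file must have columns chain, seq_pos, ss")
  data.frame(chain = d$chain, seq_pos = d$seq_pos,
             ss3 = ss8_to_ss3(d$ss, helix_states), stringsAsFactors = FALSE)
}

#' Secondary structure from PDB HELIX/SHEET header records
#'
#' Expands the author-deposited HELIX and SHEET records of a PDB entry into a
#' per-residue annotation. This is a fallback assignment for runs where no
#' DSSP output is available; author assignments broadly agree with DSSP but
#' can differ at element termini.
#'
#' @inheritParams read_pdb
#' @return data frame with columns `chain`, `seq_pos`, `ss3`.
#' @export
pdb_header_ss <- function(input, chain = NULL) {
  path <- .as_pdb_path(input)
  txt <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in grep("^HELIX ", txt, value = TRUE)) {
    ch <- trimws(substr(ln, 20, 20))
    from <- suppressWarnings(as.integer(substr(ln, 22, 25)))
    to <- suppressWarnings(as.integer(substr(ln, 34, 37)))
    if (is.na(from) || is.na(to)) next
    out[[length(out) + 1]] <- data.frame(chain = ch, seq_pos = as.character(from:to),
                                         ss3 = "H", stringsAsFactors = FALSE)
  }
  for (ln in grep("^SHEET ", txt, value = TRUE)) {
    ch <- trimws(substr(ln, 22, 22))
    from <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    to <- suppressWarnings(as.integer(substr(ln, 34, 37)))
    if (is.na(from) || is.na(to)) next
    out[[length(out) + 1]] <- data.frame(chain = ch, seq_pos = as.character(from:to),
                                         ss3 = "E", stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chain = character(), seq_pos = character(), ss3 = character()))
  ann <- do.call(rbind, out)
  if (!is.null(chain)) ann <- ann[ann$chain == chain, , drop = FALSE]
  ann[!duplicated(paste(ann$chain, ann$seq_pos)), , drop = FALSE]
}

#' Overwrite secondary-structure labels of a chain model
#'
#' Only residues present in the annotation are touched; all others keep their
#' current label. Keys that match no residue are reported and ignored.
#'
#' @param chain a `chain_model`.
#' @param ann data frame with columns `seq_pos` and `ss3` (and optionally
#'   `chain`, which is filtered to the model's chain), or a named character
#'   vector `seq_pos -> ss3`.
#' @return the updated `chain_model`.
#' @export
annotate_ss <- function(chain, ann) {
  stopifnot(inherits(chain, "chain_model"))
  if (is.character(ann) && !is.null(names(ann)))
    ann <- data.frame(seq_pos = names(ann), ss3 = unname(ann), stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(chain)
  if ("chain" %in% names(ann) && any(nzchar(ann$chain)))
    ann <- ann[ann$chain == chain$chain | !nzchar(ann$chain), , drop = FALSE]
  idx <- match(ann$seq_pos, chain$residues$seq_pos)
  miss <- is.na(idx)
  if (any(miss))
    message(sum(miss), " annotation keys match no residue (ignored)")
  chain$residues$ss3[idx[!miss]] <- ann$ss3[!miss]
  bad <- !chain$residues$ss3 %in% c("H", "E", "C")
  chain$residues$ss3[bad] <- "C"
  chain
}

SMOTIF_COLUMNS <- c("structure_id", "chain", "class",
                    "ss1_start", "ss1_end", "ss1_len", "loop_len",
                    "ss2_start", "ss2_end", "ss2_len",
                    "D", "delta", "theta", "rho", "bin_id", "frequency")

#' Write a Smotif table as TSV
#'
#' One row per Smotif; geometry printed to 3 decimals; rows ordered by
#' structure then SS1 start. A commented header records the binning scheme
#' when the set has been classified.
#'
#' @param smotifs a `smotif_set` (see [decompose()]).
#' @param file destination path, or `""` to return the text.
#' @return the TSV lines, invisibly when written to a file.
#' @export
write_smotif_table <- function(smotifs, file = "") {
  d <- as.data.frame(smotifs)[, intersect(SMOTIF_COLUMNS, names(smotifs)), drop = FALSE]
  if (nrow(d)) {
    d <- d[order(d$structure_id, d$ss1_start), , drop = FALSE]
    for (cc in c("D", "delta", "theta", "rho"))
      d[[cc]] <- sprintf("%.3f", d[[cc]])
    if ("frequency" %in% names(d)) d$frequency <- sprintf("%.6g", d$frequency)
  }
  hdr <- character()
  sch <- attr(smotifs, "scheme")
  if (!is.null(sch))
    hdr <- paste0("# scheme: ", format_scheme(sch), " rho_offset ", sch$rho_offset,
                  " D_max ", sch$D_max)
  lines <- c(hdr, paste(names(d), collapse = "\t"),
             if (nrow(d)) do.call(paste, c(unname(as.list(d)), sep = "\t")))
  if (identical(file, "")) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a Smotif table written by [write_smotif_table()]
#'
#' Coordinates are not stored in the table, so the returned set supports
#' classification, library building and novelty scoring but not
#' superposition.
#'
#' @param file path to the TSV.
#' @return a `smotif_set` data frame (without CA coordinates).
#' @export
read_smotif_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  sch <- NULL
  schln <- grep("^# scheme:", lines, value = TRUE)
  if (length(schln)) {
    m <- regmatches(schln[1],
                    regexec("^# scheme: (\\S+) rho_offset (\\S+) D_max (\\S+)", schln[1]))[[1]]
    if (length(m) == 4)
      sch <- parse_scheme(m[2], rho_offset = as.numeric(m[3]), D_max = as.numeric(m[4]))
  }
  d <- utils::read.delim(text = lines, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(structure_id = "character", chain = "character"))
  class(d) <- c("smotif_set", "data.frame")
  attr(d, "scheme") <- sch
  d
}
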