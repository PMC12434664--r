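#' @useDynLib foldscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd setNames quantile median cor dist
#' @importFrom utils read.table write.table head tail
NULL

# Atom-to-group assignment for the 3-bead mapping. O3' is grouped with the
# sugar it is bonded to (C3'), never with the downstream phosphate.
.cg_groups <- list(
  P = c("P", "OP1", "OP2", "O1P", "O2P", "OP3", "O5'"),
  S = c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'", "O3'"),
  B = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
        "N2", "N4", "N6", "O2", "O4", "O6")
)

# 5'-terminal residue without a phosphate group: P bead sits at the center of
# mass of O5' plus any attached terminal hydroxyl atoms.
.cg_terminal_p <- c("O5'", "HO5'", "H5T", "OP3")

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

.rna_residues <- c("A", "U", "G", "C", "I", "ADE", "URA", "GUA", "CYT")

.norm_atom_name <- function(x) gsub("\\*", "'", trimws(x))

.one_letter <- function(resname) {
  map <- c(A = "A", U = "U", G = "G", C = "C", I = "I",
           ADE = "A", URA = "U", GUA = "G", CYT = "C")
  out <- unname(map[resname])
  out[is.na(out)] <- "N"
  out
}

#' Load one RNA chain from PDB text
#'
#' Parses fixed-column PDB text, keeps the nucleotide residues of the
#' requested chain (first alternate location only), and collects waters,
#' ligands and ions into a separate heteroatom table.
#'
#' @param pdb_text Character scalar (whole file) or character vector of lines.
#' @param chain_id Single chain identifier.
#' @param source_id Free-text provenance label stored on the object.
#' @return An object of class \code{rna_structure} with elements
#'   \code{atoms} (data.frame: name, element, residue_index, residue_name,
#'   chain_id, x, y, z), \code{het} (non-nucleotide records of the chain and
#'   all other chains' heteroatoms) and \code{source_id}. Residue indices are
#'   renumbered 1-based along the chain; the author numbering is kept in
#'   \code{atoms$resno_orig}.
#' @export
load_structure <- function(pdb_text, chain_id, source_id = "pdb") {
  if (length(pdb_text) == 1L && grepl("\n", pdb_text))
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  chains <- sort(unique(at$chain))
  if (!chain_id %in% chains)
    stop("chain '", chain_id, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain_id, , drop = FALSE]
  is_nuc <- trimws(at$resid) %in% .rna_residues & at$type == "ATOM"
  nuc <- at[is_nuc, , drop = FALSE]
  het <- at[!is_nuc, , drop = FALSE]
  if (nrow(nuc) == 0L)
    stop("chain '", chain_id, "' contains no nucleotide residues")
  key <- paste(nuc$resno, nuc$insert)
  ridx <- match(key, unique(key))
  atoms <- data.frame(
    name = .norm_atom_name(nuc$elety),
    element = ifelse(trimws(nuc$elesy) == "", substr(trimws(nuc$elety), 1, 1),
                     trimws(nuc$elesy)),
    residue_index = ridx,
    residue_name = trimws(nuc$resid),
    chain_id = nuc$chain,
    resno_orig = nuc$resno,
    x = nuc$x, y = nuc$y, z = nuc$z,
    stringsAsFactors = FALSE
  )
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(atoms = atoms, het = het, source_id = source_id),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$source_id, ": ",
      max(x$atoms$residue_index), " residues, ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Map an atomistic RNA structure to three beads per nucleotide
#'
#' Each nucleotide is reduced to three beads placed at the mass-weighted
#' centers of mass of its phosphate group (P), sugar (S) and base (B). A
#' 5'-terminal residue lacking a phosphate carries its P bead at the center
#' of mass of the O5' group so every residue contributes exactly three beads.
#'
#' @param s An \code{rna_structure}.
#' @return An object of class \code{cg_structure}: \code{xyz} (3N x 3 matrix,
#'   bead order P, S, B within each residue), \code{role}, \code{residue_index}
#'   (per bead), \code{sequence}, \code{n_residues}.
#' @export
coarse_grain <- function(s) {
  if (inherits(s, "cg_structure"))
    stop("input is already coarse-grained; coarse_grain() needs atomistic input")
  stopifnot(inherits(s, "rna_structure"))
  at <- s$atoms
  n_res <- max(at$residue_index)
  xyz <- matrix(NA_real_, nrow = 3L * n_res, ncol = 3)
  role <- rep(c("P", "S", "B"), n_res)
  residue_index <- rep(seq_len(n_res), each = 3L)
  seqv <- character(n_res)
  for (r in seq_len(n_res)) {
    ra <- at[at$residue_index == r, , drop = FALSE]
    seqv[r] <- .one_letter(ra$residue_name[1])
    for (k in 1:3) {
      grp <- c("P", "S", "B")[k]
      sel <- ra$name %in% .cg_groups[[grp]]
      if (grp == "P" && !any(ra$name == "P")) {
        sel <- ra$name %in% .cg_terminal_p   # 5' terminus
      }
      if (!any(sel)) {
        stop("residue ", r, " (", ra$residue_name[1], ") has no atoms for the ",
             grp, " group")
      }
      m <- .atomic_masses[substr(ra$element[sel], 1, 1)]
      m[is.na(m)] <- 12.011
      w <- m / sum(m)
      xyz[3L * (r - 1L) + k, ] <- c(sum(ra$x[sel] * w), sum(ra$y[sel] * w),
                                    sum(ra$z[sel] * w))
    }
  }
  structure(list(xyz = xyz, role = role, residue_index = residue_index,
                 sequence = seqv, n_residues = n_res,
                 source_id = s$source_id),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("<cg_structure> ", x$n_residues, " residues, ", nrow(x$xyz),
      " beads (P/S/B)\n", sep = "")
  invisible(x)
}

#' Bead index for a residue/role pair
#' @param residue Residue index (1-based).
#' @param role One of "P", "S", "B".
#' @export
bead_index <- function(residue, role = "P") {
  offset <- match(role, c("P", "S", "B"))
  3L * (residue - 1L) + offset
}

#' Native contact set from a coarse-grained reference structure
#'
#' All bead pairs closer than \code{cutoff} in the reference conformation and
#' at least \code{min_sep} residues apart in sequence, in deterministic
#' (i < j, lexicographic) order. This distance-cutoff contact map is the
#' basis of the fraction of native contacts Q and of the structure-based
#' contact potential.
#'
#' @param cg A \code{cg_structure} (the native reference).
#' @param cutoff Distance cutoff in Angstrom (strict \code{<}).
#' @param min_sep Minimum residue separation.
#' @return Object of class \code{native_contacts}: \code{pairs} data.frame
#'   (i, j, res_i, res_j, r_native), \code{residue_pairs} (deduplicated),
#'   \code{cutoff_used}, \code{min_sep}.
#' @export
native_contacts <- function(cg, cutoff = 7.0, min_sep = 3L) {
  stopifnot(inherits(cg, "cg_structure"), cutoff > 0)
  n <- nrow(cg$xyz)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  sep <- abs(cg$residue_index[i] - cg$residue_index[j])
  keep <- sep >= min_sep
  i <- i[keep]; j <- j[keep]
  d <- sqrt(rowSums((cg$xyz[i, , drop = FALSE] - cg$xyz[j, , drop = FALSE])^2))
  keep <- d < cutoff
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  o <- order(i, j)
  pairs <- data.frame(i = i[o], j = j[o],
                      res_i = cg$residue_index[i[o]],
                      res_j = cg$residue_index[j[o]],
                      r_native = d[o])
  rp <- unique(pairs[, c("res_i", "res_j")])
  structure(list(pairs = pairs, residue_pairs = rp,
                 cutoff_used = cutoff, min_sep = min_sep,
                 n_beads = n),
            class = "native_contacts")
}

#' @export
print.native_contacts <- function(x, ...) {
  cat("<native_contacts> ", nrow(x$pairs), " bead pairs (",
      nrow(x$residue_pairs), " residue pairs), cutoff ", x$cutoff_used,
      " A, min_sep ", x$min_sep, "\n", sep = "")
  invisible(x)
}

#' Read a base-pair / stacking annotation list
#'
#' Plain-text TSV with lines \code{pair res_i res_j [class]} for base pairs
#' (the optional class is a free-text Leontis-Westhof label, carried through
#' but never recomputed) and \code{stack res_i res_j} for stacks.
#'
#' @param path File path, or a character vector of lines via \code{text}.
#' @param text Optional character vector of lines instead of a file.
#' @param n_residues If given, indices are validated against it.
#' @return Object of class \code{annotation_list} with data.frames
#'   \code{base_pairs} (res_i, res_j, class) and \code{stacks} (res_i, res_j).
#' @export
read_annotations <- function(path = NULL, text = NULL, n_residues = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- strsplit(lines, "[ \t]+")
  bp <- list(); st <- list()
  for (t in tok) {
    kind <- tolower(t[1])
    if (kind == "pair") {
      bp[[length(bp) + 1L]] <- data.frame(
        res_i = as.integer(t[2]), res_j = as.integer(t[3]),
        class = if (length(t) >= 4) t[4] else NA_character_)
    } else if (kind == "stack") {
      st[[length(st) + 1L]] <- data.frame(res_i = as.integer(t[2]),
                                          res_j = as.integer(t[3]))
    } else stop("unknown annotation record: ", t[1])
  }
  bp <- if (length(bp)) do.call(rbind, bp) else
    data.frame(res_i = integer(), res_j = integer(), class = character())
  st <- if (length(st)) do.call(rbind, st) else
    data.frame(res_i = integer(), res_j = integer())
  ann <- structure(list(base_pairs = bp, stacks = st),
                   class = "annotation_list")
  validate_annotations(ann, n_residues)
  ann
}

#' Build an annotation list directly from residue index pairs
#' @param base_pairs two-column matrix/data.frame of residue pairs.
#' @param stacks two-column matrix/data.frame of residue pairs.
#' @param classes optional character vector of pair class labels.
#' @param n_residues optional validation bound.
#' @export
annotations <- function(base_pairs = NULL, stacks = NULL, classes = NULL,
                        n_residues = NULL) {
  mk <- function(x, cl = FALSE) {
    if (is.null(x) || NROW(x) == 0L) {
      d <- data.frame(res_i = integer(), res_j = integer())
      if (cl) d$class <- character()
      return(d)
    }
    x <- as.data.frame(x)
    d <- data.frame(res_i = as.integer(x[[1]]), res_j = as.integer(x[[2]]))
    if (cl) d$class <- if (!is.null(classes)) classes else NA_character_
    d
  }
  ann <- structure(list(base_pairs = mk(base_pairs, TRUE),
                        stacks = mk(stacks)),
                   class = "annotation_list")
  validate_annotations(ann, n_residues)
  ann
}

validate_annotations <- function(ann, n_residues = NULL) {
  all_idx <- c(ann$base_pairs$res_i, ann$base_pairs$res_j,
               ann$stacks$res_i, ann$stacks$res_j)
  if (any(all_idx < 1L)) stop("annotation residue indices must be >= 1")
  if (!is.null(n_residues) && any(all_idx > n_residues))
    stop("annotation residue index exceeds n_residues = ", n_residues)
  if (any(ann$base_pairs$res_i == ann$base_pairs$res_j) ||
      any(ann$stacks$res_i == ann$stacks$res_j))
    stop("self-pairs are not allowed in annotations")
  invisible(ann)
}

#' Write a coarse-grained structure as a PDB-like file
#'
#' One ATOM record per bead; the bead role (P/S/B) is stored in the atom-name
#' field so the file round-trips through standard viewers.
#' @param cg A \code{cg_structure}.
#' @param path Output file.
#' @export
write_cg_pdb <- function(cg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(cg$xyz))) {
    line <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      k, cg$role[k], cg$sequence[cg$residue_index[k]],
      cg$residue_index[k], cg$xyz[k, 1], cg$xyz[k, 2], cg$xyz[k, 3])
    writeLines(line, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a native contact set as TSV
#' @param nc A \code{native_contacts} object.
#' @param path Output file.
#' @export
write_contacts_tsv <- function(nc, path) {
  write.table(nc$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a native contact set written by \code{write_contacts_tsv}
#' @param path TSV file.
#' @param cutoff,min_sep metadata to attach (not re-derivable from the table).
#' @export
read_contacts_tsv <- function(path, cutoff = NA_real_, min_sep = NA_integer_) {
  pairs <- read.table(path, header = TRUE, sep = "\t")
  structure(list(pairs = pairs,
                 residue_pairs = unique(pairs[, c("res_i", "res_j")]),
                 cutoff_used = cutoff, min_sep = min_sep,
                 n_beads = max(pairs$j)),
            class = "native_contacts")
}
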