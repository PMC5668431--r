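## Minimal structural data model: Structure -> chains -> residues -> named
## non-hydrogen atoms with 3D positions. Parsing is delegated to bio3d;
## hydrogen removal, alternate-location resolution and the positional
## residue index are applied on top of its atom table.

#' Parse PDB-format text into a structure object
#'
#' Reads `ATOM` records into a chain/residue/atom hierarchy. Hydrogen and
#' deuterium atoms are discarded, alternate locations are resolved to the
#' highest-occupancy copy (first wins on ties), `HETATM` records are
#' excluded, and only the first NMR model is kept. Residues are indexed by
#' 0-based file-order position (`seq_index`); the author-assigned residue
#' number and insertion code are retained as metadata, and sequence breaks
#' (non-consecutive author numbering) are recorded per residue.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text
#'   containing at least one `ATOM` record.
#' @param structure_id Identifier stored on the returned object.
#' @return An object of class `pep_structure`: a list with `structure_id`
#'   and `chains`, a named list of chains. Each chain holds parallel
#'   vectors `aa` (one-letter code, `"X"` for non-standard), `resno`,
#'   `insert`, `continuous` (is this residue sequence-contiguous with the
#'   previous one?) and `atoms`, a list with one `xyz` matrix, atom-name
#'   and element vector per residue.
#' @seealso [read_structure()], [residue_min_distance()]
#' @export
parse_structure <- function(pdb_text, structure_id = "structure") {
  stopifnot(is.character(pdb_text))
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text

  rec <- substr(lines, 1L, 6L)
  is_coord <- rec %in% c("ATOM  ", "HETATM")
  abort_if(!any(rec == "ATOM  "), "no ATOM records found in PDB text")

  ## Validate coordinate fields before handing off to bio3d (which is
  ## lenient): columns 31-54 must hold three numbers.
  coord_lines <- lines[is_coord]
  coords <- suppressWarnings(cbind(
    as.numeric(substr(coord_lines, 31L, 38L)),
    as.numeric(substr(coord_lines, 39L, 46L)),
    as.numeric(substr(coord_lines, 47L, 54L))))
  bad <- which(!stats::complete.cases(coords))
  abort_if(length(bad) > 0L,
           "unparseable coordinate record at line %d: %s",
           which(is_coord)[bad[1]], coord_lines[bad[1]])

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]

  ## Element symbol; infer from the atom name when absent (strip leading
  ## digits, take first character, PDB convention).
  ele <- toupper(trimws(as.character(atoms$elesy)))
  missing_ele <- is.na(ele) | ele == ""
  if (any(missing_ele)) {
    nm <- sub("^[0-9]+", "", trimws(atoms$elety[missing_ele]))
    ele[missing_ele] <- toupper(substr(nm, 1L, 1L))
  }
  keep <- !(ele %in% c("H", "D"))
  atoms <- atoms[keep, , drop = FALSE]
  ele <- ele[keep]
  abort_if(nrow(atoms) == 0L, "no standard residues with non-hydrogen atoms")

  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  ## Alternate locations: per (chain, resno, insert, atom name) keep the
  ## highest-occupancy copy, first on ties; file order restored afterwards.
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(-atoms$o)                       # stable: ties keep file order
  sel <- sort(ord[!duplicated(akey[ord])])
  atoms <- atoms[sel, , drop = FALSE]
  ele <- ele[sel]

  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  chains <- list()
  for (ch in unique(atoms$chain)) {
    in_ch <- atoms$chain == ch
    ures <- unique(rkey[in_ch])                 # residue file order
    idx <- split(which(in_ch), factor(rkey[in_ch], levels = ures))
    first <- vapply(idx, `[`, integer(1), 1L)
    aa <- unname(AA_ONE[atoms$resid[first]])
    aa[is.na(aa)] <- "X"
    resno <- atoms$resno[first]
    insert <- atoms$insert[first]
    n <- length(ures)
    continuous <- c(TRUE, (resno[-1L] == resno[-n] + 1L) |
                          (resno[-1L] == resno[-n] & insert[-1L] != insert[-n]))
    res_atoms <- lapply(idx, function(i) {
      list(xyz = cbind(x = atoms$x[i], y = atoms$y[i], z = atoms$z[i]),
           names = trimws(atoms$elety[i]),
           elements = ele[i])
    })
    names(res_atoms) <- NULL
    chains[[ch]] <- list(chain_id = ch, aa = aa, resno = resno,
                         insert = insert, continuous = continuous,
                         atoms = res_atoms)
  }
  abort_if(!any(unlist(lapply(chains, `[[`, "aa")) %in% AA_ALPHABET),
           "structure contains no standard amino-acid residues")
  structure(list(structure_id = structure_id, chains = chains),
            class = "pep_structure")
}

#' Read a PDB file into a structure object
#'
#' @param path Path to a PDB-format file.
#' @param structure_id Identifier; defaults to the file name without
#'   extension.
#' @return A `pep_structure`; see [parse_structure()].
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  parse_structure(readLines(path, warn = FALSE), structure_id = structure_id)
}

#' @export
print.pep_structure <- function(x, ...) {
  nres <- vapply(x$chains, function(ch) length(ch$aa), integer(1))
  cat(sprintf("pep_structure '%s': %d chain(s), %d residue(s)\n",
              x$structure_id, length(x$chains), sum(nres)))
  for (ch in names(x$chains))
    cat(sprintf("  chain %s: %d residues\n", ch, nres[[ch]]))
  invisible(x)
}

#' Extract one residue from a structure
#'
#' @param s A `pep_structure`.
#' @param chain_id Chain identifier.
#' @param seq_index 0-based positional index of the residue within the
#'   chain.
#' @return A `pep_residue`: list with `chain_id`, `seq_index`, `aa`,
#'   `resno`, `xyz` (atom coordinate matrix), `atom_names`, `elements`.
#' @export
residue <- function(s, chain_id, seq_index) {
  stopifnot(inherits(s, "pep_structure"))
  ch <- s$chains[[chain_id]]
  abort_if(is.null(ch), "no chain '%s' in structure '%s'", chain_id,
           s$structure_id)
  i <- seq_index + 1L
  abort_if(i < 1L || i > length(ch$aa),
           "seq_index %d out of range for chain '%s' (%d residues)",
           seq_index, chain_id, length(ch$aa))
  at <- ch$atoms[[i]]
  structure(list(chain_id = chain_id, seq_index = seq_index, aa = ch$aa[i],
                 resno = ch$resno[i], xyz = at$xyz, atom_names = at$names,
                 elements = at$elements),
            class = "pep_residue")
}

#' Minimum inter-residue distance over non-hydrogen atom pairs
#'
#' The distance between two residues is the smallest Euclidean distance
#' over all pairs of their (non-hydrogen) atoms; this is the primitive the
#' 5 / 30 Angstrom binding and non-binding cutoffs are applied to.
#'
#' @param r1,r2 `pep_residue` objects (see [residue()]).
#' @return Distance in Angstrom (numeric scalar). Symmetric in its
#'   arguments.
#' @export
residue_min_distance <- function(r1, r2) {
  for (r in list(r1, r2))
    abort_if(is.null(r$xyz) || nrow(r$xyz) == 0L,
             "residue %s:%s has no atoms", r$chain_id, r$seq_index)
  a <- r1$xyz
  b <- r2$xyz
  ## |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i.b_j, minimised over pairs
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Matrix of pairwise minimum residue distances within a chain
#'
#' Computes [residue_min_distance()] for every residue pair of one chain in
#' a single vectorized pass; used internally by [extract_tuples()].
#'
#' @param s A `pep_structure`.
#' @param chain_id Chain identifier.
#' @return An n x n symmetric numeric matrix (n = residues in the chain);
#'   entries in Angstrom, zero diagonal. Residues without atoms yield `NA`
#'   rows.
#' @export
residue_distance_matrix <- function(s, chain_id) {
  stopifnot(inherits(s, "pep_structure"))
  ch <- s$chains[[chain_id]]
  abort_if(is.null(ch), "no chain '%s' in structure '%s'", chain_id,
           s$structure_id)
  n <- length(ch$atoms)
  counts <- vapply(ch$atoms, function(a) nrow(a$xyz), integer(1))
  xyz <- do.call(rbind, lapply(ch$atoms, `[[`, "xyz"))
  ridx <- rep.int(seq_len(n), counts)
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  ## two-stage block-min: atoms x atoms -> residues x atoms -> residues^2
  m1 <- matrix(NA_real_, n, length(ridx))
  for (i in seq_len(n)) {
    rows <- which(ridx == i)
    m1[i, ] <- if (length(rows) == 1L) d2[rows, ] else
      do.call(pmin, lapply(rows, function(r) d2[r, ]))
  }
  out <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    cols <- which(ridx == j)
    out[, j] <- if (length(cols) == 1L) m1[, cols] else
      do.call(pmin, lapply(cols, function(cc) m1[, cc]))
  }
  sqrt(out)
}
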