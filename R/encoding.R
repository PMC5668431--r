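## 20-bit one-hot sequence encoding: each residue becomes a 20-bit
## indicator in the alphabetical one-letter order (alanine bit 1, tyrosine
## bit 20); a tuple of `arity` fragments of length L becomes a binary
## vector of arity * L * 20 entries with exactly arity * L ones.

#' One-hot encode a single residue
#'
#' @param aa One-letter amino-acid code (one of the 20 standard letters).
#' @return Integer vector of length 20 with a single 1 at the alphabetical
#'   rank of `aa` (`A` -> position 1, `Y` -> position 20).
#' @export
encode_residue <- function(aa) {
  i <- match(aa, AA_ALPHABET)
  abort_if(length(aa) != 1L || is.na(i),
           "cannot one-hot encode non-standard residue '%s'", paste(aa)[1])
  v <- integer(20L)
  v[i] <- 1L
  v
}

#' One-hot encode a single tuple record
#'
#' Fragments are concatenated in ascending start order, residues in
#' sequence order, each residue as its 20-bit indicator.
#'
#' @param t One tuple record (one-row data.frame or list with `arity`,
#'   `length`, `seq1..seq3`).
#' @return Integer vector of length `arity * length * 20` with
#'   `arity * length` ones.
#' @export
encode_tuple <- function(t) {
  if (is.data.frame(t)) {
    abort_if(nrow(t) != 1L, "encode_tuple takes a single tuple record")
    t <- as.list(t)
  }
  arity <- t$arity
  seqs <- unlist(t[paste0("seq", seq_len(arity))], use.names = FALSE)
  letters1 <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  idx <- match(letters1, AA_ALPHABET)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    frag <- (p - 1L) %/% t$length + 1L
    stop(sprintf("non-standard residue '%s' in fragment %d position %d",
                 letters1[p], frag, (p - 1L) %% t$length + 1L), call. = FALSE)
  }
  v <- integer(length(idx) * 20L)
  v[(seq_along(idx) - 1L) * 20L + idx] <- 1L
  v
}

#' One-hot encode a set of tuple records into a labeled dataset
#'
#' @param tuples Tuple record data.frame (single arity and length).
#' @return List of class `encoded_dataset`: `x` (n x arity*L*20 binary
#'   matrix), `y` (integer labels, 1 binding / 0 non-binding), `id`
#'   (character row identifiers), `arity`, `length`.
#' @export
encode_tuples <- function(tuples) {
  stopifnot(is.data.frame(tuples), nrow(tuples) > 0L)
  abort_if(length(unique(tuples$arity)) != 1L ||
             length(unique(tuples$length)) != 1L,
           "encode_tuples needs a single arity and fragment length")
  arity <- tuples$arity[1]; L <- tuples$length[1]
  seqs <- do.call(paste0, tuples[paste0("seq", seq_len(arity))])
  letters_m <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE),
                            AA_ALPHABET),
                      nrow = nrow(tuples), ncol = arity * L, byrow = TRUE)
  if (anyNA(letters_m))
    stop("non-standard residue in tuple ",
         which(rowSums(is.na(letters_m)) > 0)[1], call. = FALSE)
  d <- arity * L * 20L
  x <- matrix(0L, nrow(tuples), d)
  pos_offset <- (col(letters_m) - 1L) * 20L
  x[cbind(as.vector(row(letters_m)),
          as.vector(pos_offset + letters_m))] <- 1L
  id <- paste(tuples$structure_id, tuples$chain_id, tuples$start1,
              tuples$start2,
              ifelse(is.na(tuples$start3), "", tuples$start3), sep = ":")
  structure(list(x = x, y = as.integer(tuples$label), id = id,
                 arity = arity, length = L),
            class = "encoded_dataset")
}

#' Decode a one-hot vector back into fragment sequences
#'
#' Inverse of [encode_tuple()]; used for round-trip checks.
#'
#' @param v Binary vector of length `arity * length * 20`.
#' @param arity Number of fragments.
#' @param length Fragment length.
#' @return Character vector of `arity` fragment sequences.
#' @export
decode_sample <- function(v, arity, length) {
  abort_if(base::length(v) != arity * length * 20L,
           "vector length %d does not match arity %d x length %d x 20",
           base::length(v), arity, length)
  m <- matrix(v, ncol = 20L, byrow = TRUE)
  abort_if(any(rowSums(m) != 1L), "not a valid one-hot encoding")
  letters1 <- AA_ALPHABET[max.col(m)]
  vapply(seq_len(arity), function(k)
    paste(letters1[((k - 1) * length + 1):(k * length)], collapse = ""), "")
}

#' Write an encoded dataset as a plain-text matrix dump
#'
#' Space-separated 0/1 entries, one sample per line, with the label as the
#' final column; round-trips bit-exactly through [read_encoded()].
#'
#' @param ds An `encoded_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(ds, path) {
  stopifnot(inherits(ds, "encoded_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# arity=%d length=%d n=%d", ds$arity, ds$length,
                     nrow(ds$x)), con)
  utils::write.table(cbind(ds$x, label = ds$y), con, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an encoded dataset written by [write_encoded()]
#'
#' @param path Input path.
#' @param arity,length Tuple shape (echoed in the file header).
#' @return An `encoded_dataset` (without row identifiers).
#' @export
read_encoded <- function(path, arity, length) {
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  structure(list(x = m[, -ncol(m), drop = FALSE],
                 y = as.integer(m[, ncol(m)]),
                 id = NULL, arity = arity, length = length),
            class = "encoded_dataset")
}
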