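## Enumeration and distance-based labeling of peptide duos and triads.
##
## A tuple of 2 or 3 same-length, non-overlapping fragments from one chain
## is BINDING when every pairwise center-residue minimum distance is below
## the binding cutoff (5 Angstrom), NONBINDING when every one exceeds the
## non-binding cutoff (30 Angstrom), and NEITHER otherwise. Tuples are
## represented as data.frame records: structure_id, arity, chain_id,
## start1..start3 (0-based), length, seq1..seq3, label (1 binding /
## 0 non-binding).

#' Extraction configuration
#'
#' @param fragment_length Residues per fragment (all fragments of a tuple
#'   share it).
#' @param bind_cutoff Binding distance cutoff in Angstrom; default 5.0.
#' @param nonbind_cutoff Non-binding cutoff in Angstrom; default 30.
#' @param dedup_window Two same-label tuples whose fragment starts all
#'   differ by less than this many residues are considered duplicates;
#'   default 9.
#' @param min_center_separation Minimum sequence separation between
#'   fragment center positions for a pair to be considered at all; default
#'   10. Closer pairs are classified `NEITHER`.
#' @param exclude_duos_in_triads Drop duos whose two fragments both belong
#'   to some binding triad of the same structure (a binding triad is three
#'   binding duos); default `TRUE`.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(fragment_length = 7, bind_cutoff = 5.0,
                              nonbind_cutoff = 30.0, dedup_window = 9L,
                              min_center_separation = 10L,
                              exclude_duos_in_triads = TRUE) {
  abort_if(fragment_length < 1, "fragment_length must be >= 1")
  abort_if(bind_cutoff <= 0 || nonbind_cutoff <= 0,
           "distance cutoffs must be positive")
  abort_if(bind_cutoff >= nonbind_cutoff,
           "bind_cutoff must be smaller than nonbind_cutoff")
  abort_if(dedup_window < 1 || min_center_separation < 1,
           "dedup_window and min_center_separation must be >= 1")
  structure(list(fragment_length = as.integer(fragment_length),
                 bind_cutoff = bind_cutoff, nonbind_cutoff = nonbind_cutoff,
                 dedup_window = as.integer(dedup_window),
                 min_center_separation = as.integer(min_center_separation),
                 exclude_duos_in_triads = isTRUE(exclude_duos_in_triads)),
            class = "extraction_config")
}

#' Center residue indices of a fragment
#'
#' Odd-length fragments have one center residue; even-length fragments have
#' two, whose distances are averaged.
#'
#' @param length Fragment length (>= 1).
#' @return Integer vector of 1 or 2 fragment-local 0-based indices.
#' @export
center_indices <- function(length) {
  abort_if(length < 1, "fragment length must be >= 1, got %s", length)
  length <- as.integer(length)
  if (length %% 2L == 1L) length %/% 2L else c(length %/% 2L - 1L, length %/% 2L)
}

## fractional center position along the sequence, used for the
## min_center_separation precondition
center_position <- function(start, length) start + (length - 1) / 2

as_fragment <- function(f) {
  if (is.data.frame(f)) f <- as.list(f[1L, ])
  abort_if(!all(c("chain_id", "start", "length") %in% names(f)),
           "a fragment needs chain_id, start and length")
  f
}

#' Distance between two fragments (average over center-residue pairs)
#'
#' For two odd-length fragments this is the minimum distance between their
#' center residues; when either fragment has even length, the arithmetic
#' mean of [residue_min_distance()] over all center-residue pairs (2, 2 or
#' 4 of them) is used.
#'
#' @param f1,f2 Fragments: lists or one-row data.frames with `chain_id`,
#'   `start` (0-based) and `length`.
#' @param s The `pep_structure` the fragments belong to.
#' @return Distance in Angstrom.
#' @export
fragment_distance <- function(f1, f2, s) {
  f1 <- as_fragment(f1); f2 <- as_fragment(f2)
  c1 <- f1$start + center_indices(f1$length)
  c2 <- f2$start + center_indices(f2$length)
  d <- outer(c1, c2, Vectorize(function(i, j)
    residue_min_distance(residue(s, f1$chain_id, i), residue(s, f2$chain_id, j))))
  mean(d)
}

#' Enumerate candidate fragments of a structure
#'
#' All sliding windows (step 1, per chain) of the requested length whose
#' residues are all standard amino acids and sequence-contiguous (chain
#' breaks interrupt enumeration).
#'
#' @param s A `pep_structure`.
#' @param length Fragment length.
#' @return data.frame with columns `chain_id`, `start` (0-based), `length`,
#'   `sequence`; zero rows when no window qualifies.
#' @export
enumerate_fragments <- function(s, length) {
  stopifnot(inherits(s, "pep_structure"))
  abort_if(length < 1, "fragment length must be >= 1")
  L <- as.integer(length)
  out <- lapply(s$chains, function(ch) {
    n <- base::length(ch$aa)
    if (n < L) return(NULL)
    std <- ch$aa %in% AA_ALPHABET
    ## window ok iff all L residues standard and the L-1 interior steps
    ## contiguous
    ok_std <- diff(c(0, cumsum(std)), lag = L) == L
    steps <- c(ch$continuous[-1L], TRUE)        # steps[i]: i -> i+1 contiguous
    ok_cont <- if (L == 1L) rep(TRUE, n - L + 1L) else
      diff(c(0, cumsum(steps)), lag = L - 1L)[seq_len(n - L + 1L)] == L - 1L
    starts <- which(ok_std & ok_cont) - 1L
    if (base::length(starts) == 0L) return(NULL)
    data.frame(chain_id = ch$chain_id, start = starts, length = L,
               sequence = vapply(starts, function(st)
                 paste(ch$aa[(st + 1L):(st + L)], collapse = ""), ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chain_id = character(), start = integer(),
                      length = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify one fragment tuple as binding, non-binding or neither
#'
#' @param fragments data.frame of 2 or 3 fragment rows (`chain_id`,
#'   `start`, `length`), pairwise non-overlapping with center positions at
#'   least `cfg$min_center_separation` residues apart.
#' @param s The `pep_structure`.
#' @param cfg An [extraction_config()].
#' @return `"BINDING"`, `"NONBINDING"` or `"NEITHER"`.
#' @export
classify_tuple <- function(fragments, s, cfg = extraction_config()) {
  stopifnot(is.data.frame(fragments))
  k <- nrow(fragments)
  abort_if(!k %in% 2:3, "a tuple has 2 or 3 fragments, got %d", k)
  pairs <- utils::combn(k, 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    same_chain <- fragments$chain_id[i] == fragments$chain_id[j]
    if (same_chain) {
      abort_if(abs(fragments$start[i] - fragments$start[j]) <
                 max(fragments$length[i], fragments$length[j]),
               "fragments %d and %d overlap", i, j)
      sep <- abs(center_position(fragments$start[i], fragments$length[i]) -
                 center_position(fragments$start[j], fragments$length[j]))
      abort_if(sep < cfg$min_center_separation,
               "fragments %d and %d have center separation %.1f < %d",
               i, j, sep, cfg$min_center_separation)
    }
  }
  d <- apply(pairs, 2, function(p)
    fragment_distance(fragments[p[1], ], fragments[p[2], ], s))
  if (all(d < cfg$bind_cutoff)) "BINDING"
  else if (all(d > cfg$nonbind_cutoff)) "NONBINDING"
  else "NEITHER"
}

## fragment-by-fragment pairwise distance matrix from the residue-level
## matrix; centers is a matrix with one row per fragment (1 or 2 columns of
## 1-based residue indices)
fragment_distance_matrix <- function(D, centers) {
  k <- ncol(centers)
  acc <- 0
  for (a in seq_len(k)) for (b in seq_len(k))
    acc <- acc + D[centers[, a], centers[, b], drop = FALSE]
  acc / (k * k)
}

#' Extract all binding and non-binding tuples of a structure
#'
#' Enumerates fragments ([enumerate_fragments()]), forms all intra-chain
#' combinations of `arity` fragments whose center positions are pairwise at
#' least `cfg$min_center_separation` residues apart, labels each
#' combination by the distance cutoffs, deduplicates
#' ([deduplicate_tuples()]), and (for duos, when
#' `cfg$exclude_duos_in_triads`) removes duos contained in any binding
#' triad of the same structure.
#'
#' @param s A `pep_structure`.
#' @param arity 2 (duos) or 3 (triads).
#' @param cfg An [extraction_config()].
#' @return Tuple record data.frame: `structure_id`, `arity`, `chain_id`,
#'   `start1..start3` (0-based, ascending; `start3` `NA` for duos),
#'   `length`, `seq1..seq3`, `label` (1 binding, 0 non-binding).
#' @export
extract_tuples <- function(s, arity = 3, cfg = extraction_config()) {
  stopifnot(inherits(s, "pep_structure"))
  abort_if(!arity %in% 2:3, "arity must be 2 or 3")
  L <- cfg$fragment_length
  res <- list()
  for (ch in names(s$chains)) {
    fr <- enumerate_fragments(s, L)
    fr <- fr[fr$chain_id == ch, , drop = FALSE]
    nf <- nrow(fr)
    if (nf < arity) next
    D <- residue_distance_matrix(s, ch)
    centers <- outer(fr$start, center_indices(L), `+`) + 1L
    FD <- fragment_distance_matrix(D, centers)
    cpos <- center_position(fr$start, L)
    sep_ok <- abs(outer(cpos, cpos, `-`)) >= cfg$min_center_separation &
      abs(outer(fr$start, fr$start, `-`)) >= L
    close_m <- sep_ok & FD < cfg$bind_cutoff
    far_m <- sep_ok & FD > cfg$nonbind_cutoff

    idx <- utils::combn(nf, arity)
    pr <- utils::combn(arity, 2)
    all_close <- rep(TRUE, ncol(idx)); all_far <- rep(TRUE, ncol(idx))
    for (p in seq_len(ncol(pr))) {
      ii <- cbind(idx[pr[1, p], ], idx[pr[2, p], ])
      all_close <- all_close & close_m[ii]
      all_far <- all_far & far_m[ii]
    }
    keep <- which(all_close | all_far)
    if (length(keep) == 0L) next
    sel <- idx[, keep, drop = FALSE]
    starts <- matrix(fr$start[sel], nrow = arity)
    seqs <- matrix(fr$sequence[sel], nrow = arity)
    rec <- data.frame(structure_id = s$structure_id, arity = arity,
                      chain_id = ch, start1 = starts[1, ], start2 = starts[2, ],
                      start3 = if (arity == 3) starts[3, ] else NA_integer_,
                      length = L, seq1 = seqs[1, ], seq2 = seqs[2, ],
                      seq3 = if (arity == 3) seqs[3, ] else NA_character_,
                      label = as.integer(all_close[keep]),
                      stringsAsFactors = FALSE)
    res[[ch]] <- rec
  }
  out <- if (length(res)) do.call(rbind, res) else empty_tuples(arity, L)
  rownames(out) <- NULL
  out <- deduplicate_tuples(out, cfg$dedup_window)
  if (arity == 2 && cfg$exclude_duos_in_triads && nrow(out) > 0L) {
    bpt <- extract_tuples(s, 3L, within_cfg_no_exclude(cfg))
    bpt <- bpt[bpt$label == 1L, , drop = FALSE]
    if (nrow(bpt) > 0L) {
      pair_keys <- c(
        paste(bpt$chain_id, bpt$start1, bpt$start2),
        paste(bpt$chain_id, bpt$start1, bpt$start3),
        paste(bpt$chain_id, bpt$start2, bpt$start3))
      out <- out[!(paste(out$chain_id, out$start1, out$start2) %in% pair_keys), ,
                 drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

within_cfg_no_exclude <- function(cfg) {
  cfg$exclude_duos_in_triads <- FALSE
  cfg
}

empty_tuples <- function(arity, L) {
  data.frame(structure_id = character(), arity = integer(),
             chain_id = character(), start1 = integer(), start2 = integer(),
             start3 = integer(), length = integer(), seq1 = character(),
             seq2 = character(), seq3 = character(), label = integer(),
             stringsAsFactors = FALSE)
}

#' Remove near-duplicate tuples
#'
#' Greedy first-kept scan in row order: a tuple is dropped when some
#' already-kept tuple of the same structure, chain and label has, fragment
#' by fragment (fragments sorted by start), all start offsets smaller than
#' `window` residues.
#'
#' @param tuples Tuple record data.frame (one arity).
#' @param window Dedup window in residues; default 9.
#' @return The kept rows, input order preserved.
#' @export
deduplicate_tuples <- function(tuples, window = 9L) {
  stopifnot(is.data.frame(tuples))
  if (nrow(tuples) <= 1L) return(tuples)
  abort_if(length(unique(tuples$arity)) > 1L,
           "deduplicate_tuples needs tuples of a single arity")
  arity <- tuples$arity[1]
  m <- as.matrix(tuples[, paste0("start", seq_len(arity)), drop = FALSE])
  grp <- paste(tuples$structure_id, tuples$chain_id, tuples$label)
  keep <- logical(nrow(tuples))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    kept <- integer(0)
    for (r in rows) {
      if (length(kept)) {
        dmax <- abs(m[kept, 1] - m[r, 1])
        for (cc in seq_len(arity)[-1])
          dmax <- pmax(dmax, abs(m[kept, cc] - m[r, cc]))
        if (any(dmax < window)) next
      }
      kept <- c(kept, r)
    }
    keep[kept] <- TRUE
  }
  out <- tuples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count candidate triads available to a chain
#'
#' A chain of `n_residues` residues at a minimum separation of
#' `chunk_separation` residues offers roughly
#' `floor(n_residues / chunk_separation)` independent chunks; the number of
#' unordered 3-chunk combinations bounds the triad search space (a
#' 150-residue protein at separation 10 gives choose(15, 3) = 455).
#'
#' @param n_residues Chain length in residues.
#' @param chunk_separation Minimum residue separation between fragments.
#' @return Integer count (0 when fewer than 3 chunks).
#' @export
count_candidate_triads <- function(n_residues, chunk_separation = 10L) {
  abort_if(n_residues < 1 || chunk_separation < 1,
           "n_residues and chunk_separation must be >= 1")
  as.integer(round(choose(n_residues %/% chunk_separation, 3)))
}

#' Write tuple records to a tab-delimited file
#'
#' One record per line; `#`-prefixed comment lines carry the column names'
#' provenance and an echo of the extraction configuration.
#'
#' @param tuples Tuple record data.frame.
#' @param path Output path.
#' @param cfg Optional [extraction_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_tuples <- function(tuples, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(sprintf("# %s = %s", names(unclass(cfg)),
                       vapply(unclass(cfg), format, "")), con)
  writeLines(paste0("# columns: ", paste(names(tuples), collapse = "\t")), con)
  utils::write.table(tuples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read tuple records written by [write_tuples()]
#'
#' @param path Input path.
#' @return Tuple record data.frame.
#' @export
read_tuples <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
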