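## Seeded generators for every input the pipeline needs: toy PDB
## coordinate files with planted binding tuples over an otherwise extended
## backbone, and balanced labeled sequence datasets in which binding tuples
## follow a configurable class-pairing rule corrupted at a noise rate.

#' Specification of a toy coordinate file
#'
#' @param chain_lengths Integer vector: residues per chain.
#' @param contacts List of planted tuples, each a list with `chain` (index
#'   into `chain_lengths`), `starts` (0-based fragment starts, 2 or 3 of
#'   them), `length` (fragment length) and `distance` (target pairwise
#'   center distance in Angstrom).
#' @param spacing Backbone spacing in Angstrom between consecutive residue
#'   centers; default 3.8.
#' @param seed Integer seed (residue identities are random).
#' @return List of class `geometry_spec`.
#' @export
geometry_spec <- function(chain_lengths = 60L, contacts = list(),
                          spacing = 3.8, seed = 1L) {
  abort_if(any(chain_lengths < 1), "chain lengths must be positive")
  abort_if(spacing <= 0, "spacing must be positive")
  used <- lapply(seq_along(chain_lengths), function(i) integer(0))
  for (ct in contacts) {
    abort_if(!all(c("chain", "starts", "length", "distance") %in% names(ct)),
             "each contact needs chain, starts, length, distance")
    abort_if(!length(ct$starts) %in% 2:3, "a contact has 2 or 3 fragments")
    abort_if(ct$distance <= 0, "planted distance must be positive")
    n <- chain_lengths[ct$chain]
    abort_if(any(ct$starts < 0) || any(ct$starts + ct$length > n),
             "contact starts out of range for chain of %d residues", n)
    res <- unlist(lapply(sort(ct$starts), function(s) s + seq_len(ct$length)))
    abort_if(anyDuplicated(res) > 0,
             "contact fragments overlap (starts %s, length %d)",
             paste(ct$starts, collapse = ","), ct$length)
    abort_if(length(intersect(res, used[[ct$chain]])) > 0,
             "contacts share residues on chain %d", ct$chain)
    used[[ct$chain]] <- c(used[[ct$chain]], res)
  }
  structure(list(chain_lengths = as.integer(chain_lengths),
                 contacts = contacts, spacing = spacing,
                 seed = as.integer(seed)),
            class = "geometry_spec")
}

## Atoms of one residue: N, CA, C placed along the local x axis so that the
## y-z cluster geometry sets inter-fragment minimum distances exactly.
RES_ATOM_NAMES <- c("N", "CA", "C")
RES_ATOM_X <- c(-1.2, 0, 1.2)
RES_ATOM_ELE <- c("N", "C", "C")

## How far non-center residues bow away from the contact point, per residue
## of distance from the fragment center (Angstrom). Keeps any fragment
## window shifted off the planted one well clear of the binding cutoff.
CLUSTER_BOW <- 2.0

## Residue center positions of one planted fragment: centers sit on a
## circle of radius r around the cluster origin along direction v (y-z
## plane); residues run along x and bow outward along v.
cluster_fragment_positions <- function(origin, v, r, L, spacing) {
  i <- seq_len(L) - 1
  c0 <- (L - 1) / 2
  t(vapply(i, function(ii)
    origin + (r + abs(ii - c0) * CLUSTER_BOW) * v +
      c((ii - c0) * spacing, 0, 0),
    numeric(3)))
}

## Minimum atom distance between two residues whose atoms lie at
## RES_ATOM_X offsets along x around the given centers.
min_res_dist_xatoms <- function(p1, p2) {
  gap <- max(0, abs(p2[1] - p1[1]) - 2 * max(RES_ATOM_X))
  sqrt(gap^2 + (p2[2] - p1[2])^2 + (p2[3] - p1[3])^2)
}

## Circle radius r realizing a target mean center-residue distance d
## (averaged over center pairs for even fragment lengths).
solve_cluster_radius <- function(d, L, spacing, v1, v2) {
  cents <- center_indices(L) + 1L
  f <- function(r) {
    pa <- cluster_fragment_positions(c(0, 0, 0), v1, r, L, spacing)
    pb <- cluster_fragment_positions(c(0, 0, 0), v2, r, L, spacing)
    mean(outer(cents, cents, Vectorize(function(a, b)
      min_res_dist_xatoms(pa[a, ], pb[b, ])))) - d
  }
  abort_if(f(1e-3) >= 0,
           "planted distance %.2f infeasible for length %d at spacing %.2f",
           d, L, spacing)
  stats::uniroot(f, c(1e-3, 2 * d), tol = 1e-12)$root
}

#' Write a toy structure with planted binding tuples as PDB text
#'
#' Residues sit on an extended backbone (`spacing` Angstrom apart along x,
#' chains stacked far apart in z), so any two fragments at the minimum
#' center separation are > 30 Angstrom apart. Each planted contact
#' relocates its fragments to an off-axis cluster where all pairwise
#' center-residue minimum distances equal the target distance (exactly for
#' odd fragment lengths; solved numerically for even lengths, where the
#' two center residues are averaged). Each residue carries three named
#' heavy atoms (N, CA, C); no hydrogens are written and no physical realism
#' is claimed.
#'
#' @param spec A [geometry_spec()].
#' @return Character scalar of PDB-format text (parseable by
#'   [parse_structure()]).
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  sp <- spec$spacing
  nchain <- length(spec$chain_lengths)
  abort_if(nchain > 26L, "at most 26 chains supported")
  seqs <- with_seed(spec$seed, lapply(spec$chain_lengths, function(n)
    sample(AA_ALPHABET, n, replace = TRUE)))
  ## residue center positions: extended baseline
  centers <- lapply(seq_len(nchain), function(ci) {
    n <- spec$chain_lengths[ci]
    cbind((seq_len(n) - 1L) * sp, 0, (ci - 1L) * 600)
  })
  ## relocate planted fragments into off-axis clusters: fragment centers
  ## meet around the cluster origin at the target distance, the remaining
  ## residues bow outward so no shifted window reproduces the contact
  for (k in seq_along(spec$contacts)) {
    ct <- spec$contacts[[k]]
    L <- ct$length
    starts <- sort(ct$starts)
    angles <- if (length(starts) == 3L) c(90, 210, 330) * pi / 180 else
      c(90, 270) * pi / 180
    dirs <- lapply(angles, function(a) c(0, cos(a), sin(a)))
    r <- solve_cluster_radius(ct$distance, L, sp, dirs[[1]], dirs[[2]])
    origin <- c(center_position(starts[1], L) * sp, 150 * k,
                (ct$chain - 1L) * 600)
    for (j in seq_along(starts)) {
      rows <- starts[j] + seq_len(L)
      centers[[ct$chain]][rows, ] <-
        cluster_fragment_positions(origin, dirs[[j]], r, L, sp)
    }
  }
  lines <- character(0)
  serial <- 0L
  for (ci in seq_len(nchain)) {
    ch_id <- LETTERS[ci]
    for (ri in seq_len(spec$chain_lengths[ci])) {
      resn <- AA_THREE[[seqs[[ci]][ri]]]
      for (ai in seq_along(RES_ATOM_NAMES)) {
        serial <- serial + 1L
        pos <- centers[[ci]][ri, ] + c(RES_ATOM_X[ai], 0, 0)
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, RES_ATOM_NAMES[ai], resn, ch_id, ri, pos[1], pos[2],
          pos[3], 1, 0, RES_ATOM_ELE[ai]))
      }
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Serialize a parsed structure back to PDB text
#'
#' Round-trip counterpart of [parse_structure()] for synthetic structures;
#' non-standard residues are written as `UNK`.
#'
#' @param s A `pep_structure`.
#' @return Character scalar of PDB-format text.
#' @export
write_pdb <- function(s) {
  stopifnot(inherits(s, "pep_structure"))
  lines <- character(0)
  serial <- 0L
  for (ch in s$chains) {
    for (ri in seq_along(ch$aa)) {
      resn <- if (ch$aa[ri] %in% AA_ALPHABET) AA_THREE[[ch$aa[ri]]] else "UNK"
      at <- ch$atoms[[ri]]
      for (ai in seq_along(at$names)) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, at$names[ai], resn, ch$chain_id, ch$resno[ri],
          at$xyz[ai, 1], at$xyz[ai, 2], at$xyz[ai, 3], 1, 0,
          at$elements[ai]))
      }
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Default residue classes used by the implanted pairing rule
#'
#' A 3-way hydrophobic / charged / polar partition of the 20 standard
#' amino acids.
#'
#' @return Named list of three character vectors partitioning the alphabet.
#' @export
default_residue_classes <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
       charged = c("D", "E", "K", "R", "H"),
       polar = c("S", "T", "N", "Q", "Y", "G", "P"))
}

#' Specification of an implanted-pattern sequence dataset
#'
#' Binding tuples obey a class-pairing rule on the central `signal_width`
#' residues of each fragment: the class of fragment 1's residue at signal
#' position p dictates (through one permutation per partner fragment) the
#' class of each partner's residue at the same position. The rule is
#' combination-dependent — partner classes must *match* fragment 1, so no
#' per-position additive score separates the classes — which is what makes
#' the contrast between the full network and the linear model meaningful.
#'
#' @param length Fragment length L; default 7.
#' @param arity 2 or 3; default 3.
#' @param n_binding,n_nonbinding Samples per class; default 10000 each
#'   (a balanced 20,000-sample dataset).
#' @param noise Corruption rate in `[0, 1]`: with probability `noise` a
#'   binding tuple's partner signal residues are drawn uniformly instead of
#'   from the rule.
#' @param signal_width Number of rule-carrying central positions per
#'   fragment (same parity as `length`); default 3.
#' @param classes Partition of the alphabet; default
#'   [default_residue_classes()].
#' @param rules List of `arity - 1` permutations of the class indices (one
#'   per partner fragment); the default cycles the classes.
#' @param seed Integer seed.
#' @return List of class `pattern_spec`.
#' @export
pattern_spec <- function(length = 7L, arity = 3L, n_binding = 10000L,
                         n_nonbinding = n_binding, noise = 0,
                         signal_width = 3L,
                         classes = default_residue_classes(),
                         rules = NULL, seed = 1L) {
  abort_if(!arity %in% 2:3, "arity must be 2 or 3")
  abort_if(noise < 0 || noise > 1, "noise must be in [0, 1]")
  abort_if(signal_width < 1 || signal_width > length ||
             (length - signal_width) %% 2L != 0L,
           "signal_width must be 1..L with the parity of L")
  abort_if(!setequal(unlist(classes), AA_ALPHABET) ||
             anyDuplicated(unlist(classes)) > 0,
           "classes must partition the 20-letter alphabet")
  k <- base::length(classes)
  if (is.null(rules))
    rules <- lapply(seq_len(arity - 1L), function(j)
      c((seq_len(k) + j - 1L) %% k + 1L))
  abort_if(base::length(rules) != arity - 1L,
           "need one rule per partner fragment (%d)", arity - 1L)
  for (r in rules)
    abort_if(!setequal(r, seq_len(k)),
             "each rule must be a permutation covering all %d classes", k)
  structure(list(length = as.integer(length), arity = as.integer(arity),
                 n_binding = as.integer(n_binding),
                 n_nonbinding = as.integer(n_nonbinding), noise = noise,
                 signal_width = as.integer(signal_width), classes = classes,
                 rules = rules, seed = as.integer(seed)),
            class = "pattern_spec")
}

## signal positions (1-based within a fragment)
signal_positions <- function(spec) {
  first <- (spec$length - spec$signal_width) %/% 2L + 1L
  first:(first + spec$signal_width - 1L)
}

class_of_letter <- function(classes) {
  out <- integer(20L)
  for (k in seq_along(classes)) out[match(classes[[k]], AA_ALPHABET)] <- k
  stats::setNames(out, AA_ALPHABET)
}

## vectorized: one uniform letter from class cls[i] for each i
sample_from_classes <- function(cls, classes) {
  out <- character(length(cls))
  for (k in seq_along(classes)) {
    i <- which(cls == k)
    if (length(i))
      out[i] <- sample(classes[[k]], length(i), replace = TRUE)
  }
  out
}

#' Simulate a labeled implanted-pattern tuple dataset
#'
#' Binding tuples follow the pairing rule of the [pattern_spec()] with
#' probability `1 - noise` (otherwise the partner signal residues are drawn
#' uniformly); non-binding tuples draw their partner signal residues from
#' the same marginal distribution but independently of fragment 1, so the
#' two classes have matching amino-acid composition and differ only in the
#' fragment combination. All non-signal residues are uniform. Classes are
#' exactly as large as requested.
#'
#' @param spec A [pattern_spec()].
#' @return Tuple record data.frame (`n_binding + n_nonbinding` rows) in the
#'   format of [extract_tuples()]; binding rows first.
#' @export
simulate_pattern_dataset <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  L <- spec$length; arity <- spec$arity
  sig <- signal_positions(spec)
  cls_of <- class_of_letter(spec$classes)
  with_seed(spec$seed, {
    gen <- function(n, binding) {
      frags <- lapply(seq_len(arity), function(k)
        matrix(sample(AA_ALPHABET, n * L, replace = TRUE), n, L))
      destroyed <- stats::runif(n) < spec$noise
      for (k in seq_len(arity - 1L)) {
        rule <- spec$rules[[k]]
        for (p in sig) {
          driver_cls <- if (binding) cls_of[frags[[1L]][, p]] else
            cls_of[sample(AA_ALPHABET, n, replace = TRUE)]
          want <- rule[driver_cls]
          keep_rule <- !destroyed
          if (any(keep_rule))
            frags[[k + 1L]][keep_rule, p] <-
              sample_from_classes(want[keep_rule], spec$classes)
          ## destroyed tuples keep their uniform draw
        }
      }
      frags
    }
    fb <- gen(spec$n_binding, binding = TRUE)
    fn <- gen(spec$n_nonbinding, binding = FALSE)
    seq_of <- function(m) apply(m, 1L, paste, collapse = "")
    starts <- (seq_len(arity) - 1L) * (L + 13L)
    mk <- function(frags, n, label, tag) if (n == 0L) NULL else data.frame(
      structure_id = sprintf("SIM-%s-%06d", tag, seq_len(n)),
      arity = arity, chain_id = "A",
      start1 = starts[1], start2 = starts[2],
      start3 = if (arity == 3L) starts[3] else NA_integer_,
      length = L,
      seq1 = seq_of(frags[[1]]), seq2 = seq_of(frags[[2]]),
      seq3 = if (arity == 3L) seq_of(frags[[3]]) else NA_character_,
      label = label, stringsAsFactors = FALSE)
    rbind(mk(fb, spec$n_binding, 1L, "b"),
          mk(fn, spec$n_nonbinding, 0L, "n"))
  })
}

#' Does each tuple satisfy the implanted pairing rule?
#'
#' The Bayes-style rule checker: a tuple satisfies the rule when, at every
#' signal position, every partner fragment's residue class equals the rule
#' image of fragment 1's residue class. Predicting "binding" exactly for
#' rule-satisfying tuples is (near-)optimal on data from
#' [simulate_pattern_dataset()].
#'
#' @param tuples Tuple record data.frame.
#' @param spec The generating [pattern_spec()].
#' @return Logical vector, one entry per tuple.
#' @export
rule_satisfied <- function(tuples, spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  cls_of <- class_of_letter(spec$classes)
  sig <- signal_positions(spec)
  ok <- rep(TRUE, nrow(tuples))
  for (k in seq_len(spec$arity - 1L)) {
    rule <- spec$rules[[k]]
    for (p in sig) {
      c1 <- cls_of[substr(tuples$seq1, p, p)]
      ck <- cls_of[substr(tuples[[paste0("seq", k + 1L)]], p, p)]
      ok <- ok & (ck == rule[c1])
    }
  }
  unname(ok)
}
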