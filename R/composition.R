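## Amino-acid composition of tuple sets and the significance check used to
## show that binding and non-binding fragments have indistinguishable
## composition (so the classifier's signal is combinatorial, not
## compositional).

#' Amino-acid composition profile of a tuple set
#'
#' Pools residue counts over every fragment of every tuple and normalizes.
#'
#' @param tuples Tuple record data.frame.
#' @return List of class `composition_profile`: `freq` (named 20-vector
#'   summing to 1, canonical alphabetical order) and `n_residues`.
#' @export
composition_profile <- function(tuples) {
  stopifnot(is.data.frame(tuples))
  abort_if(nrow(tuples) == 0L, "empty tuple set")
  seq_cols <- intersect(paste0("seq", 1:3), names(tuples))
  letters1 <- unlist(strsplit(unlist(tuples[seq_cols], use.names = FALSE), ""),
                     use.names = FALSE)
  letters1 <- letters1[!is.na(letters1)]
  counts <- table(factor(letters1, levels = AA_ALPHABET))
  structure(list(freq = as.numeric(counts) / sum(counts),
                 n_residues = sum(counts)),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile over %d residues\n", x$n_residues))
  print(round(stats::setNames(x$freq, AA_ALPHABET), 4))
  invisible(x)
}

#' Student t-test between two composition profiles
#'
#' Compares the 20 paired per-letter frequencies of two profiles with a
#' two-sample (default) or paired Student t-test. Identical profiles give
#' t = 0 and p = 1 — the expected outcome when binding and non-binding
#' sets differ only in fragment combination, not composition.
#'
#' @param p1,p2 `composition_profile` objects.
#' @param paired Use the paired variant; default `FALSE`.
#' @return List of class `composition_test`: `statistic`, `p_value`,
#'   `delta` (named per-letter frequency differences `p1 - p2`).
#' @export
composition_ttest <- function(p1, p2, paired = FALSE) {
  stopifnot(inherits(p1, "composition_profile"),
            inherits(p2, "composition_profile"))
  delta <- stats::setNames(p1$freq - p2$freq, AA_ALPHABET)
  if (all(abs(delta) < 1e-15)) {
    ## t.test refuses essentially-constant data; a zero mean difference is
    ## exactly t = 0, p = 1
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(p1$freq, p2$freq, paired = paired,
                        var.equal = !paired)
  }
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 delta = delta, paired = paired),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("composition t-test (%s): t = %.4f, p = %.4f\n",
              if (x$paired) "paired" else "two-sample", x$statistic,
              x$p_value))
  invisible(x)
}

#' Write a composition profile as a two-column TSV
#'
#' @param profile A `composition_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(profile, path) {
  stopifnot(inherits(profile, "composition_profile"))
  utils::write.table(
    data.frame(aa = AA_ALPHABET, frequency = profile$freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
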