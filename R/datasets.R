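## Train/validation/test splitting and the two dataset-level controls:
## label randomization (negative control) and column-wise triad swapping
## (specificity control).

#' Split an encoded dataset 80/10/10
#'
#' Seeded uniform shuffle followed by a contiguous partition; the same seed
#' always yields the same membership.
#'
#' @param ds An `encoded_dataset` (see [encode_tuples()]).
#' @param fractions Train/validation/test fractions summing to 1; default
#'   `c(0.8, 0.1, 0.1)`.
#' @param seed Integer RNG seed.
#' @return List of class `split_dataset` with `train`, `validation`, `test`
#'   (each an `encoded_dataset`), plus `seed`, `fractions` and the
#'   permutation `indices` actually used.
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(ds, "encoded_dataset"))
  n <- nrow(ds$x)
  abort_if(n < 10L, "need at least 10 samples to split, got %d", n)
  abort_if(length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8,
           "fractions must be 3 numbers summing to 1")
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  parts <- list(train = perm[seq_len(n_train)],
                validation = perm[n_train + seq_len(n_val)],
                test = perm[(n_train + n_val + 1L):n])
  take <- function(i) structure(
    list(x = ds$x[i, , drop = FALSE], y = ds$y[i], id = ds$id[i],
         arity = ds$arity, length = ds$length),
    class = "encoded_dataset")
  structure(c(lapply(parts, take),
              list(seed = seed, fractions = fractions, indices = parts)),
            class = "split_dataset")
}

#' Randomize labels (negative control)
#'
#' Each label is independently reassigned Bernoulli(0.5); feature vectors
#' are untouched. A model trained on the result should perform at chance,
#' the standard sanity check that the learned signal lives in
#' the sequences and not in the pipeline.
#'
#' @param ds An `encoded_dataset`.
#' @param seed Integer RNG seed.
#' @return The dataset with new labels.
#' @export
randomize_labels <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "encoded_dataset"))
  ds$y <- with_seed(seed, sample(c(0L, 1L), nrow(ds$x), replace = TRUE))
  ds
}

#' Column-wise random swapping of binding triads (specificity control)
#'
#' Views n triads as an n x 3 table of fragments and applies an independent
#' uniform permutation to each column, then re-reads rows as new triads.
#' The swapped set has exactly the per-column fragment multisets — hence
#' exactly the amino-acid composition — of the input; only the combination
#' of fragments is destroyed. Classifying real against swapped triads
#' therefore probes combination-specific signal.
#'
#' @param triads Tuple record data.frame of triads (`arity == 3`).
#' @param seed Integer RNG seed.
#' @return Tuple records of the same size with fragments re-combined;
#'   `label` set to 0 (the convention for the swap experiment is 1 = real,
#'   0 = swapped) and `structure_id` suffixed with `"|swap"`.
#' @export
swap_triads <- function(triads, seed = 1L) {
  stopifnot(is.data.frame(triads))
  abort_if(!all(triads$arity == 3L), "swap_triads needs triads (arity 3)")
  n <- nrow(triads)
  out <- triads
  perms <- with_seed(seed, lapply(1:3, function(k) sample.int(n)))
  for (k in 1:3) {
    p <- perms[[k]]
    out[[paste0("seq", k)]] <- triads[[paste0("seq", k)]][p]
    out[[paste0("start", k)]] <- triads[[paste0("start", k)]][p]
  }
  out$structure_id <- paste0(triads$structure_id, "|swap")
  out$label <- 0L
  out
}
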