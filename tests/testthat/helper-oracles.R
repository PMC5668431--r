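## Independent reference implementations used as oracles. They share no
## code with the package paths they check: distances are recomputed from
## raw coordinates with explicit loops, AUC by O(n^2) pair ordering,
## gradients by central finite differences.

## Hand-built PDB text: one CA atom per residue at the given coordinates.
## `xyz` is an n x 3 matrix; `aa` a vector of one-letter codes.
pdb_from_points <- function(xyz, aa = rep("A", nrow(xyz)), chain = "A",
                            resno = seq_len(nrow(xyz))) {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR", X = "UNK")
  lines <- vapply(seq_len(nrow(xyz)), function(i) sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, aa3[[aa[i]]], chain, resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0),
    "")
  paste(c(lines, "TER", "END", ""), collapse = "\n")
}

## brute-force minimum distance between two residues of a parsed structure
oracle_min_dist <- function(s, chain, i, j) {
  a <- s$chains[[chain]]$atoms[[i + 1L]]$xyz
  b <- s$chains[[chain]]$atoms[[j + 1L]]$xyz
  best <- Inf
  for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[p, ] - b[q, ])^2)))
  best
}

## brute-force fragment pair distance: mean over center-residue pairs
oracle_frag_dist <- function(s, chain, s1, s2, L) {
  cents <- if (L %% 2 == 1) L %/% 2 else c(L %/% 2 - 1, L %/% 2)
  d <- c()
  for (a in cents) for (b in cents)
    d <- c(d, oracle_min_dist(s, chain, s1 + a, s2 + b))
  mean(d)
}

## reference greedy dedup over a matrix of sorted starts (one row per
## tuple); returns kept row indices
oracle_dedup <- function(starts, labels, window) {
  kept <- integer(0)
  for (r in seq_len(nrow(starts))) {
    dup <- FALSE
    for (k in kept) {
      if (labels[k] == labels[r] &&
          all(abs(starts[k, ] - starts[r, ]) < window)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, r)
  }
  kept
}

## full brute-force tuple extraction from raw coordinates (single chain)
oracle_extract <- function(s, arity, cfg) {
  chain <- names(s$chains)[1]
  ch <- s$chains[[chain]]
  n <- length(ch$aa)
  L <- cfg$fragment_length
  std <- ch$aa %in% peptriad::aa_alphabet()
  starts <- c()
  for (st in 0:(n - L)) {
    idx <- (st + 1):(st + L)
    if (all(std[idx]) && all(ch$continuous[idx[-1]]))
      starts <- c(starts, st)
  }
  nf <- length(starts)
  if (nf < arity) return(NULL)
  pd <- matrix(NA_real_, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf)
    pd[i, j] <- pd[j, i] <- oracle_frag_dist(s, chain, starts[i], starts[j], L)
  cpos <- starts + (L - 1) / 2
  ok_pair <- function(i, j)
    abs(cpos[i] - cpos[j]) >= cfg$min_center_separation &&
      abs(starts[i] - starts[j]) >= L
  rows <- list()
  combos <- utils::combn(nf, arity)
  for (cix in seq_len(ncol(combos))) {
    sel <- combos[, cix]
    prs <- utils::combn(sel, 2)
    if (!all(apply(prs, 2, function(p) ok_pair(p[1], p[2])))) next
    dd <- apply(prs, 2, function(p) pd[p[1], p[2]])
    lab <- if (all(dd < cfg$bind_cutoff)) 1L
      else if (all(dd > cfg$nonbind_cutoff)) 0L else NA_integer_
    if (is.na(lab)) next
    rows[[length(rows) + 1L]] <- c(starts[sel], lab)
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, rows)
  sm <- m[, seq_len(arity), drop = FALSE]
  kept <- oracle_dedup(sm, m[, arity + 1L], cfg$dedup_window)
  m <- m[kept, , drop = FALSE]
  if (arity == 2 && cfg$exclude_duos_in_triads) {
    bpt <- oracle_extract(s, 3L, within_no_exclude(cfg))
    if (!is.null(bpt)) {
      bpt <- bpt[bpt[, 4] == 1L, , drop = FALSE]
      if (nrow(bpt) > 0) {
        keys <- c(paste(bpt[, 1], bpt[, 2]), paste(bpt[, 1], bpt[, 3]),
                  paste(bpt[, 2], bpt[, 3]))
        m <- m[!(paste(m[, 1], m[, 2]) %in% keys), , drop = FALSE]
      }
    }
  }
  m
}

within_no_exclude <- function(cfg) {
  cfg$exclude_duos_in_triads <- FALSE
  cfg
}

## O(n^2) pair-ordering AUC with ties counted half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## central finite-difference gradients of mlp_loss
oracle_fd_gradients <- function(params, x, y, lambda, h = 1e-5) {
  num <- list(weights = params$weights, biases = params$biases)
  for (part in c("weights", "biases")) {
    for (l in seq_along(params[[part]])) {
      g <- params[[part]][[l]]
      for (i in seq_along(g)) {
        pp <- params; pp[[part]][[l]][i] <- pp[[part]][[l]][i] + h
        pm <- params; pm[[part]][[l]][i] <- pm[[part]][[l]][i] - h
        g[i] <- (peptriad::mlp_loss(pp, x, y, lambda) -
                   peptriad::mlp_loss(pm, x, y, lambda)) / (2 * h)
      }
      num[[part]][[l]] <- g
    }
  }
  num
}

## closed-form accuracy of the rule checker on a balanced implanted-pattern
## dataset, derived from the generative process
oracle_rule_checker_accuracy <- function(spec) {
  p <- vapply(spec$classes, length, 0L) / 20
  w <- spec$signal_width
  npartner <- spec$arity - 1L
  ## per partner: a uniform letter matches the required class of a uniform
  ## driver with prob sum_c p_c p_rule(c)
  rho_u <- prod(vapply(spec$rules, function(rule)
    sum(p * p[rule])^w, 0))
  ## partner drawn from the rule marginal but independent of the driver:
  ## per position sum_c p_c^2, for every partner and rule
  rho_m <- sum(p^2)^(w * npartner)
  eps <- spec$noise
  tpr <- (1 - eps) + eps * rho_u
  fpr <- (1 - eps) * rho_m + eps * rho_u
  (tpr + (1 - fpr)) / 2
}

## canonical ordering for tuple set comparison
tuple_key <- function(df) {
  k <- paste(df$start1, df$start2,
             ifelse(is.na(df$start3), "", df$start3), df$label)
  sort(k)
}
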