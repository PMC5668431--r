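test_that("center indices follow the odd/even rule", {
  expect_equal(center_indices(7), 3L)
  expect_equal(center_indices(4), c(1L, 2L))
  expect_equal(center_indices(1), 0L)
  expect_equal(center_indices(2), c(0L, 1L))
  expect_equal(center_indices(9), 4L)
  expect_error(center_indices(0), ">= 1")
})

test_that("fragment distance averages center-residue minimum distances", {
  ## single-CA residues on a line: residues i and j are |i-j| * 2 apart
  xyz <- cbind(seq(0, by = 2, length.out = 30), 0, 0)
  s <- parse_structure(pdb_from_points(xyz))
  f <- function(st, L) list(chain_id = "A", start = st, length = L)
  ## odd/odd: centers at 3 and 23 -> 40 apart
  expect_equal(fragment_distance(f(0, 7), f(20, 7), s), 40)
  ## even/odd: centers {11,12} x {23} -> mean(24, 22)
  expect_equal(fragment_distance(f(10, 4), f(20, 7), s), 23)
  ## even/even: centers {1,2} x {21,22} -> mean(40, 42, 38, 40)
  expect_equal(fragment_distance(f(0, 4), f(20, 4), s), 40)
  ## symmetry
  expect_equal(fragment_distance(f(20, 4), f(0, 4), s),
               fragment_distance(f(0, 4), f(20, 4), s))
})

test_that("fragment distance equals brute-force recomputation on random geometry", {
  set.seed(31)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(40 * 3, sd = 12), 40, 3)
    s <- parse_structure(pdb_from_points(xyz))
    L <- sample(c(4, 5, 7), 1)
    s1 <- sample(0:10, 1); s2 <- sample(20:(40 - L), 1)
    got <- fragment_distance(list(chain_id = "A", start = s1, length = L),
                             list(chain_id = "A", start = s2, length = L), s)
    expect_equal(got, oracle_frag_dist(s, "A", s1, s2, L))
  }
})

test_that("fragment enumeration slides windows and respects gaps and UNK", {
  xyz <- cbind(seq(0, by = 3.8, length.out = 10), 0, 0)
  s <- parse_structure(pdb_from_points(xyz))
  expect_equal(nrow(enumerate_fragments(s, 7)), 4L)
  ## non-standard residue at index 5 kills every 7-window
  s_unk <- parse_structure(pdb_from_points(
    xyz, aa = replace(rep("A", 10), 6, "X")))
  expect_equal(nrow(enumerate_fragments(s_unk, 7)), 0L)
  ## a numbering gap interrupts enumeration: count equals a window scan
  set.seed(5)
  resno <- c(1:25, 30:64)                       # gap after residue 25
  xyz60 <- cbind(seq(0, by = 3.8, length.out = 60), 0, 0)
  s_gap <- parse_structure(pdb_from_points(xyz60, resno = resno))
  got <- enumerate_fragments(s_gap, 7)
  cont <- s_gap$chains$A$continuous
  brute <- sum(vapply(0:(60 - 7), function(st)
    all(cont[(st + 2):(st + 7)]), TRUE))
  expect_equal(nrow(got), brute)
  expect_equal(brute, (25 - 7 + 1) + (35 - 7 + 1))
})

test_that("tuple classification applies both cutoffs to all pairs", {
  ## single-CA chain with controllable center distances: three 7-residue
  ## fragments whose centers form a triangle
  place <- function(d12, d13, d23) {
    ## triangle coordinates for the three centers
    x3 <- (d13^2 - d23^2 + d12^2) / (2 * d12)
    y3 <- sqrt(max(d13^2 - x3^2, 0))
    cents <- rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, y3, 0))
    xyz <- matrix(0, 34, 3)
    for (k in 1:3) {
      st <- c(0, 13, 26)[k]
      for (i in 1:7)
        xyz[st + i, ] <- cents[k, ] + c(0, 0, (i - 4) * 50)
    }
    parse_structure(pdb_from_points(xyz))
  }
  frs <- data.frame(chain_id = "A", start = c(0, 13, 26), length = 7)
  cfg <- extraction_config(fragment_length = 7)
  expect_equal(classify_tuple(frs, place(4.0, 4.5, 4.9), cfg), "BINDING")
  expect_equal(classify_tuple(frs, place(31, 40, 35), cfg), "NONBINDING")
  expect_equal(classify_tuple(frs, place(4.0, 4.5, 8.0), cfg), "NEITHER")
  ## invariant under fragment reordering
  s <- place(4.0, 4.5, 8.0)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(classify_tuple(frs[perm, ], s, cfg), "NEITHER")
  ## precondition violations are named
  over <- data.frame(chain_id = "A", start = c(0, 3), length = 7)
  expect_error(classify_tuple(over, s, cfg), "overlap")
  close_seq <- data.frame(chain_id = "A", start = c(0, 8), length = 7)
  expect_error(classify_tuple(close_seq, s, cfg), "center separation")
})

test_that("extraction finds exactly the planted binding tuples", {
  cfg <- extraction_config(fragment_length = 7)
  spec <- geometry_spec(chain_lengths = 60, contacts = list(
    list(chain = 1, starts = c(5, 25, 45), length = 7, distance = 4.5)),
    seed = 13)
  s <- parse_structure(make_toy_structure(spec), "toy")
  tri <- extract_tuples(s, 3, cfg)
  b <- tri[tri$label == 1, ]
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start1, b$start2, b$start3), c(5, 25, 45))
  ## every emitted binding tuple re-verifies against raw coordinates
  for (r in which(tri$label == 1)) {
    st <- c(tri$start1[r], tri$start2[r], tri$start3[r])
    dd <- utils::combn(st, 2, function(p)
      oracle_frag_dist(s, "A", p[1], p[2], 7))
    expect_true(all(dd < cfg$bind_cutoff))
  }
  ## fully extended chain: no binding, some non-binding
  s_ext <- parse_structure(make_toy_structure(
    geometry_spec(chain_lengths = 60, seed = 14)), "ext")
  tri_ext <- extract_tuples(s_ext, 3, cfg)
  expect_equal(sum(tri_ext$label == 1), 0L)
  expect_gt(sum(tri_ext$label == 0), 0L)
  ## duo exclusion removes the three duos inside the planted triad
  duo <- extract_tuples(s, 2, cfg)
  expect_equal(sum(duo$label == 1), 0L)
  duo_keep <- extract_tuples(s, 2, extraction_config(
    fragment_length = 7, exclude_duos_in_triads = FALSE))
  expect_equal(sum(duo_keep$label == 1), 3L)
})

test_that("cutoff monotonicity holds on a fixed structure", {
  spec <- geometry_spec(chain_lengths = 60, contacts = list(
    list(chain = 1, starts = c(5, 25, 45), length = 7, distance = 4.5)),
    seed = 17)
  s <- parse_structure(make_toy_structure(spec), "toy")
  count <- function(bind, nonbind) {
    t <- extract_tuples(s, 3, extraction_config(
      fragment_length = 7, bind_cutoff = bind, nonbind_cutoff = nonbind))
    c(sum(t$label == 1), sum(t$label == 0))
  }
  base <- count(5, 30)
  expect_gte(count(8, 30)[1], base[1])    # raising bind cutoff
  expect_lte(count(5, 40)[2], base[2])    # raising nonbind cutoff
})

test_that("deduplication drops only all-fragments-close duplicates, greedily", {
  mk <- function(starts_list, label = 1L) {
    m <- do.call(rbind, starts_list)
    data.frame(structure_id = "s", arity = 3L, chain_id = "A",
               start1 = m[, 1], start2 = m[, 2], start3 = m[, 3],
               length = 7L, seq1 = "AAAAAAA", seq2 = "AAAAAAA",
               seq3 = "AAAAAAA", label = label, stringsAsFactors = FALSE)
  }
  two <- mk(list(c(0, 20, 40), c(5, 24, 47)))
  expect_equal(nrow(deduplicate_tuples(two, 9)), 1L)
  expect_equal(deduplicate_tuples(two, 9)$start1, 0)
  kept <- mk(list(c(0, 20, 40), c(5, 24, 50)))
  expect_equal(nrow(deduplicate_tuples(kept, 9)), 2L)
  ## opposite labels are never merged
  mixed <- mk(list(c(0, 20, 40)))
  mixed <- rbind(mixed, transform(mk(list(c(1, 21, 41))), label = 0L))
  expect_equal(nrow(deduplicate_tuples(mixed, 9)), 2L)
  ## random tuples vs the reference greedy scan
  set.seed(23)
  for (rep in 1:10) {
    n <- 40
    starts <- cbind(sample(0:30, n, TRUE), sample(40:70, n, TRUE),
                    sample(80:110, n, TRUE))
    df <- mk(asplit(starts, 1))
    df$label <- sample(0:1, n, TRUE)
    got <- deduplicate_tuples(df, 9)
    want <- oracle_dedup(starts, df$label, 9)
    expect_equal(unname(got$start1), unname(starts[want, 1]))
    expect_equal(nrow(got), length(want))
  }
  expect_error(deduplicate_tuples(rbind(mk(list(c(0, 20, 40))),
                                        within(mk(list(c(0, 20, 40))),
                                               arity <- 2L)), 9),
               "single arity")
})

test_that("candidate triad count follows the chunk combinatorics", {
  expect_equal(count_candidate_triads(150, 10), 455L)
  expect_equal(count_candidate_triads(30, 10), 1L)
  expect_equal(count_candidate_triads(20, 10), 0L)
  expect_equal(count_candidate_triads(151, 10), 455L)
  expect_error(count_candidate_triads(0, 10), ">= 1")
})

test_that("tuple records survive a write/read round trip", {
  spec <- geometry_spec(chain_lengths = 45, contacts = list(
    list(chain = 1, starts = c(2, 22), length = 7, distance = 4.2)), seed = 2)
  s <- parse_structure(make_toy_structure(spec), "toy")
  cfg <- extraction_config(fragment_length = 7)
  tup <- extract_tuples(s, 2, extraction_config(fragment_length = 7,
                                                exclude_duos_in_triads = FALSE))
  path <- tempfile(fileext = ".tsv")
  write_tuples(tup, path, cfg)
  back <- read_tuples(path)
  expect_equal(back$start1, tup$start1)
  expect_equal(back$seq2, tup$seq2)
  expect_equal(back$label, tup$label)
})
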