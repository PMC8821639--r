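make_set <- function(seqs, prefix = "s", label = "positive",
                     family = NA_character_) {
  sequence_tbl(sprintf("%s%02d", prefix, seq_along(seqs)), seqs,
               label = label, family = family)
}

test_that("length filtering is inclusive, order-preserving and idempotent", {
  set.seed(1)
  d <- make_set(vapply(c(60, 49, 80, 120, 50), random_protein, character(1)))
  f <- filter_by_length(d, 50, 100)
  expect_equal(f$id, c("s01", "s03", "s05"))
  expect_identical(filter_by_length(f, 50, 100), f)
  expect_equal(nrow(filter_by_length(d[0, ], 50, 100)), 0L)
  expect_identical(filter_by_length(d, 1, 2000)$id, d$id)
})

test_that("pairwise identity matches hand cases and is symmetric", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("MKVLA", "MKVIA"), 4 / 5)
  set.seed(11)
  for (k in 1:10) {
    a <- random_protein(sample(10:40, 1))
    b <- random_protein(sample(10:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_gte(pairwise_identity(a, b), 0)
    expect_lte(pairwise_identity(a, b), 1)
  }
})

test_that("alignment engine scores equal the independent Gotoh oracle", {
  # optimal score is unique even when co-optimal alignments are not
  set.seed(23)
  for (k in 1:15) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    impl <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = blosum62,
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(impl, oracle_global_score(a, b))
    impl_l <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = blosum62,
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(impl_l, oracle_local_score(a, b))
  }
})

test_that("identity agrees with a DP traceback oracle on mutated copies", {
  # mutated-copy pairs have an effectively unique optimum; unrelated pairs
  # have co-optimal alignments of different lengths, where identity is
  # alignment-choice-dependent and far below any clustering threshold
  set.seed(29)
  for (k in 1:8) {
    a <- random_protein(60)
    ch <- strsplit(a, "")[[1]]
    mut <- sample(60, 10)
    ch[mut] <- sample(CANONICAL_RESIDUES, 10, replace = TRUE)
    b <- paste(ch, collapse = "")
    expected <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]) / 60
    expect_equal(pairwise_identity(a, b), expected)
  }
})

test_that("greedy clustering collapses identical sequences and keeps dissimilar ones", {
  set.seed(41)
  d <- make_set(rep(random_protein(80), 5))
  cl <- cluster_by_identity(d, 0.7)
  expect_equal(nrow(cl$representatives), 1L)
  expect_equal(sum(cl$assignment$id != cl$assignment$representative), 4L)

  d2 <- make_set(replicate(3, random_protein(60)))
  cl2 <- cluster_by_identity(d2, 0.7)
  expect_equal(nrow(cl2$representatives), 3L)
})

test_that("greedy clustering satisfies its definition on a mixed toy set", {
  set.seed(43)
  base1 <- random_protein(90)
  base2 <- random_protein(70)
  mutate_seq <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(CANONICAL_RESIDUES, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(base1, mutate_seq(base1, 5), mutate_seq(base1, 8),
            base2, mutate_seq(base2, 4),
            replicate(5, random_protein(sample(50:80, 1))))
  d <- make_set(seqs)
  thr <- 0.7
  cl <- cluster_by_identity(d, thr)
  reps <- cl$representatives
  asg <- cl$assignment
  # every non-representative is >= threshold to its representative
  for (i in seq_len(nrow(asg))) {
    if (asg$id[i] != asg$representative[i]) {
      a <- d$sequence[d$id == asg$id[i]]
      b <- d$sequence[d$id == asg$representative[i]]
      expect_gte(pairwise_identity(a, b), thr)
    }
  }
  # brute-force re-run of the greedy definition gives the same clustering
  ord <- order(-nchar(d$sequence), d$id)
  reps_bf <- character(0)
  asg_bf <- character(nrow(d)); names(asg_bf) <- d$id
  for (i in ord) {
    hit <- NA_character_
    for (r in reps_bf) {
      if (pairwise_identity(d$sequence[i],
                            d$sequence[d$id == r]) >= thr) { hit <- r; break }
    }
    if (is.na(hit)) { reps_bf <- c(reps_bf, d$id[i]); asg_bf[d$id[i]] <- d$id[i] }
    else asg_bf[d$id[i]] <- hit
  }
  expect_setequal(reps$id, reps_bf)
  expect_identical(asg$representative, unname(asg_bf[asg$id]))
})

test_that("clustering at identity 1.0 collapses only exact duplicates", {
  set.seed(47)
  s1 <- random_protein(60)
  ch <- strsplit(s1, "")[[1]]; ch[5] <- setdiff(CANONICAL_RESIDUES, ch[5])[1]
  d <- make_set(c(s1, s1, paste(ch, collapse = "")))
  cl <- cluster_by_identity(d, 1.0)
  expect_equal(nrow(cl$representatives), 2L)
})

test_that("similarity purge removes planted homology but keeps shuffled controls", {
  set.seed(53)
  pos <- make_set(replicate(3, random_protein(150)), prefix = "pos",
                  family = "alpha")
  # negative carrying a 60-residue verbatim copy of a positive segment
  seg <- substr(pos$sequence[2], 41, 100)
  carrier <- random_protein(200)
  planted <- paste0(substr(carrier, 1, 70), seg, substr(carrier, 131, 200))
  shuffled_seg <- paste(sample(strsplit(seg, "")[[1]]), collapse = "")
  control <- paste0(substr(carrier, 1, 70), shuffled_seg,
                    substr(carrier, 131, 200))
  clean <- random_protein(180)
  neg <- sequence_tbl(c("n_planted", "n_control", "n_clean"),
                      c(planted, control, clean), label = "negative")
  pg <- purge_positive_like(neg, pos)
  expect_false("n_planted" %in% pg$negatives$id)
  expect_true(all(c("n_control", "n_clean") %in% pg$negatives$id))
  expect_equal(pg$negatives$id, c("n_control", "n_clean"))  # order kept
  audit <- pg$audit
  expect_equal(audit$action[audit$id == "n_planted"], "removed")
  expect_equal(audit$best_hit[audit$id == "n_planted"], "pos02")
  # the Smith-Waterman oracle confirms a large score gap
  sc_p <- oracle_local_score(planted, pos$sequence[2])
  sc_c <- oracle_local_score(control, pos$sequence[2])
  expect_gt(sc_p, 2 * sc_c)

  # identical copy of a positive is always removed
  neg2 <- sequence_tbl("twin", pos$sequence[1], label = "negative")
  expect_equal(nrow(purge_positive_like(neg2, pos)$negatives), 0L)
})

test_that("assemble_dataset composes the three curation steps", {
  set.seed(59)
  base <- random_protein(100)
  pos <- sequence_tbl(c("p1", "p2", "p3", "p_short"),
                      c(base, base, random_protein(120), random_protein(30)),
                      label = "positive", family = "alpha")
  neg <- sequence_tbl(c("n1", "n2", "n_long"),
                      c(base, random_protein(90), random_protein(2500)),
                      label = "negative")
  cfg <- curation_config(min_length = 50, max_length = 2000)
  cur <- assemble_dataset(pos, neg, cfg)
  # p_short length-filtered; p1/p2 collapse; n_long length-filtered;
  # n1 (identical to a positive) purged
  expect_setequal(cur$positives$id, c("p1", "p3"))
  expect_equal(cur$negatives$id, "n2")
  expect_setequal(cur$audit$id, c("p_short", "n_long", "p2", "n1"))
  steps <- setNames(cur$audit$step, cur$audit$id)
  expect_equal(steps[["p2"]], "identity_cluster")
  expect_equal(steps[["n1"]], "similarity_purge")
  # matches applying the steps independently
  pos_f <- filter_by_length(pos, 50, 2000)
  reps <- cluster_by_identity(pos_f, 0.7)$representatives
  negs <- purge_positive_like(filter_by_length(neg, 50, 2000), reps)$negatives
  expect_identical(cur$positives$id, reps$id)
  expect_identical(cur$negatives$id, negs$id)
})

test_that("assemble_dataset rejects empty outcomes and overlapping ids", {
  set.seed(61)
  pos <- make_set(random_protein(20), prefix = "p")
  neg <- make_set(random_protein(100), prefix = "n", label = "negative")
  expect_error(assemble_dataset(pos, neg), "no positives")
  both <- make_set(random_protein(100), prefix = "x")
  both_neg <- both; both_neg$label <- "negative"
  expect_error(assemble_dataset(both, both_neg), "overlap")
})
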