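test_that("pairwise identity follows the shorter-sequence convention", {
  expect_equal(pairwise_identity("MKVLAW", "MKVLAW"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0)
  # vectorized subjects, symmetric, capped at 100
  expect_equal(pairwise_identity("AAAA", c("AAAT", "AAAA")), c(75, 100))
  expect_equal(pairwise_identity("AAAT", "AAAA"),
               pairwise_identity("AAAA", "AAAT"))
  # shorter-length denominator: a perfect substring scores 100
  expect_equal(pairwise_identity("MKVL", "MKVLAWAW"), 100)
  # ambiguity letters are never identical positions
  expect_equal(pairwise_identity("XXXX", "XXXX"), 0)
  expect_error(pairwise_identity("", "AA"), "empty")
})

test_that("alignment scores agree with an independent aligner", {
  al <- c(ssptools:::AA_STANDARD, ssptools:::AA_AMBIGUOUS)
  mat <- matrix(-1, length(al), length(al), dimnames = list(al, al))
  diag(mat) <- 1
  withr::local_seed(3)
  for (i in 1:40) {
    x <- paste(sample(ssptools:::AA_STANDARD, sample(5:50, 1), TRUE),
               collapse = "")
    y <- paste(sample(ssptools:::AA_STANDARD, sample(5:50, 1), TRUE),
               collapse = "")
    mine <- ssptools:::.nw_identity_count(x, y)[2, 1]
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y),
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1,
      type = "global"))
    expect_equal(mine, ref)
  }
})

test_that("greedy NR retains longest-first representatives below h", {
  d <- gen_family(n_members = 1, length = 40, within_identity = 100,
                  n_families = 6, seed = 31)
  # unrelated random sequences: nothing to remove
  nr <- greedy_nr(d, h = 80)
  expect_equal(sort(nr$id), sort(d$id))
  # two identical sequences collapse to one
  dup <- seq_dataset(c("a", "b"), rep(d$residues[1], 2))
  expect_equal(nrow(greedy_nr(dup, h = 90)), 1L)
  # clustered input collapses to one representative per cluster
  fam <- gen_family(n_members = 4, length = 60, within_identity = 95,
                    n_families = 3, seed = 32)
  nr2 <- greedy_nr(fam, h = 90)
  expect_equal(nrow(nr2), 3L)
  expect_true(oracle_all_pairs_below(nr2, 90))
})

test_that("divide-and-conquer reduction matches the global greedy pass", {
  fam <- gen_family(n_members = 3, length = 50, within_identity = 95,
                    n_families = 4, seed = 33)
  ref <- greedy_nr(fam, h = 80)
  expect_equal(nrow(ref), 4L)
  for (m in c(3L, 5L, 100L)) {
    out <- reduce_homology(fam, reduction_config(h = 80, m = m))
    expect_setequal(out$id, ref$id)
    expect_true(oracle_all_pairs_below(out, 80))
  }
})

test_that("reduction degenerate cases behave as stated", {
  fam <- gen_family(n_members = 1, length = 30, within_identity = 100,
                    n_families = 5, seed = 34)
  # single subset equals greedy_nr
  one <- reduce_homology(fam, reduction_config(h = 70, m = 1000L))
  expect_equal(one$id, greedy_nr(fam, 70)$id)
  # h = 100 with no duplicates keeps everything (sorted)
  all_kept <- reduce_homology(fam, reduction_config(h = 100, m = 2L))
  expect_setequal(all_kept$id, fam$id)
  expect_error(reduction_config(h = 0), "percent")
  expect_error(reduction_config(h = 50, m = 0), "positive")
})

test_that("NR postcondition and partition independence hold on random inputs", {
  withr::local_seed(35)
  for (i in 1:8) {
    n_fam <- sample(2:4, 1)
    fam <- gen_family(n_members = sample(2:3, 1), length = 40,
                      within_identity = sample(c(90, 95), 1),
                      n_families = n_fam, seed = 350 + i)
    h <- sample(c(70, 80), 1)
    ref <- greedy_nr(fam, h)
    expect_true(oracle_all_pairs_below(ref, h))
    m <- sample(2:6, 1)
    out <- reduce_homology(fam, reduction_config(h = h, m = m))
    expect_setequal(out$id, ref$id)
  }
})

test_that("lowering h never enlarges the NR set", {
  fam <- gen_family(n_members = 3, length = 40, within_identity = 92,
                    n_families = 3, seed = 36)
  sizes <- vapply(c(95, 85, 70, 40), function(h) nrow(greedy_nr(fam, h)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("random sampling is seeded, sized by halving, and optionally disjoint", {
  d <- random_small_dataset(64)
  # k = 0 returns the full dataset
  full <- random_sample(d, k = 0, repeats = 2, seed = 9)
  expect_equal(nrow(full[[1]]), 64L)
  # k halving with round-half-up
  expect_equal(nrow(random_sample(d, k = 2, seed = 9)[[1]]), 16L)
  d37 <- random_small_dataset(37)
  expect_equal(nrow(random_sample(d37, k = 2, seed = 9)[[1]]), 9L)
  # determinism per repeat
  s1 <- random_sample(d, k = 2, repeats = 3, seed = 9)
  s2 <- random_sample(d, k = 2, repeats = 3, seed = 9)
  expect_equal(lapply(s1, `[[`, "id"), lapply(s2, `[[`, "id"))
  # strict mode yields pairwise-disjoint subsets covering the input
  strict <- random_sample(d, target_size = 16, repeats = 4, seed = 9,
                          strict = TRUE)
  ids <- lapply(strict, `[[`, "id")
  expect_equal(length(unique(unlist(ids))), 64L)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(length(intersect(ids[[i]], ids[[j]])), 0L)
  expect_error(random_sample(d, target_size = 20, repeats = 4, seed = 1,
                             strict = TRUE), "infeasible")
  expect_error(random_sample(d, target_size = 100, seed = 1), "exceeds")
  expect_error(random_sample(d, k = 1, target_size = 3, seed = 1),
               "exactly one")
})

test_that("per-record inclusion frequency is uniform across seeds", {
  d <- random_small_dataset(20, len_range = c(10L, 12L))
  hits <- integer(20)
  n_draws <- 200
  for (s in seq_len(n_draws)) {
    idx <- match(random_sample(d, target_size = 5, seed = s)[[1]]$id,
                 d$id)
    hits[idx] <- hits[idx] + 1L
  }
  expected <- n_draws * 5 / 20
  # binomial tolerance: 5 sigma
  sigma <- sqrt(n_draws * 0.25 * 0.75)
  expect_true(all(abs(hits - expected) < 5 * sigma))
})
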