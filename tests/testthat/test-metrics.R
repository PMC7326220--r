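pair3 <- function(obs, prd, id = "p")
  ss_pair(ss_annotation(id, obs, 3), ss_annotation(id, prd, 3))
pair8 <- function(obs, prd, id = "p")
  ss_pair(ss_annotation(id, obs, 8), ss_annotation(id, prd, 8))

test_that("8-to-3 state mapping follows the standard reduction", {
  expect_equal(map_8to3("HGIEBTSC"), "HHHEECCC")
  expect_equal(map_8to3("CCCC"), "CCCC")
  expect_error(map_8to3(""), "empty")
  expect_error(map_8to3("HQX"), "outside")
  a <- ss_annotation("x", "HGIEBTSC", 8)
  m <- map_8to3(a)
  expect_equal(m$alphabet, 3L)
  expect_equal(m$states, "HHHEECCC")
})

test_that("micro Q pools residues; macro averages proteins", {
  expect_equal(q_accuracy(pair3("HHHCCC", "CCCCCC"))$q, 0.5)
  expect_equal(q_accuracy(pair3("HEC", "HEC"))$q, 1)
  a <- pair3(strrep("H", 100),
             paste0(strrep("H", 80), strrep("C", 20)), id = "a")
  b <- pair3(strrep("H", 10), strrep("E", 10), id = "b")
  expect_equal(q_accuracy(list(a, b), "micro")$q, 80 / 110)
  expect_equal(q_accuracy(list(a, b), "macro")$q, 0.4)
  # micro equals the recount of summed correct over summed length
  per <- q_accuracy(list(a, b))$per_protein
  expect_equal(q_accuracy(list(a, b))$q,
               sum(per$correct) / sum(per$length))
})

test_that("annotation pair validation rejects inconsistent input", {
  expect_error(ss_pair(ss_annotation("x", "HEC"),
                       ss_annotation("x", "HECC")), "length mismatch")
  expect_error(ss_pair(ss_annotation("x", "HEC"),
                       ss_annotation("y", "HEC")), "different proteins")
  expect_error(q_accuracy(list()), "empty")
  expect_error(ss_annotation("x", "HQZ", 3), "outside")
})

test_that("SOV reproduces hand-derived values", {
  expect_equal(sov(pair3("HHHHHHCC", "HHHCCCCC"))$sov, 0.65)
  expect_equal(sov(pair3("HHHCCC", "CCCCCC"))$sov, 1 / 3)
  expect_equal(sov(pair3("HECHECHEC", "HECHECHEC"))$sov, 1)
  expect_equal(sov(pair8("HGIEBTSC", "HGIEBTSC"))$sov, 1)
})

test_that("SOV agrees with the brute-force enumerator on random pairs", {
  withr::local_seed(11)
  for (i in 1:400) {
    len <- sample(1:30, 1)
    ab <- if (i %% 2) c("H", "E", "C") else
      c("H", "G", "I", "E", "B", "T", "S", "C")
    obs <- random_ss_string(len, ab)
    prd <- random_ss_string(len, ab)
    p <- ss_pair(ss_annotation("r", obs, length(ab)),
                 ss_annotation("r", prd, length(ab)))
    got <- sov(p)$sov
    expect_equal(got, oracle_sov(obs, prd), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("SOV is 1 exactly when segment structures coincide", {
  withr::local_seed(13)
  for (i in 1:50) {
    s <- random_ss_string(sample(5:25, 1))
    expect_equal(sov(pair3(s, s))$sov, 1)
  }
  # same residues correct count but different segmentation is not 1
  expect_lt(sov(pair3("HHHHHH", "HHHCHH"))$sov, 1)
})

test_that("size-weighted SOV averaging follows the stated weights", {
  expect_equal(weighted_sov(100, 0.8), 0.8)
  expect_equal(weighted_sov(c(50, 50, 50), c(0.2, 0.4, 0.9)),
               mean(c(0.2, 0.4, 0.9)))
  expect_equal(weighted_sov(c(100, 50), c(0.8, 0.5)), 0.7)
  expect_error(weighted_sov(numeric(), numeric()), "empty")
  expect_error(weighted_sov(c(10, 0), c(0.5, 0.5)), "positive")
})

test_that("evaluate_set couples 8-state and mapped 3-state measures", {
  perfect <- list(pair8("HGIEBTSC", "HGIEBTSC", "a"),
                  pair8("TTSSCC", "TTSSCC", "b"))
  ev <- evaluate_set(perfect)
  expect_equal(c(ev$q3, ev$q8, ev$sov3, ev$sov8), rep(1, 4))
  # an error within a helix subtype vanishes after mapping
  sub <- evaluate_set(pair8("GGGG", "HHHH"))
  expect_lt(sub$q8, 1)
  expect_equal(sub$q3, 1)
  expect_equal(sub$sov3, 1)
})

test_that("coarsening to 3 states never lowers Q", {
  withr::local_seed(17)
  for (i in 1:50) {
    len <- sample(10:60, 1)
    p8 <- pair8(random_ss_string(len, ssptools:::SS8_ALPHABET),
                random_ss_string(len, ssptools:::SS8_ALPHABET))
    q8 <- q_accuracy(p8)$q
    q3 <- q_accuracy(map_8to3(p8))$q
    expect_gte(q3, q8)
  }
})

test_that("TSV round trip feeds the evaluator", {
  withr::local_seed(5)
  pairs <- lapply(1:4, function(i)
    gen_ss_pair(60, q_target = 0.8, alphabet = 8,
                protein_id = sprintf("p%d", i), seed = i))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ss_pairs(pairs, f)
  back <- read_ss_pairs(f)
  expect_equal(back[[1]]$observed$alphabet, 8L)
  expect_equal(evaluate_set(back)$q8, evaluate_set(pairs)$q8)
})

test_that("Pearson correlation matches direct formula cases", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_correlation(1:4, -(1:4)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_correlation(c(1, 1), c(2, 3)), "degenerate")
  expect_error(pearson_correlation(1:3, 1:4), "mismatch")
})

test_that("group comparison walks the normality/variance cascade", {
  withr::local_seed(23)
  a <- rnorm(10)
  same <- compare_groups(a, a)
  expect_equal(same$test, "student_t")
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  x <- rnorm(10, 0, 1); y <- rnorm(10, 5, 1)
  r <- compare_groups(x, y)
  expect_lt(r$p_value, 1e-3)
  # direct pooled-variance t statistic recomputation
  sp <- sqrt(((9 * var(x)) + (9 * var(y))) / 18)
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(2 / 10))
  if (r$test == "student_t")
    expect_equal(r$statistic, tstat, tolerance = 1e-12)

  # grossly unequal variances push the cascade to Welch
  z <- rnorm(30, 0, 25)
  w <- compare_groups(rnorm(30, 0, 0.05), z)
  expect_equal(w$test, "welch_t")
  expect_false(is.na(w$f_test_p))

  # non-normal group falls back to Welch with the F gate skipped
  e <- compare_groups(rexp(50)^3, rnorm(50))
  expect_equal(e$test, "welch_t")
  expect_true(is.na(e$f_test_p))

  expect_error(compare_groups(c(1, 1, 1), rnorm(5)), "identical")
  expect_error(compare_groups(c(1, 2), rnorm(5)), "at least 3")
})
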