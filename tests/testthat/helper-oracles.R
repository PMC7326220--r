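# Independent brute-force oracles, deliberately written with different
# mechanics than the package implementations they check.

# Segment overlap by explicit position-set enumeration: find segments by
# scanning characters one at a time, intersect/union positions with
# set operations.
oracle_sov <- function(observed, predicted) {
  segs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- list()
    i <- 1L
    while (i <= length(ch)) {
      j <- i
      while (j < length(ch) && ch[j + 1L] == ch[i]) j <- j + 1L
      out[[length(out) + 1L]] <- list(state = ch[i], pos = i:j)
      i <- j + 1L
    }
    out
  }
  so <- segs(observed); sp <- segs(predicted)
  num <- 0; nrm <- 0
  for (s1 in so) {
    overlapping <- Filter(function(s2)
      s2$state == s1$state && length(intersect(s1$pos, s2$pos)) > 0, sp)
    len1 <- length(s1$pos)
    if (!length(overlapping)) { nrm <- nrm + len1; next }
    for (s2 in overlapping) {
      minov <- length(intersect(s1$pos, s2$pos))
      maxov <- length(union(s1$pos, s2$pos))
      delta <- min(maxov - minov, minov,
                   floor(len1 / 2), floor(length(s2$pos) / 2))
      num <- num + (minov + delta) / maxov * len1
    }
    nrm <- nrm + length(overlapping) * len1
  }
  num / nrm
}

# all-pairs identity check of the non-redundancy postcondition
oracle_all_pairs_below <- function(dataset, h) {
  n <- nrow(dataset)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    ids <- pairwise_identity(dataset$residues[i],
                             dataset$residues[(i + 1L):n])
    if (any(ids >= h)) return(FALSE)
  }
  TRUE
}

random_ss_string <- function(len, alphabet = c("H", "E", "C")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_small_dataset <- function(n, len_range = c(20L, 40L),
                                 families = NULL) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  res <- vapply(lens, function(l)
    paste(sample(ssptools:::AA_STANDARD, l, replace = TRUE),
          collapse = ""), "")
  seq_dataset(sprintf("s%03d", seq_len(n)), res)
}
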