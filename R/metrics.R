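SS3_ALPHABET <- c("H", "E", "C")
SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Secondary-structure annotation
#'
#' Per-residue secondary-structure state string for one protein, over the
#' three-state alphabet H/E/C or the eight-state DSSP alphabet
#' H/G/I/E/B/T/S/C.
#'
#' @param protein_id protein identifier.
#' @param states non-empty state string.
#' @param alphabet 3 or 8; inferred from `states` when `NULL` (a string
#'   using only H/E/C is taken as 3-state).
#' @return An object of class `ss_annotation`.
#' @export
ss_annotation <- function(protein_id, states, alphabet = NULL) {
  states <- toupper(as.character(states))
  if (length(states) != 1L || !nzchar(states))
    stop("'states' must be one non-empty string")
  ch <- strsplit(states, "")[[1]]
  if (is.null(alphabet))
    alphabet <- if (all(ch %in% SS3_ALPHABET)) 3L else 8L
  alphabet <- as.integer(alphabet)
  ok <- switch(as.character(alphabet),
               "3" = SS3_ALPHABET, "8" = SS8_ALPHABET,
               stop("'alphabet' must be 3 or 8"))
  if (!all(ch %in% ok))
    stop("state character(s) outside the ", alphabet, "-state alphabet: ",
         paste(unique(ch[!ch %in% ok]), collapse = ", "))
  structure(list(protein_id = as.character(protein_id), states = states,
                 alphabet = alphabet),
            class = "ss_annotation")
}

#' Pair an observed with a predicted annotation
#'
#' @param observed,predicted [ss_annotation()] objects of equal length,
#'   identical protein id and alphabet.
#' @return An object of class `ss_pair`.
#' @export
ss_pair <- function(observed, predicted) {
  stopifnot(inherits(observed, "ss_annotation"),
            inherits(predicted, "ss_annotation"))
  if (observed$protein_id != predicted$protein_id)
    stop("observed and predicted annotations are for different proteins")
  if (observed$alphabet != predicted$alphabet)
    stop("observed and predicted annotations use different alphabets")
  if (nchar(observed$states) != nchar(predicted$states))
    stop("length mismatch for protein ", observed$protein_id, ": ",
         nchar(observed$states), " vs ", nchar(predicted$states))
  structure(list(observed = observed, predicted = predicted),
            class = "ss_pair")
}

#' Collapse an 8-state annotation to 3 states
#'
#' Applies the standard reduction H,G,I -> H; E,B -> E; T,S,C -> C.
#'
#' @param annotation an 8-state [ss_annotation()], an 8-state [ss_pair()]
#'   (both strings are mapped), or a plain 8-state string.
#' @return The same kind of object in the 3-state alphabet.
#' @export
map_8to3 <- function(annotation) {
  if (inherits(annotation, "ss_pair"))
    return(ss_pair(map_8to3(annotation$observed),
                   map_8to3(annotation$predicted)))
  if (inherits(annotation, "ss_annotation")) {
    if (annotation$alphabet != 8L)
      stop("annotation is not 8-state")
    return(ss_annotation(annotation$protein_id,
                         map_8to3(annotation$states), alphabet = 3L))
  }
  s <- toupper(as.character(annotation))
  if (!nzchar(s)) stop("empty state string")
  if (grepl(sprintf("[^%s]", paste(SS8_ALPHABET, collapse = "")), s))
    stop("state character(s) outside the 8-state alphabet")
  chartr("GIBTS", "HHECC", s)
}

#' Q accuracy of secondary-structure predictions
#'
#' Fraction of residues whose predicted state matches the observed state.
#' The micro average (the default, and the measure reported as Q3/Q8)
#' pools residues: total correct residues over all proteins divided by
#' total residues. The macro average — the unweighted mean of per-protein
#' fractions — is provided for comparison only; it over-weights short
#' proteins.
#'
#' @param pairs an [ss_pair()] or a list of them, all on one alphabet.
#' @param mode `"micro"` (default) or `"macro"`.
#' @return List with `q` (the aggregate in \[0,1\]), `mode`, and
#'   `per_protein`, a data frame of id, length, correct and q.
#' @export
q_accuracy <- function(pairs, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  pairs <- as_pair_list(pairs)
  per <- do.call(rbind, lapply(pairs, function(p) {
    o <- strsplit(p$observed$states, "")[[1]]
    e <- strsplit(p$predicted$states, "")[[1]]
    data.frame(protein_id = p$observed$protein_id,
               length = length(o), correct = sum(o == e),
               stringsAsFactors = FALSE)
  }))
  per$q <- per$correct / per$length
  q <- if (mode == "micro") sum(per$correct) / sum(per$length)
       else mean(per$q)
  list(q = q, mode = mode, per_protein = per)
}

as_pair_list <- function(pairs) {
  if (inherits(pairs, "ss_pair")) pairs <- list(pairs)
  if (!length(pairs)) stop("empty list of annotation pairs")
  stopifnot(all(vapply(pairs, inherits, logical(1), "ss_pair")))
  ab <- vapply(pairs, function(p) p$observed$alphabet, integer(1))
  if (length(unique(ab)) != 1L)
    stop("annotation pairs mix 3-state and 8-state alphabets")
  pairs
}

# maximal runs of one state as (state, start, end) intervals
ss_segments <- function(states) {
  ch <- strsplit(states, "")[[1]]
  r <- rle(ch)
  end <- cumsum(r$lengths)
  data.frame(state = r$values, start = end - r$lengths + 1L, end = end,
             stringsAsFactors = FALSE)
}

#' Segment-overlap (SOV) score of one prediction
#'
#' Segment-level accuracy measure in the 1999 revision: for every observed
#' segment `s1` of a state, every predicted segment `s2` of the same state
#' that overlaps it contributes
#' \deqn{\frac{minov(s1,s2) + \delta(s1,s2)}{maxov(s1,s2)} \times len(s1)}
#' where `minov` is the length of the position intersection, `maxov` the
#' length of the position union, and
#' \eqn{\delta = \min(maxov - minov,\ minov,\ \lfloor len(s1)/2 \rfloor,
#' \ \lfloor len(s2)/2 \rfloor)}. The normalizer sums `len(s1)` once per
#' overlapping predicted segment for matched observed segments and once in
#' total for unmatched ones, so SOV lies in \[0,1\] and equals 1 exactly
#' when the segment structures coincide. Unlike per-residue Q accuracy,
#' SOV rewards correctly placed secondary-structure elements and tolerates
#' small boundary shifts.
#'
#' @param pair an [ss_pair()].
#' @return List with `sov` in \[0,1\], `length`, and `per_state`, a data
#'   frame of the per-state numerator and normalizer contributions.
#' @examples
#' p <- ss_pair(ss_annotation("x", "HHHHHHCC"), ss_annotation("x", "HHHCCCCC"))
#' sov(p)$sov  # 0.65
#' @export
sov <- function(pair) {
  stopifnot(inherits(pair, "ss_pair"))
  obs <- ss_segments(pair$observed$states)
  prd <- ss_segments(pair$predicted$states)
  states <- unique(obs$state)
  per_state <- do.call(rbind, lapply(states, function(st) {
    s1s <- obs[obs$state == st, , drop = FALSE]
    s2s <- prd[prd$state == st, , drop = FALSE]
    num <- 0; nrm <- 0
    for (i in seq_len(nrow(s1s))) {
      s1 <- s1s[i, ]
      len1 <- s1$end - s1$start + 1L
      ov <- s2s[s2s$start <= s1$end & s2s$end >= s1$start, , drop = FALSE]
      if (!nrow(ov)) { nrm <- nrm + len1; next }
      for (j in seq_len(nrow(ov))) {
        s2 <- ov[j, ]
        len2 <- s2$end - s2$start + 1L
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
        delta <- min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L)
        num <- num + (minov + delta) / maxov * len1
      }
      nrm <- nrm + nrow(ov) * len1
    }
    data.frame(state = st, numerator = num, normalizer = nrm,
               stringsAsFactors = FALSE)
  }))
  n <- sum(per_state$normalizer)
  if (n == 0) stop("SOV undefined: empty observed annotation")
  list(sov = sum(per_state$numerator) / n,
       length = nchar(pair$observed$states), per_state = per_state)
}

#' Size-weighted average SOV over a query set
#'
#' SOV cannot be pooled residue-by-residue, so per-protein SOV values are
#' averaged with protein size (residue count) as the weight:
#' \deqn{\bar{SOV} = \sum_i size_i \cdot SOV_i / \sum_i size_i.}
#' With equal sizes this reduces to the unweighted mean.
#'
#' @param sizes per-protein residue counts (positive).
#' @param sovs per-protein SOV values in \[0,1\].
#' @return The weighted average SOV.
#' @export
weighted_sov <- function(sizes, sovs) {
  if (!length(sizes)) stop("empty input")
  if (length(sizes) != length(sovs)) stop("length mismatch")
  if (any(sizes <= 0)) stop("protein sizes must be positive")
  sum(sizes * sovs) / sum(sizes)
}

#' Evaluate a set of 8-state predictions on all four accuracy measures
#'
#' Computes micro-average Q8 and size-weighted SOV8 on the 8-state
#' strings, then collapses both strings of every pair with [map_8to3()]
#' and computes micro-average Q3 and size-weighted SOV3.
#'
#' @param pairs8 list of 8-state [ss_pair()] objects.
#' @return An object of class `ssp_evaluation`: list with `q3`, `q8`,
#'   `sov3`, `sov8` (all in \[0,1\]), `n_proteins`, `n_residues` and a
#'   `per_protein` data frame.
#' @export
evaluate_set <- function(pairs8) {
  pairs8 <- as_pair_list(pairs8)
  if (pairs8[[1]]$observed$alphabet != 8L)
    stop("evaluate_set expects 8-state annotation pairs")
  pairs3 <- lapply(pairs8, map_8to3)
  q8 <- q_accuracy(pairs8, "micro")
  q3 <- q_accuracy(pairs3, "micro")
  s8 <- vapply(pairs8, function(p) sov(p)$sov, numeric(1))
  s3 <- vapply(pairs3, function(p) sov(p)$sov, numeric(1))
  per <- q8$per_protein[, c("protein_id", "length")]
  per$q8 <- q8$per_protein$q
  per$q3 <- q3$per_protein$q
  per$sov8 <- s8
  per$sov3 <- s3
  structure(list(q3 = q3$q, q8 = q8$q,
                 sov3 = weighted_sov(per$length, s3),
                 sov8 = weighted_sov(per$length, s8),
                 n_proteins = nrow(per), n_residues = sum(per$length),
                 per_protein = per),
            class = "ssp_evaluation")
}

#' @export
print.ssp_evaluation <- function(x, digits = 4, ...) {
  cat(sprintf("SSP evaluation: %d protein(s), %d residue(s)\n",
              x$n_proteins, x$n_residues))
  cat(sprintf("  Q3   %.*f   Q8   %.*f\n", digits, x$q3, digits, x$q8))
  cat(sprintf("  SOV3 %.*f   SOV8 %.*f\n", digits, x$sov3, digits, x$sov8))
  invisible(x)
}

#' Read annotation pairs from a TSV file
#'
#' Expects columns `protein_id`, `observed`, `predicted` (one protein per
#' row, with a header line).
#'
#' @param path TSV file path.
#' @param alphabet 3, 8, or `NULL` to infer per file (8 if any row uses a
#'   state outside H/E/C).
#' @return List of [ss_pair()] objects.
#' @export
read_ss_pairs <- function(path, alphabet = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "observed", "predicted")
  if (!all(need %in% names(tab)))
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(alphabet)) {
    all3 <- all(grepl("^[HEC]+$", c(tab$observed, tab$predicted)))
    alphabet <- if (all3) 3L else 8L
  }
  lapply(seq_len(nrow(tab)), function(i)
    ss_pair(ss_annotation(tab$protein_id[i], tab$observed[i], alphabet),
            ss_annotation(tab$protein_id[i], tab$predicted[i], alphabet)))
}

#' Pearson correlation
#'
#' Product-moment correlation between two equal-length value vectors,
#' e.g. mean PSSM entropy versus Q3 across reduction levels.
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation coefficient in \[-1,1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Two-group comparison with a normality/variance decision cascade
#'
#' Reproduces the test cascade used for comparing repeated performance
#' measurements of two experimental groups: Shapiro-Wilk normality on each
#' group; if both pass at `alpha`, an F test for variance equality; equal
#' variances give Student's t test, unequal variances Welch's t test. If
#' either group fails the normality check the comparison falls back to
#' Welch's t test, and the branch taken is always reported so the decision
#' path can be audited.
#'
#' @param a,b numeric vectors with at least 3 values each and nonzero
#'   variance.
#' @param alpha significance level for the Shapiro-Wilk and F gates.
#' @return List with `p_value` (two-sided), `test` (`"student_t"` or
#'   `"welch_t"`), `branch` (human-readable decision path),
#'   `shapiro_p` (length 2), and `f_test_p` (`NA` when skipped).
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate group: all values identical")
  sw <- c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
  if (all(sw > alpha)) {
    fp <- stats::var.test(a, b)$p.value
    if (fp > alpha) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      branch <- "normal/equal-variance -> Student's t"
      test <- "student_t"
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      branch <- "normal/unequal-variance -> Welch's t"
      test <- "welch_t"
    }
  } else {
    fp <- NA_real_
    tt <- stats::t.test(a, b, var.equal = FALSE)
    branch <- "non-normal -> Welch's t (fallback)"
    test <- "welch_t"
  }
  list(p_value = tt$p.value, test = test, branch = branch,
       statistic = unname(tt$statistic), shapiro_p = sw, f_test_p = fp)
}
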