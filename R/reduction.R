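#' Percent sequence identity under global alignment
#'
#' Globally aligns two protein sequences with an affine-gap
#' Needleman-Wunsch (Gotoh) routine (match +1, mismatch -1, gap open 2,
#' gap extend 1; compiled, deterministic tie-breaks) and reports identity
#' as 100 x identical aligned positions / length of the shorter sequence,
#' the convention of the greedy incremental clustering tool family.
#' Ambiguity letters (X, B, Z, U, O, J) never count as identical
#' positions. `b` may be a character vector; one identity per element is
#' returned, and the measure is symmetric in its two arguments.
#'
#' @param a a single residue string.
#' @param b one or more residue strings.
#' @return Percent identity value(s) in \[0,100\].
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 75
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != 1L) stop("'a' must be a single sequence")
  if (!nzchar(a) || any(!nzchar(b))) stop("empty sequence")
  ident <- .nw_identity_count(a, b)[1L, ]
  shorter <- pmin(nchar(a), nchar(b))
  pmin(100, 100 * ident / shorter)
}

#' Greedy incremental non-redundant set construction
#'
#' Classic greedy clustering by representative: sequences are visited
#' longest first (ties broken by id, ascending, for reproducibility) and a
#' sequence is retained exactly when its identity to every
#' already-retained sequence is below `h` percent. Every discarded
#' sequence therefore has >= `h`% identity to some retained, longer-or-
#' equal sequence, and the output is a non-redundant set at threshold `h`.
#'
#' @param dataset a [seq_dataset()].
#' @param h identity threshold in percent, 0 < h <= 100; retained pairs
#'   share < `h`% identity.
#' @param identity_fun identity engine: `function(a, b)` returning percent
#'   identities of one sequence `a` against a vector `b`. Defaults to
#'   [pairwise_identity()]; pluggable so external clustering engines can
#'   be adapted for very large production runs.
#' @return The retained [seq_dataset()], in retention (length-sorted)
#'   order.
#' @export
greedy_nr <- function(dataset, h, identity_fun = pairwise_identity) {
  stopifnot(inherits(dataset, "seq_dataset"))
  check_threshold(h)
  d <- sort_by_length(dataset)
  if (nrow(d) < 2L) return(d)
  keep <- logical(nrow(d))
  keep[1L] <- TRUE
  for (i in 2:nrow(d)) {
    ids <- identity_fun(d$residues[i], d$residues[keep])
    keep[i] <- all(ids < h)
  }
  subset_dataset(d, keep, label = sprintf("%s [nr<%g%%]",
                                          attr(d, "label"), h))
}

check_threshold <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0 || h > 100)
    stop("'h' must be a single percent value in (0, 100]")
}

sort_by_length <- function(dataset) {
  ord <- order(-nchar(dataset$residues), dataset$id)
  subset_dataset(dataset, ord)
}

subset_dataset <- function(dataset, i, label = attr(dataset, "label")) {
  seq_dataset(dataset$id[i], dataset$residues[i],
              dataset$description[i], label = label)
}

#' Homology-reduction configuration
#'
#' @param h identity threshold in percent: all output pairs share < `h`%
#'   identity.
#' @param m subset capacity in sequences for the divide-and-conquer pass.
#'   The default of 100000 suits production runs where each subset must
#'   fit a memory-bounded clustering engine; tests use small values.
#' @param seed RNG seed for operations that sample.
#' @return An object of class `reduction_config`.
#' @export
reduction_config <- function(h, m = 100000L, seed = 1L) {
  check_threshold(h)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be a positive integer")
  structure(list(h = h, m = m, seed = as.integer(seed)),
            class = "reduction_config")
}

#' Divide-and-conquer homology reduction of a sequence dataset
#'
#' Produces a non-redundant set at identity threshold `h` from an input
#' too large for a single clustering pass, by processing bounded subsets:
#' \enumerate{
#'   \item sort all sequences by length, descending (ties by id);
#'   \item partition in order into `N = ceiling(n/m)` subsets of capacity
#'     `m`;
#'   \item intra-subset pass: replace each subset by its own greedy
#'     non-redundant set at `h`;
#'   \item inter-subset pass: taking each subset in turn as the invariable
#'     head set, purge every remaining (body) subset of sequences with
#'     >= `h`% identity to any head sequence, then append the head to the
#'     output collection.
#' }
#' Because the head is held fixed while bodies are purged against it, the
#' output coincides, as a set, with a single global greedy pass
#' ([greedy_nr()]) for any subset capacity: both enforce the same
#' longest-first dominance order. The subset machinery exists so that no
#' single clustering step ever holds more than `m` sequences.
#'
#' @param dataset a [seq_dataset()].
#' @param config a [reduction_config()].
#' @param identity_fun identity engine, as in [greedy_nr()].
#' @return The reduced [seq_dataset()]; deterministic given the input,
#'   `h` and `m`.
#' @export
reduce_homology <- function(dataset, config,
                            identity_fun = pairwise_identity) {
  stopifnot(inherits(dataset, "seq_dataset"),
            inherits(config, "reduction_config"))
  h <- config$h; m <- config$m
  d <- sort_by_length(dataset)
  n <- nrow(d)
  if (n == 0L) return(d)
  bounds <- split(seq_len(n), ceiling(seq_len(n) / m))
  subsets <- lapply(bounds, function(i) subset_dataset(d, i))
  # intra-subset reduction
  subsets <- lapply(subsets, greedy_nr, h = h, identity_fun = identity_fun)
  out <- vector("list", length(subsets))
  for (x in seq_along(subsets)) {
    head_set <- subsets[[x]]
    if (x < length(subsets)) {
      for (y in (x + 1):length(subsets)) {
        body <- subsets[[y]]
        if (!nrow(body) || !nrow(head_set)) next
        keep <- vapply(seq_len(nrow(body)), function(i)
          all(identity_fun(body$residues[i], head_set$residues) < h),
          logical(1))
        subsets[[y]] <- subset_dataset(body, keep)
      }
    }
    out[[x]] <- head_set
  }
  res <- do.call(rbind, lapply(out, as.data.frame))
  seq_dataset(res$id, res$residues, res$description,
              label = sprintf("%s [nr<%g%%, m=%d]",
                              attr(dataset, "label"), h, m))
}

#' Seeded random subsampling of a sequence dataset
#'
#' Draws `repeats` uniform samples without replacement (within each
#' sample) from a dataset. The sample size is either given directly
#' (`target_size`) or as a halving exponent `k`, in which case it is
#' `round-half-up(n / 2^k)` — the series used to study how shrinking a
#' PSSM target dataset trades prediction speed against accuracy. By
#' default different repeats may share entries (inter-subset
#' replacement); `strict = TRUE` forbids any overlap across repeats,
#' which is feasible only when `repeats * size <= n`. Repeat `r` uses
#' seed `seed + r`, so each repeat is independently reproducible.
#'
#' @param dataset a [seq_dataset()].
#' @param k halving exponent >= 0 (`k = 0` returns full-size samples).
#'   Exactly one of `k` and `target_size` must be given.
#' @param target_size explicit sample size.
#' @param repeats number of samples to draw.
#' @param seed integer RNG seed.
#' @param strict logical; forbid overlap between repeats.
#' @return List of `repeats` [seq_dataset()] objects, each in original
#'   dataset order.
#' @export
random_sample <- function(dataset, k = NULL, target_size = NULL,
                          repeats = 1L, seed = 1L, strict = FALSE) {
  stopifnot(inherits(dataset, "seq_dataset"))
  n <- nrow(dataset)
  if (is.null(k) == is.null(target_size))
    stop("give exactly one of 'k' and 'target_size'")
  if (!is.null(k)) {
    if (k < 0) stop("'k' must be >= 0")
    target_size <- floor(n / 2^k + 0.5)   # round half up
  }
  target_size <- as.integer(target_size)
  if (target_size < 1L) stop("sample size is zero; reduce 'k'")
  if (target_size > n)
    stop("sample size ", target_size, " exceeds dataset size ", n)
  repeats <- as.integer(repeats)
  if (strict && repeats * target_size > n)
    stop("strict (non-overlapping) sampling infeasible: ",
         repeats, " x ", target_size, " > ", n)
  available <- seq_len(n)
  lapply(seq_len(repeats), function(r) {
    idx <- withr::with_seed(as.integer(seed) + r, {
      available[sample.int(length(available), target_size)]
    })
    if (strict) available <<- setdiff(available, idx)
    subset_dataset(dataset, sort(idx),
                   label = sprintf("%s [sample %d/%d, size %d]",
                                   attr(dataset, "label"), r, repeats,
                                   target_size))
  })
}
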