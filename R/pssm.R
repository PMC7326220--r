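#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the plain-text position-specific scoring matrix written by
#' PSI-BLAST (`-out_ascii_pssm`, BLAST+ 2.6.0 dialect): header lines, then
#' one row per query residue holding the position, the query letter, 20
#' integer log-odds scores, 20 observed probabilities in percent, the
#' per-position information content and the relative pseudocount weight,
#' followed by a trailing K/lambda block.
#'
#' Percentages are converted to fractions. Rows whose percentages do not
#' sum exactly to 1 (PSI-BLAST rounds to integers) are renormalized by
#' their sum. All-zero rows, which PSI-BLAST emits when no homologs align
#' at a position, are replaced by the one-hot distribution on the query
#' residue so that every row is a valid 20-state probability
#' distribution.
#'
#' @param path path to an ASCII PSSM file.
#' @param query_id identifier to attach; defaults to the file name minus
#'   extension.
#' @return An object of class `pssm_profile`: a list with `query_id`,
#'   `residues` (query letters), `log_odds` (L x 20 integer matrix) and
#'   `probs` (L x 20 row-stochastic matrix), columns named by amino acid.
#' @export
parse_pssm <- function(path, query_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  tok <- strsplit(trimws(lines), "\\s+")
  # matrix rows: 1-based position, residue letter, then 42 numeric fields
  is_row <- vapply(tok, function(f)
    length(f) == 44L && grepl("^[0-9]+$", f[1L]) &&
      grepl("^[A-Z]$", f[2L]), logical(1L))
  rows <- tok[is_row]
  if (!length(rows)) stop("no PSSM matrix rows found in ", path)
  pos <- as.integer(vapply(rows, `[`, "", 1L))
  res <- vapply(rows, `[`, "", 2L)
  num <- t(vapply(rows, function(f) {
    v <- suppressWarnings(as.numeric(f[3:44]))
    if (anyNA(v)) stop("non-numeric cell in PSSM row ", f[1L])
    v
  }, numeric(42L)))
  if (!identical(pos, seq_along(pos)))
    stop("PSSM rows are not consecutively numbered from 1")
  # column order of both blocks is taken from the alphabet header line
  hdr <- tok[[which(is_row)[1L] - 1L]]
  if (length(hdr) != 40L || !all(hdr %in% AA_STANDARD))
    stop("unrecognized PSSM column header")
  aa <- hdr[1:20]
  log_odds <- num[, 1:20, drop = FALSE]
  pct <- num[, 21:40, drop = FALSE]
  colnames(log_odds) <- colnames(pct) <- aa
  ord <- match(AA_STANDARD, aa)
  log_odds <- log_odds[, ord, drop = FALSE]
  pct <- pct[, ord, drop = FALSE]
  if (any(pct < 0)) stop("negative probability cell in PSSM")
  probs <- pct / 100
  s <- rowSums(probs)
  zero <- s == 0
  if (any(zero)) {             # no-homolog rows: one-hot on the query letter
    j <- match(res[zero], AA_STANDARD)
    if (anyNA(j))
      stop("all-zero row with non-standard query residue: ",
           paste(res[zero][is.na(j)], collapse = ", "))
    probs[zero, ] <- 0
    probs[cbind(which(zero), j)] <- 1
    s[zero] <- 1
  }
  probs <- probs / s
  structure(list(query_id = query_id, residues = res,
                 log_odds = log_odds, probs = probs),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("pssm_profile '%s': %d residue position(s) x 20 amino acids\n",
              x$query_id, nrow(x$probs)))
  invisible(x)
}

#' Shannon information entropy of a PSSM profile
#'
#' Computes, for each residue position, the Shannon entropy
#' \eqn{S = -\sum_c p_c \log_2 p_c} of the 20-state observed-probability
#' distribution (convention \eqn{0 \log_2 0 = 0}), in bits, together with
#' the profile mean. Entropy quantifies the complexity of the profile: a
#' conserved (near one-hot) position scores near 0 bits, a maximally
#' diverse position scores \eqn{\log_2 20 \approx 4.32} bits. The mean
#' entropy of the profiles of a query set tracks the quality of the PSSMs
#' a target dataset produces, and with it the attainable prediction
#' accuracy.
#'
#' @param profile a `pssm_profile` from [parse_pssm()] or [gen_pssm()].
#' @return An object of class `entropy_profile`: list with `query_id`,
#'   `per_residue` (bits, one value per position) and `mean`.
#' @examples
#' p <- gen_pssm(length = 10, concentration = 1, seed = 1)
#' pssm_entropy(p)$mean
#' @export
pssm_entropy <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  p <- profile$probs
  if (!nrow(p)) stop("empty PSSM profile")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  s <- -rowSums(plogp)
  structure(list(query_id = profile$query_id, per_residue = s,
                 mean = mean(s)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy_profile '%s': %d position(s), mean %.4f bits\n",
              x$query_id, length(x$per_residue), x$mean))
  invisible(x)
}

#' Average PSSM entropy over a query set
#'
#' Pools per-protein entropy profiles into one dataset-level average. The
#' default residue-weighted mode pools all residue positions of all
#' proteins (the micro-average philosophy also used for Q accuracy); the
#' protein-weighted mode averages the per-protein means.
#'
#' @param profiles list of `entropy_profile` objects.
#' @param weight `"residue"` (default) or `"protein"`.
#' @return Mean entropy in bits.
#' @export
dataset_mean_entropy <- function(profiles, weight = c("residue", "protein")) {
  weight <- match.arg(weight)
  if (!length(profiles)) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "entropy_profile")))
  if (weight == "residue") {
    mean(unlist(lapply(profiles, `[[`, "per_residue")))
  } else {
    mean(vapply(profiles, `[[`, numeric(1), "mean"))
  }
}
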