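#' Generate a family of homologous sequences at controlled identity
#'
#' Emulates the redundancy structure of UniRef-style datasets: a random
#' root sequence of the given length plus `n_members` members, each made
#' by substituting `round((1 - within_identity/100) * length)` positions
#' of the root with a different residue (drawn uniformly from the 19
#' other standard amino acids). Member-vs-root identity therefore hits
#' the target to within one position's worth. The background composition
#' is uniform over the 20 standard amino acids.
#'
#' @param n_members members per family (the root is included as the first
#'   record).
#' @param length sequence length in residues.
#' @param within_identity target member-vs-root identity in percent,
#'   0 < within_identity <= 100.
#' @param n_families number of independent families.
#' @param seed integer RNG seed; the generator is seed-deterministic.
#' @param id_prefix prefix for record ids (`<prefix><fam>_<member>`).
#' @return A [seq_dataset()] of `n_families * n_members` records.
#' @examples
#' fam <- gen_family(n_members = 3, length = 50, within_identity = 90,
#'                   seed = 1)
#' pairwise_identity(fam$residues[1], fam$residues[2])
#' @export
gen_family <- function(n_members, length, within_identity,
                       n_families = 1L, seed = 1L, id_prefix = "fam") {
  if (within_identity <= 0 || within_identity > 100)
    stop("'within_identity' must be in (0, 100]")
  if (n_members < 1L || length < 1L) stop("invalid family spec")
  n_sub <- round((1 - within_identity / 100) * length)
  withr::with_seed(as.integer(seed), {
    recs <- lapply(seq_len(n_families), function(f) {
      root <- sample(AA_STANDARD, length, replace = TRUE)
      members <- lapply(seq_len(n_members), function(i) {
        if (i == 1L) return(root)
        m <- root
        pos <- sample.int(length, n_sub)
        m[pos] <- vapply(m[pos], function(orig)
          sample(setdiff(AA_STANDARD, orig), 1L), "")
        m
      })
      data.frame(
        id = sprintf("%s%d_%d", id_prefix, f, seq_len(n_members)),
        residues = vapply(members, paste, "", collapse = ""),
        stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    seq_dataset(recs$id, recs$residues,
                label = sprintf("synthetic %d-family set (%g%% within)",
                                n_families, within_identity))
  })
}

#' Generate an observed/predicted secondary-structure pair
#'
#' Builds an observed string as alternating secondary-structure segments
#' with geometric segment lengths (minimum 1, mean `mean_segment` — the
#' scale of typical secondary-structure elements), then corrupts exactly
#' `round((1 - q_target) * length)` positions to a different state to
#' create the prediction, so the realized per-protein Q accuracy equals
#' `q_target` to within `1/length`.
#'
#' @param length residues.
#' @param q_target target per-protein accuracy in \[0,1\].
#' @param alphabet 3 or 8.
#' @param mean_segment mean segment length in residues.
#' @param protein_id id for the generated pair.
#' @param seed integer RNG seed.
#' @return An [ss_pair()].
#' @export
gen_ss_pair <- function(length, q_target, alphabet = 3L, mean_segment = 7,
                        protein_id = "synth", seed = 1L) {
  if (q_target < 0 || q_target > 1) stop("'q_target' must be in [0,1]")
  states <- switch(as.character(alphabet), "3" = SS3_ALPHABET,
                   "8" = SS8_ALPHABET, stop("'alphabet' must be 3 or 8"))
  withr::with_seed(as.integer(seed), {
    obs <- character(0)
    last <- ""
    while (base::length(obs) < length) {
      st <- sample(setdiff(states, last), 1L)
      seg <- 1L + stats::rgeom(1L, prob = 1 / mean_segment)
      obs <- c(obs, rep(st, seg))
      last <- st
    }
    obs <- obs[seq_len(length)]
    prd <- obs
    n_err <- round((1 - q_target) * length)
    if (n_err > 0) {
      pos <- sample.int(length, n_err)
      prd[pos] <- vapply(prd[pos], function(orig)
        sample(setdiff(states, orig), 1L), "")
    }
    ss_pair(ss_annotation(protein_id, paste(obs, collapse = ""), alphabet),
            ss_annotation(protein_id, paste(prd, collapse = ""), alphabet))
  })
}

#' Generate a synthetic PSSM profile with controlled entropy
#'
#' Draws each residue row from a symmetric Dirichlet distribution (via
#' normalized gamma deviates). Small concentrations give near-one-hot
#' rows (low Shannon entropy, as produced by searches that find few or
#' highly similar homologs); large concentrations approach the uniform
#' distribution (entropy near `log2(20)` bits, the signature of diverse
#' homolog sets). Log-odds are derived from the probabilities against a
#' uniform background, mirroring how a profile's score block relates to
#' its probability block.
#'
#' @param length residue positions.
#' @param concentration positive Dirichlet concentration parameter.
#' @param query_id id for the profile.
#' @param seed integer RNG seed.
#' @return A `pssm_profile`, as from [parse_pssm()].
#' @export
gen_pssm <- function(length, concentration, query_id = "synth",
                     seed = 1L) {
  if (concentration <= 0) stop("'concentration' must be positive")
  if (length < 1L) stop("'length' must be >= 1")
  withr::with_seed(as.integer(seed), {
    g <- matrix(stats::rgamma(length * 20L, shape = concentration),
                nrow = length)
    # guard against all-zero rows from underflow at tiny concentrations
    zero <- rowSums(g) == 0
    if (any(zero))
      g[cbind(which(zero),
              sample.int(20L, sum(zero), replace = TRUE))] <- 1
    probs <- g / rowSums(g)
    colnames(probs) <- AA_STANDARD
    res <- AA_STANDARD[apply(probs, 1L, which.max)]
    log_odds <- round(2 * log2(pmax(probs, 1e-4) / 0.05))
    structure(list(query_id = query_id, residues = res,
                   log_odds = log_odds, probs = probs),
              class = "pssm_profile")
  })
}

#' Write a profile in the PSI-BLAST ASCII PSSM dialect
#'
#' Serializes a `pssm_profile` in the layout produced by
#' `psiblast -out_ascii_pssm` (header, 44-field matrix rows with integer
#' log-odds and integer percentages, trailing K/lambda block), so
#' synthetic profiles exercise [parse_pssm()] end to end. Probabilities
#' are written as rounded integer percentages, reproducing the rounding
#' that makes renormalization on parse necessary.
#'
#' @param profile a `pssm_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  # PSI-BLAST column order
  ncbi <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  lo <- profile$log_odds[, ncbi, drop = FALSE]
  pct <- round(100 * profile$probs[, ncbi, drop = FALSE])
  n <- nrow(pct)
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, and pseudocounted",
    paste0("            ", paste(c(ncbi, ncbi), collapse = "   ")))
  rows <- vapply(seq_len(n), function(i) {
    paste0(sprintf("%5d %s ", i, profile$residues[i]),
           paste(sprintf("%3d", lo[i, ]), collapse = " "), "  ",
           paste(sprintf("%4d", pct[i, ]), collapse = " "),
           sprintf("  %5.2f %9.2f", 0.8, 0.1))
  }, "")
  footer <- c("", "                      K         Lambda",
              "Standard Ungapped    0.1337     0.3176",
              "Standard Gapped      0.0410     0.2670",
              "PSI Ungapped         0.1337     0.3176",
              "PSI Gapped           0.0410     0.2670")
  writeLines(c(lines, rows, footer), path)
  invisible(path)
}

#' Sample noisy points from a performance model curve
#'
#' Supports fit-recovery exercises: evaluates a performance model at the
#' given inputs and adds Gaussian noise of standard deviation `noise_sd`
#' (zero gives exact curve samples).
#'
#' @param model a [size_perf_model()] or [homology_perf_model()].
#' @param quantity `"TC"`, `"Q3"` or `"Q8"`.
#' @param xs inputs (`n_t`, or `c_t` for homology accuracy curves).
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed integer RNG seed.
#' @return Data frame with columns `x` and `y`.
#' @export
gen_perf_points <- function(model, quantity, xs, noise_sd = 0,
                            seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  y <- if (inherits(model, "size_perf_model")) {
    predict(model, quantity = quantity, n_t = xs)
  } else if (inherits(model, "homology_perf_model")) {
    if (quantity == "TC") predict(model, quantity = "TC", n_t = xs)
    else predict(model, quantity = quantity, c_t = xs)
  } else stop("unknown model class")
  if (noise_sd > 0)
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(xs), 0, noise_sd))
  data.frame(x = xs, y = y)
}

#' Write annotation pairs to the evaluation TSV format
#'
#' @param pairs list of [ss_pair()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ss_pairs <- function(pairs, path) {
  pairs <- as_pair_list(pairs)
  tab <- data.frame(
    protein_id = vapply(pairs, function(p) p$observed$protein_id, ""),
    observed = vapply(pairs, function(p) p$observed$states, ""),
    predicted = vapply(pairs, function(p) p$predicted$states, ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
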