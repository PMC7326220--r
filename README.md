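# ssptools

Protein secondary structure prediction (SSP) pipelines spend almost all of
their time running PSI-BLAST against a huge *target dataset* (UniRef90-scale,
tens of millions of proteins) to build the position-specific scoring matrix
(PSSM) that the predictor consumes. The size and the sequence redundancy of
that dataset control both the wall-clock cost and the attainable accuracy:
shrinking the dataset cuts time roughly linearly while accuracy decays only
slowly, and reducing redundancy (homology) at fixed size *raises* accuracy by
making the PSSMs more informative. `ssptools` packages the machinery needed
to study and exploit that trade-off:

- **Accuracy evaluation** — micro-average Q3/Q8 (pooled over residues) and
  the 1999-revision segment-overlap scores SOV3/SOV8, averaged over proteins
  with protein size as the weight:
  `SOV̄ = Σᵢ sizeᵢ·SOVᵢ / Σᵢ sizeᵢ`,
  plus the standard 8→3 state mapping (H,G,I→H; E,B→E; T,S,C→C), Pearson
  correlation, and a Shapiro–Wilk → F-test → Student's/Welch's *t*
  significance cascade for comparing repeated measurements.
- **PSSM quality** — a parser for PSI-BLAST ASCII PSSMs and the Shannon
  information entropy of the profile, `S = −Σ_c p_c log₂ p_c` (bits), whose
  dataset mean tracks prediction accuracy.
- **Target-dataset reduction** — seeded random subsampling in a `1/2^k`
  halving series, and a divide-and-conquer non-redundant (NR) set
  construction that partitions a length-sorted dataset into bounded subsets,
  clusters each greedily, and purges every body subset against an invariable
  head subset, so that no output pair reaches the identity threshold *h*. A
  compiled affine-gap Needleman–Wunsch engine (identity = matches / shorter
  length) backs it, and is pluggable.
- **Performance models** — the fitted speed/accuracy curves
  `TC(n_t) = 2.8658·10⁻⁵ n_t + 5.8248`,
  `Q3(n_t) = 0.1363/(1+e^{(17.0963−log₂ n_t)/2.1447})^{0.6205} + 0.6716`,
  `Q8(n_t) = 0.1281/(1+e^{(15.6095−log₂ n_t)/2.5405}) + 0.5621`
  over dataset size, the homology-series quadratic/cubic models over size
  and identity cutoff `c_t`, and deterministic refitting of all curve forms
  to user-measured points.
- **Synthetic generators** — sequence families at controlled pairwise
  identity, observed/predicted secondary-structure pairs at controlled Q,
  and Dirichlet PSSMs at controlled entropy, so everything is testable
  without downloads.

## Worked example

```r
library(ssptools)

# What does the size model predict for a full 2018 UniRef90 search?
m <- size_perf_model()
predict(m, "TC", n_t = 87.3e6)   # 2507.668  (seconds per query protein)
predict(m, "Q3", n_t = 87.3e6)   # 0.8068    (three-state accuracy)

# Build a redundant synthetic dataset and reduce it to < 80% identity
fam <- gen_family(n_members = 3, length = 60, within_identity = 95,
                  n_families = 4, seed = 1)
nr <- reduce_homology(fam, reduction_config(h = 80, m = 5))
nrow(fam); nrow(nr)              # 12 -> 4 (one representative per family)

# Score a set of 8-state predictions
pairs <- lapply(1:5, function(i)
  gen_ss_pair(length = 200, q_target = 0.8, alphabet = 8,
              protein_id = paste0("p", i), seed = i))
evaluate_set(pairs)
#> SSP evaluation: 5 protein(s), 1000 residue(s)
#>   Q3   0.8360   Q8   0.8000
#>   SOV3 0.4157   SOV8 0.4207
```

Q8 lands on the 0.80 generation target exactly; Q3 is higher because the
8→3 mapping collapses within-class substitutions (e.g. a 3₁₀-helix G
predicted as H stops being an error), and the SOV values are much lower
than Q because the generator corrupts isolated residues, which fragments
segments — exactly the failure mode the segment-overlap measure is designed
to punish harder than per-residue accuracy does.

The same operations are available from a shell via the thin wrapper
`inst/exec/ssptool`, e.g.
`ssptool model eval --eq q3-size --n 87300000` prints `0.807`, and
`ssptool nr-reduce --in seqs.fasta --identity 25 --subset-size 100000
--out nr.fasta` writes a `<25%` identity NR set.

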