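---
title: "Identifying protein sectors by statistical coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying protein sectors by statistical coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectorscan)
```

## The model

A deep multiple sequence alignment of a protein family carries two kinds
of statistical signal at each column: *conservation* (how far the column's
amino-acid composition departs from a background distribution) and
*coupling* (how strongly the composition of one column covaries with
another's). Statistical coupling analysis combines the two: covariances
are weighted by conservation gradients, so that correlated variation
among moderately conserved positions — the signature of functional
constraint acting on a group — dominates the resulting matrix. Groups of
co-evolving positions found this way are called **sectors**. They need not
be contiguous in sequence or space and are distinct from domains.

### Frequencies and regularization

For an alignment of $M$ sequences and $L$ columns over the 20-letter
amino-acid alphabet, raw frequencies are counts over $M$:
$f_i^a = n_i^a / M$ and $f_{ij}^{ab} = n_{ij}^{ab} / M$. Gaps and
non-standard residues (`X`, `B`, `Z`, ...) carry no frequency mass; the
lost mass is compensated by regularization toward the background $q$:

$$f \leftarrow (1-\lambda)\,f + \lambda\,q^a, \qquad
  f_{ij}^{ab} \leftarrow (1-\lambda)\,f_{ij}^{ab} + \lambda\,q^a q^b
  \;(i \neq j),$$

with $f_{ii}^{ab} = f_i^a\,\delta_{ab}$ by construction. The default
$\lambda = 0.03$ keeps every frequency strictly inside $(0,1)$, which the
logarithms below require; the value is small enough to leave conservation
estimates essentially unchanged at $M \gtrsim 100$. The default background
is the average Swiss-Prot composition (`background_frequencies()`),
overridable when a family-specific background is preferred.

### Conservation, weights, coupling

Per-position conservation is the binary relative entropy (in nats)

$$D_i^a = f \ln\frac{f}{q} + (1-f)\ln\frac{1-f}{1-q},$$

with the per-position summary $D_i = \sum_a f_i^a \ln(f_i^a/q^a)$ (full
Kullback–Leibler divergence). The weight applied to each covariance axis
is the magnitude of the conservation gradient,

$$\varphi_i^a = \left|\,\ln\frac{f_i^a(1-q^a)}{q^a(1-f_i^a)}\,\right|,$$

zero at background composition and growing rapidly with conservation. The
weighted covariance tensor
$\tilde C_{ij}^{ab} = \varphi_i^a \varphi_j^b (f_{ij}^{ab} - f_i^a f_j^b)$
is reduced to an $L \times L$ matrix by the Frobenius norm of each
$20 \times 20$ block,
$\tilde C_{ij} = \sqrt{\sum_{ab} (\tilde C_{ij}^{ab})^2}$ — symmetric and
entrywise nonnegative.

The implementation never materializes the dense tensor: the block-sums
split exactly into a sparse pair-count part, rank-two corrections and
dense $M \times L$ cross-products, verified against a straight-loop
tensor oracle to $10^{-10}$ (see `test-acceptance.R`). A single
evaluation at $M=500$, $L=100$ takes ~0.3 s, which the randomization null
below depends on.

### Significance by alignment randomization

The spectrum of $\tilde C$ is compared with the spectra of alignments in
which residues are shuffled independently **within each column**. This
null preserves each column's composition exactly — hence conservation,
and the conservation contribution to the spectrum — while destroying all
inter-column correlation. With `n_rand` trials (default 100), an
eigenvalue is significant when it exceeds the 95th percentile (the
`percentile` parameter) of the null **top** eigenvalues; `k_star` counts
the significant eigenvalues.

A design note on the leading eigenvalue. Classic treatments discard the
first eigenmode outright as a conservation/phylogeny mode. We instead let
the null decide: because the null preserves composition, a leading
eigenvalue that merely reflects conservation is matched by the null tops
and is not counted. This matters in validation worlds where the strongest
mode *is* a sector: with two near-degenerate planted sectors the top two
eigenvalues are both sector modes (e.g. 61.8 and 54.2 against a null
threshold near 15), and both must enter the ICA step for the rotation to
unmix them. On an i.i.d. alignment the true top eigenvalue is
exchangeable with the null tops, so `k_star = 0` with probability about
`percentile` — the calibration the acceptance suite checks across 20
seeds.

### Independent components and sector definition

Near-degenerate sector eigenvalues mix sectors across eigenvectors (the
symmetric/antisymmetric pair of a two-block matrix). A symmetric
fixed-point ICA (tanh contrast, iteration cap 1000, tolerance $10^{-8}$,
seeded initialization; on non-convergence the unrotated eigenvectors are
returned with a warning) rotates the significant eigenspace to axes on
which each sector loads alone. Components are oriented so their
largest-magnitude loading is positive and ordered by their associated
eigenvector.

Membership is decided per component. A Student-t location-scale
distribution is fitted by maximum likelihood to the component's $L$
loadings; positions above the `cutoff_quantile` (default 0.95) of the
fitted distribution are candidates. A fitted distribution — rather than
the empirical quantile — is essential: the empirical 0.95 quantile of
$L = 100$ loadings would cap every sector at 5 positions regardless of
the true sector size.

Candidates are then trimmed at the largest multiplicative break (ratio
> 2 between consecutive sorted loadings), when one exists. The reason is
a systematic artifact: strongly conserved but *uncoupled* positions
acquire small spurious loadings, because their large $\varphi$ amplifies
finite-sample covariance noise and the Frobenius reduction makes all
couplings positive. These positions sit an order of magnitude below
genuine members (≈ 0.02 versus ≈ 0.3 in the benchmark), separated by a
wide gap; the break rule removes them, and when loadings are graded with
no clear break, all candidates are retained. Each candidate joins the one
component where its loading is maximal, so sectors are disjoint; sectors
are labeled red, blue, green, ... in component order.

## Structure mapping and annotation

The ungapped reference sequence is aligned globally (identity scoring,
affine gaps) to the chain sequence taken from the PDB coordinate records
(first model, first alternate location; residue identity = author number
plus insertion code). Author numbering is authoritative for every report,
matching how clinical mutations are named (e.g. G56A). Unresolved
residues are simply absent from the coordinate records, so coverage
(mapped residues / chain residues) reflects what the crystal actually
shows. If more than 5% of paired positions mismatch
(`max_mismatch_fraction`), the reference and structure are deemed to
disagree and mapping fails loudly rather than silently misnumbering.

Mutations are parsed from short substitution form (`G56A`, `R70TER`),
joined to sectors by author residue number, cross-checked against the
mapped reference residue (mismatches are flagged, never dropped), and
classified into user-configured closed-interval regions
(N-terminal / central / C-terminal); outside every region the class is
`"other"`. When no scheme is configured, tertiles of the mapped range are
used and marked as a default. Stop-gain variants are annotated
positionally like missense; interpretation is left to the user. Phenotype
text is carried verbatim — no severity scoring is computed, because that
judgment is interpretive, not algorithmic.

## The synthetic world

`generate_planted_alignment()` draws, per sequence and per sector, a
latent binary state; each sector column emits the state-linked residue
with probability $\rho$ and a background draw otherwise. This two-state
emission model is the simplest generator producing block-correlated
columns detectable by covariance methods; a full Potts sampler is out of
scope. The default benchmark (`two_sector_benchmark()`) is $M = 500$,
$L = 100$, two disjoint 10-column sectors at $\rho = 0.9$, five conserved
columns at level 0.95 — desk-scale yet comfortably above the detection
threshold.

What a green test does and does not establish: the generator produces
independent sequences with all-or-none sector membership and no indels.
Real families carry phylogenetic correlation (partially mitigated by
redundancy clustering, not modeled here), graded membership, and
alignment errors. Recovery of planted sectors validates the machinery —
the algebra, the null calibration, the rotation, the bookkeeping — not
the biological interpretation of sectors in any particular family.

## Numerical choices and degenerate inputs

- $\lambda > 0$ and strictly positive $q$ are enforced wherever logs are
  taken; violations raise an instructive error.
- All-gap columns are rejected by `compute_frequencies()`; they must be
  removed by `drop_gapped_columns()` (which also records the
  original-column index map consumed by structure mapping).
- The reference row is immune to every row filter — all downstream
  position mapping depends on it — and its removal-threshold violations
  warn instead.
- Redundancy clustering is a deterministic surrogate for legacy
  score-based tools: gap-free pairwise identity (matches / longer length)
  and coverage (shorter / longer length), greedy single-linkage with
  merge-on-contact, which equals the transitive closure of the link
  relation regardless of processing order; the longest member (reference
  preferred) represents each cluster.
- All randomness flows from one user seed; `run_sca()` splits it into
  independent sub-seeds for the null and the ICA initialization.
- Eigenvalues are reported in descending order; ties in the greedy
  component-to-eigenvector matching resolve to the lower index.

## Known limitations

- No phylogenetic correction beyond redundancy clustering: shared
  ancestry can masquerade as coupling in real families.
- PDB-format only (no mmCIF); first model, first chain occurrence.
- The alignment itself is an external prerequisite: the package curates
  and analyzes an existing alignment, it does not compute one. The
  optional realignment after column dropping is left to external tools.
- Sector membership is hard (one sector per position, as in published
  sector tables); graded or overlapping membership is not represented.
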