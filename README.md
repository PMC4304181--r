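# sectorscan

Protein **sectors** are groups of amino-acid positions that co-evolve
across a protein family: their correlated variation in a deep multiple
sequence alignment marks functional units that can cut across sequence
domains and 3D neighborhoods. Mutations that cause the same syndrome but
land in different sectors are often associated with different clinical
phenotypes, so clustering disease mutations *by sector* rather than by
domain is a useful analytic lens for clinical genetics and structural
bioinformatics.

`sectorscan` implements the full desk-scale pipeline:

1. **Curation** of an aligned FASTA around a flagged reference sequence:
   redundancy clustering (default 85% identity / 100% coverage),
   gap-heavy row removal, trimming to the reference span, gapped-column
   dropping (with a column index map).
2. **Statistical coupling analysis (SCA)**. With column frequencies
   `f_i^a` regularized toward background `q^a`
   (`f ← (1−λ)f + λq`, λ = 0.03):
   - positional conservation as binary relative entropy
     `D_i^a = f ln(f/q) + (1−f) ln((1−f)/(1−q))` (nats),
   - conservation-gradient weights
     `φ_i^a = |ln[f(1−q) / (q(1−f))]|`,
   - the weighted covariance tensor
     `C̃_ij^ab = φ_i^a φ_j^b (f_ij^ab − f_i^a f_j^b)`, reduced to an
     L×L coupling matrix by the Frobenius norm of each 20×20 block,
   - eigenvalue significance against a null built by shuffling residues
     within every column (conservation preserved, correlation destroyed),
   - independent component analysis (fixed-point, tanh contrast) of the
     significant eigenspace,
   - sector definition by a fitted loading-distribution cutoff, labeled
     red, blue, green, ... in eigenvalue order.
3. **Structure mapping** of alignment columns onto author residue numbers
   of one PDB chain (global alignment of the ungapped reference against
   the chain sequence), with a coverage report.
4. **Mutation annotation**: substitutions such as `G56A` or `R70TER`
   joined to sector labels and N-terminal/central/C-terminal regions,
   producing a publication-style table.
5. **Visualization export**: a PDB copy with the sector ordinal in the
   B-factor column, plus Jmol/PyMOL coloring scripts.
6. **Synthetic data**: planted-sector alignments (two-state latent
   emission model), i.i.d. null alignments and toy PDB files, so the whole
   pipeline is validated without any network access.

## Worked example

```r
library(sectorscan)

# simulated family: 500 sequences x 100 columns, two planted 10-column
# sectors (coupling strength 0.9), 5 conserved columns
sim <- generate_planted_alignment(two_sector_benchmark(), seed = 42)
res <- run_sca(sim$alignment, n_rand = 100, seed = 42)

res$coupling$k_star
#> [1] 2
round(res$coupling$eigenvalues[1:4], 2)
#> [1] 61.76 54.18  4.00  1.49
round(res$coupling$significance_threshold, 2)
#> [1] 14.82
res$sectors
#> Sector assignment over 100 alignment columns
#>   red: 10 positions (2, 10, 18, 26, 34, 42, 50, 58, 66, 74)
#>   blue: 10 positions (6, 14, 22, 30, 38, 46, 54, 62, 70, 78)
#>   unassigned: 80 positions
evaluate_recovery(res$sectors, sim$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

Two eigenvalues stand far above the randomization null (61.8 and 54.2
versus a null 95th percentile of 14.8), so `k_star = 2`; the ICA rotation
separates the two planted sectors, and both are recovered exactly.

Mapping onto a structure and annotating mutations:

```r
ref <- paste0(reference_row(sim$alignment), collapse = "")
generate_toy_pdb(ref, "structure.pdb", start_number = 28)
chain <- read_chain("structure.pdb", "A")
smap  <- map_alignment_to_chain(sim$alignment, chain)
coverage_report(smap, chain)
#> [1] 1

muts <- parse_substitutions("G56A")   # wild type G, position 56, variant A
```

The command line mirrors the same stages:

```sh
sectorscan simulate --preset two-sector --seed 42 --out sim/
sectorscan curate   --alignment sim/alignment.fasta --reference REF \
                    --out curated.fasta
sectorscan sca      --alignment curated.fasta --reference REF \
                    --seed 42 --out results/
sectorscan map      --alignment curated.fasta --reference REF \
                    --pdb sim/structure.pdb --chain A --out map.tsv
sectorscan annotate --mutations muts.tsv --sectors results/sectors.tsv \
                    --map map.tsv --out table.tsv
sectorscan viz      --pdb sim/structure.pdb --chain A \
                    --sectors results/sectors.tsv --map map.tsv \
                    --dialect jmol --out sectors.spt
```

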