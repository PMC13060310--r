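# burialcode

Tools for encoding protein folds as low-dimensional categorical label
channels and measuring how much information each channel needs to pin down a
structure.

## The problem

A protein with N residues has ~2N backbone dihedral degrees of freedom. How
few bits does it take to specify which fold those degrees of freedom adopt?
A classic answer encodes structure as the binary Cα **contact map**

```
c_ij = 1  if  |r_i - r_j| < 8 Å,   0 otherwise
```

over all N(N−1)/2 residue pairs. A much smaller encoding is per-residue
**core identity**: compute each residue's relative solvent accessibility
(rSASA = SASA in the fold / SASA in an extended Gly-X-Gly reference) and set

```
b_i = 1  if  rSASA_i < 0.1,   0 otherwise.
```

`burialcode` implements both channels (plus simplified secondary-structure
and backbone hydrogen-bond-satisfaction channels, and ingestion of external
alphabets such as 3Di strings), scores native/model agreement with the
Matthews correlation coefficient

```
φ = det M / √(r₁ r₂ c₁ c₂)          (2×2 confusion matrix M)
φ = (cs − Σₖ pₖtₖ) / √((s²−Σpₖ²)(s²−Σtₖ²))   (k classes)
```

measures model accuracy with superposition-free Cα **LDDT**, and quantifies
each channel's cost in bits per residue: every label outcome x carries
ι(x) = −log₂ p(x) bits under the corpus frequency p(x), and passing a random
fraction of native labels as restraints spends I = Σ ι(sᵢ)/N bits per
residue. Tracing the flattened-bootstrap Spearman correlation ρ between φ
and LDDT as a function of I gives a ρ-vs-I curve; I\* is the interpolated
information needed to reach ρ = 0.9. Robustness of the burial channel is
probed by randomly flipping native labels, and core composition with the
core hydrophobicity ℋ = (1/N) Σ hᵢbᵢ and its native-minus-model difference
Δℋ.

Because no external structure sets ship with the package, a synthetic
benchmark generator builds idealized coarse backbones (N, Cα, C, O plus one
typed side-chain sphere), compacts them with a crude hydrophobic-collapse
refinement, and perturbs them into decoys with a controlled LDDT spread.

## Worked example

```r
library(burialcode)

bench <- make_benchmark(n_targets = 2, n_decoys = 16, seed = 42)
glance(bench)
#> # A tibble: 1 × 6
#>   n_targets n_decoys n_residues lddt_min lddt_max lddt_bins_occupied
#>       <int>    <int>      <dbl>    <dbl>    <dbl>              <int>
#> 1         2       32        122    0.261        1                 12

curve <- rho_vs_I_curve(bench, "burial", fractions = c(0.1, 0.5, 1),
                        n_repeats = 10, seed = 1)
curve
#> # A tibble: 3 × 5
#>   fraction   n_r i_bits   rho n_draws
#>      <dbl> <int>  <dbl> <dbl>   <int>
#> 1      0.1    12 0.0464 0.228      10
#> 2      0.5    61 0.259  0.634      10
#> 3      1     122 0.514  0.829      10
```

(Output printed by this exact call; the same seeds reproduce it.)
`i_bits` is the information spent per residue and
`rho` the flattened bootstrap Spearman correlation between per-decoy φ and
LDDT — more restraints buy a better ranking of model quality. `autoplot()`
draws any curve, robustness table or binned-Δℋ summary, and
`summarize_channels()` collates I\* across channels.

A thin command-line wrapper is installed under `inst/scripts/burialcode`:

```sh
Rscript inst/scripts/burialcode encode --pdb target.pdb --out labels.tsv
Rscript inst/scripts/burialcode score --native t.pdb --model m.pdb --out scores.json
Rscript inst/scripts/burialcode synth --targets 3 --decoys 40 --seed 7 --out bench/
Rscript inst/scripts/burialcode curve --benchmark bench/bench.json --channel burial --out curve.tsv
```

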