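# rsalor

Unsupervised prediction of mutational effects in proteins from two signals
that together explain a surprising share of what much larger models learn:
**residue conservation** in a multiple sequence alignment (MSA) and the
mutated residue's **relative solvent accessibility** (RSA) in a 3D
structure. The package is aimed at structural bioinformaticians and protein
engineers who want an interpretable, training-free baseline score for every
possible point mutation of a target protein — or who want to rescale the
output of any other predictor by structural burial.

## The model

For target position $i$, let $f_i(a)$ be the weighted, pseudocount-regularized
frequency of amino acid $a$ in the curated MSA. The log-odd ratio

$$\mathrm{LOR}(i, wt, mt) = \log\frac{f_i(wt)}{1-f_i(wt)} -
\log\frac{f_i(mt)}{1-f_i(mt)}$$

is positive when the wild type is more represented than the mutant
(typically deleterious) and exactly antisymmetric. The structural term
scales it by the complement of the residue's RSA (percent, clipped to
[0, 100], from a deterministic Shrake–Rupley SASA calculation normalized by
Tien et al. 2013 reference areas):

$$\mathrm{RSALOR}(i, wt, mt) = \Bigl(1 - \tfrac{\mathrm{RSA}_i}{100}\Bigr)\,
\mathrm{LOR}(i, wt, mt)$$

so core mutations keep their full evolutionary penalty while fully exposed
sites score neutral. Multi-site mutations are scored additively (no
epistasis). There are no free parameters to train.

Before scoring, the MSA is deduplicated and stripped of twilight-zone
homologs (< 35% identity to the target by default), sequences are weighted
by inverse identity-cluster size (threshold 0.80) as in coevolutionary
models, and frequencies get an additive pseudocount (λ = 5). The structure
is mapped onto the target by global Needleman–Wunsch alignment, tolerating
missing residues and homologous templates. See the methods vignette
(`vignettes/rsalor-methods.Rmd`) for every assumption and numerical choice.

## Worked example

The package ships seed-deterministic generators of synthetic alignments and
structures, so a complete run needs no external data:

```r
library(rsalor)

simulate_msa("ex.fasta", length = 20, n_random = 80,
             clusters = list(msa_cluster(4)), gap_rate = 0.05, seed = 42)
target <- read_msa("ex.fasta")$target_sequence
simulate_pdb("ex.pdb", target, mode = "helix")

fit <- rsalor("ex.fasta", "ex.pdb", chain_id = "A")
fit
#> <rsalor fit>
#>   target length: 20  (380 mutations scored)
#>   MSA: 84 records (84 before curation), n_effective 78.44
#>   structure: chain A, 20/20 positions mapped (0 mismatched), identity 1.00

head(tidy(fit), 5)
#> # A tibble: 5 × 10
#>   mutation position aa_wt aa_mt gap_freq wt_freq mt_freq   rsa   lor rsalor
#>   <chr>       <int> <chr> <chr>    <dbl>   <dbl>   <dbl> <dbl> <dbl>  <dbl>
#> 1 T1A             1 T     A       0.0797   0.289  0.0290  67.8  2.61  0.839
#> 2 T1C             1 T     C       0.0797   0.289  0.0465  67.8  2.12  0.682
#> 3 T1D             1 T     D       0.0797   0.289  0.0348  67.8  2.42  0.778
#> 4 T1E             1 T     E       0.0797   0.289  0.0407  67.8  2.26  0.727
#> 5 T1F             1 T     F       0.0797   0.289  0.0415  67.8  2.24  0.720
```

Each row is one candidate mutation: `T1A` replaces the threonine at
position 1 by alanine. `wt_freq`/`mt_freq` are the regularized frequencies
entering the LOR (threonine dominates its column, so every substitution at
position 1 scores positive, i.e. predicted deleterious), `gap_freq` is the
weighted gap fraction of the column, and `rsalor` is the LOR damped by the
site's 67.8% solvent exposure. Multi-site mutations are sums of their
parts:

```r
score_multi(tidy(fit), c("A3G", "R8G", "A3G:R8G"))
#> # A tibble: 3 × 4
#>   mutation n_sites   lor rsalor
#>   <chr>      <int> <dbl>  <dbl>
#> 1 A3G            1  2.70  0.882
#> 2 R8G            1  2.51  1.90
#> 3 A3G:R8G        2  5.21  2.79
```

`glance(fit)` summarizes curation, effective sequence number and mapping
coverage; `autoplot(fit)` draws the position × mutant heatmap;
`rsa_rescale_external()` applies the same RSA complement to any external
predictor's per-mutation scores. A shell front end is installed with the
package (`exec/rsalor`): `rsalor score --msa ex.fasta --pdb ex.pdb
--chain A --out landscape.csv`, with subcommands `rescale` and `fixtures`;
output CSVs are byte-identical across runs and `--threads` settings.

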