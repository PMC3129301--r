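# retroclock

Molecular-clock dating of LTR retrotransposon insertions from LTR–LTR
divergence, with phylogenetic grouping of family members by genome of
origin.

## The problem and who this is for

When an LTR retrotransposon inserts, its two long terminal repeats (LTRs)
are identical copies; afterwards each accumulates mutations independently.
The divergence *D* between the two LTRs of one element therefore dates the
insertion:

> *T* = *D* / (2 *r*)

with *r* the substitution rate per site per year (default 1.3 × 10⁻⁸, the
standard value for plant LTR retrotransposons). *D* is estimated with the
Kimura two-parameter distance — transitions (*P*) and transversions (*Q*)
corrected separately over *n* compared sites —

> *D* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*)

with its delta-method standard error, under complete deletion of gap/`N`
columns.

`retroclock` is aimed at researchers analysing transposable-element families
in plant genomes (the motivating case is the *Fatima* gypsy family across
the A/B/D subgenomes of wheat and its diploid relatives). It covers the
whole desk workflow:

* **`detect_ltrs()`** — find the terminal direct-repeat pair of each element
  by seed-and-extend self-comparison, anchored on the canonical
  5′-TG…CA-3′ motifs;
* **`global_align()`** — exact affine-gap global alignment of the two LTRs
  (C++ Gotoh, deterministic traceback);
* **`date_elements()`** — K2P divergence, standard error, and insertion age
  per element; truncated copies are reported as undatable;
* **`k2p_matrix()` / `neighbor_joining()` / `bootstrap_support()`** —
  distance trees of family members from pre-aligned conserved domains, with
  column-resampling bootstrap supports;
* **`classify_genome_groups()`** — genome-specific vs mixed clades from a
  labelled tree (purity ≥ 0.9, ≥ 5 members, by default);
* **`composition_report()`, `gene_island()`, `gene_density()`,
  `protein_length_from_cds()`, `insilico_pcr()`** — Table-style composition
  accounting of an annotated BAC and ISBP marker checks;
* **`simulate_elements()` / `simulate_family()`** — a seeded K80 simulator
  emitting elements and families with known ground truth.

Everything takes and returns tibbles, chains with the pipe, and has
broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods. Trees are
`ape::phylo` objects.

## Worked example

Simulate five elements that inserted 1.6 million years ago, detect their
LTRs, and date them:

```r
library(retroclock)

sim   <- simulate_elements(5, T_years = 1.6e6, cfg = sim_config(), seed = 42)
ltrs  <- detect_ltrs(sim$seqs)
dates <- date_elements(sim$seqs, ltrs)
tidy(dates)
#> # A tibble: 5 × 6
#>   id          n      D      SE T_mya status
#>   <chr>   <int>  <dbl>   <dbl> <dbl> <chr>
#> 1 elem001  1500 0.0418 0.00539  1.61 dated
#> 2 elem002  1500 0.0397 0.00525  1.53 dated
#> 3 elem003  1500 0.0468 0.00572  1.80 dated
#> 4 elem004  1500 0.0426 0.00545  1.64 dated
#> 5 elem005  1500 0.0468 0.00572  1.80 dated
glance(dates)
#> # A tibble: 1 × 7
#>   n_elements n_dated n_undatable mean_T_mya median_T_mya min_T_mya max_T_mya
#>        <int>   <int>       <int>      <dbl>        <dbl>     <dbl>     <dbl>
#> 1          5       5           0       1.67         1.64      1.53      1.80
```

Each detected LTR pair spans positions 1–1500 and 7501–9000 (the simulated
truth), with ~96% identity — the expected residue of 4% LTR–LTR divergence —
and both TG/CA motifs in place. The per-element ages scatter around the true
1.6 MYA within their standard errors (±~0.2 MY at this LTR length).

Composition accounting of the bundled wheat BAC annotation (113 605 bp):

```r
rec <- read_annotation(system.file("extdata", "bac2383a24_te_table.tsv",
                                   package = "retroclock"))
composition_report(rec, 113605)
#> <composition_report> total 113605 bp
#> # A tibble: 12 × 4
#>    category             copies length_bp fraction_pct
#>    <chr>                 <int>     <dbl>        <dbl>
#>  1 class_I                  11     58604         51.6
#>  2 LTR_retrotransposons     10     57590         50.7
#>  3 gypsy                     6     31708         27.9
#>  4 copia                     3     24316         21.4
#>  ...
#> 10 genes                     5      4913          4.3
#> 12 unassigned               NA     44638         39.3
family_fraction(rec, "Fatima")
#> [1] 47.2
```

Class I elements are 51.6% of the clone, LTR retrotransposons 50.7%, and the
three *Fatima* copies are 47.2% of all LTR-retrotransposon base pairs.

A thin command-line front end over the same functions ships in
`inst/scripts/retroclock.R` with subcommands `simulate`, `detect-ltr`,
`date`, `phylo`, and `compose`.

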