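# magsecretome

Predicted secretome profiling of metagenome-assembled genomes (MAGs).

Microbial genomes interact with their environment through secreted
proteins — extracellular hydrolases that digest polymeric substrates,
outer-membrane transporter components, and redox-active multi-heme
cytochromes. For a cohort of MAGs, `magsecretome` integrates the tabular
outputs of standard annotation tools into a per-genome secreted-proteome
niche profile, for microbial ecologists studying nutrient partitioning
in communities such as activated sludge.

## What it computes

For each protein, a **compartment** from one localization call, the
signal-peptide calls of up to three detectors and the MAG's envelope
type: extracellular (EC), outer-membrane (OM), cell-wall (CW),
periplasmic (PP), cytoplasmic-membrane (CM), cytoplasmic (CY) or
unknown (UNK). EC ∪ OM ∪ CW ∪ PP is the *extra-cytoplasmic* union (the
predicted secretome); UNK proteins whose primary detector calls a signal
peptide form the **UNK+SP** class, treated as likely secreted.

On top of that, four **catabolic-enzyme classifications**:

- *CAZymes* — accepted when called by ≥ 2 of 3 detection methods;
  glycosyltransferases and a fixed biosynthetic exclusion list dropped;
  subtypes GH / CBM / CE / PL by family prefix.
- *Nutrient peptidases* — best peptidase-database e-value ≤ 1e-20, COG
  category E only, glutathione hydrolases excluded.
- *Lipases* — seed-database hit at e ≤ 1e-5 or lipase annotation
  keyword, plus a lipase domain; any PhoD domain vetoes.
- *Nucleases / RNases / nucleotidases* — iterative seed expansion: each
  round, proteome-vs-database hits at e ≤ 1e-10 with a class accept
  domain join the database; domain-negative hits are discarded
  permanently; iterate to convergence (cap 10 rounds).

**Heme profiling** scans every sequence for the canonical heme-binding
motif CxxCH (overlaps counted individually); ≥ 4 sites defines a
multi-heme protein, and secreted motif-bearing proteins are classified
as cytochromes by name, descriptor, domain, or the
heat-shock-plus-multi-heme rule.

**Per-MAG profiles** count every compartment, enzyme class and heme
metric, label MAGs above 0.1% mean relative abundance as abundant, flag
counts > mean + 2 SD across the cohort, correlate UNK+SP with
extra-cytoplasmic counts (Pearson), and rank/cluster orthogroup content
(correlation distance, average linkage, Newick export).

A **synthetic-cohort generator** (`generate_cohort()`) emulates all tool
tables with planted ground truth — compartment proportions, per-category
signal-peptide fractions, homology chains, decoy evidence — so the whole
pipeline is testable without external tools or downloads.

## Worked example

```r
library(magsecretome)

co  <- generate_cohort(cohort_config(seed = 42))   # 20 MAGs x 500 proteins
res <- run_secretome_pipeline(co)
res
#> Secretome profiling result
#>   MAGs: 20  proteins: 10000
#>   extra-cytoplasmic: 697 (7.0%)  UNK+SP: 1932
#>   enzyme calls: 360  multi-heme: 60  cytochromes: 40
#>   UNK+SP vs extra-cytoplasmic: Pearson r = 0.746 (p = 0.000159)
```

697 proteins sit in predicted extra-cytoplasmic compartments and another
1,932 are UNK+SP; the two counts correlate across MAGs (r = 0.746)
because genomes differ in overall secretion propensity. Recovery against
the planted truth is exact for every class:

```r
evaluate_recovery(co$truth, res$catalog)
#>                 class n_truth n_called tp precision recall
#>               cazy_gh      80       80 80         1      1
#>    peptidase_nutrient      60       60 60         1      1
#>                lipase      40       40 40         1      1
#>              nuclease      40       40 40         1      1
#>  multiheme_cytochrome      40       40 40         1      1
#>  ...
```

MAG0018 is a secretion outlier, flagged for several metrics at the
> 2 SD rule:

```r
head(res$flags, 5)
#>             metric  mag_id flag
#>                 EC MAG0018 HIGH
#>                 OM MAG0018 HIGH
#>                 PP MAG0018 HIGH
#>  EXTRA_CYTOPLASMIC MAG0018 HIGH
#>            CAZY_GH MAG0018 HIGH
```

`res$og_ranking` lists orthogroups by total secreted-protein counts
(OG0021 first with 112), and `res$og_clustering` holds the row/column
dendrograms as `hclust` objects and Newick strings.
`write_result(res, "out/")` writes the sorted catalog and profile
tables, the flags, the Newick files and a JSON run manifest;
`write_cohort(co, "cohort/")` materializes a cohort as FASTA + TSV for
the command-line wrapper in `inst/scripts/secretome-profile.R`.

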