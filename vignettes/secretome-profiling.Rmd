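---
title: "Predicted secretome profiling of MAG cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted secretome profiling of MAG cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsecretome)
```

# The problem

Microbial communities interact with their surroundings through secreted
proteins: extracellular hydrolases that break down polymeric substrates
(proteins, polysaccharides, lipids, nucleic acids), surface-bound
transporter components, and redox-active proteins such as multi-heme
cytochromes. For a cohort of metagenome-assembled genomes (MAGs), the
secreted-proteome ("secretome") profile of each genome is a compact
summary of its nutrient-acquisition niche. This package integrates the
tabular outputs of standard annotation tools — subcellular-localization
calls, signal-peptide predictions from up to three detectors,
conserved-domain hits, functional annotations with COG categories, CAZyme
detections, peptidase-database hits, and similarity-search tables — into
per-protein compartment assignments, secreted catabolic-enzyme calls,
heme-binding profiles, and per-MAG count profiles with cohort statistics.

The predictors themselves (localization, signal peptides, domains,
functional mapping) are consumed as emulated tabular inputs and are out
of scope; the package's contribution is the integration, classification
and profiling logic, plus a synthetic-cohort generator with planted
ground truth that makes every stage testable offline.

# Compartment integration

Each protein carries exactly one localization call drawn from the closed
vocabulary `EXTRACELLULAR`, `OUTER_MEMBRANE`, `CELL_WALL`,
`PERIPLASMIC`, `CYTOPLASMIC_MEMBRANE`, `CYTOPLASMIC`, `UNKNOWN`.
Localization tools print different labels for monoderm and diderm
profiles ("Cellwall", "cell wall", "Unknown (multiple localizations)",
…); a versioned normalization table maps them onto the vocabulary and is
idempotent, and the raw label is retained in the catalog. The first four
categories form the *extra-cytoplasmic* union — the predicted secretome.

Proteins with `UNKNOWN` location but a signal peptide called by the
*primary* detector form the `UNK+SP` class, treated as likely secreted.
Only the primary method defines membership: the tri-method evidence is
carried separately as `sp_support` (0–3), because in the emulated
workflow the additional detectors are applied to predicted extracellular
proteins rather than to the unknowns. Compartments must be compatible
with the MAG's envelope: outer-membrane and periplasmic locations exist
only in diderms, cell-wall locations only in monoderms, and archaeal
envelopes are treated as monoderm (their localization profiles lack
OM/periplasm); violations are integrity errors rather than silent
reassignments. Localization confidence scores are accepted as given —
no additional score threshold is applied beyond what the upstream tool
already enforced.

# Enzyme classification rules

All thresholds live in `pipeline_config()`; the defaults are the
published analysis values.

**CAZymes.** A call is accepted when at least `cazy_min_methods = 2` of
the three detection methods (HMM, HotPep-style peptide matching,
DIAMOND-style similarity) agree. Glycosyltransferase (GT) families and
six explicitly listed biosynthetic/cell-wall-recycling descriptions
(lytic murein transglycosylases and relatives) are excluded; surviving
families map to the GH/CBM/CE/PL subtype by prefix. Auxiliary-activity
(AA) families pass the family grammar but belong to none of the four
reported classes and are dropped.

**Nutrient peptidases.** A protein qualifies when its best (minimum)
peptidase-database e-value passes `merops_evalue_cutoff = 1e-20`, its
COG assignment is category E ("Amino acid transport and metabolism"),
and no descriptor annotates it as a glutathione hydrolase. "Mapped to
other categories" is interpreted strictly: a multi-letter COG string
containing E plus anything else is excluded (`cog_mode = "strict"`); a
`"contains"` switch relaxes this to E-among-others. Using the *best*
hit per protein (rather than any passing hit) is a deliberate choice
where the procedure was ambiguous; with a single hit per protein the two
readings coincide.

**Lipases.** Candidates come from two routes: a hit against the lipase
seed database at `lipase_evalue_cutoff = 1e-5`, or a gene-caller
descriptor containing one of the lipase keywords (multifunctional
esterase, lipase, glycerophosphodiester phosphodiesterase;
case-insensitive substring). Candidates are accepted when they carry at
least one domain from the lipase accept list, and vetoed regardless of
other evidence when they carry a PhoD (alkaline phosphatase D) domain.

**Nucleases, RNases, nucleotidases — iterative expansion.** Starting
from a seed database, each round searches the proteome against the
current database at `nuclease_evalue_cutoff = 1e-10`; hits carrying at
least one class-specific accept domain are added to the database, hits
without one are discarded *permanently* (they can never re-enter as
candidates, and because they never join the database they cannot
propagate the expansion). Rounds repeat to convergence with a cap of
`max_expansion_iterations = 10`; reaching the cap emits a warning and
returns the partial result, and each accepted protein records the round
of first acceptance. The accept-domain lists ship as editable, versioned
YAML files under `inst/extdata/rules/` rather than hard-coded constants.
One printed nuclease domain token joins two names with a slash; it is
stored as the two separate domain names, both of which also occur in the
nucleotidase list.

**E-value boundary semantics.** Emulated tool tables print e-values with
two or three significant digits, so cutoff comparisons allow a small
relative slack (`evalue_rel_tol = 0.05`): 1.01e-20 passes a 1e-20
cutoff, while 1e-19 — a full order of magnitude away — does not. This is
a numerical-robustness choice, not a change of threshold.

# Heme-binding proteins and cytochromes

The canonical c-type heme attachment motif C-x-x-C-H is scanned at every
position; the two wildcard positions accept any letter (including
ambiguity codes), the three anchors require literal C/C/H (an `X` does
not match an anchor). Overlapping occurrences are counted individually —
the count is of distinct attachment sites, and individual counting is
the only deterministic reading when sites share a cysteine. Proteins
with at least `multiheme_min_sites = 4` motifs are multi-heme.

A motif-bearing protein is classified a cytochrome if any rule fires:
(i) the gene-caller name contains "cytochrome"; (ii) the functional
descriptor contains "cytochrome" or a respiration-related keyword;
(iii) it carries a cytochrome-type conserved domain; (iv) its
descriptor contains "heat shock protein" *and* it is multi-heme (such
proteins empirically cluster with cytochromes). The respiration keyword
list is open-ended in the source procedure; here it is a configurable
list defaulting to respiration, respiratory, denitrification, nitrate
reductase, oxidase, reductase — flagged as an interpretation. Domain
entries are matched as case-insensitive substrings because the printed
names are truncations of database identifiers ("Cytochrom",
"decahem").

Cytochrome classification is reported for extra-cytoplasmic and UNK+SP
proteins (the secreted-heme analysis); motif counts are computed for the
whole proteome so that periplasmic and cytoplasmic-membrane heme tallies
remain available, and `heme_secreted_only = FALSE` extends
classification to everything.

# Per-MAG profiles and cohort statistics

Profiles count, per MAG, each compartment, the UNK+SP class, the
extra-cytoplasmic union, each enzyme class, and the heme metrics
(multi-heme among EC+OM+CW, multi-heme among UNK+SP, periplasmic and
membrane heme proteins, secreted cytochromes).

*High-count flagging*: a MAG is flagged for a metric when its count
exceeds the cohort mean by more than `flag_sd_multiplier = 2` standard
deviations. The sample standard deviation (n−1) is used — the estimator
was unspecified, and the sample form is the conservative default for a
cohort treated as a sample. The inequality is strict, so an all-equal
metric flags nothing. *Abundance*: MAGs with mean relative abundance
strictly above `abundance_cutoff = 0.1` (%) are labelled abundant;
exactly 0.1 is not abundant, mirroring the strict inequality as printed.
*Correlation*: the per-MAG UNK+SP count against the extra-cytoplasmic
total, Pearson product–moment r with the two-sided t-based p-value
(n−2 df).

*Orthogroups*: membership tables become an orthogroup-by-MAG count
matrix; orthogroups are ranked by descending count sums over a MAG
subset (ties broken lexicographically by id, truncation to
`top_og_n = 100`). The clustering recipe centers and unit-variance
scales rows, uses correlation distance (1 − Pearson r; Pearson is
assumed where "correlation distance" was unqualified, and is the
package's fixed choice) and average linkage (UPGMA) on both rows and
columns. `stats::hclust` provides the linkage; an independent
brute-force average-linkage oracle cross-checks the merge heights in the
test suite. Dendrograms are exported as Newick with merge heights as
node heights. Zero-variance rows or columns have no defined correlation
and are reported as errors naming the offender.

# The similarity engine

External similarity tables in the 12-column tabular layout can drive the
expansion searches directly; a built-in engine with the same contract is
provided for self-contained runs. It computes affine-gap Smith–Waterman
local alignments (BLOSUM62; a gap of length k costs
`gap_open + k * gap_extend` with defaults −11/−1) with a deterministic
traceback (ties prefer diagonal, then vertical, then horizontal; the
optimal end cell is the first in row-major order). Letters without
substitution-matrix rows (U, O) score the matrix minimum. E-values use
the Karlin–Altschul form `E = K·m·n·exp(−λ·score)` with the published
gapped BLOSUM62/11/1 constants (λ = 0.267, K = 0.041) against the actual
supplied database size; bit scores are `(λ·s − ln K)/ln 2`. The search
is exhaustive — no heuristic prefilter skips pairs — so the reported hit
set is exactly the set passing the cutoff. The engine does not attempt
to reproduce any specific aligner's composition-based statistics; test
thresholds for planted hits are therefore placed orders of magnitude
away from decision boundaries.

# The synthetic-data generator

`generate_cohort()` produces a cohort whose *marginal structure* matches
a full-scale activated-sludge data set: compartment fractions
(extracellular 1.9%, outer-membrane 1.6%, cell-wall 0.05%, periplasmic
1.6%, cytoplasmic-membrane 19.9%, unknown 36.1%, of which 32.3% carry a
primary signal peptide) and per-category signal-peptide fractions
(81/73/63/67%). Because real cohorts differ strongly between genomes in
how much they secrete — published per-MAG UNK+SP means span roughly
44 to 1,186 across phyla — each MAG receives a lognormal secretion
propensity factor (sd 0.8 on the log scale, chosen once to reproduce a
~25-fold spread) applied to the secreted categories and the UNK+SP
share, with small per-category jitter so the two are correlated but not
collinear. Rare classes are allocated by cohort-level largest remainder
so that the 0.05% cell-wall class is non-empty even at desk scale. The
default scale, 20 MAGs × 500 proteins, keeps the full suite at
desk-scale runtime while leaving every class populated.

Planted evidence is exact: background sequences are drawn from the 18
residues excluding C and H, so CxxCH motifs occur exactly where planted
(4–9 for multi-heme cytochromes, 4–6 for multi-heme non-cytochromes, 1–3
for low-heme proteins); homology chains are realized as similarity rows
with e-values well below the class cutoffs, linking each member to its
predecessor; signal peptides are planted as table rows, not as realistic
N-terminal sequences, because the detectors are out of scope. Decoy
classes plant true-negative evidence the classifiers must reject:
single-method and GT/excluded-label CAZyme rows, housekeeping (non-E
COG) and glutathione-hydrolase peptidases, a weak-e-value peptidase
class, PhoD-carrying lipase candidates, domain-negative expansion
blockers and proteins that hit only blockers, and multi-heme proteins
without cytochrome evidence.

What passing recovery does and does not show: with noise-free planted
evidence, precision = recall = 1 demonstrates that the classification
logic implements the stated rules exactly — it does not demonstrate
robustness to the score distributions, annotation errors, or chimeric
sequences of real tools, which the generator deliberately does not
simulate (similarity hits are generated graph-first rather than by
sequence evolution, and tool score distributions are modeled only near
the decision thresholds).

# Numerical and degenerate-input choices

One location call per protein is required (duplicates and omissions are
integrity errors). Empty cohorts produce header-only outputs and
NA percentages rather than errors. The flagging rule needs at least two
MAGs, the correlation at least three and non-degenerate variance, and
clustering a 2×2 matrix without zero-variance rows. Output tables are
deterministically sorted by (MAG, protein) and numeric fields printed
with round-trip-exact precision, so identical configuration and seed
give byte-identical catalogs, profiles and Newick files; a JSON run
manifest records the package version, seed and a configuration hash.

# Problem sizes used in the checks

The shipped test suite and the acceptance script run the full pipeline
on the default 20 × 500 cohort (10,000 proteins), the motif scanner
against an independent sliding-window oracle on 1,000 random sequences
of length 50–2,000, the aligner against a pure-R dynamic-programming
oracle on 200 random pairs (length ≤ 60), and the expansion against an
igraph-reachability oracle on 100 random planted graphs. These sizes
exercise every code path and decision boundary while completing in
well under a minute.

# Known limitations

The package classifies from emulated tool tables; it cannot detect
errors made by the upstream predictors. The catabolic-versus-
housekeeping distinction is exactly the stated rule set (COG-E plus
exclusions), no more. Guild labels (PAO, GAO, nitrifier, denitrifier,
filamentous) are user-supplied annotations, not inferred. Non-canonical
heme motifs (CxxxCH, CX15CH) are out of scope, as is any structural
modeling of heme pockets.
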