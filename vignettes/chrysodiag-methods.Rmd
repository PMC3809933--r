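---
title: "Methods and design notes: diagnostics for a cryptic species complex"
author: "chrysodiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes: diagnostics for a cryptic species complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrysodiag)
```

## The scientific setting

The *Penicillium chrysogenum* complex contains four cryptic species —
*P. chrysogenum*, *P. rubens*, *P. chainii* and *P. floreyi* — that cannot
be told apart morphologically. They are separable in multilocus sequence
data (*benA*, *trpC*, *crt1*, *ITS*), where the complex shows a crown
divergence of roughly 0.75 million years under a fixed Eurotiomycete clock
of $\mu = 3\times10^{-9}$ substitutions/site/yr, and the nearest outgroup
species split about 2.75 million years ago. At that depth, species differ by
a handful of fixed substitutions per locus; within-species diversity is an
order of magnitude lower. `chrysodiag` turns those fixed differences into
PCR assays and provides the statistics used to analyse the resulting
isolate surveys.

## Diagnostic sites

A column of a multilocus alignment is *diagnostic* for a target species iff

1. every target-species sequence carries the same unambiguous base, and
2. that base occurs in zero non-target sequences.

Fixation in the target is required: the aim is exclusive detection, and a
primer anchored on a polymorphic column would miss part of the target
species. The scanner is deliberately conservative about partial information:

- by default (`allow_missing = FALSE`) a column containing a gap or IUPAC
  ambiguity code in any counted sequence is skipped — the reader keeps such
  characters on ingest and the scanner refuses to guess;
- with `allow_missing = TRUE` those sequences are ignored column-wise,
  provided at least one target and one non-target sequence remain; however a
  non-target ambiguity code whose set contains the target allele (target T
  against a non-target Y, say) always disqualifies the column, because the
  ambiguous read may hide the target base. Specificity is preferred over
  sensitivity throughout.
- `min_target_depth` (default 2) does not reject thin columns; it flags them
  `low_support`, because real per-species panels can be as small as one or
  two isolates. The design stage skips low-support sites.

Outgroup species can be excluded from the non-target set
(`outgroup_species`, with `include_outgroups = TRUE` to re-include them).
The default excludes them from catalogue targets but the choice of whether
assays must also discriminate against outgroups is surfaced, not assumed;
requiring it can only shrink the site list.

Alignment coordinates are 0-based half-open everywhere in the package.

## Primer design

The 3′-terminal base of a primer must pair perfectly for polymerase
extension, so a primer whose 3′ end sits on a diagnostic column amplifies
only the target species — the standard rationale of allele-specific PCR.
Candidates are enumerated at lengths 17–29 nt (the range observed in
published assays of this kind): forward primers end on the site read on the
plus strand of the target-species consensus, reverse primers end on it read
on the minus strand. Pairs must yield amplicons of 100–200 bp, measured 5′
end to 5′ end inclusive of both primers (so a forward primer anchored at
column $c_f$ with length $L_f$ and a reverse primer whose anchor ends at
$e_r$ give an amplicon of $e_r - (c_f - L_f + 1)$ bases).

Only one primer of a pair must be 3′-anchored on a diagnostic site: short
amplicons frequently cannot span two diagnostic columns, and a single
perfect 3′ mismatch against non-targets already blocks extension. When no
anchored–anchored pair is feasible, anchored primers are paired with
unanchored partners on the opposite strand; anchoring both primers earns a
score bonus instead of being a constraint.

The original assays were designed with commercial software, so every scoring
ingredient here is a package decision, surfaced in `pair_weights()`:

$$\mathrm{score} = -w_{tm}\,|T_{m,f}-T_{m,r}|
  - w_{gc}\,(|g_f-0.5|+|g_r-0.5|)
  + w_{anchor}\,[\text{both anchored}]
  - w_{dimer}\,d_3(f,r)$$

with defaults $w_{tm}=1$, $w_{gc}=2$, $w_{anchor}=5$, $w_{dimer}=1$;
$d_3$ counts consecutive complementary bases where the two 3′ ends appose (a
primer-dimer proxy). Ties break deterministically: smaller amplicon, then
lexicographically smaller forward sequence, so re-running the design is
byte-identical. Two melting-temperature models are provided: the Wallace
rule $2(A+T)+4(G+C)$ (default, adequate for ranking 17–29-mers) and unified
nearest-neighbour thermodynamics (SantaLucia's 1998 duplex parameters,
entropic salt correction $\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$,
defaults 50 mM Na⁺ and 250 nM total primer).

A species with no diagnostic site, or none pairable within the amplicon
bounds, is reported absent with a reason — never an error — since a finite
panel at this divergence occasionally yields no usable site for one species
(about 0.6 expected fixed differences per species per locus; roughly one
simulated complex in sixteen leaves some species without a site).

## In-silico PCR

Binding uses a two-parameter tolerance (`pcr_tolerance()`): at most $m$
mismatches overall (default 2) and zero mismatches within the terminal $k$
bases of the 3′ end (default 3, the clamp). The clamp dominates: it is what
makes the designed assays specific, and loosening $m$ never removes a
binding site (a monotonicity property under test). IUPAC codes in the
template match optimistically — a template Y matches a primer C or T — and
such binding sites are flagged `degenerate` in the output, favouring
sensitivity while keeping the evidence visible. Every forward-site ×
reverse-site combination in the right orientation with a product inside
`length_bounds` (default 50–2000 bp) is an amplicon.

Classification applies the no-overlapping-positives contract per isolate:
exactly one positive assay gives a species call, none gives `"other"`, more
than one gives `"conflict"`; an assay whose template locus an isolate does
not supply is `"untested"` and never positive. On synthetic panels the
designed assays produce zero conflicts and per-assay sensitivity above 95 %
(the expected sensitivity loss is only the chance of a within-species
mutation landing in a primer clamp, about 0.3 % at the default
polymorphism).

## Survey statistics

All count statistics are classical and deliberately plain:

- `chi2_independence()` is the Pearson test with **no continuity correction
  and no exact-test switch**. The published survey analysis was done in a
  spreadsheet, and its printed p-values — including small-count cells —
  reproduce exactly under this choice (all 40 cells of the ratio-comparison
  table match to ±0.001 in the test suite). Cells with expected counts
  below 5 are annotated with a warning note, never silently re-analysed.
- `ratio_comparison_matrix()` builds, for every location pair and each of
  the ratios C:R, C:O, R:O and C+R:O over the columns (chrysogenum, rubens,
  other), the corresponding 2×2 table and applies the independence test;
  pairs with an empty margin get `NA`.
- `chi2_goodness_of_fit()` tests category counts against a fixed ratio
  (mating types against 1:1 being the motivating case).
- `one_way_anova()` and `tukey_kramer()` implement the classical F test and
  the studentized-range post-hoc comparison with the Kramer standard error
  $\sqrt{MSW\cdot\tfrac12(1/n_i+1/n_j)}$ for unequal group sizes. The
  replicate unit is caller-defined (vectors in, groups out): the package
  does not guess how samples were pooled. The survey's two printed ANOVA
  p-values are not reproducible from the published count table alone — the
  per-sample replicate structure (plates and volumes per station) was never
  published — so these two operations are validated against closed-form and
  numerical-integration oracles rather than against those two numbers.
- `exposure_rate()` converts an air-sample colony count into viable conidia
  inhaled per minute, (count / air volume) × tidal volume × breaths per
  minute, with defaults 0.5 l and 15 breaths/min.

## Distances, assignment, and the clock

`pairwise_distance()` offers p, JC69 ($-\tfrac34\ln(1-\tfrac43 p)$, `NA`
when $p \ge 3/4$) and K80 closed forms with *strict pairwise deletion*: any
site where either sequence carries a gap or ambiguity code is dropped for
that pair. The tree software behind the original analysis reported
"maximum likelihood distances" without naming a model; JC69 is the default
approximation here (K80 as an option) and full GTR ML distances are out of
scope. Neighbour-joining trees (via `ape::nj`) are emitted for inspection;
the species call itself is by nearest type isolate per locus, which is
simpler, directly testable, and equivalent on clean data.

Cross-locus concordance decides the overall call: all informative loci must
agree, else `"discordant"`. A locus where the query is exactly equidistant
to two species' nearest types (typically because those types are identical
over the locus) is called by a deterministic lexicographic tie-break and
flagged `ambiguous` — and ambiguous loci are *ignored* by the concordance
verdict, because an uninformative locus cannot veto agreement among
informative ones. At the complex's divergence roughly a quarter of
sister-species loci are identical, so treating ties as evidence would label
most isolates discordant; queries informative at no locus are `"ambiguous"`
overall rather than mis-called.

`node_height_to_years()` is the fixed-clock conversion $t = h/\mu$: a node
height of $2.25\times10^{-3}$ substitutions/site is $7.5\times10^5$ yr and
$8.25\times10^{-3}$ is $2.75\times10^6$ yr at the default rate. Bayesian
species-tree inference itself (the source of such heights and their
credibility intervals) is out of scope; only this deterministic conversion
is implemented.

## The synthetic generator: what it does and does not claim

`simulate_locus_alignments()` evolves each locus by a Jukes–Cantor process
along the fixed species tree
`(outgroup, ((chrysogenum, chainii), (rubens, floreyi)))` with branch
lengths = years × rate. Defaults encode the stated world: crown age
$7.5\times10^5$ yr, within-complex splits at $4.7/4.5\times10^5$ yr (the
mean node ages the dating supports; the branching order itself is weakly
supported, so the topology is configurable), outgroup split
$2.75\times10^6$ yr, rate $3\times10^{-9}$/site/yr, four loci of 450–600 bp,
ten isolates per species. Within-species variation is added as independent
Poisson substitutions per isolate with expected pairwise diversity $\pi =
10^{-3}$ — a deliberate simplification (no coalescent, no recombination, no
indels, no base-composition bias, equal rates across loci even though real
loci differ severalfold). JC rather than HKY is used because the generator's
job is statistical structure, not model fidelity; the substitution model is
isolated in one function and straightforward to extend.

Consequently a green test establishes that the pipeline is correct *given*
clean, ungapped, tree-structured data with rare independent polymorphism; it
does not establish robustness to alignment error, indels, contamination or
intragenic recombination, which real surveys must still assess.

Two estimator notes. Between two species split $T$ years ago the expected
p-distance is $\tfrac34(1-e^{-\tfrac43\cdot 2\mu T}) + \pi$ — the
polymorphism of both isolates rides on top of the divergence — so
`estimate_divergence_time()` uses Nei's net divergence
$d_a = d_{xy} - (\pi_x+\pi_y)/2$, making $\hat T = d_a/(2\mu)$ unbiased for
the configured crown age; the recovery test checks it within three
Monte-Carlo standard errors across replicate simulations. And the 1:1
mating-type test at $n = 24$ has an exact pass probability of
$0.9361$ (binomial enumeration), which is what the generator's calibration
test asserts.

`simulate_isolate_panel()` draws species counts per location from the
configured multinomial, attaches each isolate the multilocus sequences of a
randomly chosen simulated isolate of its species ("other" draws from the
outgroup), and assigns mating types Bernoulli(0.5 by default). Both
generators are fully deterministic given their integer seeds (R's default
Mersenne-Twister stream).

## Numerical and interface choices

- Sequence readers normalise to uppercase and map U→T, nothing else; gaps
  and ambiguity codes are kept, and downstream operations decide their
  semantics. Duplicate ids, empty files and non-IUPAC characters are errors
  naming the offender and position.
- Count-table readers strip rows/columns labelled "total" (they are
  re-derivable marginals) and reject negative or non-integer cells with
  coordinates.
- All selection and agglomeration steps have explicit deterministic
  tie-breaks so identical inputs give byte-identical outputs.
- Distance matrices must be symmetric to 1e-12 for tree building; NJ on an
  additive matrix reproduces the generating tree exactly (tested up to 12
  taxa).
- The CLI (`chrysodiag_cli()`; subcommands simulate / design / scan /
  stats / assign) accepts a key=value config file with command-line flags
  winning on conflict, rejects unknown keys, writes only under `--out`, and
  stamps every artifact with version, seed and a hash of the
  analysis-relevant options.

## Known limitations

- Tm models rank candidates; they are not calibrated predictions of assay
  annealing behaviour, and no thermodynamic amplification efficiency, qPCR
  quantification or touchdown-cycle modelling is attempted. Optimised cycle
  numbers are carried as metadata only.
- The in-silico mismatch model (total + clamp counts) ignores mismatch
  identity and position-dependent penalties beyond the clamp.
- Multi-column haplotype diagnostics and indel-based diagnostics are out of
  scope; so are multiplexing constraints and probe design.
- ANOVA/Tukey–Kramer results depend on the caller's replicate structure;
  the package cannot reconstruct unpublished per-sample layouts.
- Bayesian divergence dating (and its credibility intervals) is not
  reimplemented; the clock conversion assumes the fixed rate it is given.
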