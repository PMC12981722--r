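---
title: "Star-allele calling and metaboliser phenotyping with pgxstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele calling and metaboliser phenotyping with pgxstar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxstar)
```

## The problem

CYP2D6 and CYP2C19 encode liver enzymes that metabolise a large share of
commonly prescribed drugs. Both genes are highly polymorphic, and their
haplotypes are catalogued as *star alleles* (PharmVar nomenclature): a star
allele such as `*2` is defined by a set of *core variants* that must all be
present on one phased haplotype, and finer-grained *suballeles* (`*2.039`)
add non-core variants on top. CYP2D6 additionally shows whole-gene
structural variation: the `*5` allele is a deletion of the entire gene, and
duplications (written `*1x2`) multiply a functional copy.

`pgxstar` takes phased per-haplotype variant calls (the output of long-read
amplicon sequencing pipelines, after alignment and phasing, which are out of
scope here), assigns star alleles and suballeles, combines them with
CNV-amplicon evidence into diplotypes, translates diplotypes into
metaboliser phenotypes, and summarises cohorts with chi-square comparisons
against reference population frequencies.

## Allele definitions and coordinates

Definition tables are plain TSV (`load_definition_table()`, and packaged
tables via `builtin_table()`). Positions are 1-based on the gene reference
sequence (NG_008376.4 for CYP2D6); GRCh38 positions are optional
annotations, never used for matching. Because CYP2D6 lies on the reverse
strand, a gene-reference position and its GRCh38 coordinate must sum to one
gene-wide constant — `check_coordinate_consistency()` verifies this across
the whole table and is run in the test suite as a fixture-integrity check:

```{r}
d6 <- builtin_table("CYP2D6")
check_coordinate_consistency(d6)
```

The packaged tables are *discriminating subsets*, not the full PharmVar
catalogue: each allele carries enough core variants to separate it from
every other catalogued allele (e.g. `*2` = rs16947 + rs1135840; `*4` =
rs1065852 + rs3892097, so `*10` = rs1065852 remains a strict subset). This
is a deliberate desk-scale design: calls are correct *relative to the
packaged catalogue*, and a production deployment would swap in full
PharmVar tables through the same TSV dialect.

## Haplotype matching

`match_haplotype()` scores every non-structural allele by the size of its
core set when the core set is contained in the haplotype's variants, and
picks the largest — the most specific catalogued allele. Ties are broken by
(1) fewer unexplained variants after suballele refinement, then (2) the
lower star-allele number; a residual tie is an error rather than a silent
pick. A haplotype with no complete core set falls back to the default
allele (`*1`); the definition of the reference haplotype is "no catalogued
core set present". This fallback is a documented package choice — manual
curation workflows resolve partial core sets case by case, and no published
rule exists for them. Variants left over after core and suballele matching
are reported as `unexplained`, flagging a candidate novel suballele exactly
the way newly catalogued suballeles arise (a known variant set plus one
extra phased variant).

Matching is exact token matching on `pos:ref>alt`: amplicon consensus
variants are assumed pre-normalised upstream, and no indel-window fuzzing
is attempted.

## Structural alleles and diplotypes

Deletion/duplication evidence arrives as a per-sample flag
(`structural_status()`), mirroring assays in which a separate diagnostic
CNV amplicon — not read depth — detects the event, with phase assignment
taken from input. A deletion replaces the carrier haplotype's call with
`*5` (and a deletion haplotype showing variants is an input inconsistency,
rejected); a duplication suffixes the carrier label (`*1x2`). In frequency
tables a duplication counts as **one** observed haplotype of its own
labelled allele, and a deletion as one haplotype, so the denominator is
always exactly `2 × individuals`.

## Phenotype translation

CYP2D6 uses the standardised activity-score system: each allele carries a
value (1 for `*1`/`*2`/`*33`/`*35`, 0.5 for `*9`/`*41`/`*59`, 0.25 for
`*10`, 0 for `*4`/`*5`/`*6`), a duplication contributes `N ×` its base
value, and the diplotype score is the sum. Bins follow the consensus
convention: poor = 0, intermediate = (0, 1.25), normal = [1.25, 2.25],
ultra-rapid > 2.25. The bin edges are the cited consensus values — the
underlying study tables print scores, not edges.

Uncertainty propagates: any diplotype containing an uncertain-function
(`*71`) or unknown-function (`*108`) allele is classed `uncertain`, never
given a number. The two classes are merged for phenotype purposes, as
published cohort tables do.

CYP2C19 has no activity score. Phenotype is a categorical rule on the pair
of function classes (two no-function = poor; no-function + normal/increased
= intermediate; normal + normal = normal; normal + increased = rapid;
increased + increased = ultra-rapid). Decreased-function CYP2C19 alleles
are deliberately outside the rule table — none occur in the packaged
catalogue — and hit an explicit error rather than a guessed class. For the
same reason the packaged CYP2C19 alleles carry no activity values: the
activity-score invariant enforced is "uncertain/unknown must not have a
value", with presence otherwise optional per gene system.

`reassign_function()` supports what-if analyses: it returns a modified
table copy so a cohort can be re-phenotyped under, say, `*71` treated as
nonfunctional — the reclassification scenario for populations where `*71`
is common:

```{r}
scen <- reassign_function(d6, "*71", "no_function", 0)
phenotype_call("*71/*1", scen)
```

## Cohort statistics

`summarise_cohort()` keeps counts and full-precision frequencies; rounding
to 3 d.p. happens only in `render_allele_table()` /
`render_phenotype_table()`, which mirror the published table layout
(empty phenotype classes render as count 0, frequency 0).

`compare_to_reference()` compares a study allele count against a reference
population frequency via a 2×2 haplotype-count table and Pearson's
chi-square (1 df). Reference sources report `n` individuals, so reference
haplotype counts are `round(freq × 2n)` — the interpretation of `n` as
individuals is a documented choice. Yates' continuity correction and any
multiple-testing adjustment are exposed as options but off by default,
since published per-allele significance stars are conventionally
uncorrected; the test suite asserts the strong (`***`) verdicts are
invariant to the Yates option. A reference frequency of exactly 0 with a
positive study count still gives finite statistics because the table
margins stay positive; a reference that reports no data yields a skipped,
unstarred comparison.

## The synthetic cohort generator

Raw sequence data for the motivating cohort cannot be deposited publicly
for data-sovereignty reasons, so `simulate_cohort()` generates fully
specified stand-ins: each individual draws two allele labels independently
from a star-allele frequency vector (Hardy–Weinberg random mating), labels
may include `*5` and `*1x2`, haplotypes expand to the catalogue's variant
sets, and a configurable per-haplotype rate injects novel variants at
reserved positions (9501–9900) that no catalogued allele uses — so every
downstream novel flag is attributable. A ground-truth ledger records every
sampled diplotype, injection, depth and structural flag, and everything is
reproducible from the seed.

Two modelling simplifications are deliberate. First, at most one structural
allele per individual: the structural-evidence model carries one event per
sample, and under realistic frequencies a double-structural draw has
probability ~4×10⁻⁴, so the second haplotype is redrawn from the
non-structural alleles. Second, per-sample depth is a truncated normal
(default mean 500×, sd 120×) standing in for amplicon coverage; with the
strict >100× QC rule this fails a realistic handful of samples per few
thousand. The generator emulates allele sampling, CNV flags, novel variants
and depth — it does **not** emulate sequencing error, misphasing, hybrid
CYP2D6/CYP2D7 fusion genes, or amplicon dropout, so passing end-to-end
tests demonstrates correctness of the calling logic, not robustness to
noisy consensus sequences.

## Reconstructed cohort

`example_cohort()` provides an explicit per-sample diplotype list whose
marginal allele counts equal the published haplotype counts (270 CYP2D6 /
146 CYP2C19) *and* whose phenotype translation reproduces the published
class counts, including the constraint that 28 uncertain haplotypes occupy
26 individuals (forcing one `*71/*71` and one `*71/*108` pair) and exactly
one `*4/*5` poor metaboliser. The CYP2D6 pairing is further chosen so the
`*71`-to-no-function scenario yields 55/135 intermediate and 5/135 poor —
the reported what-if proportions. Per-sample pairings were never published,
so this is a consistent synthetic reconstruction; all marginal-count
results are invariant to the choice.

## Problem sizes and numerical choices

The test suite enumerates all haplotypes of up to 6 variants over a
10-variant discriminating pool (848 haplotypes) against an independent
exhaustive-search oracle, verifies the chi-square statistic against a
direct Σ(O−E)²/E computation on 100 random tables at 1e−9, and runs the
end-to-end recovery simulation at 5,000 individuals with a 3-binomial-SE
acceptance band per allele — sizes chosen so the whole suite completes in
well under a minute per file while keeping the binomial bands tight.
Frequency normalisation is asserted at 1e−9; all frequency arithmetic is
double precision with rounding only at presentation.

## Known limitations

* Calls are relative to the packaged discriminating catalogue; rare alleles
  outside it surface as novel-suballele candidates rather than named calls.
* Hybrid-gene structural variants and tandem-copy sequence differences are
  out of scope (one label plus suballele notes per duplication).
* The CYP2C19 rule table covers only the function-class pairs that can
  arise from the packaged catalogue.
* Reference-population comparisons inherit whatever ascertainment the
  reference aggregates carry; the package computes the statistics and makes
  no ancestry adjustment.
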