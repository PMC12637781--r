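---
title: "Autozygosity mapping and variant prioritization: models and methods"
author: "autozygr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and variant prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygr)
```

## The problem

In consanguineous families, both parental haplotypes at a locus can descend
from one recent common ancestor. The offspring is then *autozygous* there,
and the genotypes across the region are homozygous — a run of homozygosity
(ROH). Recessive disease alleles carried by the shared ancestor surface as
homozygotes inside such runs, which is why autozygosity mapping is a
powerful prioritization aid in multiplex consanguineous cohorts: a causal
recessive genotype should (i) sit inside an ROH of every affected child,
(ii) be absent from the homozygous state in unaffected siblings, and (iii)
usually fall inside the larger, more recent runs.

`autozygr` implements that reasoning as a pipeline of small, testable
parts: a pedigree model for expectations, a sliding-window ROH caller, an
affected/unaffected ROH segregation step, inheritance-model variant filters
with explicit read-level thresholds, a mutability-based de novo burden
test, and multilocus pathogenic variant (MPV) detection. Because raw
patient exomes from such studies are access-restricted, the package ships a
gene-drop simulator that generates cohorts with *known* autozygous
segments and planted causal variants; every claim the test suite makes is
measured against that ground truth.

## Pedigree expectations

Kinship is computed by the classical recursion — founders mutually
unrelated and non-inbred, `phi(i,i) = (1 + F_i)/2`,
`phi(i,j) = (phi(father_i, j) + phi(mother_i, j))/2` descending the
individual that appears later in a topological order — memoized on
unordered pairs so that deep consanguinity loops stay tractable
(memoization is contract-checked against the naive recursion in the test
suite). `F` of an individual is the kinship of its parents. An unknown
single parent is treated as an anonymous unrelated founder, which keeps
partial pedigrees usable at the cost of underestimating `F` when the
missing parent was actually related.

The expected autozygous burden is `F * G` with `G` the autosomal genome
size in Mb (default 3,200 Mb, the conventional human figure). The
multiplier is `F`, not `2F`: `F` is already the probability that a locus
is autozygous, i.e. the expected autozygous *fraction*. The gene-drop
simulator is the independent check — the long-run mean simulated
autozygous fraction of a first-cousin offspring converges to `F = 1/16`.

The "observed exceeds expected by 2 SD" flag needs a per-family SD that no
convention fixes; we compute it by gene-drop Monte Carlo under each
family's own pedigree (default 200 replicates) and expose it as a plain
argument so a fixed global SD can be supplied instead.

## The gene-drop simulator

Founders receive uniquely labeled haplotypes; each meiosis draws a
crossover count from Poisson(map length in Morgans) without interference,
with breakpoints uniform on the chromosome, under a uniform 1 cM/Mb map.
Interference and map heterogeneity are deliberately omitted: the
quantities this package validates (mean IBD fraction, segment overlap
logic, filter behavior) depend on map length, not on crossover spacing
detail. A child's autozygous truth segments are the maximal intervals
where its two haplotype labels coincide. Haplotypes are stored as
piecewise-constant label tracks, so simulation cost scales with crossover
count rather than genome size.

Two genome presets exist: the 250 Mb toy genome (5 x 50 Mb; all shipped
analyses and tests use it, with problem sizes of 10-50 families chosen so
the full suite runs in minutes) and a 22-autosome human-scale genome
rescaled to 3,200 Mb.

Markers are placed every 20 kb by default and founder alleles drawn from a
Beta(1.2, 3) frequency distribution (mean MAF ~0.29). This emulates the
*informative, polymorphic* marker content that drives ROH detection in WES
data; it is explicitly not a rare-variant site-frequency spectrum, carries
no linkage disequilibrium, and has no machine-specific error profile —
conclusions about ROH detection power on real exomes therefore transfer
only qualitatively. Read evidence is Poisson depth (default 30x) with
Binomial alternate-read counts at per-read error 0.002 (a realistic
post-QC base error), and emitted genotypes are maximum-likelihood calls
from those reads, so the ROH caller and the filters see genuine
genotyping noise. GQ is the phred-scaled likelihood gap between the best
and second-best genotype, capped at 99 — deterministic given the reads;
only its thresholding behavior matters downstream.

Causal configurations are planted by placing alleles on founder
haplotypes, never by overwriting genotypes, so Mendelian consistency is
automatic: a homozygous-recessive plant picks a label for which every
affected child is autozygous, each transmitting parent carries exactly one
copy and no unaffected sibling carries two; compound-het plants pick one
paternal-origin and one maternal-origin label in the same gene; X-linked
plants ride a maternal X label shared by the affected (hemizygous) males;
MPV plants repeat the recessive construction in two genes, optionally
inside one shared segment. When a particular gene drop admits no eligible
placement the drop is redrawn until one exists (an outbred trio therefore
correctly refuses a recessive-in-ROH plant). This conditioning has a
visible side effect worth knowing: families that survive it carry more
autozygosity than the unconditional pedigree expectation (about twice
`F` in the shipped 20-family scenario), so burden comparisons on planted
cohorts show an excess over `F * G` that has nothing to do with hidden
consanguinity. Unconditional gene drops (no planting) remain unbiased and
are what the expectation-recovery tests use. Benign de novo
variants are scattered per proband from a synthetic mutability table whose
per-gene probabilities are proportional to gene length with fixed class
fractions (LoF 0.10, D-Mis 0.20, missense 0.35, synonymous 0.35) — a
deliberately simple stand-in for trinucleotide-context mutability models,
declared synthetic because the coverage adjustment of the real tables is
not reproducible from published information.

## ROH detection and segregation

The caller slides a window of 20 genotyped markers and flags windows with
at most 1 heterozygous call; maximal unions of flagged windows are merged
across gaps up to 100 kb, trimmed to the outermost homozygous marker, and
emitted when spanning at least 1 Mb and 25 markers. Only the 1 Mb floor is
a fixed analysis convention (sub-megabase runs reflect old haplotype
sharing rather than recent consanguinity); the window geometry is chosen
to tolerate sporadic genotyping error at 30x and is fully exposed in
`roh_params()`. Missing genotypes are skipped rather than run-breaking.
The X chromosome is excluded from burden and segregation: hemizygous males
are trivially "homozygous" there, and the 3,200 Mb expectation is
autosomal.

Segregation per chromosome intersects all affected children's ROH and
subtracts every basepair covered by an unaffected sibling's ROH. We
subtract covered basepairs instead of discarding whole intervals because
siblings routinely share *flanking* autozygosity: an unaffected sib's run
overlapping the edge of the affected-shared interval says nothing about
the untouched interior, and whole-interval removal empirically deletes the
causal region in a large fraction of simulated first-cousin families. The
retained output provably shares no basepair with any unaffected ROH
(checked against a per-basepair oracle).

Variant ROH context is ranked against the proband's three largest
segments genome-wide (ties broken by length, then chromosome, then start,
for determinism): `top3`, `smaller_roh` or `outside_roh`.

## Inheritance-model filters

All thresholds live in `default_thresholds()` and are applied in a fixed,
documented order so that every failure reports the *first* violated rule;
relaxing any single threshold can only grow the passing set (a tested
monotonicity property). Population frequencies missing from a panel are
treated as 0 — a novel allele must not be discarded for lack of an entry.
Allele ratio is always `alt / (ref + alt)`.

* **De novo**: Bravo and gnomAD-genome MAF <= 5e-4 (each panel
  separately); proband >= 10 total reads, >= 5 alternate reads, alternate
  ratio >= 20% (>= 28% when alternate reads < 10 — 10 is the boundary, so
  exactly 10 alternate reads uses the 20% rule); each parent >= 10
  reference reads and alternate ratio < 3.5%; exonic or canonical-splice
  consequence; not in a segmental duplication. Missing parents make a
  variant *not evaluable*, which is distinct from failing.
* **Recessive** (homozygous and compound het): MAF <= 1e-3, GME Variome
  MAF <= 0.01, VQSR pass, >= 8 proband reads (probands only — the source
  protocol states the depth rule for probands and we do not extend it to
  parents), damaging class required (LoF, D-Mis, or non-frameshift
  indel). Homozygous candidates demand proband and all affected siblings
  homozygous-alt, genotyped parents heterozygous, and no homozygous-alt
  unaffected sibling. Compound hets require two distinct qualifying
  heterozygous variants in trans as witnessed by parental genotypes; with
  an ungenotyped parent the pair is emitted flagged `phase_unknown`
  rather than silently kept or dropped, and genes with more than two
  qualifying hets emit all trans-consistent pairs flagged `multi_pair`.
* **X-linked**: male hemizygous proband; MAF <= 5e-5, VQSR pass, >= 8
  reads, GQ >= 20, MQ >= 40, the same 20%/28% ratio rule; carrier mother
  heterozygous when genotyped; no unaffected hemizygous-alt male.
* **Damaging classes**: LoF = stop-gain, stop-loss, frameshift indel,
  canonical splice, start-loss; D-Mis = missense with MetaSVM "D" *or*
  CADD >= 20; non-frameshift indels are their own class.
* **Constraint gene set** (for downstream enrichment): missense support
  needs MetaSVM "D" *and* CADD >= 24 *and* gene mis-Z >= 2; LoF support
  needs gene pLI >= 0.9; compound-het pairs need both alleles passing
  independently; genes without a constraint entry are excluded with an
  explicit reason.

Manual IGV-style review is out of scope; the per-variant reason codes are
the audit trail instead.

## De novo burden

The expected count for a class (or gene set) is `2 * N * sum(p)` over the
mutability table — the factor 2 for diploidy, `N` probands. Enrichment is
the one-tailed Poisson upper tail `P(X >= observed)`; per-gene tests run
LoF and D-Mis separately and keep the lower p-value, with Bonferroni
control at `0.05 / (19,365 * 2) ~ 1.29e-6` genome-wide (module and
cell-type regressions use `0.05/17` and `0.05/16`). Recurrence is tested
by redistributing the *observed total* number of DNVs multinomially across
genes in proportion to mutability; the empirical p-value for "some gene
hit >= k times" uses the `(r + 1)/(B + 1)` estimator, which cannot return
zero and is the conservative standard for permutation p-values. The
redistribution conditions on the observed total rather than Poisson-drawing
it; at cohort scale the two nulls are indistinguishable for the recurrence
event, and conditioning matches the phrase "redistributed".

Because the test statistic is discrete, null p-values are super-uniform:
the realized type-I rate at nominal 0.05 sits slightly *below* 0.05. The
calibration tests therefore check the rejection rate against the exact
discrete size (about 0.046 at the shipped cohort scale of 188 probands),
not against 0.05 itself.

## MPV and cohort summary

A family carries multilocus pathogenic variants when its causative tier
spans two or more genes; gene pairs are additionally flagged co-localized
when both supporting variants fall in one segregated ROH segment — the
autozygosity-linkage signature in which a single long shared haplotype
carries two disease genes. `summarize_cohort()` recomputes every
percentage from integer counts with fixed denominators (inheritance
breakdown, MPV and actionable shares over *solved* families; consanguinity
and multiplex shares over *all* families) and renders each one both
half-up-rounded and truncated at two decimals, because published tables
mix the two conventions.

## Gene-set enrichment

`enrichment_regression()` fits `outcome ~ membership + covariates` with a
binomial GLM (IRLS as implemented in `stats::glm`, deviance tolerance
1e-8) and reports the Wald test on the membership coefficient, adjusting
for GC content, gene length and mean expression — the covariates that
confound naive overlap tests because long, GC-atypical, highly expressed
genes are both easier to hit with variants and unevenly distributed across
co-expression modules. Complete separation (e.g. a module containing
every disease gene) is reported as a flagged status, never as a numeric
p-value.

## Numerical and degenerate-input conventions

Internal coordinates are 1-based inclusive (VCF convention); BED output is
0-based half-open. Overlapping ROH within one sample is a hard error in
burden computation, not silently merged. `observed_vs_expected()` refuses
zero-variance differences rather than returning an infinite t. The
genotype-based inbreeding estimator `1 - het / sum(2q(1-q))` requires at
least 100 informative markers and may legitimately go slightly negative at
`F = 0`. Seeded runs are reproducible bit-for-bit; all simulator
randomness descends from the scenario seed.

## What passing tests do and do not show

The simulator validates *internal correctness*: that the caller finds the
segments that exist, that the filters implement their thresholds exactly,
that expectation formulas match the process that generated the data. It
does not validate performance on real exomes — real marker spacing is
irregular, LD makes homozygosity-by-state runs longer, error rates are
context-dependent, and real pedigrees carry unreported loops (which is
precisely why observed ROH burden exceeds pedigree expectations in real
cohorts; the simulator, which knows its pedigrees exactly, shows no such
excess). Quantities that depend on those real-data properties — group
burden p-values, the fraction of families flagged 2 SD above expectation,
the observed split of causative variants across top-3/smaller/outside ROH
— are study observables, not desk-reproducible targets, and the package
makes no claim to reproduce their numeric values.
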