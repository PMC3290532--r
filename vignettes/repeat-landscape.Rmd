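---
title: "Quantifying repeat landscapes from genome survey clone libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat landscapes from genome survey clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
library(dplyr)
```

## The estimation problem

Before whole-genome assemblies, the repetitive fraction of a large plant
genome was commonly surveyed by sampling it: a few thousand random
short-insert clones are screened by hybridization against probes for known
repeat families, and the per-family hit counts are scaled up to the whole
genome. `repeatscape` implements that estimator and everything needed to
validate it in silico, with the *Silene vulgaris* / *S. latifolia* survey
as its worked reference: a library of N = 7,720 clones with mean insert
length 603 bp sampled from a 1C = 1,102.50 Mbp genome.

The estimator has three steps. The library's **genome-coverage fraction**
is

$$ f = \frac{N \bar{L}}{G} $$

(about 0.42% for the reference design; the exact summed insert length is
used when clone lengths are known). A family observed in $c_i$ clones —
one clone counts as one hit, however many repeat units it contains — is
present in

$$ n_i = \left\lfloor c_i / f \right\rfloor $$

copies per genome, and occupies the genome fraction

$$ p_i = n_i \, s_i / G $$

where $s_i$ is the family's mean element size. Two species are compared by
the ratio of their $p_i$ percentages; ratios below 1 mark families more
expanded in species B.

### Why the floor?

"Scaling by the reciprocal of the coverage fraction" leaves the rounding
convention open. We floor the quotient: with $f = 0.0042$ the fixture hit
counts `r paste(silene_hits_sv()$hits, collapse = ", ")` regenerate the
published *S. vulgaris* copy column exactly under flooring (e.g.
$\lfloor 118/0.0042 \rfloor = 28{,}095$ and
$\lfloor 40/0.0042 \rfloor = 9{,}523$), while round-half-up fails on
several rows (it would give 9,524 for the last). The fixture counts were
themselves obtained by inverting the published column under this rule, so
the test states its oracle rather than assuming one.

### Mean element sizes

The $s_i$ used for the genome-fraction step are not printed in the survey
table itself; `silene_element_sizes()` ships the values implied by
inverting $p_i = n_i s_i / G$ on the published rows (≈11.0 kb for
*Retand*, ≈7.0 kb for *Copia*, consistent with full-length elements) and
documents them as derived, not measured.

### What the estimator estimates

The one-clone-one-hit count is a *clone-equivalent* copy number. Three
properties matter for interpreting it, all visible in simulation:

* For elements much longer than the insert ($s_i \gg \bar L$), each hit
  represents one insert-sized piece of the family, so $n_i$ counts
  element-derived clone equivalents, not physical insertions. The
  copy-number scale is exact when an element's detectable footprint equals
  the insert length, i.e. $s_i = 2m$ with $m$ the minimum detectable
  overlap.
* At high library coverage a clone can straddle two copies of a dense
  family yet still count once, so the count saturates slightly; the effect
  scales with the per-clone hit multiplicity and is negligible at
  survey-scale coverage ($f \approx 0.004$ gives corrections < 0.2%), the
  regime the estimator was designed for.
* With several families on the panel, a chimeric clone is assigned only to
  its best-scoring family, so dense families absorb a small share of rare
  families' clones.

The end-to-end recovery test therefore compares estimates against the
estimator's sampling expectation computed from placement truth by a purely
geometric oracle (largest overlap wins, one clone one hit) — that is the
quantity the pipeline should recover without bias — and the
confidence-interval machinery is tested against that same estimand.

### Confidence intervals

The survey reports point estimates only; we add a Clopper–Pearson exact
binomial interval on the per-clone hit probability, transformed through
$n_i = c_i/f$ (bounds floored/ceiled so the point estimate always lies
inside). Exactness costs conservatism at small counts, which is the right
trade-off for hit counts of 2–120.

## Screening model

Filter hybridization is emulated by thresholded local alignment
(Smith–Waterman, affine gaps, defaults match +1 / mismatch −1 / gap open 2
/ gap extend 1): a clone hits a family when some probe aligns with ≥ 80%
identity over ≥ 100 bp of the clone, on either strand. The survey does not
state numeric stringencies, so both thresholds are exposed; the defaults
mimic the stringency of genomic Southern/filter hybridization. A clone
passing for several families is assigned to the best-scoring one (ties:
higher identity, longer overlap, panel order), and assignments whose
runner-up is within 5% of the best score are flagged ambiguous rather than
silently resolved.

For speed, alignment is run only on clones that share an exact 14-mer with
the probe (or its reverse complement), aligned on the seeded strand — a
BLAST-style heuristic. At the default thresholds a true hit carries many
clean 14-mers even at 5% divergence, and the equivalence with exhaustive
alignment on divergent libraries is part of the test suite; `seed_length =
0` disables the filter.

## The synthetic-data generator

`build_genome()` realises a declarative genome: random background of given
GC content plus repeat families placed uniformly at random without overlap
(rejection sampling), each copy independently substituted at the family's
divergence rate and strand-flipped at random. LTR retrotransposons carry a
segment structure (5'LTR, internal domains, 3'LTR with identical LTRs) and
a solo-LTR fraction — the fraction of insertions reduced to a bare 5'LTR,
the relic left by intra-element recombination. Tandem families are placed
as arrays of monomer units. What it deliberately does not model: nested or
fragmented insertions, indel divergence, and chromosome-scale structure
(centromere or subtelomere positioning), so passing recovery tests says
nothing about clustering effects in real genomes; clone sampling is
uniform, so cloning bias against hairpin-forming satellites — a real
phenomenon for this library type — is also out of model.

Clone libraries are error-free verbatim substrings (plasmid inserts are
Sanger-grade; divergence lives in the genome copies), with
truncated-normal insert lengths floored at 50 bp: the reference library
reports only a mean (603 bp) and a sonication range (600–1200 bp), which
are in mild tension, so the mean and spread are both exposed as knobs with
defaults 603/150. A single seed governs everything; per-stage sub-seeds
are derived deterministically, so a rerun with the same configuration is
byte-identical.

### Problem sizes used by the test suite

The recovery studies run at desk scale, chosen so each study completes in
minutes on one CPU while keeping every estimated quantity's Monte-Carlo
error well below its test tolerance: a 1 Mbp genome with two 200 bp
families at true fractions 8% and 1%, 2,000 clones of 300 ± 50 bp, 3%
divergence, 100 replicates for the estimator study; 50 replicates of a
2,500 bp single-copy element read at 4× depth for the profiler; the
packaged demo pipeline uses two 300 kb genomes and 300 clones each.

## Microsatellite scanner

`scan_microsatellites()` reports every maximal perfect tandem run whose
unit is primitive (not itself a repetition of a shorter string) with at
least 3 complete units, over unit lengths 2–4 by default (the classical
perfect-repeat finder's conventions: minimum 3 repeats, unit lengths from
2, configurable up to 100). Choices that the tool family leaves open, and
how this scanner resolves them:

* A trailing partial unit counts toward the run's length in bp but not
  toward its unit count — array sizes are conventionally reported in bp
  (a 50 bp AC array is "50 bp", 25 complete units); summaries emit both
  bp-based and complete-unit-based percentages since the original tool's
  denominator is unstated.
* Each interval is reported once, at its smallest primitive unit length,
  so an AC array is not double-counted in the tetranucleotide class.
* Canonical motifs are the lexicographically minimal rotation *on the
  given strand*; reverse-complement merging is off by default (per-strand
  motif names like AC and TA are conventional in this literature) and
  available via a flag.
* Runs break at N and at IUPAC ambiguity codes; soft-masked lowercase is
  scanned as ordinary sequence; non-IUPAC symbols are an error naming the
  offender.
* Two maximal runs of the same unit length can share up to unit_len − 1
  bases at a junction (…ACACAC**A**CGCGC… ends one run and starts
  another); maximality is kept and the property suite asserts the overlap
  never reaches a full unit.

The scanner is verified against a brute-force oracle (every start × unit
length, extended maximally) on random sequences.

## Copy-number profiling

`map_read_hits()` aligns each read locally against a reference element and
keeps one best hit per read, retained when its Karlin–Altschul E-value
$E = K m n e^{-\lambda S}$ (database size m = total read bp, query size n
= element length) is at most 1e−15. For ungapped ±1 scoring λ solves
$\sum p_i p_j e^{\lambda s_{ij}} = 1$ (λ = ln 3 under uniform base
frequencies); K is kept at the fixed 0.711, and a fixed gapped-mode pair
(1.37, 0.711) is available, since no simple procedure exists for gapped
statistics. `depth_to_copies()` converts per-base hit depth to genomic
copy number by dividing by the read set's expected genome-wide depth,
total read bp / genome size — the normalisation is a stated choice
validated by simulation recovery (a single-copy element profiles at ~1
per window; spiked copy numbers recover with slope 1).

One consequence of best-hit counting deserves emphasis: a reference
element carries **two** identical LTR windows, so reads deriving from all
genomic LTR copies (two per full-length element plus every solo LTR) split
between them. A spike of F full-length and S solo insertions therefore
profiles at an LTR/internal ratio of $(2F+S)/(2F)$ — 2.0 for F = 20,
S = 40 — while counting every significant locus per read would give
$(2F+S)/F = 4$. Either way the LTR windows sit clearly above the internal
region, which is the diagnostic solo-LTR signature; the package follows
the one-best-hit rule so that depth reflects read multiplicity.

`compare_profiles()` aligns two elements globally, reports a windowed
identity track on the alignment coordinate and projects both copy-number
tracks onto it — conserved cores (gag-pol) show as a high-identity central
stripe between divergent LTRs and accessory ORFs.

## Pipeline and outputs

`run_pipeline()` ties the stages together from a YAML configuration (one
or two species blocks, a probe panel, thresholds) and returns per-species
estimates, the hierarchical comparison table, and microsatellite
summaries, plus a manifest with the config hash, seed and package version.
All coordinates in all outputs are 0-based half-open; percentages print at
2 decimals (1 in table-compatibility mode) with half-up rounding, the
convention used throughout for reproducing printed tables. Category
subtotals are summed from unrounded child values; a category supplied with
its own independent count *and* differing child rollup (the published
Gypsy row: 13,112 printed vs 13,808 summed from its subfamilies) keeps
both values with a flag rather than resolving the discrepancy.

## Known limitations

* The estimator's copy numbers are clone-equivalents (see above); genome
  fractions inherit the derived element sizes' uncertainty.
* Probe-based screening only sees families on the panel; the "complex
  genomic probe" arm of the original survey (discovering novel repeats) is
  not modelled.
* E-value statistics use a fixed K; absolute E-values are therefore
  approximate, which is immaterial at a 1e−15 cutoff separating
  hundreds-of-bp matches from noise.
* Genome sizes are consumed in bp; the pg → bp conversion constant is
  explicit (`pg_to_bp()`, default 0.978e9 bp/pg) because the reference
  pairing 1.13 pg = 1,102.50 Mbp implies a slightly different constant.

## A worked example

```{r example}
lib <- silene_library()
est <- estimate_abundance(silene_hits_sv(), silene_element_sizes(),
                          n_clones = lib$n_clones,
                          genome_size_bp = lib$genome_size_bp,
                          f = lib$coverage_fraction)
est |> select(family, hits, copies_per_genome, percent_of_genome,
              ci_low, ci_high)
```

```{r ratios}
pub <- silene_table_published()
compare_fractions(pub$percent_sv[pub$family == "Copia"],
                  pub$percent_sl[pub$family == "Copia"])
```
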