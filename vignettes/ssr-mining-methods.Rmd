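---
title: "Microsatellite mining and marker statistics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite mining and marker statistics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

ssrscape detects perfect microsatellites (simple sequence repeats, SSRs) in
genome assemblies, characterizes the genome-wide SSR landscape, assigns loci
to exonic/intronic/intergenic space, screens marker candidates against
primer-design constraints, and computes marker polymorphism statistics from
diploid genotype tables.  This vignette records the model behind each stage,
the tunable parameters, and the design decisions taken where conventions in
the field genuinely differ.

## Repeat detection model

A microsatellite here is a *perfect* tandem repeat of a 2–6 bp unit.  The
scanner reports every maximal run whose **minimal period** is 2–6 and whose
whole-unit repeat count meets its period's threshold.  The default
thresholds follow the common MISA parameterization for fish genomes:

| period | minimum repeats | minimum tract |
|--------|-----------------|---------------|
| 2 (di) | 6 | 12 bp |
| 3–6    | 5 | 15–30 bp |

Key conventions, all of which the test suite pins down against a brute-force
oracle that inspects every (start, period) pair by direct substring
comparison:

* **Minimal period only.** A run such as `(ATAT)8` is the same tract as
  `(AT)16` and is reported once, under period 2.  Mononucleotide runs are
  never reported and never seed a locus.
* **Maximality and truncation.** A run extends as far as the perfect
  periodicity continues at the character level; the reported locus is then
  truncated to whole units, so `length_bp = period × n_repeats` and the
  spanned sequence equals the unit repeated exactly `n_repeats` times.
* **Overlap resolution.** After the minimal-period rule, runs of different
  periods can still overlap at their edges.  Remaining conflicts are
  resolved leftmost-first, with ties broken by length (longer wins) and then
  by period.  Reported loci therefore never overlap, and the output is
  deterministic and order-independent.
* **N handling.** `N` never matches anything: a run is broken at an `N`,
  and a threshold-passing fragment on either side is kept.  Lowercase
  (soft-masked) residues are uppercased and scanned; IUPAC codes other than
  `N` are mapped to `N` with a warning.
* **Coordinates.** Everything is 1-based inclusive, the convention shared
  by MISA and GFF3; no conversion happens internally.

## Motif canonicalization

Repeat units that are cyclic rotations of one another, or rotations of each
other's *reverse complement*, describe the same tract read in a different
phase or from the other strand.  Each unit is first reduced to its minimal
period, then the class is named by the lexicographically smallest member
(A < C < G < T) of the rotation ∪ reverse-complement-rotation set.  So
`CTA`, `TAC`, `AGT`, `GTA` and `TAG` all report as `ACT`, while `GAT`,
`ATG`, `TGA`, `TCA` and `CAT` report as `ATC`.

A note on strand convention: summaries of this kind are sometimes written
using the plain (unreversed) complement, under which `TGA` would group with
`ACT`.  That convention can never produce `ATC` as a class name, yet `ATC`
is a standard motif category in published top-10 motif tables for fish
genomes; the reverse-complement convention used here (and by the MISA family
of tools) is the one consistent with such tables.

Brute-force enumeration of all `4^k` units, reduced and canonicalized, gives
universes of 4, 10, 33, 102 and 350 classes for periods 2–6.  Observed motif
sets on any input are necessarily subsets of these.

```{r universes}
vapply(2:6, function(k) length(enumerate_motif_classes(k)), integer(1))
```

## Compound SSRs

Two or more loci on one sequence merge into a compound record when each
intervening gap (`next start − previous end − 1`) is **strictly less than**
100 nt.  The strict inequality follows the wording of the protocol this
package operationalizes, even though MISA's own interval semantics are often
stated as ≤; the threshold is exposed (`max_gap`) so either behaviour is a
one-argument change.  Merging conserves loci exactly: the multiset of
members across all records equals the scanner output.

Two counting conventions coexist deliberately, matching how genome-wide SSR
surveys tabulate their results: *landscape* statistics (totals, per-period
and per-motif counts, frequencies, densities) count compound members
individually, while *region* tables count a compound record once, as its own
`compound` category.

## Landscape statistics

With `Mb = 10^6 bp` exactly:

* frequency = loci / Mb,
* density = SSR bp / Mb,
* SSR length = period × repeat count.

Genome-wide surveys sometimes print frequency and density computed over
slightly different denominators (e.g. with and without unplaced scaffolds).
The denominator here defaults to the summed length of the scanned sequences
and can be overridden (`genome_size_bp`), and both statistics are computed
from whichever denominator is chosen; the package does not attempt to guess
a source's denominator.  Size–abundance relationships use the standard
two-sided Pearson test (`stats::cor.test`).

## Genomic-region assignment

From gene/mRNA/exon features the package partitions each sequence into
exon (union of all exon features, across all isoforms), intron (gene span
minus exon union) and intergenic (the rest).  Exon takes precedence where
isoforms disagree, gene spans are `min(start)..max(end)` over a gene's
features, and UTRs are exonic because exon features include them in typical
GFF3; there is no separate UTR category.  A record straddling a boundary is
classified by the category of its **start base** — a single-point rule that
is deterministic and order-independent; a majority-overlap alternative is
available (`boundary_rule = "majority"`, ties resolved exon > intron >
intergenic).  The partition is exact: exon + intron + intergenic widths sum
to the sequence length, a property the tests check per base.

## Marker screening

Candidate markers are SSR loci with usable flanks: up to 250 bp each side
(default; a 100–300 bp product window fits comfortably inside), clipped at
sequence ends.  A candidate is not designable when a flank is shorter than
the minimum primer length plus a 2 nt margin (i.e. < 20 nt) or contains a
run of ≥ 10 `N`s; the margin is this package's choice, small enough not to
discard usable loci and large enough to leave the primer a foothold.

Primer pairs are screened against inclusive constraint windows: length
18–30 nt, Tm 50–60 °C, GC 40–60 %, product 100–300 bp.  Tm is the basic GC
formula `64.9 + 41 × (GC − 16.4) / len` for oligos ≥ 14 nt and the Wallace
rule `2(A+T) + 4(G+C)` below that.  This is deliberate: the screening
contribution is the constraint logic, not thermodynamics, so no
nearest-neighbour model is re-implemented; the formulas are documented,
deterministic, and swappable.  Product size comes from exact string matches
of the forward primer and the reverse complement of the reverse primer on
the template, using the first (lowest-coordinate) occurrence with a warning
when a primer binds more than once.  All violated constraints are reported,
not just the first.

## Polymorphism statistics

For each locus with `N` genotyped diploid individuals and allele
frequencies `p_i` estimated by direct count over `2N` observations:

* `Na` — observed allele count;
* `Ne = 1 / Σ p_i²` — effective allele count;
* `Ho` — fraction of genotyped individuals with two different alleles;
* `He = (2N / (2N − 1)) (1 − Σ p_i²)` — expected heterozygosity with
  Levene's small-sample correction.  The correction is the default because
  the classic software whose outputs these tables mirror (Popgene) reports
  unbiased He — and on published nine-marker tables the printed He and Ne
  columns are mutually consistent *only* under this correction, which the
  test suite verifies row by row to ±0.0002 at N = 29.  The uncorrected
  `1 − Σ p_i²` is available via `unbiased = FALSE`;
* `I = −Σ p_i ln p_i` — Shannon's information index;
* `PIC = 1 − Σ p_i² − Σ_i Σ_{j>i} 2 p_i² p_j²` — Botstein's polymorphism
  information content (PowerMarker convention), computed stably as
  `1 − s2 − (s2² − s4)` with `s2 = Σ p²`, `s4 = Σ p⁴`.

Missing genotypes drop the individual from that locus's `N` (no
imputation), and a half-called genotype counts as missing.  Allele identity
is the integer fragment length; no binning or stutter correction is applied
because genotypes are assumed pre-called.  A marker is "highly informative"
when `PIC > 0.5`, strictly.  Cross-species transferability is simply
`100 × amplified / tested`, reported to 2 decimals.

## The synthetic genome generator

Real assemblies are hundreds of Mb; the generator builds desk-scale genomes
in which *every* repeat is known, so precision and recall are measurable
exactly rather than estimated:

* **Background** is i.i.d. sequence at a chosen GC fraction (default 0.40,
  a typical teleost value), scanned and locally regenerated until the
  scanner finds nothing that is not planted.  Junction bases flanking each
  planted repeat are adjusted so a run cannot extend into the background.
  A final scan-and-repair loop guarantees the scanner output equals the
  truth table exactly.
* **Planted loci** default to 2,000 across 24 chromosomes of 200 kb, with
  a dinucleotide-dominated period mix (~77/16/6/1/0.3 % for periods 2–6), a
  region mix of ~8.6/56.9/34.5 % exon/intron/intergenic, and repeat counts
  between each period's threshold and 15 — numbers chosen once to mirror
  the shape of genome-wide SSR surveys of marine fish.  Loci are kept
  ≥ 200 nt apart (beyond the 100 nt compound window) so they stay
  standalone; a dedicated fixture generator plants two loci at any exact
  gap for compound boundary testing.
* **Gene models** are a regular lattice (up to 10 genes per chromosome,
  4 × 400 bp exons separated by 600 bp introns); the request is an upper
  bound and is scaled down on short chromosomes.
* **Genotypes** are drawn allele-by-allele from given frequency vectors
  (Hardy–Weinberg), with optional per-genotype missingness; the default
  panel size of 29 individuals matches a typical wild validation panel.
* A single seed drives all randomness; equal seeds give byte-identical
  FASTA/GFF3/TSV outputs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: interrupted/imperfect repeats, indel polymorphism
in flanks, sequencing stutter, GC heterogeneity along chromosomes, repeat
families beyond microsatellites, and realistic gene architecture.  Perfect
recovery on synthetic genomes validates the implementation, not the
biology of any particular assembly.

## Verification strategy and problem sizes

The test suite (testthat, 3rd edition) checks every stage at these sizes,
chosen to keep a full run in the low minutes on one core:

* detector–oracle equivalence on 1,000 random 2 kb sequences (acceptance)
  plus 150 shorter ones (unit), against an independently written
  brute-force oracle;
* planted recovery and region-label agreement on the full 24 × 200 kb /
  2,000-locus genome;
* exhaustive canonicalization checks for periods 2–4; universe sizes by
  enumeration for 2–6;
* published nine-marker panel reproduction (totals, means, standard
  deviations, PIC > 0.5 count, He↔Ne consistency);
* Hardy–Weinberg recovery: 200 replicates at N = 29 per frequency vector
  (He unbiased within 3 Monte-Carlo standard errors) and frequency
  convergence at N = 10⁴ (|p̂ − p| < 0.01).

`scripts/acceptance.R` recomputes the headline quantities from scratch
against the installed package and writes them as JSON.

## Known limitations

* Imperfect/interrupted repeats and mononucleotide runs are out of scope.
* The scanner is plain R (vectorized per period); it is comfortable at
  tens of Mb but a 680 Mb assembly is better processed chromosome by
  chromosome.
* Tm is a screening estimate, not a thermodynamic prediction; real primer
  design should hand the extracted flanks to Primer3.
* Region assignment is strandless and has no promoter/flanking-window
  categories.
* No Hardy–Weinberg exact tests, F-statistics, linkage disequilibrium or
  null-allele estimation; the popgen module reproduces marker-descriptive
  statistics only.
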