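---
title: "Methods and models behind mitomir"
author: "mitomir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind mitomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomir)
```

`mitomir` implements a complete in-silico discovery chain for candidate
microRNA in small genomes — inverted-repeat detection, hairpin folding and
filtering, physicochemical characterization, target scanning, homology
search, and multi-tool site intersection — as one auditable code base.
This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions taken where the classical web-server pipeline left
the procedure under-specified.

## Coordinates and alphabets

Every interval in the package is 1-based and inclusive, so a mature miRNA
spanning positions `s..e` has length `e − s + 1`; this is the convention
under which published mature lengths of 19–22 nt reproduce from printed
start/end coordinates. BED output converts to 0-based half-open and GFF3
stays 1-based inclusive (both via `rtracklayer`). `U` is accepted on input
and normalized to `T` so that one alphabet serves all dynamic programs;
FASTA output can re-emit RNA with `rna = TRUE`. Mitochondrial genomes are
circular, but the discovery chain treats them as linear by default —
wrap-around extraction exists (`extract_interval(..., wrap = TRUE)`) and
must be requested explicitly, because the classical pipeline ran every tool
on the linear reference record.

## Inverted repeats

`find_inverted_repeats()` scores stems between a left arm and the reverse
complement of a right arm with the einverted-style scheme: +3 per
complementary column, −4 per mismatch, −12 per gapped column, report
threshold 10, maximum repeat span 500 nt. Design choices worth stating:

* **Linear gap penalty.** The classical parameterization prints a single
  gap number, so the penalty is 12 per gapped column with no separate
  open/extend.
* **Banded exactness.** The DP cell `(i, j)` holds the best stem whose
  innermost columns consume positions `i` and `j`. Because the outermost
  pair of a repeat is its widest column, restricting the band to
  `j − i + 1 ≤ 500` enforces the span cap *exactly*, not approximately.
* **Redundancy suppression.** Local DPs produce nested local maxima;
  reports are accepted in order of decreasing score, and a candidate is
  dropped when either arm overlaps the corresponding arm of an accepted
  repeat by more than 50% of its length (configurable). No claim is made to
  reproduce another implementation's report list byte-for-byte; the test
  suite instead proves that the best attainable score matches an
  independent split-alignment oracle on random genomes.
* **Window band.** Precursor windows are the full repeat spans filtered to
  `span_band = (60, 150)` nt, operationalizing a "~120 nt" precursor
  target. The band is a calibrated guess: the filter separating repeats
  from precursor-sized windows was never specified numerically in the
  classical chain, so the default is a documented, configurable choice, and
  `calibrate_reference()` recomputes repeat/window counts from a local copy
  of a reference genome for users who wish to tune it.

## The folding model

`fold_mfe()` is an exact Zuker-style DP over pseudoknot-free structures:
stacks, hairpin loops (minimum loop 3 nt), bulges, internal loops
(two-sided size ≤ 30, the standard restriction), and affine multiloops
(`3.4 + 0.4·branches + 0.0·unpaired` kcal/mol; the closing pair counts as a
branch). There are no dangles or terminal-pair corrections. The
nearest-neighbor stack table uses Turner-style Watson–Crick free energies
at 37 °C; stacks involving G:U wobble pairs are mapped to their A:U
analogues plus a fixed 0.7 kcal/mol destabilization per wobble pair, capped
at −0.1 kcal/mol so every canonical stack remains stabilizing. Loop
penalties are tabulated to size 30 and extrapolated as
`E(30) + 1.75·R·T·ln(L/30)`.

The table is data, not code: `fold_model()` builds it, any entry can be
overridden, and `write_fold_model()`/`read_fold_model()` round-trip the
model through YAML. The package deliberately reports only the single MFE
structure — no suboptimal ensembles, partition functions, or pair
probabilities — because the discovery chain only consumes the MFE fold.

Two implementation details matter for reproducibility. First, tie-breaks
are fixed-order (hairpin before two-loop before multiloop; exterior prefers
the unpaired extension), so folding is deterministic. Second,
`structure_energy()` evaluates an explicit dot-bracket by loop
decomposition under the same model; the test suite enumerates *all*
structures of short sequences and verifies the DP optimum equals the
enumerated minimum, which pins the DP and the evaluator to the same energy
function.

## Real-vs-pseudo filtering

Classical pipelines delegate the real/pseudo pre-miRNA call to trained
classifiers behind web servers (a random forest, structure-alignment and
SVM scorers). Those models are not redistributable, so `mitomir` replaces
them with a transparent rule filter and keeps the features:

* **single terminal loop** (a hairpin, not a multi-loop structure), with at
  least 16 paired bases and a loop of 3–30 nt;
* **MFE ≤ −18 kcal/mol**;
* **shuffle P ≤ 0.05**, where
  `P = (1 + #{MFE_shuffle ≤ MFE_observed}) / (n + 1)` over `n`
  dinucleotide-preserving shuffles (default 1000, seeded; the add-one form
  keeps `0 < P ≤ 1`).

Shuffles preserve dinucleotide composition via the Altschul–Erikson
Eulerian-walk construction because stacking — hence MFE — is a dinucleotide
property; mononucleotide shuffles would overstate significance. The
32-dimensional triplet structure–sequence features (central base × local
paired/unpaired pattern) are computed and exported for every window so
users can substitute their own classifier.

A consequence worth understanding: windows reach the filter *because* an
inverted repeat was found there, so they are pre-selected for
self-complementarity and some random windows will legitimately pass
(the classical chain also pruned 110 windows to 6 candidates only with
additional evidence). The filter's operating characteristics are therefore
tested on planted-versus-shuffled fixtures, not asserted as a universal
false-positive rate. The mature arm is chosen by sliding a 21-nt window
(19–22 accepted) along each stem arm and maximizing paired positions,
tie-breaking to the 5′-most window — the classical chain never specified
this step, so it is deliberately simple and deterministic.

## Physicochemical properties

Molecular weight is the oligonucleotide-calculator formula
`Mw = An·329.21 + Un·306.17 + Cn·305.18 + Gn·329.21 + 159.0` g/mol (the
constant is the 5′ triphosphate, counted once per molecule; T counts as U).
%GC and %AU partition the sequence exactly. The annealing free energy of a
sequence with its perfect complement is computed as `ΔG = ΔH − TΔS` from an
RNA nearest-neighbor ΔH/ΔS step table with a duplex initiation term,
evaluated at 298.15 K by default. The thermodynamic definition printed in
oligo calculators (`δG = RT ln([RNA·template]/[RNA][template])`) is a
definition rather than an algorithm; the nearest-neighbor sum is the
standard way to evaluate it, and the stated standard conditions (50 nM
strand, 50 mM Na+, pH 7.0) are recorded in the report rather than used for
salt corrections. Exact numeric agreement with any particular web
calculator is not claimed.

## Target scanning

`predict_targets()` is a two-phase scan. Phase 1 scores 5′-weighted
complementarity by local alignment of the miRNA against each target strand
(antiparallel): Watson–Crick +5, G:U wobble +1, mismatch −3, with scores at
miRNA positions 2–8 multiplied by `w = 3` (position 1 unweighted, per the
seed convention); gaps cost `open + extend·length` and are never weighted.
The miRanda-scale base scores are adopted because the published cutoff
`S ≥ 150` is only meaningful on that scale — a perfect 22-mer scores
`15·5 + 7·5·3 = 180`. The printed gap penalties (open 2.0, extend 8.0) are
used exactly as printed even though extend > open is unusual for affine
schemes; the package flags the configuration in a message and supports both
orderings via configuration, treating the printed values as authoritative.

Phase 2 evaluates each surviving site with an RNAhybrid-style
intermolecular duplex DP — only miRNA-to-site pairs, no intramolecular
structure — under the same stack/loop tables as the folding model, with an
option to disallow G:U in the seed. `ΔG = −25.00 kcal/mol` is interpreted
as the cutoff `ΔG ≤ −25` since it is listed among cutoff values. Sites must
pass both filters; the invariant is re-checked on every run, not only in
tests. Cross-species conservation weighting and pattern-discovery style
site inference are out of scope; externally produced site lists can be
imported as TSV for the intersection stage instead.

## Homology search

`homology_search()` follows the BLAT DNA-mode design: an index of the
*nonoverlapping* 11-mers of the target genome (grid positions 1, 12, 23, …)
on both strands, with words occurring more than 8 times masked as
repeat-heavy; query k-mers are looked up, and each seeded diagonal is
extended ungapped to its maximal match−mismatch segment. Hits require
identity ≥ 0.95 and length ≥ 20. The grid gives the classical guarantee by
pigeonhole: any exact match of length ≥ 2k − 1 = 21 contains a full grid
word and is always found, while 20-mers placed to straddle grid words can
be missed — the tests construct both cases. Extension is ungapped because
the intended queries are ≤ 25-nt mature miRNAs; gapped stitching of long
alignments is out of scope. Best hits per (query, genome) break ties by
identity, then length, then start. Strand is searched and reported on both
sides; no assumption is made about which genome strand hosts a miRNA.

## Intersection and annotation

"Tools agreeing on a binding site" is operationalized as single-linkage
clustering of site intervals pooled across tools, linking two sites when
they overlap by ≥ 1 nt (the minimum overlap is configurable); a cluster's
interval is the union of its members, and only clusters containing ≥ 2
distinct tools count as shared. Because narrative descriptions of shared
counts are ambiguous between site-level and cluster-level counting, the
Venn summary exports both (`pairwise_clusters` and `pairwise_sites`).
Clusters do not require distinct miRNAs — the same miRNA predicted at the
same locus by two tools is a legitimate shared site. Gene annotation is
plain 1-based inclusive interval intersection; genes sharing a single
boundary position (e.g. an ATPase subunit gene ending at the position where
a cytochrome oxidase gene begins) both count when a site covers that
position, and sites hitting no gene are labeled intergenic. The disease
report joins gene hits against a disease→genes table, listing per disease
which member genes carry sites (and by which miRNAs) and which carry none;
unresolved gene symbols are logged and skipped rather than failing the run.

## Synthetic fixtures

`make_genome()` draws i.i.d. bases at a requested GC fraction;
`plant_hairpin()` writes `arm + loop + revcomp(arm)` with a chosen number
of interior arm mismatches, and `plant_target()` writes a perfect,
seed-only-conserved, or heavily mismatched (8 substitutions) reverse
complement of a miRNA. All generators are seeded and restore the caller's
RNG state, and every fixture serializes to FASTA/TSV so failures replay.

Two deliberate artificialities keep ground truth exact: planted hairpin
loops are poly-A (so the stem cannot grow inward) and the hairpin is
flanked by 6-nt non-complementary guard bands (A opposite C, so random
flanks cannot extend the stem outward). Mismatches are placed at interior
arm positions because a terminal mismatch would be trimmed by local
alignment and change the expected score. Real genomes offer no such
insulation — fixtures validate coordinate bookkeeping and scoring algebra,
not detection difficulty on real sequence. Likewise the i.i.d. composition
model reproduces none of the strand asymmetry, codon structure, or repeat
landscape of real mitochondrial DNA, so passing the planted-recovery tests
demonstrates correctness of the machinery, not expected yield on a real
genome.

## Numerical choices and problem sizes

Energies are doubles in kcal/mol throughout; DP traceback comparisons use a
1e-7 tolerance; the shuffle P estimator never returns 0. The test suite
verifies the DPs against independent oracles at sizes where exhaustive
computation is feasible: split-alignment best scores on 500 random genomes
of 20–60 nt, full structure enumeration on 200 sequences of 8–18 nt, duplex
pairing enumeration on duplexes up to 10 nt, 500 null draws for the shuffle
P-value (length-60 sequences, 49 shuffles each, so the discrete-uniform
mean bias 1/(2(n+1)) = 0.01 stays well inside the acceptance band), 1000
planted-exact homology recoveries, and an end-to-end fixture with five
planted hairpins and three planted target sites. Pipeline defaults
(`default_config()`) use 1000 shuffles per window for the P-value except
where a smaller `shuffle_n` is configured.

## Known limitations

* The energy tables are Turner-style but not the complete Turner 2004 set
  (no tetraloop bonuses, terminal mismatches, or dangles); absolute MFE
  values will differ from other folding engines even when structures agree.
* The rule filter is a documented stand-in for trained classifiers; its
  thresholds (−18 kcal/mol, P ≤ 0.05) are defaults to be tuned per
  application, and no claim is made that it reproduces any particular
  published candidate count.
* Repeat discovery reports local optima under a greedy overlap rule, which
  can differ from other implementations' report sets for heavily nested
  repeat families even when best scores agree.
* The target scan evaluates duplex energy on the phase-1 alignment
  interval; sites whose optimal duplex would extend beyond that interval
  may be scored slightly conservatively.
* Wrap-around (origin-spanning) features are supported in extraction but
  not searched for by the repeat and target scanners, which treat the
  genome as linear.
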