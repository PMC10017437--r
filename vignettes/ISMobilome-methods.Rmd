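---
title: "ISMobilome: methods, conventions and detection limits"
author: "ISMobilome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ISMobilome: methods, conventions and detection limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ISMobilome)
```

# Overview

ISMobilome characterizes the insertion-sequence (IS) mobilome of an
annotated bacterial genome and calls individual transposition events from
wild-type/mutant allele pairs. This vignette documents the conventions the
package commits to — coordinate systems, scoring, tie-breaking, and the
places where detection is fundamentally ambiguous — so results can be
interpreted and reproduced precisely.

# The IS element model

A full-length IS element is modeled as

```
5'-[DR][TIR-L][ ... transposase ORF ... ][TIR-R][DR]-3'
```

* **TIR** (terminal inverted repeats): the left arm read 5'→3' equals the
  reverse complement of the right arm, up to a small number of mismatches.
* **DR** (direct repeat / target-site duplication): an exact duplication of
  the target sequence flanking the element, created on integration. Its
  length is a family-characteristic parameter (commonly 2–14 nt); DR = 0
  (blunt insertion) is supported.

All coordinates are 1-based and inclusive, on the forward strand of the
genome or allele in which they are reported.

# TIR discovery

`findTIR()` scans the flanking window of an annotated transposase
exhaustively (compiled C++ kernel). For a window of width $W$ with the
transposase at `tpaseStart..tpaseEnd`:

* left arm start $i \in [1,\ \text{tpaseStart} + o - 1]$ and right arm end
  $e \in [\text{tpaseEnd} - o + 1,\ W]$, where $o$ is the permitted ORF
  overlap (default 3 nt);
* arm length $L \in [6, 40]$, arms may not touch, at most 2 mismatches;
* bases are compared as complement pairs walking inward from $i$ and $e$;
  ambiguous (non-ACGT) positions never match.

The score of a candidate is $L - \text{mismatches}$. Ties are broken, in
order: fewer mismatches, smaller span $e - i + 1$, leftmost $i$, leftmost
$e$. This makes the reported TIR a deterministic function of the window.

## Detection limit for short TIRs

A genuine 6-nt TIR (e.g. the IS5-family `AGGCTG`) scores 6. In a window of
a few hundred nucleotides of random sequence, accidental partial
palindromes scoring 7 or more are common, so short TIRs **cannot** be
reliably recovered unguided from large windows; the scan will prefer the
accidental higher-scoring pair. This is a property of the objective, not a
bug. Long TIRs (≥16 nt) are safe: an accidental score ≥ 16 has negligible
probability in any realistic window. When a catalog is available,
`callInsertion()` therefore matches inserted sequence against *catalog*
TIRs rather than re-scanning, which restores exact identification for
short-TIR families.

# DR discovery

Given a TIR pair, `findDR()` grows the duplication outward from the arms:
the $k$-mer immediately 5' of the left arm must equal the $k$-mer
immediately 3' of the right arm, maximizing $k$ up to `maxDup` (default
14). The catalog records `minDr` (default 2): shorter duplications are
reported as absent, because 1-nt "duplications" are indistinguishable from
coincidence at a 25% background rate. All functions accept `minDr = 1`
explicitly when single-base DRs are of interest (the property-based test
suite does this to exercise the full 0–12 range).

# Junction calling and canonicalization

For a wild-type allele $w$ and mutant allele $m$ (insertion of length
$d = |m| - |w|$), the raw junction is located as $P = \mathrm{lcp}(w, m)$
(longest common prefix) and the shared suffix $S$. Because the element was
inserted *with* a duplication, many $(q, k)$ decompositions

$$ m = w_{1..q} \,\|\, \text{ins} \,\|\, w_{(q-k+1)..q} \,\|\, w_{(q+1)..} $$

can explain the same pair; the duplication makes the junction intrinsically
ambiguous. `callInsertion()` canonicalizes:

* **with a catalog**: enumerate valid $(q, k)$ with $k \le$ `maxDup` and
  prefer decompositions whose inserted sequence begins and ends with an
  exact catalog TIR (forward or reverse orientation); among those, larger
  $k$, then larger $q$. This recovers the *biological* junction whenever
  the element is cataloged.
* **without a catalog**: the maximal-duplication convention (largest $k$,
  then largest $q$). The reported DR can then be an ambient extension of
  the biological one by chance ($\Pr \approx 1/4$ per extra base).

Every call is checked against the reconstruction invariant — the reported
$(q, \text{ins}, k)$ must regenerate $m$ from $w$ exactly — and the
package refuses to return a call that violates it.

Orientation is `forward` if the inserted sequence carries the catalog TIR
in genome orientation, `reverse` if reverse-complemented. Transposition
mode is classified separately (`classifyTranspositionMode`) from donor
occupancy evidence: donor copy still present → `replicative`, donor site
restored → `conservative`, no evidence → `indeterminate`.

# Subtype clustering and family assignment

Transposase translations are compared by global alignment (BLOSUM62,
affine gaps, opening 10 / extension 0.5); identity is
$\text{matches} / \min(|a|, |b|)$, computed in a canonical argument order
so it is exactly symmetric. Subtypes are single-linkage clusters at
identity ≥ 0.90; each cluster's representative is assigned to the IS
family of its best exemplar at identity ≥ 0.30, otherwise `unclassified`.
Subtype names `IS<strainTag><n>` are numbered by family, then by leftmost
genomic occurrence, so naming is deterministic.

# Key parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `minArm` / `maxArm` | 6 / 40 | `catalogConfig` | TIR arm length bounds (nt) |
| `maxMismatch` | 2 | `catalogConfig` | mismatches tolerated in a TIR pair |
| `orfOverlap` | 3 | `catalogConfig` | nt a TIR arm may reach into the ORF |
| `flankLen` | 1000 | `extractFlankWindow` | window extension past the ORF |
| `minDr` | 2 | `catalogConfig`, `callInsertion` | shortest reportable DR |
| `maxDup` | 14 | `findDR`, `callInsertion` | longest considered DR |
| `subtypeThreshold` | 0.90 | `catalogConfig` | single-linkage clustering identity |
| `familyThreshold` | 0.30 | `catalogConfig` | exemplar assignment identity |
| `maxMismatch` | 0 | `inSilicoPCR` | per-primer mismatch budget |
| `conf` | 0.95 | `transpositionFrequency` | Wilson interval level |

# The simulator: scope and honesty

The simulator exists to make every claim in this package testable with
known ground truth; it is deliberately simple and openly synthetic:

* `synthGenome()` writes GC-biased random codons behind ATG starts —
  realistic composition (GC ≈ 0.674, Deinococcus-like), no realistic gene
  content, operons or codon usage.
* `plantElement()` inserts a complete element with its duplication at an
  intergenic site and annotates the transposase CDS. `findClearSites()`
  returns junctions where the planted TIR/DR cannot be extended by ambient
  sequence, guaranteeing that unguided recovery is exact — use it when a
  test needs planted truth to be the unique answer; real junctions carry
  the ambiguity described above.
* `simulateTransposition()` applies a replicative or conservative event in
  gene coordinate space, on either gene strand, and returns the edited
  genome; it refuses positions that collide with the duplication or events
  whose donor overlaps the target.
* `simulateSelectionCounts()` is binomial sampling; `simulateCtTable()` is
  Gaussian Ct noise around `baseline − log2(effect)`. Neither models plate
  effects or amplification efficiency ≠ 2.

All simulator functions are pure functions of their `seed` argument.

# Statistics

`transpositionFrequency()` pools events and CFU across experiments and
reports the Wilson score interval (`prop.test`, no continuity correction).
`relativeExpression()` computes per-replicate ΔCt against the reference
gene, ΔΔCt against the control condition, fold change $2^{-\Delta\Delta
Ct}$, and a Welch t-test on the ΔCt vectors with conventional significance
stars. With 3 replicates at Ct sd 0.2 a *single* plate estimates a 6-fold
change only to within ~±12%; accuracy claims in the test suite therefore
average over many simulated plates.

# Session info

```{r}
sessionInfo()
```
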