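---
title: "Motif enrichment and minimalistic peptide design for phase-separating proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment and minimalistic peptide design for phase-separating proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemotif)
```

## The problem

Liquid--liquid phase separation (LLPS) of proteins into biomolecular
condensates is driven in large part by short, recurring sequence motifs
inside droplet-promoting regions (DPRs) -- intervals that an upstream
predictor (e.g. FuzDrop) flags as condensate-prone, as opposed to
non-droplet-promoting regions (NODPRs). `phasemotif` implements a
complete, deterministic pipeline for

1. profiling amino-acid composition of full proteins, DPRs and NODPRs;
2. discovering 3--6-residue motifs enriched in the DPRs of
   phase-separating proteins relative to a negative protein set;
3. scoring all trios of enriched motifs by how often and how
   symmetrically they co-occur within DPRs;
4. merging top-scoring trios into minimal peptides under 20 residues and
   filtering them with disorder-associated sequence parameters; and
5. converting the two standard bench readouts (turbidity, fluorophore
   partitioning) used to validate such peptides.

Region calls and droplet-promoting probabilities are always inputs; the
package never predicts them.

## Motif discovery

Every distinct k-mer (k = 3..6 by default) occurring in at least one
positive DPR is a candidate. For each candidate two counts are taken in
each universe:

* **presence** -- the number of distinct sequences (DPRs, or whole
  negative proteins) containing the motif at least once;
* **frequency** -- total occurrences, counting overlapping matches
  (a step-1 sliding window, so `QQQQ` occurs twice in `QQQQQ`).

Overlap counting is deliberate: homopolymeric motifs such as `GGGGG`
only make sense with it, and embedding relations like `QQQQ` inside
`QQQQQ` presuppose it. The negative universe is the full negative
protein sequences: negatives average well under one DPR each, so a
region restriction would be vacuous.

Raw folds are ratios of positive to negative counts with the denominator
floored at one occurrence -- a motif absent from the negatives keeps a
finite fold, preserving order without infinities; such rows carry a
`neg_floor` flag. The presence fold (PF) and frequency fold (FF) are
min--max normalizations of the raw folds across the candidate set being
scored, and the combined score is

$$ \mathrm{CF} = 0.5\,\mathrm{PF} + 0.5\,\mathrm{FF}, $$

with selection at CF $\ge$ 0.2 (inclusive). Min--max is the
minimal-assumption reading of "normalized on a scale of 0 to 1"; its
scope is the scoring run, so per-family discovery normalizes within each
family's own candidate set. A degenerate candidate set whose folds are
all equal normalizes to zero and is logged. Embedded motifs (proper
substrings of other selected motifs) are reported but never removed:
single-residue additions can matter for condensation behaviour, so the
set keeps both host and guest.

## Trio scoring

For a trio (A, B, C) over the DPR set, with $n_{AB}$-style pairwise
co-occurrence counts, $n_{ABC}$ the triple count, and $p_m$ each motif's
presence:

$$ \mathrm{coverage} = \frac{n_{ABC}}{\min(p_A, p_B, p_C)}, \qquad
   \mathrm{symmetry} = \frac{\min(n_{AB}, n_{AC}, n_{BC})}
                            {\max(n_{AB}, n_{AC}, n_{BC})}, $$

$$ \mathrm{FS} = 100\,(0.5\,\mathrm{coverage} + 0.5\,\mathrm{symmetry}). $$

The exact arithmetic behind the published score was never printed; this
formula is the package's own definition, chosen as the simplest one that
reproduces all three stated anchors -- FS = 100 exactly when all three
motifs appear in every DPR any of them touches in equal pairwise
proportions, FS near 50 for asymmetric pairs or limited joint presence,
and FS = 0 with no pairwise co-occurrence. It is isolated in one
function (`trio_score_fields()`) so an alternative can be swapped in.
Degenerate denominators (no presence, no co-occurring pair) define the
corresponding factor as 0 rather than NA, keeping FS total over all
trios.

`score_all_trios()` represents motif-in-region membership as a dense
0/1 matrix; pairwise counts come from one cross-product and triple
counts from one masked cross-product per leading motif, so all
C(129, 3) = 349,504 trios over ~700 regions take seconds on one CPU.

```{r}
regions <- c("AAGGDRAAQQPGAASYGSAA", "TTGGDRTTQQPGTTSYGSTT")
score_trio("GGDR", "QQPG", "SYGS", regions)[c("coverage", "symmetry", "fs")]
```

## Peptide construction

For each top trio, motifs that are substrings of another trio member are
absorbed first; every ordering of the survivors is merged left-to-right
with maximal suffix--prefix overlap; duplicates are removed and anything
of 20 residues or more discarded. Because the surviving motifs are
substring-free, the per-ordering maximal-overlap merge is optimal for
that ordering, and the minimum over all six orderings is the true
shortest superstring of the trio -- verified in the tests against an
exhaustive search over orderings *and* overlap amounts.

```{r}
build_peptides(c("FGGG", "RGGF", "GGDRGG"))
```

## Sequence parameters and filtering

Five parameters annotate every candidate peptide:

* **FCR** $= f_+ + f_-$ and **NCPR** $= f_+ - f_-$, with K/R positive,
  D/E negative, and histidine neutral by default (the common
  neutral-pH convention; `his_positive = TRUE` flips it).
* **kappa**: for blob sizes g = 5 and 6, the charge asymmetry
  $\sigma = (f_+ - f_-)^2 / (f_+ + f_-)$ of every fully contained
  window is compared with the whole-sequence $\sigma$; the mean squared
  deviation is normalized by the maximum attainable over rearrangements
  of the same charge multiset, and kappa is the mean over usable blob
  sizes. 0 means well-mixed charge, 1 maximally segregated.
* **mean hydropathy**: mean Kyte--Doolittle value shifted by +4.5, i.e.
  the 0--9 scale customary for disordered-region work.
* **disorder fraction**: share of residues in {A, R, G, Q, S, P, E, K}.

The kappa normalizer is computed by exhaustive enumeration of distinct
charge arrangements whenever their count is at most $10^5$ -- which
covers every designed peptide -- and otherwise as the maximum over a
constructed family of extremal arrangements (segregated blocks and
their reflection, charges split to opposite ends, charges centered)
*plus the observed arrangement*, which guarantees kappa $\le$ 1. The
result records which route was used in its `kappa_method` attribute.
Windows are fully contained (no partial edge blobs); a blob size larger
than the sequence is skipped. Kappa is *not applicable* -- returned as
`NA`, never a number -- for chargeless sequences, sequences shorter
than every blob size, and the degenerate case where the charge multiset
admits no rearrangement variation at all (e.g. a fully charged
single-sign homopolymer), where the normalizer is exactly zero.

Filtering annotates, it never deletes: each candidate gets a
`passes_filter` verdict and the list of parameters that fell outside
their closed intervals. The default intervals
(`default_filter_ranges()`: FCR [0, 0.7], NCPR [-0.35, 0.35], kappa
[0, 0.5], hydropathy [0, 4.8], disorder fraction [0.55, 1]) are this
package's own configuration, broadly shaped on published human-IDR
distributions -- they are deliberately editable and carry no claim of
matching any external tool's cutoffs. Peptides with non-applicable
kappa pass that check by default (`kappa_na = "pass"`).

## The synthetic database generator

`generate_database()` emulates the structure of the curated study
databases so that every downstream stage is testable without downloads:

* 178 positives and 208 negatives, protein lengths uniform in 400--800
  residues;
* positives carry 1--6 DPRs (and a similar number of NODPRs) per
  protein; region lengths follow a 10-shifted geometric distribution
  with means 72.1 (DPR) and 90.2 (NODPR) residues, truncated to half
  the protein -- a heavy right tail, as real disordered-region length
  distributions have;
* DPR residues are drawn i.i.d. from a Gly/Ser/Pro/Ala-rich table
  (Gly 11.5%, Ser 11.7%, Pro 10.6%), NODPR and unannotated background
  residues from an intermediate table, and negative proteins from a
  Leu-rich hydrophobic table (Leu 11.1%);
* motifs are planted by overwriting a random window fully inside a
  target region (never straddling a boundary, preserving all lengths),
  in an exactly chosen number of regions;
* one private RNG stream per call, consumed in a fixed documented
  order: equal configs give byte-identical databases, and the caller's
  RNG state is untouched.

Two honest limitations follow from the i.i.d. design. First, segments
drawn for a tight protein are dropped from the tail until they fit, so
realized region counts and mean lengths sit somewhat below their
nominal values when many long regions are requested of short proteins.
Second, i.i.d. draws have no positional grammar: real DPRs carry
repeats and patterned charge that the generator only produces through
explicit planting. Passing recovery tests therefore demonstrate that
the discovery statistics behave correctly under controlled enrichment,
not that the generator is a realistic protein model.

The bundled list `inst/extdata/motifs129_synthetic.tsv` is a
**synthetic stand-in** for the curated 129-motif enrichment list: it
contains the motifs the study narrative names plus constructed fillers,
assembled once so the set reproduces the published summary statistics
(length distribution 2/54/31/13% across lengths 3--6; Gly 59%, Pro 47%,
Ser 29%, Arg 23%, Gln 20%, Tyr 19% membership; 36% embedded; 19
RGG-containing motifs). It is not the original supplementary table, and
motif-level conclusions should not be drawn from its individual
entries.

## Numerical and design choices

* Internal coordinates are 1-based inclusive (the R convention);
  readers translate from `one_inclusive` or `zero_half_open` TSV
  dialects at the boundary.
* Non-canonical letters (B, J, O, U, X, Z, ...) become the sentinel
  `X`; any k-mer window containing a sentinel is excluded from
  counting, so non-canonical residues can never create a motif.
* Ties are broken lexicographically everywhere (motif tables, trio
  ranking, design ranking), making every artifact byte-reproducible.
* Designed-peptide ranking puts filter-passing candidates first, then
  FS descending, length ascending, sequence lexicographic.
* Assay formulas: relative turbidity $= 100 - 100 \cdot 10^{-A_{600}}$;
  encapsulation efficiency $= 100\,(C_T - C_{sup})/C_T$ (the printed
  formula reported in percent, matching the convention of the published
  partitioning table); supernatant readings above the total are clamped
  to 0% with a warning.

## Test problem sizes

The test suite validates counting against a brute-force oracle on 200
random motif/region-set pairs, kappa against exhaustive enumeration on
100 random peptides of length at most 10, superstring minimality
against exhaustive search on 50 random trios, planted-motif recovery on
a full-scale synthetic database (178 positives, 208 negatives, five
motifs planted at ten times the negative rate, plus a no-planting null
control), and the complete C(129, 3) trio scan over 700 synthetic
regions. These sizes were chosen to exercise each property at the scale
the method is meant for while keeping the default test run fast.

## Known limitations

* The FS formula is this package's calibrated definition, not the
  unpublished original; published FS values for specific peptides are
  not expected to reproduce exactly.
* The negative universe is whole proteins, not negative DPRs; with a
  pathological negative set consisting of very long proteins, presence
  folds shrink mechanically.
* Min--max normalization makes CF relative to the candidate set: adding
  or removing candidates rescales everyone's CF. This mirrors the
  original design but means CF values are not comparable across runs
  with different candidate universes.
* Kappa's extremal fallback for long sequences is a lower bound on the
  true maximum; enumerated (short) and fallback (long) kappas are
  internally consistent but the fallback can overestimate kappa
  slightly. All designed peptides use the exact route.
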