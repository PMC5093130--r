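---
title: "Methods: classifying Pro-rich 8C hevein-like peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying Pro-rich 8C hevein-like peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heveinscan)
```

## The problem and the model

Hevein-like peptides are small (29–45 aa) cysteine- and glycine-rich
plant defense peptides that bind chitin. They fall into three
subfamilies named by cysteine count — 6C, 8C and 10C — sharing a
cystine-knot core and a conserved chitin-binding domain. The
ginkgotides of *Ginkgo biloba* define a distinct class within the 8C
subfamily: they are proline-rich (3–6 Pro), carry Pro at both termini,
and their precursors end in a short, protein-cargo-free C-terminal
tail. `heveinscan` implements the sequence-level machinery needed to
recognise this class and to replicate the transcriptome screen that
mapped its distribution across plants.

The class definition is operational and fully testable. A mature
peptide is called **Pro-rich 8C** when all of the following hold:

* exactly eight cysteines, in the framework `C-C-CC-C-C-C-C` (the
  adjacent CC pair at framework positions III/IV is diagnostic);
* a chitin-binding-domain motif `S-X-φ-X-φ-C-G-X₄-φ` spanning
  intercysteine loops 3–4 (in gB5: S19, F21, Y23, CysV24, G25, Y30);
* 3–6 prolines;
* a Pro within the first three and the last two residues.

`classify_subfamily()` evaluates exactly these criteria and exposes the
per-criterion evidence, so a call is never a black box.

## Loop numbering

Loops are the backbone segments between consecutive framework
cysteines. We number them 1–7 for the 8C framework with one
convention fixed throughout the package: the empty segment inside the
adjacent CC pair carries no number, so loop 3 runs CysIV→CysV and holds
the motif's Ser and two aromatics, loop 4 (CysV→CysVI) holds the third
aromatic, and loop 7 is the tail after CysVIII. This is the only
numbering under which the chitin-binding residues fall in loops 3–4 as
the field describes them, and it is the sole supported convention for
8C/10C. Whether the post-terminal-Cys tail should be a numbered loop
for other frameworks is not settled usage; we count it as a loop only
for 8C/10C and report it as `c_term` otherwise.

## Motif definition choices

The literal motif statement (`X` = small residue, `φ` = Tyr or Trp) is
narrower than the peptides it describes: gB5 itself has Phe at the
first aromatic position and Lys at an X position, and hevein has Gln at
an X position. Defaults therefore use the aromatic set `{F, W, Y}` at
all three aromatic positions and wildcard X; `x_mode = "strict_small"`
restores the literal reading (and, deliberately, rejects gB5 — the
tests pin this behaviour down). The Pro "flank" windows (first 3 / last
2 residues) are configuration, since "flanking" is nowhere defined
numerically; the defaults are the smallest windows that accept the
reference peptide's P2 and P41.

## Mass arithmetic

`peptide_mass()` sums standard monoisotopic (or average) residue
masses plus one water; each disulfide removes exactly two hydrogen
atoms (2 × 1.007825 Da), and S-alkylation adds the reagent mass once
per cysteine to the reduced species. `[M+H]⁺` adds the proton mass
(1.007276 Da), not the hydrogen atom mass. Cysteine counting from an
observed alkylation shift divides by the per-Cys shift and rejects
calls whose residual exceeds a quarter of one cysteine equivalent
(configurable). The default reagent is carboxymethyl (58.00548 Da)
measured against the reduced species, because the 8 × 58 ≈ 464 Da
arithmetic used to infer eight cysteines corresponds to that model;
carbamidomethyl (57.02146 Da) and a nominal integer 58 Da model are
also provided, as experimental reports of this chemistry name both
iodoacetamide and iodoacetic acid.

Isoelectric points use a Henderson–Hasselbalch sum over termini and
D/E/C/Y/H/K/R side chains with the EMBOSS pKa set, solved by bisection
on pH 0–14 to |charge| < 10⁻⁶. The charge curve is strictly decreasing,
so the root is unique; the iteration cap exists only as a guard.

## Precursor parsing and the homolog filter

Precursors have three domains: ER signal peptide, mature hevein-like
domain, C-terminal tail. Rule-based partitioning places the signal
cleavage at the first Gly|Asp dipeptide in a positional window
(default 15–35, covering plausible signal lengths), then ends the
mature domain at the eighth cysteine plus one residue — the short
post-CysVIII tail seen in gB5 (…CP). Both window and tail allowance
are configuration; records with no site in the window are returned
unpartitioned with a diagnostic rather than guessed at. C-tails
shorter than 50 aa are called cargo-free; the threshold sits midway
between observed ginkgotide tails (20 aa) and the shortest protein
cargo (126 aa Barwin-like), and the boundary is half-open (50 is
cargo).

The five-criterion filter removes, in order: odd mature-domain
cysteine counts; signals shorter than 10 aa; undetermined residues
(any `X`, or an unlocatable mature domain); identical same-plant full
sequences (keeping the first in input order); and missing terminal Pro
flanks. Each removal is attributed to the *first* violated criterion.
The source screen reports disjoint per-criterion counts but not an
application order, so the listed order is frozen as the default and
exposed as configuration; permuting it can move attributions but — as
the tests verify — never changes the survivor set except through the
inherently order-dependent duplicate rule. Survivors are then grouped
by exact mature-domain string: records from different plants with
identical mature domains count as one putative peptide.

## The synthetic screen fixture

Real screen inputs are transcript accessions we do not redistribute,
so the generator builds the screen's composition from scratch with
ground truth attached. `screen_fixture(seed)` emits 85 precursor
records: 52 valid Pro-rich 8C precursors whose mature domains collapse
to 42 unique sequences — six domains shared across plants with
multiplicities (6, 2, 2, 2, 2, 2), one of them spanning six conifers —
plus decoys at the screen's published category counts (1 odd-Cys, 3
short-signal, 3 with an `X`, 9 same-plant duplicates, 17 lacking Pro
flanks). The shared-domain multiplicities are this package's
construction: only the totals (52 precursors, 42 domains, 6 shared,
one in six plants) are constrained by the screen, and (6,2,2,2,2,2) is
the simplest composition satisfying them. Organisms are drawn from 47
distinct plant labels, matching the screen's breadth.

Generator sequences are realistic in the features the pipeline reads —
framework, motif anchors, Pro placement, domain lengths (mature 40–50
aa, signal 20–30 aa, tails 20/126/254 aa), cleavage site — but
deliberately not in residue statistics: non-anchor positions are drawn
uniformly from the 18 non-Cys, non-Pro residues, which prevents
accidental frameworks, flanks or cleavage sites and makes every decoy
violate exactly its assigned criterion (asserted at generation time by
running the filter). Passing tests on the fixture therefore
demonstrate the pipeline's logic, not robustness to the composition
biases, truncations and sequencing errors of real EST data. Signal
peptides likewise have no hydrophobic-core structure; the Gly|Asp rule
is a stand-in for annotation or a dedicated predictor, not a
replacement for one.

## Disulfide combinatorics

Connectivity candidates are perfect matchings of cysteine labels
I..n. With eight cysteines there are 7!! = 105 matchings; fixing one
experimentally unambiguous bond (CysII–CysV in gB5) leaves 5!! = 15.
Enumeration is exhaustive and deterministic (canonical bond order,
lexicographic pattern order), and `rank_patterns()` orders candidates
by externally supplied structural energies with a stable tie-break.
Computing those energies is out of scope by design — the package
reproduces the combinatorics and the argmin selection, not the
structure calculation.

## Phylogenetics

Distances are p-distances with pairwise gap deletion (an explicit
choice — the upstream analysis names only the clustering algorithm,
not its distance), optionally Poisson-corrected. Neighbor joining is
implemented in full (Q-criterion, standard branch lengths) with two
numerical policies: ties in Q are broken by the lexicographically
smallest pair of cluster labels so results are reproducible, and
negative branch lengths are clamped to zero with a message. On
additive matrices the algorithm is exact; the tests verify path-length
recovery to 10⁻⁹ across random 4–12-leaf trees and topological
agreement with an independent implementation (`ape::nj`). Profile
matrices for sequence logos exclude gaps from column denominators and
report information content `R = log2(20) − H` in bits; the small-sample
correction is off by default.

Because the real screen's alignment parameters are unknown, the
published tree's topology is not something this package claims to
reproduce — only NJ correctness itself is asserted.

## Problem sizes and determinism

Every stochastic check runs under a fixed seed. The suite exercises:
10³ random peptides against an elemental-composition mass oracle, 10³
generator/classifier agreement draws, 100 additive matrices for NJ,
400 motif-scanner windows against a regex oracle, 500 precursor
boundary recoveries, and the 85-record fixture at several seeds. These
sizes keep the full suite under half a minute while leaving the
property space densely sampled; all scale linearly if enlarged.

## Known limitations

* Classification is sequence-only; chitin-binding affinity and
  antifungal activity are outside what sequence features can assert.
* The Gly|Asp cleavage rule is specific to ginkgotide-like precursors;
  other hevein-like signal peptides cleave at different dipeptides and
  need annotations or a predictor.
* `X` residues block classification and mass computation outright
  rather than being marginalised over.
* p-distance + NJ is a deliberately simple phylogenetic treatment;
  no substitution-model fitting or support values are offered.
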