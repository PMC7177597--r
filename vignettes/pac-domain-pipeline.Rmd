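---
title: "Finding and classifying PAC domain proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and classifying PAC domain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacfinder)
library(dplyr)
```

## The biology and the model

PAC domains (Proline-rich, Arabinogalactan protein, Conserved Cysteines)
are plant cell-wall protein domains built around six conserved cysteines
that form three disulfide bridges — Cys1–Cys5, Cys3–Cys4 and Cys2–Cys6 —
stabilising a seven-stranded β-barrel. The domain is defined less by
overall sequence conservation (which can drop to ~15% identity between
family members) than by a rigid spacing grammar: a glycine anchor, then
Cys1 after exactly 3 residues, Cys2 after exactly 2 more, and Cys3–Cys6
at bounded but variable distances. `pacfinder` turns that grammar into a
scanner, layers the remaining bona fide criteria on top as pluggable
gates, and classifies the proteins that carry the domain by their
associated-domain architecture.

The spacing rule is held in a `pac_rule()` object, with the canonical
defaults

```
Gly (3) Cys1 (2) Cys2 (10,30) Cys3 (20,50) Cys4 (8,20) Cys5 (25,60) Cys6
```

where the bracketed numbers are residues *between* consecutive anchors.
Summing anchors and spacers, a bona fide domain spans between 75 and 172
residues (`min_max_span()`).

```{r rule}
pac_rule()
min_max_span(pac_rule())
```

## Scanning

`scan_strict()` enumerates every glycine anchor. Because strict spacers
are cysteine-free, the Cys chain from a given anchor is forced (the next
Cys either satisfies the bound or the anchor dies), so scanning is linear
and provably equivalent to evaluating the regular expression
`G[^C*]{3}C[^C*]{2}C[^C*]{10,30}C[^C*]{20,50}C[^C*]{8,20}C[^C*]{25,60}C`
anchored at every position — the test suite checks that equivalence
against a literal regex oracle on tens of thousands of random sequences.
Stop characters (`*`, retained from six-frame translations of
transcriptome contigs) are hard walls: no span may cross one. `X` is
treated as "not Gly, not Cys" and scores zero against everything in
alignments.

```{r scan}
toy <- paste0("G", strrep("A", 3), "C", strrep("A", 2), "C",
              strrep("A", 10), "C", strrep("A", 20), "C",
              strrep("A", 8), "C", strrep("A", 25), "C")
scan_strict(c(toy = toy)) %>% select(record_id:c6, span_len)
```

`scan_relaxed()` admits the variants seen in real surveys — domains with
five or up to nine cysteines, a missing glycine anchor (the rule in
Chlorophyta ancestors), or spacers slightly out of bounds — and records
every admitted deviation in a `violations` column. Two conventions are
worth stating:

* a missing Cys is only admitted at the interior ordinals 2–5. A missing
  Cys1 or Cys6 would redefine the domain boundary itself, so there is no
  well-defined span to report;
* chains that touch the same physical residues are one site. A 5-Cys hit
  can be read as "Cys4 missing" or "Cys5 missing" when both merged-gap
  constraints happen to hold; the scanner reports the site once,
  preferring the reading with fewest violations, deterministically.

Enumeration is depth-first and capped at 64 chains per anchor with a
warning, which in practice only triggers on adversarial Cys-dense input.

### Coordinates

All user-facing coordinates in this package are 1-based inclusive — the
native R and GFF3 convention — including the match columns `c1`..`c6`,
spans, and annotation ranges.

## The bona fide gates

The scanner's hits are filtered by three independent, commutative gates,
each of which accepts precomputed external predictions (TargetP-, SABLE-,
or hmmscan-style tables) and falls back to a built-in heuristic
otherwise:

* **Signal peptide** (`signal_peptide_gate()`): the built-in heuristic
  requires, within residues 1–35, an 8-residue window with ≥ 6
  hydrophobic residues preceded by an n-region of net charge ≥ 0.
  Records translated from incomplete contigs (no initial Met) are
  `unknown`, and `unknown` never excludes a candidate — incomplete
  transcriptome sequences should not be punished for missing their
  N-terminus.
* **Secondary structure** (`ss_admissible()`): the exclusion rule in the
  source analysis is qualitative ("no predicted β-sheets, large
  α-helices"). The package quantifies it as: ≥ 3 strand segments of ≥ 3
  residues within the span, and helix fraction ≤ 0.5. Both thresholds are
  arguments. The built-in predictor (`predict_ss_fallback()`) is a
  deterministic Chou–Fasman propensity smoother (window 5, arg-max of
  averaged helix/strand/turn propensities, ties preferring coil); it is a
  stand-in for neural predictors, good enough to separate β-rich spans
  from helical decoys, and not more.
* **Foreign domains** (`foreign_domain_gate()`): any external hit at
  e-value ≤ 1e-5 whose accession is not on the allow list (the PAC/Ole e 1
  accessions PF01190/PS00925 plus the package's own associated-domain
  kinds) fails the record, mirroring the exclusion of candidates carrying
  intracellular domains such as PF00171 or the JmjC/JmjN factors.

## Architecture classification

Five detectors locate the associated domains: W-x8-W (`detect_ww()`,
anchored at the first motif occurrence and extending to the C-terminus,
as the W-W domain is terminal and encoded by its own exon),
Ser-(Pro)≥2 extensin clusters (≥ 3 motifs within 30 residues), His
stretches (≥ 4 His in a 6-window, trimmed to the His), Pro-rich windows
(≥ 30% Pro over 20 residues) and AGP-like windows (≥ 30% coverage by
AP/PA/SP/TP/VP dipeptides). The thresholds quantify domain descriptions
that the literature names but never numerically defines; they are
centralized as defaults and exposed as arguments.

`classify_pdp()` then assigns each protein to:

* **Type 1** — the mature protein is essentially the PAC domain alone
  (PAC ≥ 80% of the mature length, no other annotation);
* **Type 2** — N-terminal PAC followed by other domains (flag `ww_2prime`
  when a W-W domain follows);
* **Type 3** — C-terminal PAC preceded by His-rich/Pro-rich/AGP-like
  domains;
* **Type 4** — central PAC flanked by two extensin domains.

"N-terminal"/"C-terminal" means the flanking mature sequence is at most
`max(30, 10%)` of the mature length; the margin makes the calls robust to
ragged transcript ends (a Type 3 call is invariant to appending a few
unannotated residues). Annotations mostly contained in the PAC span are
treated as part of the domain — Pro-rich stretches inside PAC spacers are
a feature of the domain, not a separate architecture element. The
subtype flag `conserved_1prime` marks Type 1 domains with ≥ 60% identity
to a user-supplied reference set of highly conserved clade members;
60% is the lower edge of the identity range reported for that subtype
and is an argument, since the published account does not say whether the
value was a definition or an observation.

Multi-PAC proteins are not described in the source family survey; the
classifier uses the most N-terminal match and flags the record.

## Genomic context

`intron_position()` maps the diagnostic intron: PAC genes carry either no
intron or one intron between the codons of Cys2 and Cys3 (strictly
between the last base of the Cys2 codon and the first base of the Cys3
codon, in CDS coordinates). Introns elsewhere in the span are `atypical`.
`find_tandems()` chains neighbouring PAC genes on a scaffold
(single-linkage, at most one intervening non-PAC gene by default) whose
PAC-domain amino-acid identity exceeds 85% — identity computed on the
PAC span only, matching how tandem duplicates are reported. Adjacency is
not quantified in the source, and mixed orientations are observed there,
so orientation is reported but not filtered on.

## Alignment, dedupe, conservation

`global_align()` is a Needleman–Wunsch implementation with affine gaps at
the needle defaults (open 10, extend 0.5, BLOSUM62). It is implemented in
the package rather than delegated, because downstream checks need fully
specified semantics: gap cost `open + L·extend`, gap states opening only
from the match state, traceback preferring diagonal, then up, then left,
and inputs ordered canonically (shorter first, ties lexicographic) so
identity and similarity are exactly symmetric. Identity is identical
columns over alignment length; similarity is positive-scoring columns
(the EMBOSS definition, stated here because published similarity
percentages rarely define it). Whether published identities were computed
over alignment length or shorter-sequence length is not stated; the
alignment-length convention is adopted. An independently coded dynamic
program and `Biostrings::pairwiseAlignment` scores serve as oracles in
the tests.

`dedupe()` collapses, within a species, single-linkage clusters at ≥ 85%
identity — the published retention rule — keeping the longest member
(ties: smallest id). `distance_matrix()` (100 − identity) and the PHYLIP
writer prepare input for external tree building, which stays external.

`build_profile()` computes per-column frequencies, information content
`log2(20) − H` on the gap-excluded distribution scaled by the non-gap
fraction (so gappy columns score low — a stated package choice), and a
plurality-at-0.5 consensus. `match_prosite()` implements the PROSITE
subset (residues, `[sets]`, `x`, `(n)`, `(n,m)`) and returns all match
locations including overlaps. `map_accessibility()` joins conservation
with RSA/secondary-structure tracks of a representative model and labels
conserved buried columns `core` versus conserved exposed columns
`candidate_functional_site` (buried means RSA < 0.2, a common
convention; both cutoffs are arguments).

One wrinkle worth recording: the consensus-pattern compatibility check
enumerates the pattern `[EQT]-G-x-V-Y-C-D-[TNP]-C-R` over its finite
alphabet with the wildcard ranging over the 19 non-Cys residues. A
wildcard realized as Cys would change the cysteine numbering itself (a
7-Cys variant, relaxed-scanner territory), so it is outside the strict
rule whose anchor spacing the check verifies.

## Structure QC

`check_disulfides()` verifies the branched-loop topology on coordinate
models: all three expected SG–SG pairs within 2.5 Å (covalent ≈ 2.05 Å
plus modelling slack; the threshold is an argument because the original
modelling pipeline enforced bridges as constraints rather than measuring
them) **and** no extra SG pair within threshold — an extra bridge is
reported, not silently passed. `shrake_rupley_rsa()` computes accessible
surface with a deterministic golden-spiral point lattice (default 960
points, probe 1.4 Å, standard van der Waals radii).

Normalisation deserves a note. The conventional reference for RSA is the
residue's maximum ASA in a Gly-X-Gly tripeptide (the bundled Tien et al.
2013 table, `reference = "tien"`). But an isolated residue has *more*
surface than the same residue flanked by glycines, so under that
reference an unoccluded residue exceeds 1. The default is therefore
`reference = "self"`: each residue's ASA divided by the ASA of its own
atoms in isolation, computed by the same algorithm. This is
self-consistent (unoccluded ⇒ exactly 1, fully caged ⇒ 0) and is what
the package's sanity checks pin down; the Tien reference remains
available for comparability with published RSA values. DSSP itself is
consumed as input (H/E/C tracks), never reimplemented.

## The synthetic cohort

Real mining of 78 genomes and transcriptomes, and the external predictors
used to gate them, are out of scope; the package instead ships a
generator whose defaults define the simulated study conditions:

* spacers drawn uniformly within the rule bounds; spacer background is
  coil-forming residues (G/S/N/D) with one 6-residue strand block
  (V/I/F/Y/T) per long spacer, so a corruption-free record passes the
  built-in secondary-structure gate *by construction*. Pro is excluded
  from the spacer background so that chance Ser-Pro motifs cannot merge
  with planted extensin blocks across the domain boundary; a
  `composition = "uniform"` mode (uniform over the 19 non-Cys residues)
  exists for scanner stress-testing, where structural gates are not at
  stake.
* a gate-passing signal peptide (`MKK` + 10 hydrophobics + `ASA`);
* per-type associated domains: W-W with tail (Type 2), His stretch +
  AP-repeat block (Type 3), two `(SPPPP)×6` extensins (Type 4);
* single-fault corruptions, one per record, so each gate is tested in
  isolation: `missing_cys`, `extra_cys`, `gap_violation`, `missing_gly`
  (scanner-level), `helix_decoy` (secondary-structure gate),
  `foreign_domain` (domain gate), `no_signal_peptide` (signal gate). The
  `extra_cys` fault constrains the Cys4–Cys5 spacer to ≥ 17 so the
  planted chain stays the unique relaxed interpretation — the corruption
  is meant to test one gate, not to create ambiguous sites.

Gene models are produced by back-translation with random synonymous
codons and GT..AG introns planted in the diagnostic window, an atypical
window (between Cys4 and Cys5 codons) or not at all; the CDS always
translates back to the protein exactly. Tandem clusters mutate a seed
gene inside its spacers with a per-copy mutation count solved from the
target pairwise identity (accounting for the chance that two copies hit
the same site), which keeps realized identities within ±3 points of
target. Synthetic structures place SG atoms pairwise at 2.05 Å with the
correct (or deliberately scrambled) topology and > 6 Å between
non-partner cysteines.

What the simulations do *not* emulate: evolutionary divergence along
trees, realistic amino-acid composition, O-glycosylation, transcript
noise beyond `*`/missing-Met fragments, or real predictor errors. Green
tests on synthetic data therefore demonstrate the pipeline's internal
correctness — that each rule does exactly what it says — not field
performance on real proteomes, where gate quality is bounded by the
external predictors supplied.

## Problem sizes and numerical choices

The shipped verification runs use 10,000 random sequences (plus 20
perturbed rules × 500 sequences) for scanner–oracle equivalence, 1,000
corruption-free and 150-per-fault corrupted records for recovery and
gating, 200 random pairs for the alignment oracle, 300 gene models for
the intron round trip, and 100 rigid-body transforms for the disulfide
invariance check — sizes chosen so the whole suite completes in about a
minute on a laptop core while leaving each property with comfortable
statistical room. Ties in the profile's best-window search resolve
leftmost with a 1e-9 numerical tolerance; alignment traceback ties are
fixed (diagonal > up > left); generator RNG is isolated from the caller's
stream and fully determined by explicit seeds.

## Limitations

The built-in gates are deliberately simple stand-ins: the signal-peptide
heuristic knows nothing about cleavage-site grammar, and the propensity
predictor is far from a neural secondary-structure method — in real use
both should be replaced with external prediction tables, which every gate
accepts. De novo motif discovery (MEME-style) is out of scope; profiles
are extracted from alignments the user supplies. Phylogeny (alignment,
ML trees, bootstraps) and homology modelling remain external; the
package prepares their inputs (deduplicated FASTA, PHYLIP distances) and
validates their outputs (bridge topology, RSA), nothing more.
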