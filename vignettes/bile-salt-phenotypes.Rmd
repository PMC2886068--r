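---
title: "Comparative bile-salt phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative bile-salt phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biliphy)
```

## The problem

Bile salts — bile alcohols and bile acids, the amphipathic end-metabolites of
cholesterol — vary structurally across vertebrates in ways that track
phylogeny far more than ecology. Comparative surveys of biliary bile from
hundreds of reptile and mammal species record, per species, which compounds
are present and what fraction of the biliary pool each contributes. biliphy
implements the quantitative backbone of such a survey: structural
representation and nomenclature parsing, compound and species-profile
classification, diet cross-tabulation, parsimony mapping of discrete
bile-salt characters on phylogenies, and annotation of negative-mode
mass-spectrometry peak lists (the route by which bile acids are identified in
ancient coprolites). A seeded generator produces synthetic cohorts with the
statistical structure these analyses assume, so the entire pipeline is
testable without any external data.

## Structural model and nomenclature

A `bile_salt` descriptor captures what matters downstream: total skeleton
carbons (23, 24 or 27), side-chain terminal group (carboxylic acid vs
alcohol), the A/B ring junction (5&alpha; "allo"/trans vs 5&beta;/cis),
hydroxyl positions with orientation (&alpha;/&beta; on the nucleus, *R*/*S*
at side-chain stereocentres), oxo positions, double bonds, and conjugation
(none, glycine, taurine, sulfate). The parser accepts the steroid
nomenclature found in survey tables — `3α,7α-dihydroxy-5β-cholan-24-oic
acid`, with Greek, ASCII (`3a`) or spelled-out (`3alpha`) orientations — plus
trivial names and abbreviations (CA, CDCA, DCA, LCA, UDCA, varanic,
pythocholic, bitocholic, hyocholic, the muricholic acids, allocholic acid,
the cyprinols). The canonical rendered form uses ASCII `a`/`b`, because
source tables mix encodings; every descriptor round-trips through
render-then-parse, which the suite checks for the whole registry and for
randomized descriptors.

Two conventions deserve note. First, the hydroxyl at the terminal side-chain
carbon of a bile alcohol is part of the terminal group: it is implied when a
name such as `3a,7a-dihydroxy-...-cholestan` omits it, and the formula
arithmetic counts it in the alcohol base rather than as a substituent.
Second, the C23 skeleton (24-nor bile acids, found in some viperid snakes)
is rendered `norcholan` and accepted in `24-nor-cholan` spellings; C23 acids
fall outside the three broad compound types and classify as `other`.

## Compound types and the class I–VI scheme

Side-chain length and terminal oxidation state define three broad compound
types: C27 bile alcohols, C27 bile acids and C24 bile acids. A species'
profile class is determined by which types reach 10% or more of its total
biliary bile salts: I (alcohols only), II (alcohols + C27 acids), III
(alcohols + C24 acids), IV (C27 acids only), V (C27 + C24 acids), VI (C24
acids only).

Decisions where the rules leave room:

* **Thresholds.** "10% or greater" is inclusive (&ge;10); "more than 50%"
  for a *major* bile salt is strict (&gt;50). The *minor* label covers
  (10, 50], making the major/minor/trace partition exhaustive; a component
  at exactly 10% is trace for labelling purposes even though it counts
  toward classification.
* **No renormalization.** Classification uses reported percents as printed;
  the remainder up to 100% is unidentified material and is not
  redistributed. An absolute 10% threshold is deliberately not
  scale-invariant, so the package never rescales percents on the user's
  behalf. The invariances that do hold — row order, duplication of input
  rows — are property-tested.
* **All three types &ge;10%** is reported as `mixed` rather than silently
  forced into the one-or-two-type scheme.
* **Conjugation is ignored for aggregation**: glyco- and tauro-conjugates of
  the same acid contribute to the same aglycone type.

A profile is *complex* when two or more types each reach 10%, and/or three
or more individual bile salts each reach 10%. The diet cross-tabulation
reports, per diet group (carnivore &gt;90% meat, herbivore &gt;90% plant,
omnivore otherwise), the percent of complex profiles, the percent whose
major bile salt is cholic acid, chenodeoxycholic acid or another C24 acid,
and the percent "primarily" using C27 bile acids — operationalized as an
aggregate C27-acid percent above 50, since no sharper definition is
standard. Percentages are half-up rounded to one decimal.

## Mass spectrometry annotation

Molecular formulas are built arithmetically from saturated scaffold bases
(C24 acid C24H40O2, C27 acid C27H46O2, C27 alcohol C27H48O): +O per
hydroxyl, +O −2H per oxo, −2H per double bond, and the conjugate residue
(glycine amide +C2H3NO, taurine amide +C2H5NO2S, sulfate ester +SO3).
Whether an oxo arose from a hydroxyl or de novo is irrelevant — only the
final composition matters for mass. Monoisotopic masses come from a single
embedded six-decimal table, and the [M−H]&minus; ion subtracts a fixed
proton mass of 1.007276 u, for bit-reproducible output. The resulting
conjugation mass deltas (glycine 57.0215, taurine 107.0041, sulfate
79.9568 Da) are verified against independent elemental summation to 1e-4.

`annotate_peaks()` matches observed m/z against a bounded search space of
*structural equivalence classes* — position-agnostic counts of hydroxyls
(0–4), oxo groups (0–2) and double bonds (0–2) over C23/C24/C27 acids and
C27 alcohols with each conjugation state — because a single m/z cannot
localize substituents. The default mass window is 0.5 Da, appropriate to
unit-resolution quadrupole data; narrow it (e.g. 0.005 Da) for
high-resolution spectra. No instrument tolerance is standard for calling a
peak "consistent with" an assignment, so the default is a documented choice,
and every candidate inside the window is reported sorted by absolute error.
Out of scope: MS/MS fragment prediction, isotope patterns, sterol/stanol
annotation, retention modelling.

## Parsimony ancestral states

`fitch_ancestral()` performs a bottom-up most-parsimonious reconstruction of
a discrete character on a rooted tree. At each internal node the state set
is the set of states supported by the maximum number of child sets —
Hartigan's generalization of the Fitch intersection/union rule — and the
change count accumulates (children − maximum support). For binary nodes this
is exactly Fitch; for polytomies it remains exact, which matters because a
naive pairwise intersection pass undercounts changes (four children coded
x, x, y, y yield one change pairwise but the true minimum is two). The suite
verifies count *and* root-set equality against exhaustive enumeration of all
internal labelings on 1,000 random trees of up to six tips and three states,
polytomies included.

The full most-parsimonious root set is always reported; ties are
information, not errors. Tips without states are pruned by default (an
`error` policy is available). Characters for group-level inference are
presence/absence of each broad compound type at the 10% threshold, rather
than the seven-level class character, because ancestral arguments are about
gains and losses of types. The shipped amniote fixture
(`inst/extdata/amniote_tree.nwk` + `amniote_tip_codings.csv`) encodes the
group-level topology with Testudines sister to Crocodylia+Aves and tip
codings assembled from descriptive accounts of each group's bile; it is an
editable working hypothesis, not a published data table. On it, the
Testudines/Crocodylia/Aves ancestor reconstructs with both C27 alcohols and
C27 acids present — the profile paleognath birds retain.

## Protein identity

`pairwise_identity()` aligns two amino-acid sequences globally
(Needleman–Wunsch, BLOSUM62, gap open 10, gap extend 0.5) and reports
identical positions over alignment columns *including gap columns*, times
100, to one decimal. Published identity figures rarely state their alignment
method, so values computed here should be treated as approximations of such
figures rather than exact reproductions; the scoring choices are fixed and
documented for reproducibility. When several alignments tie on score the
traceback choice can shift identity by a few tenths of a percent between
argument orders on unrelated sequences; for diverged copies of a sequence
the optimum is unambiguous and the measure is symmetric.

## The synthetic cohort generator

`sim_config()` + `simulate_tree_and_characters()` + `generate_profile_table()`
emulate the structure a comparative survey assumes:

* **Trees**: Yule (pure-birth) family backbone scaled to unit height;
  within-family subtrees of height 0.1.
* **Characters**: symmetric Mk process along backbone branches
  (`ape::rTraitDisc`), with true internal states retained so recovery can be
  scored. Species inherit the family state, flipping with a configurable
  (default zero) probability — mirroring the strong within-family
  conservation of real profiles, where heterogeneous families are rare
  exceptions.
* **Compositions**: component percents are Dirichlet draws over
  class-appropriate compound menus, concentration 50. Single-type classes
  are made *complex* (three balanced components, each &ge;10% with
  overwhelming probability) with a per-diet probability `complexity_q`, and
  otherwise get one dominant plus one trace component; two-type classes draw
  one component per type and are complex by construction.
* **Defaults as study conditions**: the default `complexity_q`
  (carnivore 0.398, herbivore 0.705, omnivore 0.500) reproduces the observed
  mammalian complexity rates; the acceptance script also builds a
  reptile-style cohort (183/15/17 species per diet; C27-acid use 0.246 /
  0.667 / 0.882; complexity 0.098 / 0.067 / 0.059) from the published group
  rates.

All randomness flows from the config seed (profile generation derives a
fixed offset so tree and composition draws are independent); identical
config + seed gives byte-identical tables, and configs serialize to flat
`key=value` text. What the generator does **not** emulate: mass-spectral
noise beyond optional Gaussian m/z jitter, secondary (microbial)
modification dynamics, unidentified material (generated percents sum to
100), and correlation between diet and profile — diet is assigned
independently of the class character, which is exactly the null the
cross-tabulation should recover. Passing tests on generated data therefore
demonstrate the pipeline's internal correctness and calibration, not claims
about any real cohort.

## Problem sizes and numerical choices

The test suite runs at desk scale: the class/complexity truth table is
exhaustive over the \{0, 5, 10, 50, 90, 100\}&sup3; percent grid; the
parsimony oracle covers 1,000 random trees of &le;6 tips (&le;3 states,
&le;243 labelings each); root-state recovery uses 500 replicates of 64-tip
Yule trees with a 2-state character at rate 0.05 per unit height (recovery
&ge;90% required; the analysis of record reports the observed rate);
generator calibration uses 400 species per diet group, checked against 99%
binomial intervals of the configured probabilities. Percent reporting is
half-up at one decimal, m/z at four decimals. Ties in `major_minor` (two
components at exactly 50%) yield no major component, by the strict &gt;50
rule.

## Known limitations

* The nomenclature parser covers the hydroxy/oxo/unsaturation/conjugation
  vocabulary of comparative bile-salt tables, not full IUPAC steroid
  nomenclature (no ring-seco, homo/nor variants beyond 24-nor, or ester
  side-chains).
* Classification thresholds are absolute; with large unidentified fractions
  a profile can be legitimately unclassifiable (reported as an error naming
  the species, never coerced).
* Parsimony is unweighted; Dollo or weighted-step matrices and
  likelihood/Bayesian reconstruction are out of scope.
* m/z annotation is aglycone-composition-level only; isobaric positional
  isomers (e.g. cholic vs pythocholic acid) are indistinguishable by [M−H]−
  mass, and the reported equivalence classes make that explicit.
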