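---
title: "Methods: screening mitochondrial 12S rRNA variants for deafness association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening mitochondrial 12S rRNA variants for deafness association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mito12s)
```

## The screening problem

Aminoglycoside ototoxicity has a strong mitochondrial component: mutations
in the 12S rRNA gene (MT-RNR1), foremost 1555A>G and 1494C>T at the
ribosomal A-site, predispose carriers to irreversible hearing loss after
exposure to drugs such as gentamicin or streptomycin. A screening study of
a hearing-impaired cohort asks, for every nucleotide change observed in
the gene: how often does it occur in cases versus unaffected controls, how
conserved is the position across primates, what does it do to the rRNA
secondary structure, and — combining these — is it plausibly pathogenic?
This package implements that entire analysis as reusable, tested
functions, exercisable end to end on packaged fixtures and synthetic data
so that no external download is ever required.

All genomic coordinates are 1-based rCRS (revised Cambridge Reference
Sequence) positions, because that is how the field names these variants
(1555A>G). The analyzed rRNA region is fixed at rCRS 648–1601 in the
packaged configuration — the amplicon (618–2007) is what the assay
dictates, while the gene span itself is configurable rather than
hard-coded.

## Variant calling

Subject amplicons are compared with the reference by global
Needleman–Wunsch alignment with match +1, mismatch −1, gap open −4 and gap
extend −1 (delegated to `Biostrings::pairwiseAlignment`). Any sensible
scoring scheme agrees on Sanger-quality input that is ≥ 90% identical to
the reference; the fixed scheme exists so that tie-breaking is
reproducible, not because the calls depend on it. Sequences outside ±10%
of the region length or below 90% aligned identity are rejected as
unalignable, and reverse-complement input is detected (by realigning the
reverse complement) and rejected rather than silently miscalled.

Indels are left-normalized to the 5'-most equivalent position, which makes
the call independent of where in a homopolymer the aligner happened to
open the gap. Canonical left-normalized names are then mapped through a
small alias table to the legacy spellings the field prints — on the
packaged reference the extra C in the 957–960 homopolymer normalizes to
956insC and is reported under its legacy name 961insC. Every call is
emitted as homoplasmic, matching the screening assumption for this locus;
ambiguous bases (N) produce a recorded no-call at the position, never a
variant. Heteroplasmy fractions, base qualities and chromatogram parsing
are out of scope.

## Conservation index

The conservation index of a position is the percentage of a 14-species
primate panel — the human reference row included — carrying the human
wild-type base:

$$\mathrm{CI}(p) = 100 \cdot \frac{n_\text{matching}(p)}{14}$$

Counting the human row means a position where every other species differs
still has CI = 1/14 ≈ 7.1%, never 0, and the attainable values form the
lattice {0, 7.1, 14.3, 21.4, …, 85.7, 92.9, 100}. Rounding is half-up to
one decimal (so 78.571 → 78.6 and 92.857 → 92.9). Gaps and ambiguity
codes in non-human rows count as non-matching — the strictest reading of
"carries the wild-type nucleotide". Insertion variants take the CI of
their named flanking reference position, so an insertion and a
substitution at the same position report the same value. Threshold
comparisons downstream always use the integer species count, never the
rounded percent, because the lattice has no value strictly between 71.4
and 78.6. No tree inference or model-based conservation score (phyloP,
GERP) is attempted.

## Secondary structure

The structure model is data, not computation: a curated table of apposed
position pairs, each flagged Watson-Crick-paired or apposed-but-unpaired
in the wild type. The A-site appearance of the model is the pair
(1494, 1555), apposed but unpaired, so that 1494C>T creates U-A and
1555A>G creates G-C. A position is *stem* iff it belongs to a pair;
everything else is *loop*. For a stem substitution the effect is derived
by comparing the WC status of (reference base, partner base) against
(alternate base, partner base): non-WC → WC is *creates*, WC → non-WC is
*abolishes*, anything else — including wobble-to-wobble changes and all
loop positions and indels — is *none*. Pair labels use the RNA alphabet
with the variant position's base first.

The packaged model reproduces all 17 arrow-annotated pairing effects in
the variant catalogue (5 creating, 12 abolishing) and therefore marks 17
of the 41 variants as stem-located. Published prose counts of 18 stem
variants exist for this catalogue; the 18th stem position is not
identifiable from the arrow annotations, so the curated model ships with
17 covered variant positions and this mismatch documented rather than an
invented extra pair. Pairs not constrained by the catalogue are
configurable. De-novo thermodynamic folding is explicitly out of scope.

## Three-criterion classification

Variants are classified by, in order of precedence:

1. **Registry** — {1555A>G, 1494C>T, 1095T>C} are `known_pathogenic`
   unconditionally. 1095T>C appears in one of 449 controls, yet is an
   established deafness mutation; the registry exists precisely so that
   prior knowledge overrides the control-absence criterion.
2. **Criteria 1 ∧ 2** — absent in the control panel (count = 0) *and*
   conserved in ≥ 11 of 14 species (CI ≥ 78.6%) →
   `putative_deafness_associated`.
3. **Haplogroup markers** — 13 registered lineage-defining variants across
   haplogroups A, B4, B5, D4, D5, F2, M9a and R5b →
   `haplogroup_polymorphism` (adaptive or neutral).
4. Everything else → `polymorphism`.

Criterion 3 (structural/functional evidence) is reported as an evidence
tier — `stem_wc_change` for stem substitutions altering a WC pair,
`loop_high_ci` for loop positions conserved in ≥ 13 of 14 species — but
does **not** gate the putative call: the canonical putative set includes a
loop variant (1027A>G, CI 92.9%), so membership is decidable from
criteria 1 ∧ 2 alone while the tier preserves the stem/loop argument. On
the packaged catalogue this yields 19 control-absent variants, 18 at or
above the conservation threshold, 7 passing both criteria, and — after
removing the registry — the putative set
{747A>G, 839A>G, 1027A>G, 1310C>T, 1413T>C}.

## Cohort statistics

The pure-tone average is the mean of the five audiometric thresholds at
500/1000/2000/4000/8000 Hz; severity follows the five-grade scale
(normal < 26 dB, mild 26–40, moderate 41–70, severe 71–90, profound
> 90), with subject-level severity defined as the grade of the worse
(higher-PTA) ear. On the packaged 44-subject clinical table this rule
reproduces 42 of 44 recorded labels; the two discordant subjects
(FE122-III-2 at 71 dB, NB038-III-1 at 90 dB) sit exactly on grade
boundaries and are flagged as fixture-level discrepancies rather than
silently corrected.

All percentages are recomputed from integer counts — never read from a
fixture — rounded half-up to one decimal, with two decimals below 1% so
that 2/440 reports as 0.45 rather than an ambiguous 0.5. The
aminoglycoside-attributable fraction is the share of exposed subjects
carrying at least one variant classified known or putative; the package
reports the exact fraction (27/98 = 27.6% under the packaged study
conditions) rather than a rounded headline figure.

## Synthetic data: what it emulates and what it does not

Because neither the true rCRS nor primate GenBank records can be bundled,
the packaged reference is a *synthetic* rCRS-like amplicon: random
sequence carrying the documented bases at all 41 catalogued variant
positions, at every curated stem-partner position, and a bounded C
homopolymer before position 961 to exercise insertion normalization. The
GJB2 reference is likewise a synthetic CDS of the correct length (678 nt)
with the documented bases at the screened positions; a real sequence can
be dropped in by path without code change. Both filenames mark them
synthetic.

The generators are pure functions of (specification, seed):

* `generate_primate_alignment()` builds a gapless 14-row alignment whose
  human row is the reference and where each specified position has
  exactly the requested number of matching species; unspecified positions
  diverge at a background rate of 0.1 per non-human row — an arbitrary but
  documented figure that no assertion depends on, since tests always
  target specified positions. There is no phylogenetic correlation
  between rows.
* `generate_cohort()` plants variants into subject and control sequences
  so that re-calling recovers the plan exactly. The default plan *is* the
  packaged study's marginals: 440 cases (227 male), 449 controls, 98
  exposed (58 male), the catalogue's carrier counts, the clinical table's
  exposure split for known/putative carriers (21 + 2 + 2 + 2 exposed),
  severity histograms {22 severe, 76 profound} (exposed) and {26
  moderate, 167 severe, 149 profound} (unexposed). Carriers of known and
  putative mutations are mutually exclusive, matching the non-overlapping
  carrier groups of the clinical table; other variants co-occur freely
  except at conflicting positions.
* Audiograms draw five thresholds uniformly within the planned grade's
  dB interval (worse ear), so the recomputed PTA provably lands in the
  planned grade; `generate_audiogram()` recenters jitter to hit a
  prescribed PTA exactly.

Passing tests on these data demonstrate the *bookkeeping* — calling,
counting, classification and grading are exact inverses of the planting
process — not that the pipeline tolerates real-world artifacts such as
chromatogram noise, alignment-ambiguous structural variation,
heteroplasmy or phylogenetically structured conservation. Those are
documented non-goals.

## Numerical and design choices

* Rounding is half-up everywhere a percent is printed; base R's
  round-half-even would disagree on lattice values like 85.714.
* Alignment tie-breaks are delegated to the alignment engine and are
  deterministic; calls on ≥ 90%-identity input do not depend on them.
* Degenerate inputs fail loudly with named errors: multiple FASTA
  records, alphabet violations, duplicate structure-pair positions,
  duplicate subject ids, infeasible cohort plans, empty subgroups.
* The classifier compares integer counts (control carriers, species
  matches); rounded percents are display-only.
* Problem sizes in the test suite are the package's own choice of desk
  scale: the full 440/449 cohort is generated as a subject table, while
  sequence-level plant-and-recall round-trips run on 200 random variant
  sets and 50 random small cohort plans, which together exercise every
  code path of the generator/caller pair.

## Known limitations

* The curated structure model covers the 17 arrow-annotated variant
  positions; it is not a complete 12S rRNA secondary structure.
* The conservation generator matches per-position counts, not realistic
  primate substitution processes.
* GJB2 screening assumes per-allele input (phase known); a single
  consensus sequence is screened as one allele with a phase-unknown
  warning, and non-coding GJB2/GJB6 lesions are not screened.
* Attributable-fraction logic requires a classification for every carried
  variant and refuses to guess at unclassified names.
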