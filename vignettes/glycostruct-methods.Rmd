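---
title: "Branch-resolved N-glycopeptide identification and TMT quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-resolved N-glycopeptide identification and TMT quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glycostruct implements a quantitative, site-specific N-glycoproteomic
analysis for dual-energy HCD experiments: each glycopeptide precursor is
fragmented twice, once at high collision energy (peptide b/y ions, TMT
reporter region) and once at low collision energy (glycan B and Y ions).
The high-energy scan identifies the peptide backbone; the low-energy scan
resolves the attached glycan down to its branch structure, including the
discrimination of LacdiNAc (GalNAc&beta;1-4GlcNAc, modeled HexNAc–HexNAc)
from its composition-isomeric LacNAc arrangements. This vignette documents
the model, its conventions, its noise assumptions, and what the test suite
does and does not establish.

## The glycan model

A glycan structure is a rooted tree summarised as one of four core motifs —
the trimannosyl-chitobiose core HexNAc2Hex3, optionally core-fucosylated
and/or carrying a bisecting GlcNAc — plus a multiset of branch motifs drawn
from a 12-motif library (four families: GlcNAc, LacNAc, LacdiNAc, Mannose;
NeuAc and Fuc decorations). The library ships as editable YAML
(`inst/extdata/branch_library.yaml`); the exact motif inventory beyond the
family structure and count is a curated reconstruction, so it is
configuration, not code. Linkage annotations (&alpha;2-6, &beta;1-4) are
carried for reporting only — MS2 at this granularity cannot resolve them,
and no matching decision uses them.

Masses are fixed monoisotopic residue masses (Hex 162.052824, HexNAc
203.079373, Fuc 146.057909, NeuAc 291.095417; proton 1.007276; water
18.010565). These reproduce the conventional diagnostic oxonium ions at two
decimals: HexNAc2 407.17, HexNAc1NeuAc1 495.18, HexNAc2NeuAc1 698.26.

Theoretical B ions are all contiguous sub-fragments of each decorated
branch (so a sialylated LacdiNAc yields 407.17, 495.18 and 698.26) plus the
single-residue oxonium ions every core produces. Theoretical Y ions are the
peptide plus every connected remnant obtainable by pruning branches
terminally: the core ladder (Y0, Y1, HexNAc2, +Hex1..3), Fuc-shifted
variants for core-fucosylated structures, and the full core combined with
every branch root-prefix. Enumeration of candidate structures for a
composition is exhaustive over the library under two caps chosen to bound
the search to observed biology: at most 4 HexNAc-initiated antennae and at
most 6 mannose-family branches (enough for Man9).

## Identification and scoring

Spectrum pairs are formed greedily: each low-energy scan takes the
unclaimed high-energy scan nearest in retention time whose precursor agrees
within 10 ppm at equal charge. Pairs must pass the classic oxonium screen
(at least 2 reference oxonium ions among the 10 most intense peaks, 20 ppm).

Peptide candidates come from an in-silico tryptic digest (cleave after K/R
except before P, up to 2 missed cleavages, length 6–45, mass 600–6000 Da)
restricted to sequon-bearing peptides (N-X-S/T, X &ne; P) whose
precursor-minus-peptide remainder is decomposable into a glycan composition
within 10 ppm. The peptide score is the -log10 tail probability of the
matched b/y count under a hypergeometric null (theoretical ions drawn
against observed peaks spread over 0.02 Da bins); this is a documented
surrogate for proprietary search-engine scores, chosen because it is
monotone in matched ions and has no tunable weights.

The glycan score for a candidate structure is
`0.5 * (fraction of theoretical B+Y ions matched) + 0.5 * (fraction of
observed intensity explained) + 0.1 per confirmed branch`, where a branch is
confirmed by its intact decorated oxonium ion and only multi-residue
oxonium ions count (single residues are produced by every core and carry no
branch information). Two hard gates implement isomer discrimination: a
structure containing a LacdiNAc branch is admissible only if a
HexNAc2-containing B ion (HexNAc &ge; 2, Hex = 0) is matched, and a LacNAc
branch requires a HexNAc1Hex1-containing ion. Y-ion charges are tested at
1..min(2, precursor charge); B ions at charge 1.

Some assemblies are genuinely indistinguishable at this granularity: a
bisecting GlcNAc produces exactly the same theoretical B/Y composition sets
as a bare GlcNAc antenna, and Hex-only branch groupings (e.g. Man7 as two
versus three mannose branches) can coincide. Score ties are therefore
resolved by a fixed convention — fewer branches first (reading an
unassignable core-proximal HexNAc as bisecting), then the simpler core,
then library order, then canonical text — and the synthetic generator emits
only convention-canonical representatives, so closed-loop recovery measures
the pipeline rather than the convention. Real data interpreted with this
package inherits the same convention, and bisecting/antennary-GlcNAc calls
should be read accordingly.

When a peptide carries two sequons the site is reported at the first sequon
and flagged ambiguous; fragment-level site localization is not attempted.

## Decoys and FDR

FDR is controlled independently at the peptide and glycan levels at 1%.
Peptide decoys are pseudo-reversed (C-terminal residue fixed), which
preserves tryptic mass and charge properties; because reversal destroys
N-X-S/T motifs, decoys inherit their parent's glycopeptide-space membership
with nominal sites at N residues — the attachment position does not affect
any competed mass, and an unbiased target-decoy competition requires equal
target and decoy space sizes. Glycan decoys are mass-shifted structural
hypotheses (+17.0027 Da per branch motif) scored against the same spectra;
the shift is arbitrary but fixed, seedable and documented. The threshold is
the smallest score at which #decoys/#targets above it drops to the nominal
level; when a level produces no decoy wins at all (routine on clean
synthetic data) that level's FDR estimate is zero at any cutoff and all
targets pass. Module-level confidence is surfaced as per-module evidence
counts (matched B ions per branch, matched Y ions for the core) rather than
a calibrated probability; calibrating such probabilities would need a
reference implementation that is out of scope here.

## Quantification

Reporter intensities (channels 129C, 130C, 130N, 131 = HCC paracancer, ICC
paracancer, HCC tumor, ICC tumor; extraction window &plusmn;0.003 m/z) are
first rescaled by global factors derived from the proteome run
(`mean(channel totals) / channel total`), then aggregated per glycopeptide
key (protein, peptide, site, canonical structure) as per-channel medians
over at least 5 PSMs; missing channels are excluded from the median, never
imputed as zero. The four between-group ratios and, where the parent
protein is quantified, normalized glycosylation (glycopeptide ratio divided
by protein ratio) follow. Protein rollup uses the median over PSMs; with a
pooled one-channel-per-group design no per-patient variance exists and none
is claimed. Total-intensity scaling assumes the proteome is dominated by
unchanged proteins with direction-balanced changes; the generator enforces
that balance because at a scaled-down proteome size a one-sided shift
visibly contaminates the factors.

## Fold-change categorization

With a twofold cutoff, each quantified glycopeptide receives exactly one
label by a fixed-precedence decision tree: paracancer baselines differing
(ICCP/HCCP outside [0.5, 2]) are set aside first; changes whose normalized
glycosylation stays inside the band while the glycopeptide ratio is outside
are `protein_level_only` (protein-expression exclusion takes precedence
over the common/specific labels); both tumor arms changed gives
`common_up`/`common_down`; exactly one arm changed gives the
ICC-/HCC-specific labels; opposite directions give `opposite`. Requiring an
additional twofold ICC/HCC contrast for the specific labels is available as
`require_tumor_contrast = TRUE` but is off by default: the reference
worked example (ratios 2.21 / 1.30 / 1.56 / 0.92) is an ICC-specific
increase even though its tumor-tumor contrast is below twofold, so the
contrast requirement cannot be part of the default rule.

PCA operates on log2 per-channel medians with channels as observations;
hierarchical clustering of log2 fold changes uses Euclidean distance with
average linkage (complete linkage is a common default elsewhere; average is
less sensitive to single outlier rows, and the linkage is switchable).

## The synthetic study and what the tests show

The generator emulates the pooled four-channel design: 200 glycopeptides on
a 30-protein proteome, 5–8 PSMs each, log-normal base abundances
(meanlog log 1e5, sdlog 0.8), a LacdiNAc class comprising 15% of
glycopeptides of which 96% are elevated in the ICC channel with folds
uniform on [2, 5] (HCC arm ~1), background glycosylation changes on 15% of
the rest, protein-level expression changes on 10% of proteins
(direction-balanced, magnitude 2–3), multiplicative log-normal reporter
noise (sigma 0.1), Poisson noise peaks (mean 30/scan), 3 ppm m/z jitter,
and optional per-channel loading bias and junk-spectrum spiking for FDR
calibration. Oxonium-region B ions are drawn more intense than Y ions, as
in real low-energy HCD of glycopeptides. Everything is deterministic per
seed, and a manifest records each glycopeptide's true structure and channel
abundances.

The generator does not model chromatographic elution, isotope envelopes,
co-isolation interference, missing fragment ions, or peptide-level
interference — so passing tests demonstrate the correctness of the
matching, gating, FDR and quantification logic under the stated noise
model, not robustness to every artifact of real acquisitions.

One quantitative consequence of the noise model is worth stating: with
sigma 0.1 reporter noise and medians over 5–8 PSMs, a single
between-group ratio carries ~6–8% standard error, so across the ~800
ratios of a full study roughly 1% land more than 20% from their designed
value (observed at seed 1: 7 of ~800, largest deviation ~24%).
Per-glycopeptide ratio recovery is therefore summarised as the fraction of
ratios within &plusmn;20% rather than a guarantee that every single ratio
is. A second, seed-dependent term comes from the scaled-down proteome:
with 30 proteins of log-normal abundance, the realized direction imbalance
of protein-level changes leaves a few-percent residual in the
total-intensity scaling factors that shifts all ratios of a channel pair
together — at some seeds this pushes the within-20% fraction down to
~90%. At realistic proteome sizes (thousands of quantified proteins) this
residual vanishes; it is a property of the scale-down, not of the
normalization logic, which the loading-bias tests verify directly.

Problem sizes in the test suite (a 200-glycopeptide default study, 25–60
glycopeptide studies for unit fixtures, five 60-glycopeptide spiked studies
for FDR calibration) were chosen to keep the whole suite in the
few-minutes range on one CPU while leaving every statistical check
well-powered.

## Known limitations

* Linkage isomers (e.g. &alpha;2-3 vs &alpha;2-6 sialylation) are outside the
  model; branch families, decorations and core variants are the resolution
  limit.
* The bisecting-vs-GlcNAc-antenna convention above means those two readings
  are reported by convention, not evidence.
* TMT is applied as a static modification on peptide N-termini and, by
  default, on lysines (`tmt_k = FALSE` switches K labeling off); variable
  oxidation/acetylation are supported in mass computation but not searched
  variably by the engine.
* Isotope-impurity correction of reporter channels and O-glycans are out of
  scope.
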