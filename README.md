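# glycostruct

Branch-resolved identification and TMT quantification of intact
N-glycopeptides from dual-energy HCD MS/MS.

## The problem

Most glycoproteomic searches report glycan *compositions* (e.g. `N5H4F1S1` =
HexNAc5 Hex4 Fuc1 NeuAc1). But isomeric structures with very different
biology share a composition: in particular the uncommon LacdiNAc antenna
(GalNAcβ1-4GlcNAc, i.e. HexNAc–HexNAc) is isomeric with common LacNAc
(Galβ1-4GlcNAc) arrangements combined with a bisecting GlcNAc. LacdiNAc
elevation is a candidate tissue signature of intrahepatic cholangiocarcinoma
(ICC) versus hepatocellular carcinoma (HCC), so resolving it matters.

glycostruct is for analysts working with paired-energy HCD acquisitions:
each precursor is fragmented at high collision energy (peptide b/y ions +
TMT reporters) and at low collision energy (glycan B/Y ions). The package

* builds a glycosite-restricted tryptic search space from a protein FASTA
  (N-X-S/T sequons, X ≠ P; TMT and carbamidomethyl statics),
* pairs low/high-energy MS2 scans and screens them by oxonium ions
  (≥ 2 of the top-10 peaks),
* assigns the glycan structure — core (plain / core-fucosylated / bisecting /
  both) plus a multiset of branch motifs from a 12-motif library — by
  scoring theoretical B and Y ions against the low-energy scan under a
  10 ppm precursor / 20 ppm fragment tolerance, with hard diagnostic gates:
  a LacdiNAc branch is only accepted when a HexNAc2-containing B ion
  (m/z 407.17, 553.22 or 698.26) is matched,
* controls FDR at 1% independently for peptide and glycan assignments
  (pseudo-reverse peptide decoys; mass-shifted glycan decoy hypotheses),
* quantifies glycopeptides from TMT reporter channels
  (129C/130C/130N/131 = HCC-paracancer/ICC-paracancer/HCC-tumor/ICC-tumor)
  with proteome-derived scaling factors, per-channel medians over ≥ 5 PSMs,
  between-group ratios and normalized glycosylation (glycopeptide ratio /
  protein ratio),
* categorizes each quantified glycopeptide at a twofold cutoff into
  common / tumor-specific / protein-level-only / opposite / unchanged
  alterations, with structural feature summaries, PCA and hierarchical
  clustering exports.

A fully ground-truthed synthetic study generator (FASTA + paired-energy
runs + manifest) makes every stage testable end to end without any
external data.

## Worked example

```r
library(glycostruct)
library(dplyr)

# a ground-truthed synthetic study: 200 glycopeptides, 4 TMT channels,
# LacdiNAc class elevated 2-5x in the ICC channel
st    <- generate_study(study_design(), seed = 1)
index <- build_peptide_index(st$proteins)
pairs <- pair_spectra(st$glyco_run)
psms  <- identify_pairs(pairs, index)
fdr   <- apply_dual_fdr(psms, alpha = 0.01)

sf    <- proteome_scaling_factors(st$proteome_psms)
quant <- aggregate_glycopeptides(apply_scaling(fdr$accepted, sf), min_psm = 5)
prot  <- protein_quant(apply_scaling(st$proteome_psms, sf))
res   <- quant |>
  add_normalized_glycosylation(prot) |>
  add_structure_features() |>
  categorize_glycopeptides(cutoff = 2)

table(res$category)
#> paracancer_differs protein_level_only          common_up        common_down
#>                  0                 10                  5                  3
#>    icc_specific_up  icc_specific_down    hcc_specific_up  hcc_specific_down
#>                 33                  1                  5                  3
#>           opposite          unchanged
#>                  0                139
```

Most of the ICC-specific increases are the designed LacdiNAc class, and
every structure call is branch-resolved:

```r
res |> filter(has_lacdinac) |> count(category)
#>             category  n
#> 1 protein_level_only  4
#> 2    icc_specific_up 24
#> 3          unchanged  2

tidy(parse_structure("core_fucosylated(LacdiNAc+NeuAc,LacNAc)"))
#>   canonical                               composition  mass subtype core_kind        ... has_lacdinac
#> 1 core_fucosylated(LacdiNAc+NeuAc,LacNAc) N5H4F1S1    2101. complex core_fucosylated ... TRUE
```

The category table and LacdiNAc counts above are the pipeline's own output
for seed 1: the glycopeptides recovered as ICC-specific increases are
dominated by the elevated LacdiNAc class, the pattern this analysis is
built to detect (LacdiNAc glycopeptides landing on proteins whose
expression also shifts are attributed to the protein level or masked, as
the normalization defines).

Plots: `plot_pca()`, `plot_feature_frequencies()`,
`plot_fold_change_heatmap()`; broom-style `tidy()`/`glance()` methods cover
FDR results and structures. See `vignette("glycostruct-methods")` for the
model, scoring and design conventions.

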