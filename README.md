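# lungspectral

Spectral unmixing, autofluorescence dissection and hierarchical gating
for full-spectrum flow cytometry of murine lung.

Lung tissue is one of the hardest targets for high-parameter flow
cytometry: alveolar macrophages and other resident cells fluoresce
across the entire detector range, and that background bleeds into
antibody channels after unmixing.  `lungspectral` is a tested R
implementation of the desk-side workflow that deals with this — for
immunologists and cytometrists who want the procedure as inspectable,
reproducible code rather than as clicks in acquisition software.

Per event, the 64-detector signal $y$ is modelled as a linear mixture
$y = Ma + \varepsilon$ over an endmember matrix $M$ whose columns are
the unit-norm spectra of 27 fluorochromes **plus selected
autofluorescence (AF) signatures treated as virtual fluorochromes**;
abundances $a$ are recovered by per-event least squares (QR, signed
solutions).  The AF columns come from the package's scatter-based
dissection of an unstained sample: 35 quantile-grid FSC/SSC bins →
median bin spectra → near-duplicate pruning (keep the brighter of any
pair with cosine similarity ≥ 0.98) → greedy forward selection that
minimizes the mean absolute unmixed fluorochrome abundance on unstained
events.  Panel QC (cosine similarity index, condition-number complexity
index, stain index, spillover-spreading matrix, bead-versus-cell
carrier choice) and a declarative 17-population gating hierarchy with
auto-derived thresholds complete the pipeline.  A synthetic generator
with ground truth — spectra, single-stain controls, unstained and fully
stained samples — makes every stage testable without instrument data.

## Worked example

```r
library(lungspectral)

panel    <- default_lung_panel()            # 26 antibodies + viability dye
profiles <- default_lung_profiles(panel)    # the 17 lung immune populations
endm     <- make_endmember_spectra(27, 3, seed = 7,
                                   names = panel$entries$fluorochrome,
                                   af_names = default_af_names())

sample <- simulate_sample(profiles, endm, panel, n = 20000, seed = 11)
#> <event_table> 20000 events x 64 detectors (+FSC-A/SSC-A/FSC-H);
#>   17 truth populations; seed=11

m  <- build_mixing_matrix(endm[panel$entries$fluorochrome],
                          endm[default_af_names()])
#> <endmember_matrix> 64 detectors x 30 endmembers (27 panel + 3 AF)

um <- unmix(sample, m)
#> <unmix_result> 20000 events x 30 endmembers (ols);
#>   median residual RMS = 0.7839

tree  <- derive_thresholds(build_lung_gate_tree(), um, sample,
                           profiles, panel)
gates <- apply_gates(um, sample, tree, panel)
evaluate_recovery(sample$truth_labels, gates$labels)$accuracy
#> [1] 0.9496

head(subset(gates$frequency, !is.na(population) & !parallel,
            c(population, count, freq_of_parent)), 8)
#>               population count freq_of_parent
#>               Neutrophil  1132            6.0
#>                   B cell  1121           12.5
#>    Inflammatory monocyte  1099           50.3
#>        Resident monocyte  1086           49.7
#>              Cytotoxic T  1112           33.3
#>                 T helper  2225           66.7
#>      Alveolar macrophage  1119           50.0
#>  Interstitial macrophage  1120           50.0
```

The frequency table follows the frequency-of-parent convention: each
count is expressed as a percentage of its immediate parent gate
(neutrophils of CD45+ leukocytes, inflammatory monocytes of the
monocyte gate, T helper of CD3+CD19− T cells, and so on).  With 17
equally weighted populations, sibling pairs sit near 50/50 and the
overall per-event label accuracy against the generator's ground truth
is ~0.95 at default noise.

`run_pipeline(run_config(seed = 1))` chains the whole thing — simulate,
extract and QC controls, choose carriers, dissect/prune/select AF,
unmix, gate — and writes CSV/JSON outputs plus an MD5-hashed manifest;
identical configurations reproduce identical hashes.

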