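#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: panel, layout, noise,
#' sample sizes, the AF dissection grid and thresholds, the unmixing
#' method and the master seed.  Defaults reproduce the standard
#' all-synthetic demonstration run.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_sample events in the fully stained sample.
#' @param n_unstained events in the unstained sample.
#' @param n_control events per single-stain control.
#' @param grid AF dissection grid `(fsc_cols, ssc_rows)`.
#' @param prune_threshold near-duplicate similarity threshold.
#' @param max_af maximum AF signatures to select.
#' @param select_tol relative-improvement stop tolerance for selection.
#' @param unmix_method `"ols"` or `"wls"`.
#' @param noise a [noise_model()].
#' @param panel a [panel_config()].
#' @param layout a [detector_layout()].
#' @param write_fcs also write FCS files next to the CSV outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_sample = 20000, n_unstained = 6000,
                       n_control = 1500, grid = c(7, 5),
                       prune_threshold = 0.98, max_af = 12,
                       select_tol = 0.05, unmix_method = "ols",
                       noise = noise_model(), panel = default_lung_panel(),
                       layout = detector_layout(), write_fcs = FALSE) {
  structure(list(seed = seed, n_sample = n_sample,
                 n_unstained = n_unstained, n_control = n_control,
                 grid = grid, prune_threshold = prune_threshold,
                 max_af = max_af, select_tol = select_tol,
                 unmix_method = unmix_method, noise = noise, panel = panel,
                 layout = layout, write_fcs = write_fcs),
            class = "run_config")
}

.stage_file <- function(out_dir, name) file.path(out_dir, name)

#' Run the full analysis pipeline
#'
#' Executes the six stages in order — simulate inputs, extract and QC
#' single-stain controls (choosing the bead/cell carrier per
#' fluorochrome), dissect/prune/select autofluorescence signatures,
#' assemble the endmember matrix and unmix the stained sample, derive
#' thresholds and gate, and write the QC/frequency report.  Every output
#' file is content-hashed (MD5) into the returned manifest; re-running
#' with an identical configuration reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return A `run_manifest`: per-stage file paths, MD5 hashes and
#'   summary values, plus the gating [evaluate_recovery()] summary.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("lsrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_seed = config$seed, stages = list())
  hash_add <- function(stage, files, info = list()) {
    manifest$stages[[stage]] <<- list(
      files = as.list(tools::md5sum(files)), info = info)
  }
  panel <- config$panel
  fluors <- panel$entries$fluorochrome
  af_names <- default_af_names()

  ## stage 1: simulate every input the wet workflow would provide
  endm <- make_endmember_spectra(length(fluors), length(af_names),
                                 layout = config$layout,
                                 seed = sub_seed(config$seed, 1),
                                 names = fluors, af_names = af_names)
  true_fluor <- endm[fluors]
  true_af <- endm[af_names]
  ## the biological sample carries the on-cell spectra of the channels
  ## whose emission shifts on cells; the shift is dye chemistry, shared
  ## with the cell-carrier controls
  sample_spectra <- c(cell_spectra(true_fluor), true_af)
  profiles <- default_lung_profiles(panel)
  stained <- simulate_sample(profiles, sample_spectra, panel,
                             n = config$n_sample, noise = config$noise,
                             seed = sub_seed(config$seed, 3))
  unstained <- simulate_unstained(profiles, true_af, noise = config$noise,
                                  n = config$n_unstained,
                                  seed = sub_seed(config$seed, 4))
  beads <- simulate_single_stain_controls(panel, true_fluor, "beads",
                                          noise = config$noise,
                                          seed = sub_seed(config$seed, 5),
                                          n_events = config$n_control)
  cells <- simulate_single_stain_controls(panel, true_fluor, "cells",
                                          noise = config$noise,
                                          seed = sub_seed(config$seed, 6),
                                          n_events = config$n_control,
                                          af_endmembers = true_af)
  f_sample <- .stage_file(out_dir, "stained_sample.csv")
  f_unst <- .stage_file(out_dir, "unstained_sample.csv")
  write_events_csv(stained, f_sample)
  write_events_csv(unstained, f_unst)
  if (isTRUE(config$write_fcs)) {
    write_fcs(stained, .stage_file(out_dir, "stained_sample.fcs"))
    write_fcs(unstained, .stage_file(out_dir, "unstained_sample.fcs"))
  }
  hash_add("simulate", c(f_sample, f_unst),
           list(n_sample = config$n_sample, n_unstained = config$n_unstained))

  ## stage 2: extract signatures from both carriers, QC, choose carrier
  bead_sigs <- lapply(fluors, function(f)
    extract_signature(beads[[f]], control_blank(beads[[f]]), name = f))
  names(bead_sigs) <- fluors
  cell_sigs <- lapply(fluors, function(f)
    extract_signature(cells[[f]], control_blank(cells[[f]]), name = f))
  names(cell_sigs) <- fluors
  m_bead <- build_mixing_matrix(bead_sigs)
  m_cell <- build_mixing_matrix(cell_sigs)
  ## both carriers are judged on the cell-carrier controls, the closest
  ## stand-in for the biological sample the matrix will unmix
  bead_qc <- qc_report(cells, m_bead, carrier = "beads")
  cell_qc <- qc_report(cells, m_cell, carrier = "cells")
  carrier <- choose_carrier(bead_qc, cell_qc)
  chosen_sigs <- lapply(fluors, function(f)
    if (carrier$carrier[carrier$fluorochrome == f] == "cells")
      cell_sigs[[f]] else bead_sigs[[f]])
  names(chosen_sigs) <- fluors
  f_sigs <- .stage_file(out_dir, "extracted_signatures.csv")
  f_carrier <- .stage_file(out_dir, "carrier_choice.csv")
  write_signatures(chosen_sigs, f_sigs)
  utils::write.csv(carrier, f_carrier, row.names = FALSE)
  hash_add("controls", c(f_sigs, f_carrier),
           list(cells_chosen = sum(carrier$carrier == "cells")))

  ## stage 3: AF dissection, pruning, greedy selection
  cand <- af_dissect(unstained, grid = config$grid)
  pruned <- af_prune(cand, threshold = config$prune_threshold)
  af_sel <- af_select(pruned, chosen_sigs, unstained,
                      max_af = config$max_af, tol = config$select_tol)
  f_af <- .stage_file(out_dir, "af_selected.csv")
  f_trace <- .stage_file(out_dir, "af_selection_trace.json")
  if (length(af_sel$signatures)) write_signatures(af_sel$signatures, f_af)
  else utils::write.csv(data.frame(), f_af, row.names = FALSE)
  jsonlite::write_json(af_sel$trace, f_trace, auto_unbox = TRUE, digits = NA)
  hash_add("af_dissection", c(f_af, f_trace),
           list(n_candidates = length(cand), n_pruned = length(pruned),
                n_selected = length(af_sel$members)))

  ## stage 4: assemble matrix and unmix the stained sample
  m_full <- build_mixing_matrix(chosen_sigs, af_sel)
  um <- unmix(stained, m_full, method = config$unmix_method)
  f_ab <- .stage_file(out_dir, "unmixed_abundances.csv")
  utils::write.csv(data.frame(um$abundances, check.names = FALSE), f_ab,
                   row.names = FALSE)
  hash_add("unmix", f_ab,
           list(endmembers = ncol(m_full),
                median_residual_rms = stats::median(um$residual_rms)))

  ## stage 5: derive thresholds and gate
  tree <- build_lung_gate_tree()
  tree <- derive_thresholds(tree, um, stained, profiles, panel)
  gr <- apply_gates(um, stained, tree, panel)
  rec <- evaluate_recovery(stained$truth_labels, gr$labels)
  f_freq <- .stage_file(out_dir, "population_frequencies.csv")
  f_labels <- .stage_file(out_dir, "event_labels.csv")
  utils::write.csv(gr$frequency, f_freq, row.names = FALSE)
  utils::write.csv(data.frame(event = seq_along(gr$labels),
                              label = gr$labels,
                              truth = stained$truth_labels),
                   f_labels, row.names = FALSE)
  hash_add("gate", c(f_freq, f_labels),
           list(populations = length(gate_targets(tree)),
                accuracy = rec$accuracy))

  ## stage 6: QC report
  f_qc <- .stage_file(out_dir, "qc_report.json")
  jsonlite::write_json(
    list(seed = config$seed,
         stain_indices_beads = as.list(bead_qc$stain_indices),
         stain_indices_cells = as.list(cell_qc$stain_indices),
         total_spread_beads = sum(bead_qc$spread),
         total_spread_cells = sum(cell_qc$spread),
         af_selected = af_sel$members,
         gating_accuracy = rec$accuracy),
    f_qc, auto_unbox = TRUE, digits = NA)
  hash_add("qc", f_qc, list())

  structure(list(out_dir = out_dir, stages = manifest$stages,
                 seed = config$seed, recovery = rec,
                 frequency = gr$frequency, af_selection = af_sel,
                 carrier = carrier),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed=", x$seed, ", ", length(x$stages),
      " stages completed, gating accuracy ",
      format(x$recovery$accuracy, digits = 4), "\n", sep = "")
  for (s in names(x$stages))
    cat("  ", s, ": ", length(x$stages[[s]]$files), " file(s)\n", sep = "")
  invisible(x)
}

#' Content hashes of a run manifest
#'
#' @param manifest a [run_pipeline()] result.
#' @return Named character vector of MD5 hashes, one per output file.
#' @export
manifest_hashes <- function(manifest) {
  unlist(lapply(manifest$stages, function(s) unlist(s$files)))
}
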