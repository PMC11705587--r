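## shared fixtures, built once per test run and memoised

.fx <- new.env(parent = emptyenv())

fx_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- default_lung_panel()
  .fx$panel
}

fx_profiles <- function() {
  if (is.null(.fx$profiles)) .fx$profiles <- default_lung_profiles(fx_panel())
  .fx$profiles
}

## the standard endmember set: 27 panel fluorochromes + 3 AF components
fx_endmembers <- function() {
  if (is.null(.fx$endm)) {
    panel <- fx_panel()
    .fx$endm <- make_endmember_spectra(
      nrow(panel$entries), 3, seed = 7,
      names = panel$entries$fluorochrome,
      af_names = default_af_names())
  }
  .fx$endm
}

fx_fluors <- function() fx_panel()$entries$fluorochrome

fx_mixing_matrix <- function() {
  if (is.null(.fx$m)) {
    endm <- fx_endmembers()
    .fx$m <- build_mixing_matrix(endm[fx_fluors()],
                                 endm[default_af_names()])
  }
  .fx$m
}

## the standard fully stained lung-like sample: 17 populations, equal
## weights, default noise, n = 20000, fixed seed — unmixed against the
## true endmember matrix with auto-derived thresholds
fx_standard_run <- function() {
  if (is.null(.fx$run)) {
    st <- simulate_sample(fx_profiles(), fx_endmembers(), fx_panel(),
                          n = 20000, seed = 11)
    um <- unmix(st, fx_mixing_matrix())
    tree <- derive_thresholds(build_lung_gate_tree(), um, st,
                              fx_profiles(), fx_panel())
    gates <- apply_gates(um, st, tree, fx_panel())
    .fx$run <- list(sample = st, unmixed = um, tree = tree, gates = gates,
                    recovery = evaluate_recovery(st$truth_labels,
                                                 gates$labels))
  }
  .fx$run
}

## small toy layouts for spectral unit tests
lay_n <- function(n) detector_layout(stats::setNames(as.integer(n), "A"))

## random non-negative spectrum on a layout
rand_spectrum <- function(n) stats::runif(n)
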