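# Shared fixtures: the three-drug reference setup and small helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_design <- function() {
  design_parallel(three_drug_targets(), reference_hardware())
}

ref_schedule <- function(design = ref_design(), horizon = 24) {
  build_schedule(design, horizon = horizon)
}

design_line <- function(design, drug) {
  design$lines[design$lines$drug == drug, , drop = FALSE]
}

# single first-dose-only schedule for one drug, with a long horizon for
# mass-balance integrations
single_dose_schedule <- function(design, drug, horizon = 400) {
  full <- build_schedule(design, horizon = 24)
  ev <- full[full$drug == drug & full$start == 0, , drop = FALSE]
  dose_schedule(ev, horizon = horizon)
}

max_rel_dev <- function(a, b, floor = 1e-9) {
  max(abs(a - b) / pmax(abs(b), floor))
}
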