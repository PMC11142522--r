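# Shared fixtures, built once per test run and cached: one 48^3 phantom
# subject with noiseless acquisitions of every sequence, plus the fitted
# maps. Several test files reuse these to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_phantom <- function() fixture("phantom", function() {
  build_phantom(c(48, 48, 48), asymmetry = 0, seed = 11)
})

fix_subject <- function() fixture("subject", function() {
  sample_subject(fix_phantom(), subject_seed = 21)
})

fix_series <- function() fixture("series", function() {
  simulate_acquisitions(fix_subject(), default_protocol(), snr = Inf,
                        noise_seed = 31)
})

fix_maps <- function() fixture("maps", function() {
  suppressWarnings(
    fit_subject_maps(fix_series(), fix_subject()$labels))
})

# Mean of a quantitative map over one ROI of the fixture phantom.
fix_roi_mean <- function(map, roi_id) {
  m <- (fix_subject()$labels == roi_id) & map$valid
  mean(map$data[m])
}

fix_truth_roi_mean <- function(map_type, roi_id) {
  sub <- fix_subject()
  mean(sub$truth[[map_type]][sub$labels == roi_id])
}
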