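# shared fixtures, memoized so expensive solves run once per test session

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# compact phantom for unit tests: 36^3 at 2 mm, 6 applicators (12 electrodes)
small_config <- function(...) {
  args <- utils::modifyList(
    list(shape = c(36, 36, 36), spacing = c(2, 2, 2),
         n_applicators = 6, prostate_semiaxes = c(18, 15, 15),
         fat_radius = 30, bladder_radius = 12,
         rectum_radius = 8, rectum_air_radius = 5, rectum_gap = 3),
    list(...))
  do.call(phantom_config, args)
}

small_model <- function() memo("small_model", generate_phantom(small_config(), seed = 7))

small_bases <- function() memo("small_bases", precompute_bases(small_model()))

small_bt <- function() memo("small_bt", heuristic_dwell_weights(small_model()))

# a bare-bones model wrapper for geometric rasterization tests
line_model <- function(p0, p1, shape = c(31, 31, 31), spacing = c(1, 1, 1),
                       radius = 1) {
  el <- data.frame(s_start = 0, s_end = sqrt(sum((p1 - p0)^2)))
  structure(list(
    grid = voxel_grid(shape, spacing),
    labels = tissue_labels,
    properties = tissue_table(),
    blood = blood_properties(),
    applicators = list(applicator("L1", p0, p1, el, radius = radius)),
    frequency = 27e6
  ), class = "tbt_model")
}
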