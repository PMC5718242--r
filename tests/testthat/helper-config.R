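# Shared helpers: fast Monte Carlo configurations (coarse 2.5 mm voxels) for
# unit tests, and a lazily filled cache so expensive runs are shared across
# test files within a session.

fast_config <- function(...) {
  base <- list(
    source = list(mean_energy = 8.0, sigma_e = 0.5, sigma_y = 1.0,
                  sigma_z = 1.0, sigma_m = 6.0, n_histories = 3000),
    scoring = list(voxel_size = 2.5, detector = c(70, 150, 150)),
    transport = list(batches = 4L))
  modifyList(base, list(...))
}

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# small no-disc run reused by several scoring/transport tests
fast_run_nodisc <- function() {
  cached("fast_nodisc", run_simulation(fast_config(), seed = 42))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
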