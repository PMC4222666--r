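# Shared fixtures, built once per test run and memoized.
# Solver settings are deliberately smaller than the package defaults so the
# suite stays fast; accuracy at these settings is itself verified in
# test-sfs-engine.R.

ctl_test <- dfemap::solver_control(grid_points = 401, dt = 2e-3)

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# best-fit-style growth demography used throughout: scaled rate 1, 13000
# generations, N0 = 10000, n = 18 haploids
growth_model <- function() dfemap::demog_exponential(1, 13000)

# coarse selection grid (log10 step 0.05 -> 81 negative points + 0)
s_grid_test <- function() dfemap::s_grid_default(step = 0.05)

growth_cache <- function() {
  memo("growth_cache", function() {
    dfemap::precompute_spectra(growth_model(), n = 18, s_grid_test(),
                               control = ctl_test)
  })
}

const_cache <- function() {
  memo("const_cache", function() {
    dfemap::precompute_spectra(dfemap::demog_constant(), n = 18,
                               s_grid_test(), control = ctl_test)
  })
}

# exact neutral constant-model sample spectrum, p_i proportional to 1/i
neutral_p <- function(n = 18) {
  h <- 1 / seq_len(n - 1)
  h / sum(h)
}

# nearest grid coefficient in a cache
snap_to_grid <- function(cache, s) {
  vapply(s, function(si) cache$s[which.min(abs(cache$s - si))], numeric(1))
}
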