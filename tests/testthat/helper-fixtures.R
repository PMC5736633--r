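# Shared fixtures: the default maze and a short training protocol used by
# unit tests; expensive cohort computations for the acceptance checks are
# cached lazily in `acc_cache` (filled by test-acceptance.R).

default_maze <- build_default_maze()
short_protocol <- protocol_spec(max_days = 1L)

mf_fixture_params <- list(eta = 0.3, beta = 5, gamma = 0.9)
pi_fixture_params <- list(eta = 0.5, beta = 8, sigma0 = 0.1)
mb_fixture_params <- list(eta = 0.6, beta = 10, gamma = 0.85)

# point-mass parameter window (all subjects share the fixture values)
point_ranges <- function(p) lapply(p, function(v) c(v, v))

acc_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = acc_cache)) assign(name, expr, envir = acc_cache)
  get(name, envir = acc_cache)
}
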