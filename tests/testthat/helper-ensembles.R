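# Lazily computed, memoised study ensembles shared by the acceptance tests,
# so the heavy Monte-Carlo conditions are simulated once per session.

.ens_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ens_cache)) {
    assign(key, force(expr), envir = .ens_cache)
  }
  get(key, envir = .ens_cache)
}

ens_2x1_control_1000 <- function() cached("c2x1", run_ensemble(
  lesion_config(2, 1), engine_config("Control"), m = 1000, base_seed = 101
))

ens_2x1_rad_1000 <- function() cached("r2x1", run_ensemble(
  lesion_config(2, 1), engine_config("Rad223"), m = 1000, base_seed = 1101
))

ens_8x7_control_200 <- function() cached("c8x7", run_ensemble(
  lesion_config(8, 7), engine_config("Control"), m = 200, base_seed = 2101
))

ens_8x7_rad_200 <- function() cached("r8x7", run_ensemble(
  lesion_config(8, 7), engine_config("Rad223"), m = 200, base_seed = 2301
))

ens_8x7w20_control_200 <- function() cached("c8x7w20", run_ensemble(
  lesion_config(8, 7, margin_thickness = 20), engine_config("Control"),
  m = 200, base_seed = 3101
))

ens_8x7w20_rad_200 <- function() cached("r8x7w20", run_ensemble(
  lesion_config(8, 7, margin_thickness = 20), engine_config("Rad223"),
  m = 200, base_seed = 3301
))
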