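# Shared, lazily-computed fixtures.  The heavier whole-model runs are reused
# across test files through this cache.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, make) {
  if (is.null(.fx[[name]])) .fx[[name]] <- make()
  .fx[[name]]
}

fx_hfs <- function() make_train(100, duration_s = 1)

fx_control_hfs <- function() fx_get("control_hfs", function()
  run_simulation(fx_hfs(), keep_occupancies = TRUE))

fx_desinh_hfs <- function() fx_get("desinh_hfs", function() {
  p <- control_perturbation()
  p$desens_inhibition$s_nr2a <- 1
  run_simulation(fx_hfs(), p, keep_occupancies = FALSE)
})

fx_g0_hfs <- function() fx_get("g0_hfs", function() {
  p <- control_perturbation()
  p$molecules_per_release <- 10000
  run_simulation(fx_hfs(), p, keep_occupancies = FALSE)
})

fx_astro <- function() fx_get("astro", function()
  run_simulation(make_astro_protocol(20), keep_occupancies = FALSE))

fx_1pulse <- function() fx_get("one_pulse", function()
  run_simulation(make_train(100, n_pulses = 1, tail_ms = 300),
                 keep_occupancies = FALSE))
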