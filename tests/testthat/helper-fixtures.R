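# Shared fixtures, built lazily and cached for the whole test run.
# Small grids keep the suite fast: 48^3 at 4 mm (or 32^3 at 6 mm) spans the
# same 192 mm head field of view as the 64^3 x 3 mm default.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_params48 <- function() phantom_params(grid_n = 48, spacing = 4)
fx_params32 <- function() phantom_params(grid_n = 32, spacing = 6)

fx_hc48 <- function() fx_get("hc48", function()
  generate_subject(fx_params48(), "HC", seed = 3))
fx_pd48 <- function() fx_get("pd48", function()
  generate_subject(fx_params48(), "PD", seed = 5))

# small cohort + template set on the 48^3 grid
fx_cohort48 <- function() fx_get("cohort48", function()
  generate_cohort(4, 3, fx_params48(), seed = 42))
fx_templates48 <- function() fx_get("templates48", function() {
  hc <- Filter(function(s) s$group == "HC", fx_cohort48()$subjects)
  build_template_set(hc)
})

# default-scale (64^3 at 3 mm) subject for full-fidelity checks
fx_hc64 <- function() fx_get("hc64", function()
  generate_subject(phantom_params(), "HC", seed = 11))

# precision registration schedule used by warp-recovery checks: finer
# pyramid, moderate basis
fx_fine_config <- function()
  register_config(basis_k = 6L, nl_levels = list(c(8, 3), c(4, 2), c(2, 2)))

# quick uniform-value volume on a small grid
fx_uniform_vol <- function(value, n = 8L, spacing = 2, unit = "SUV") {
  g <- iso_grid(n, spacing)
  new_volume(array(value, g$dim), g$affine, unit)
}
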