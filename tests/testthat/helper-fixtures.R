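# Memoized fixtures: the default chamber simulation is shared across test
# files (it is deterministic, so one run serves all assertions).
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

opc_default_run <- function() {
  memo("default_run",
       solve_quasi1d(chamber_geometry(), burst_model(), t_end = 0.06))
}

opc_lumped_default <- function() {
  memo("lumped_default",
       lumped_blowdown(chamber_geometry(), burst_model(), t_end = 0.06))
}

opc_wavelet_default <- function() {
  memo("wavelet_default",
       solve_spherical_burst(burst_model(), r_target = 0.127))
}

# Sod shock tube on the compiled kernel at a given resolution, with the
# exact Riemann solution (helper-riemann.R) evaluated on the same grid.
sod_run <- function(n = 1000) {
  memo(paste0("sod_", n), {
    x_face <- seq(0, 1, length.out = n + 1)
    init <- function(xc)
      data.frame(rho = ifelse(xc < 0.5, 1, 0.125), u = 0,
                 p = ifelse(xc < 0.5, 1, 0.1), s = as.numeric(xc < 0.5))
    out <- solve_euler1d(x_face, rep(1, n + 1), init, t_end = 0.2,
                         gamma = 1.4, cfl = 0.5, snap_dt = 0.2)
    ex <- exact_riemann(1, 0, 1, 0.125, 0, 0.1)(out$x_center, 0.2, 0.5)
    last <- ncol(out$snap_rho)
    list(x = out$x_center,
         num = data.frame(rho = out$snap_rho[, last],
                          u = out$snap_u[, last],
                          p = out$snap_p[, last]),
         exact = ex)
  })
}

# Shock/ramp classification over a batch of seeded synthetic records.
shock_batch_fraction <- function(n_records = 200) {
  memo(paste0("shock_batch_", n_records), {
    hits <- vapply(seq_len(n_records), function(s) {
      rec <- gen_opc_record(record_spec(seed = s), duration = 0.03)
      classify_shock(rec$stagnation)
    }, logical(1))
    mean(hits)
  })
}
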