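# Shared fixtures, built in code at test time.

langerin_cell <- function() unit_cell(79.959, c = 90.419)

# Independent orbit enumeration by repeated (h, k) -> (-k, h), used as the
# oracle for symmetry handling.
oracle_orbit_4m <- function(h, k) {
  out <- matrix(c(h, k), ncol = 2)
  for (i in 1:3) {
    hk <- out[nrow(out), ]
    out <- rbind(out, c(-hk[2], hk[1]))
  }
  unique(out)
}

# Small analytic pseudo-Voigt written independently of the package, for
# closed-form cross-checks.
oracle_pv <- function(x, eta, gg, gl) {
  gauss <- (2 / gg) * sqrt(log(2) / pi) * 2^(-4 * (x / gg)^2)
  lor <- (2 / (pi * gl)) / (1 + 4 * (x / gl)^2)
  eta * gauss + (1 - eta) * lor
}

# A tiny reflection set with hand-set F2, for model/extraction tests:
# cell chosen so all peaks sit well inside a small grid.
tiny_model_case <- function(n = 96, q_max = 0.05, d_min = 25,
                            width_scale = 0.25, seed = 42) {
  cell <- langerin_cell()
  geom <- grid_geometry(n, q_max)
  refl <- enumerate_reflections(cell, d_min, quadrant_only = TRUE)
  astar <- 1 / cell$a
  params <- peak_params(0.6, 0.7, width_scale * astar, 1.2 * width_scale * astar,
                        0.8 * width_scale * astar, width_scale * astar)
  set.seed(seed)
  refl$refl$F2 <- runif(nrow(refl$refl), 0.5, 10)
  list(cell = cell, geom = geom, refl = refl, params = params,
       obs = model_intensity(refl, params, geom))
}
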