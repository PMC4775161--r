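# Finite-lattice nanocrystal diffraction simulator: per-crystal (hk0)
# patterns from the 1D Laue interference function and equal-weight merging
# over log-normal-sized needle ensembles.

#' Log-normal crystal-size distribution
#'
#' Needle crystals are described by the number of whole unit cells along the
#' two in-plane axes. Counts are drawn from independent log-normal
#' distributions parameterized so that the distribution MEAN equals
#' `mean_nx` (resp. `mean_ny`), i.e. meanlog = log(mean) - sigma_log^2/2.
#'
#' @param mean_nx,mean_ny mean unit-cell counts along X and Y (`>= 1`).
#' @param sigma_log log-scale standard deviation (`>= 0`); 0 gives a
#'   degenerate single-size ensemble.
#' @param n_crystals ensemble size.
#' @param seed integer RNG seed.
#' @return an object of class `"size_distribution"`.
#' @export
size_distribution <- function(mean_nx, mean_ny, sigma_log = 0.25,
                              n_crystals, seed = 1L) {
  if (mean_nx < 1 || mean_ny < 1) abort_invalid("mean sizes must be >= 1")
  if (sigma_log < 0) abort_invalid("sigma_log must be >= 0")
  if (n_crystals < 1) abort_invalid("n_crystals must be >= 1")
  structure(list(mean_nx = mean_nx, mean_ny = mean_ny, sigma_log = sigma_log,
                 n_crystals = as.integer(n_crystals), seed = as.integer(seed)),
            class = "size_distribution")
}

#' Sample crystal sizes
#'
#' Draws `n_crystals` independent (N_X, N_Y) pairs from the distribution,
#' rounds to the nearest integer and floors at 1. The same seed produces the
#' identical sample.
#'
#' @param dist a [size_distribution()].
#' @return an integer matrix with columns `nx`, `ny`.
#' @export
sample_sizes <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  draw <- function(mean_n) {
    if (dist$sigma_log == 0) {
      rep(round(mean_n), dist$n_crystals)
    } else {
      meanlog <- log(mean_n) - dist$sigma_log^2 / 2
      round(stats::rlnorm(dist$n_crystals, meanlog, dist$sigma_log))
    }
  }
  with_seed(dist$seed, {
    nx <- pmax(1, draw(dist$mean_nx))
    ny <- pmax(1, draw(dist$mean_ny))
    cbind(nx = as.integer(nx), ny = as.integer(ny))
  })
}

#' One-dimensional Laue interference function
#'
#' The intensity envelope of a row of `N` unit cells:
#' `sin^2(pi N t) / sin^2(pi t)` as a function of the dimensionless lattice
#' phase `t` (`t = q_x a` along the first axis). The removable singularity at
#' integer `t` is evaluated analytically as `N^2`; the function is periodic
#' with period 1 and its mean over one period is `N`.
#'
#' @param N number of unit cells (`>= 1`).
#' @param t dimensionless lattice phase (vectorized).
#' @return non-negative values of the interference function.
#' @export
laue_interference <- function(N, t) {
  if (!is.finite(N) || N < 1) abort_invalid("N must be >= 1")
  tr <- t - round(t)
  out <- numeric(length(t))
  at_peak <- abs(tr) < 1e-9
  out[at_peak] <- N^2
  tt <- t[!at_peak]
  out[!at_peak] <- sin(pi * N * tt)^2 / sin(pi * tt)^2
  out
}

#' Single-crystal diffraction pattern
#'
#' The (hk0) intensity of one needle crystal of `N_X` by `N_Y` whole unit
#' cells: `I(q) = |F(q)|^2 L(N_X, q_x a) L(N_Y, q_y b)`, with the separable
#' Laue factors computed as two 1D vectors and combined as an outer product.
#'
#' @param F2cont `n x n` matrix of `|F(q)|^2` sampled on `geom` (see
#'   [unit_cell_transform()]).
#' @param cell a [unit_cell()].
#' @param N_X,N_Y unit-cell counts along the two axes.
#' @param geom a [grid_geometry()].
#' @param oversample sub-pixel sampling factor for the Laue factors.
#'   1 (the default) evaluates the interference function at pixel centers;
#'   larger odd values average it over `oversample` sub-offsets per pixel,
#'   emulating a detector pixel that integrates the narrow interference
#'   maxima over its area (the unit-cell transform varies on the much
#'   coarser reciprocal-cell scale and is always center-sampled).
#' @return a [pattern()].
#' @export
crystal_pattern <- function(F2cont, cell, N_X, N_Y, geom, oversample = 1L) {
  if (!is.matrix(F2cont) || nrow(F2cont) != geom$n || ncol(F2cont) != geom$n)
    abort_invalid("F2cont must be an n x n matrix matching geom")
  lx <- laue_axis(N_X, cell$a, geom, oversample)
  ly <- laue_axis(N_Y, cell$b, geom, oversample)
  pattern(geom, F2cont * outer(lx, ly),
          meta = list(N_X = N_X, N_Y = N_Y))
}

# 1D Laue factor along one grid axis, optionally pixel-area averaged.
laue_axis <- function(N, edge, geom, oversample = 1L) {
  q <- q_axis(geom)
  if (oversample <= 1L) return(laue_interference(N, q * edge))
  offs <- ((seq_len(oversample) - (oversample + 1) / 2) / oversample) *
    geom$dq
  rowMeans(vapply(offs, function(o) laue_interference(N, (q + o) * edge),
                  numeric(geom$n)))
}

#' Merge patterns with equal weight
#'
#' Pixel-wise unweighted sum of single-crystal (or partial ensemble)
#' patterns sharing one grid geometry.
#'
#' @param patterns a list of [pattern()] objects.
#' @return the merged [pattern()]; `meta$n_merged` records the count.
#' @export
merge_patterns <- function(patterns) {
  if (length(patterns) == 0L) abort_invalid("no patterns to merge")
  g <- patterns[[1L]]$geom
  for (p in patterns) {
    if (!inherits(p, "pattern")) abort_invalid("inputs must be patterns")
    if (!same_geometry(g, p$geom))
      abort_invalid("patterns have mixed grid geometries")
  }
  I <- Reduce(`+`, lapply(patterns, `[[`, "I"))
  pattern(g, I, meta = list(n_merged = length(patterns)))
}

#' Simulate a merged SFX diffraction pattern
#'
#' Computes the continuous unit-cell transform once on the grid, streams
#' crystals from [sample_sizes()] and accumulates the equal-weight merged
#' intensity. Because each crystal contributes a separable product of two 1D
#' Laue vectors, the ensemble sum is evaluated as a single matrix product
#' over the distinct (N_X, N_Y) pairs.
#'
#' @param atoms an [atom_sites()] table.
#' @param cell a [unit_cell()].
#' @param dist a [size_distribution()].
#' @param geom a [grid_geometry()].
#' @inheritParams crystal_pattern
#' @return a [pattern()] with provenance in `meta`.
#' @export
simulate_merged <- function(atoms, cell, dist, geom, oversample = 1L) {
  F2cont <- uc_transform_grid(atoms, cell, geom)
  sizes <- sample_sizes(dist)
  ux <- sort(unique(sizes[, "nx"]))
  uy <- sort(unique(sizes[, "ny"]))
  W <- table(factor(sizes[, "nx"], levels = ux),
             factor(sizes[, "ny"], levels = uy))
  Lx <- vapply(ux, function(N) laue_axis(N, cell$a, geom, oversample),
               numeric(geom$n))
  Ly <- vapply(uy, function(N) laue_axis(N, cell$b, geom, oversample),
               numeric(geom$n))
  S <- Lx %*% unclass(W) %*% t(Ly)  # sum over crystals of outer(lx, ly)
  pattern(geom, F2cont * S,
          meta = list(seed = dist$seed, n_crystals = dist$n_crystals,
                      mean_nx = dist$mean_nx, mean_ny = dist$mean_ny,
                      sigma_log = dist$sigma_log, oversample = oversample))
}
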