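# Whole-pattern fitting engine: continuous model intensity, error-cost
# minimisation over the peak-shape parameters, P-matrix extraction of squared
# structure-factor moduli, Le Bail-style alternation and fit diagnostics.

#' Fitting configuration
#'
#' @param max_cycles maximum number of alternation cycles (`>= 1`).
#' @param cost_rel_tol relative cost-change convergence threshold.
#' @param optimizer `"least-squares"` (Levenberg-Marquardt on the residual
#'   vector, the default) or `"simplex"` (Nelder-Mead).
#' @param init_mode `"flat"` initializes all squared moduli at a robust scale
#'   estimate (median observed peak intensity over the profile maximum);
#'   `"provided"` takes them from the reflection set's `F2` column.
#' @param weak_exclusion_fraction reflections whose reference modulus falls
#'   below this fraction of the median are flagged weak downstream.
#' @param weighting `"unit"` or `"inverse-intensity"` pixel weights for the
#'   cost and the weighted profile R factor.
#' @param p_mode `"interpolated"` evaluates the P matrix through the same
#'   bilinear sampling operator used to read observed peak intensities
#'   (grid-registration consistent); `"exact"` evaluates profiles at the
#'   exact Bragg offsets.
#' @param optim_maxit iteration budget of the per-cycle parameter search.
#' @return an object of class `"fit_config"`.
#' @export
fit_config <- function(max_cycles = 50L, cost_rel_tol = 1e-6,
                       optimizer = c("least-squares", "simplex"),
                       init_mode = c("flat", "provided"),
                       weak_exclusion_fraction = 0.1,
                       weighting = c("unit", "inverse-intensity"),
                       p_mode = c("interpolated", "exact"),
                       optim_maxit = 300L) {
  optimizer <- match.arg(optimizer)
  init_mode <- match.arg(init_mode)
  weighting <- match.arg(weighting)
  p_mode <- match.arg(p_mode)
  if (max_cycles < 1) abort_invalid("max_cycles must be >= 1")
  if (cost_rel_tol <= 0) abort_invalid("cost_rel_tol must be > 0")
  if (weak_exclusion_fraction < 0 || weak_exclusion_fraction >= 1)
    abort_invalid("weak_exclusion_fraction must lie in [0, 1)")
  structure(list(max_cycles = as.integer(max_cycles),
                 cost_rel_tol = cost_rel_tol, optimizer = optimizer,
                 init_mode = init_mode,
                 weak_exclusion_fraction = weak_exclusion_fraction,
                 weighting = weighting, p_mode = p_mode,
                 optim_maxit = as.integer(optim_maxit)),
            class = "fit_config")
}

# Reduce a full-plane reflection set to orbit representatives.
quadrant_reduce <- function(rs) {
  if (rs$symmetry_applied) return(rs)
  reps <- t(mapply(hk_representative, rs$refl$h, rs$refl$k,
                   MoreArgs = list(laue_class = rs$cell$laue_class)))
  keep <- rs$refl$h == reps[, 1L] & rs$refl$k == reps[, 2L]
  refl <- rs$refl[keep, , drop = FALSE]
  refl$orbit <- NULL
  new_reflection_set(rs$cell, refl, TRUE)
}

# Model intensity on the grid for an expanded reflection data frame with
# per-row F2. Fast separable path (two matrix products over the distinct h
# and k index values) when the widths carry no |q| dependence.
model_grid <- function(refl, cell, params, geom, F2) {
  qx <- q_axis(geom)
  if (all(params$slopes == 0)) {
    hs <- sort(unique(refl$h))
    ks <- sort(unique(refl$k))
    U <- vapply(hs, function(h)
      pv1d(qx - h / cell$a, params$eta_x, params$gamma_gx, params$gamma_lx),
      numeric(geom$n))
    V <- vapply(ks, function(k)
      pv1d(qx - k / cell$b, params$eta_y, params$gamma_gy, params$gamma_ly),
      numeric(geom$n))
    F2mat <- matrix(0, length(hs), length(ks))
    F2mat[cbind(match(refl$h, hs), match(refl$k, ks))] <- F2
    U %*% F2mat %*% t(V)
  } else {
    I <- matrix(0, geom$n, geom$n)
    qmag <- sqrt(refl$qx^2 + refl$qy^2)
    for (i in seq_len(nrow(refl))) {
      wx <- widths_at(params, "x", qmag[i])
      wy <- widths_at(params, "y", qmag[i])
      I <- I + F2[i] * outer(pv1d(qx - refl$qx[i], params$eta_x, wx$g, wx$l),
                             pv1d(qx - refl$qy[i], params$eta_y, wy$g, wy$l))
    }
    I
  }
}

#' Modelled continuous intensity distribution
#'
#' Evaluates `I_calc(q) = sum_k F2_k Phi_k(q - q_k)` on the grid, where
#' `Phi_k` is the extended pseudo-Voigt profile. The model is linear in the
#' squared moduli. A quadrant-reduced set is symmetry-expanded first, orbit
#' members sharing their representative's F2.
#'
#' @param rs a `"reflection_set"` with `F2` filled.
#' @param params a [peak_params()].
#' @param geom a [grid_geometry()].
#' @return a [pattern()].
#' @export
model_intensity <- function(rs, params, geom) {
  stopifnot(inherits(rs, "reflection_set"))
  if (any(!is.finite(rs$refl$F2)))
    abort_invalid("all reflections need finite F2 for model_intensity")
  full <- symmetry_expand(rs)
  I <- model_grid(full$refl, rs$cell, params, geom, full$refl$F2)
  I[I < 0] <- 0  # guard against negative rounding dust
  pattern(geom, I, meta = list(model = "pseudo-voigt"))
}

#' Error-cost function between observed and calculated patterns
#'
#' `Psi = sum_i w_i (I_obs,i - I_calc,i)^2` over ALL pixels of the pattern
#' (not only near Bragg positions). With `weighting = "inverse-intensity"`
#' the weights are `1 / max(I_obs, 1e-6 max(I_obs))`.
#'
#' @param observed,calculated [pattern()]s on the same geometry.
#' @param weighting `"unit"` or `"inverse-intensity"`.
#' @return the scalar cost `Psi >= 0`.
#' @export
fit_cost <- function(observed, calculated,
                     weighting = c("unit", "inverse-intensity")) {
  weighting <- match.arg(weighting)
  if (!same_geometry(observed$geom, calculated$geom))
    abort_invalid("observed and calculated patterns have different geometries")
  r <- observed$I - calculated$I
  if (weighting == "unit") return(sum(r * r))
  w <- 1 / pmax(observed$I, 1e-6 * max(observed$I))
  sum(w * r * r)
}

#' Observed peak intensities at Bragg positions
#'
#' Bilinear interpolation of the merged intensity grid at the exact Bragg
#' position of each reflection. Reflections whose interpolation stencil
#' falls outside the grid are returned as `NA` with a warning.
#'
#' @param pat a [pattern()].
#' @param rs a `"reflection_set"`.
#' @return numeric vector of per-reflection intensities.
#' @export
observed_peak_intensities <- function(pat, rs) {
  stopifnot(inherits(pat, "pattern"), inherits(rs, "reflection_set"))
  n <- pat$geom$n
  ix <- q_to_index(pat$geom, rs$refl$qx)
  iy <- q_to_index(pat$geom, rs$refl$qy)
  x0 <- floor(ix); y0 <- floor(iy)
  ok <- x0 >= 1 & x0 + 1 <= n & y0 >= 1 & y0 + 1 <= n
  if (!all(ok))
    warning(sprintf("%d reflection(s) outside the grid were excluded",
                    sum(!ok)))
  fx <- ix - x0; fy <- iy - y0
  out <- rep(NA_real_, nrow(rs$refl))
  i <- which(ok)
  out[i] <- (1 - fx[i]) * (1 - fy[i]) * pat$I[cbind(x0[i], y0[i])] +
    fx[i] * (1 - fy[i]) * pat$I[cbind(x0[i] + 1, y0[i])] +
    (1 - fx[i]) * fy[i] * pat$I[cbind(x0[i], y0[i] + 1)] +
    fx[i] * fy[i] * pat$I[cbind(x0[i] + 1, y0[i] + 1)]
  out
}

# Exact profile cross-contribution matrix: rows are evaluation positions
# (qjx, qjy), columns contributing reflections at (qix, qiy). With
# |q|-independent widths the entries factor over per-axis offsets, and the
# evaluation/contributor coordinates take few distinct values (reflections
# sit on a lattice), so each factor is a small pv1d table expanded by
# indexing.
p_block <- function(qjx, qjy, qix, qiy, params) {
  qmag <- sqrt(qix^2 + qiy^2)
  if (all(params$slopes == 0)) {
    axis_factor <- function(qj, qi, eta, gg, gl) {
      u <- unique(qj); v <- unique(qi)
      M <- pv1d(outer(u, v, "-"), eta, gg, gl)
      M[match(qj, u), match(qi, v), drop = FALSE]
    }
    PX <- axis_factor(qjx, qix, params$eta_x, params$gamma_gx,
                      params$gamma_lx)
    PY <- axis_factor(qjy, qiy, params$eta_y, params$gamma_gy,
                      params$gamma_ly)
    PX * PY
  } else {
    P <- matrix(0, length(qjx), length(qix))
    for (i in seq_along(qix)) {
      wx <- widths_at(params, "x", qmag[i])
      wy <- widths_at(params, "y", qmag[i])
      P[, i] <- pv1d(qjx - qix[i], params$eta_x, wx$g, wx$l) *
        pv1d(qjy - qiy[i], params$eta_y, wy$g, wy$l)
    }
    P
  }
}

#' Build the P matrix of peak-shape cross-contributions
#'
#' `P[j, i] = Phi_i(q_j - q_i)`: the contribution of the i-th reflection's
#' profile at the position of the j-th reflection. The diagonal equals
#' [peak_value()]; all entries are non-negative; P is symmetric when the
#' widths carry no |q| dependence. With a grid geometry supplied, each entry
#' is instead evaluated through the bilinear sampling operator at `q_j`, so
#' that the model prediction and [observed_peak_intensities()] apply the
#' identical linear functional to model and data.
#'
#' @param rs a `"reflection_set"` (symmetry-expanded or any explicit list).
#' @param params a [peak_params()].
#' @param geom optional [grid_geometry()] for sampling-consistent evaluation
#'   (`NULL` = exact evaluation at the Bragg offsets).
#' @return a square matrix with one row/column per reflection.
#' @export
build_P <- function(rs, params, geom = NULL) {
  stopifnot(inherits(rs, "reflection_set"))
  qx <- rs$refl$qx; qy <- rs$refl$qy
  if (is.null(geom)) return(p_block(qx, qy, qx, qy, params))
  interp_rows_P(qx, qy, qx, qy, params, geom)
}

# P with rows evaluated through the bilinear interpolation stencil of the
# grid: weighted sum of four exact blocks at the surrounding pixel centers.
interp_rows_P <- function(qjx, qjy, qix, qiy, params, geom) {
  ix <- q_to_index(geom, qjx); iy <- q_to_index(geom, qjy)
  x0 <- floor(ix); y0 <- floor(iy)
  fx <- ix - x0; fy <- iy - y0
  px0 <- (x0 - 1 - geom$n / 2) * geom$dq
  py0 <- (y0 - 1 - geom$n / 2) * geom$dq
  P <- (1 - fx) * (1 - fy) * p_block(px0, py0, qix, qiy, params)
  P <- P + fx * (1 - fy) * p_block(px0 + geom$dq, py0, qix, qiy, params)
  P <- P + (1 - fx) * fy * p_block(px0, py0 + geom$dq, qix, qiy, params)
  P + fx * fy * p_block(px0 + geom$dq, py0 + geom$dq, qix, qiy, params)
}

# Orbit-aggregated linear system over representatives: rows at the
# representatives' Bragg positions, one column per orbit with the orbit
# members' profile tails summed. `full` may be passed to reuse a cached
# symmetry expansion.
build_P_system <- function(reps, params, geom = NULL, full = NULL) {
  if (is.null(full)) full <- symmetry_expand(reps)
  qjx <- reps$refl$qx; qjy <- reps$refl$qy
  Pfull <- if (is.null(geom)) {
    p_block(qjx, qjy, full$refl$qx, full$refl$qy, params)
  } else {
    interp_rows_P(qjx, qjy, full$refl$qx, full$refl$qy, params, geom)
  }
  P <- t(rowsum(t(Pfull), group = full$refl$orbit, reorder = TRUE))
  list(P = P, full = full)
}

#' Solve the linear system P F = I for squared moduli
#'
#' Gaussian elimination with partial pivoting, the classical solver for the
#' peak-untangling system. A pivot below `tol * max|P|` raises a
#' singular-system error carrying a condition estimate. Negative solution
#' components (possible for weak reflections swamped by neighbours) are
#' clamped to zero with a warning when `clamp = TRUE`; the remaining system
#' is not re-solved.
#'
#' @param P square cross-contribution matrix.
#' @param I per-reflection observed peak intensities.
#' @param clamp clamp negative solutions to zero?
#' @param tol relative pivot tolerance.
#' @return the vector of squared structure-factor moduli `F2`.
#' @export
solve_moduli <- function(P, I, clamp = TRUE, tol = 1e-12) {
  n <- nrow(P)
  if (ncol(P) != n || length(I) != n)
    abort_invalid("P must be square and conformable with I")
  if (any(!is.finite(P)) || any(!is.finite(I)))
    abort_invalid("P and I must be finite")
  A <- cbind(P, I)
  scale <- max(abs(P))
  for (j in seq_len(n)) {
    p <- which.max(abs(A[j:n, j])) + j - 1L
    if (abs(A[p, j]) < tol * scale)
      abort_singular("singular or near-singular P matrix",
                     cond_estimate = tryCatch(kappa(P, exact = TRUE),
                                              error = function(e) Inf))
    if (p != j) A[c(j, p), ] <- A[c(p, j), ]
    if (j < n) {
      rows <- (j + 1L):n
      fac <- A[rows, j] / A[j, j]
      A[rows, ] <- A[rows, ] - tcrossprod(fac, A[j, ])
    }
  }
  x <- numeric(n)
  for (j in rev(seq_len(n))) {
    x[j] <- (A[j, n + 1L] - sum(A[j, seq_len(n)] * x)) / A[j, j]
  }
  if (clamp && any(x < 0)) {
    warning(sprintf("%d negative squared moduli clamped to zero", sum(x < 0)))
    x[x < 0] <- 0
  }
  x
}

#' Condition number of the P matrix
#'
#' Ratio of the largest to the smallest singular value; values near 1 mean
#' the peak-untangling system is well posed.
#'
#' @param P a matrix.
#' @return `sigma_max / sigma_min` (`Inf` for a singular matrix).
#' @export
condition_number <- function(P) {
  s <- svd(P, nu = 0, nv = 0)$d
  if (min(s) == 0) return(Inf)
  max(s) / min(s)
}

#' Profile and weighted-profile R factors
#'
#' `R_p = sum|I_o - I_c| / sum I_o` and
#' `R_wp = sqrt(sum w (I_o - I_c)^2 / sum w I_o^2)` over all pixels, the
#' standard agreement residuals of whole-pattern refinement.
#'
#' @inheritParams fit_cost
#' @return a list with elements `r_p` and `r_wp`.
#' @export
r_factors <- function(observed, calculated,
                      weighting = c("unit", "inverse-intensity")) {
  weighting <- match.arg(weighting)
  if (!same_geometry(observed$geom, calculated$geom))
    abort_invalid("observed and calculated patterns have different geometries")
  Io <- observed$I; Ic <- calculated$I
  r_p <- sum(abs(Io - Ic)) / sum(Io)
  w <- if (weighting == "unit") 1 else 1 / pmax(Io, 1e-6 * max(Io))
  r_wp <- sqrt(sum(w * (Io - Ic)^2) / sum(w * Io^2))
  list(r_p = r_p, r_wp = r_wp)
}

# Unconstrained parameterization of the six profile parameters.
params_to_theta <- function(p) {
  e <- pmin(pmax(c(p$eta_x, p$eta_y), 1e-6), 1 - 1e-6)
  c(stats::qlogis(e),
    log(c(p$gamma_gx, p$gamma_lx, p$gamma_gy, p$gamma_ly)))
}

theta_to_params <- function(theta, slopes) {
  peak_params(stats::plogis(theta[1L]), stats::plogis(theta[2L]),
              exp(theta[3L]), exp(theta[4L]), exp(theta[5L]), exp(theta[6L]),
              slopes = slopes)
}

#' Whole-pattern refinement of peak shapes and structure-factor moduli
#'
#' Le Bail-style alternation against the full merged pattern. Each cycle
#' first re-estimates the squared moduli by solving the orbit-aggregated
#' linear system `P F = I` at the current peak-shape parameters (observed
#' peak intensities read by bilinear interpolation at the exact Bragg
#' positions), then minimises the error-cost function over the six profile
#' parameters at fixed moduli. A cycle is accepted only if the cost does not
#' increase; refinement stops on convergence of the relative cost change, on
#' the cycle budget, or on a rejected cycle.
#'
#' @param observed the merged [pattern()].
#' @param refl a `"reflection_set"` enumerated to the grid's resolution
#'   (quadrant-reduced or full plane; reduced internally).
#' @param init_params starting [peak_params()].
#' @param cfg a [fit_config()].
#' @param reference optional `"reflection_set"` with reference `F2` used to
#'   apply the final Wilson `(k, B)` correction.
#' @return an object of class `"fit_result"` with elements `reflections`
#'   (representatives with extracted `F2`), `params`, `r_p`, `r_wp`, `cond`,
#'   `n_cycles`, `cost_trace`, `converged`, and — when a reference is given —
#'   `wilson` and `F2_scaled`.
#' @export
refine <- function(observed, refl, init_params, cfg = fit_config(),
                   reference = NULL) {
  stopifnot(inherits(observed, "pattern"), inherits(refl, "reflection_set"))
  reps <- quadrant_reduce(refl)
  geom <- observed$geom
  p_geom <- if (cfg$p_mode == "interpolated") geom else NULL
  Iobs <- observed_peak_intensities(observed, reps)
  if (any(!is.finite(Iobs))) {  # off-grid reflections are dropped, not fatal
    keep <- is.finite(Iobs)
    reps <- new_reflection_set(reps$cell, reps$refl[keep, , drop = FALSE],
                               TRUE)
    Iobs <- Iobs[keep]
  }
  if (nrow(reps$refl) < 1L) abort_invalid("no reflections inside the grid")

  params <- init_params
  pv0 <- peak_value(params)
  F2 <- if (cfg$init_mode == "provided") {
    if (any(!is.finite(reps$refl$F2)))
      abort_invalid("init_mode 'provided' needs F2 in the reflection set")
    reps$refl$F2
  } else {
    rep(stats::median(Iobs) / pv0, nrow(reps$refl))
  }

  full <- symmetry_expand(reps)
  orbit <- full$refl$orbit
  calc_of <- function(F2v, par) {
    I <- model_grid(full$refl, reps$cell, par, geom, F2v[orbit])
    I[I < 0] <- 0
    pattern(geom, I)
  }
  cost_of <- function(F2v, par) fit_cost(observed, calc_of(F2v, par),
                                         weighting = cfg$weighting)

  psi_best <- cost_of(F2, params)
  if (!is.finite(psi_best))
    abort_numeric("non-finite initial cost; fit diverged")
  best <- list(F2 = F2, params = params)
  trace <- numeric(0)
  converged <- FALSE
  n_cycles <- 0L
  no_improve <- 0L
  psi_scale <- sum(observed$I^2)

  # Moduli implied by a trial parameter set: the Le Bail re-estimation
  # (observed peak reads untangled through the P system at those shapes).
  F2_of <- function(par) {
    P <- build_P_system(reps, par, p_geom, full = full)$P
    suppressWarnings(solve_moduli(P, Iobs, clamp = TRUE))
  }

  # Profile-parameter refinement with the moduli re-estimation folded into
  # every evaluation (variable projection): fixing the moduli at their
  # P-solved values makes the peak reads insensitive to the shapes and
  # leaves spurious stationary points, so the search always scores a trial
  # shape together with the moduli it implies.
  opt_params <- function(theta0) {
    if (cfg$optimizer == "simplex") {
      obj <- function(theta) {
        val <- tryCatch({
          par <- theta_to_params(theta, params$slopes)
          cost_of(F2_of(par), par)
        }, error = function(e) Inf)
        if (!is.finite(val)) return(1e300)
        val
      }
      stats::optim(theta0, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$optim_maxit,
                                  reltol = 1e-12))$par
    } else {
      big <- sqrt(1e300 / length(observed$I))
      resid <- function(theta) {
        r <- tryCatch({
          par <- theta_to_params(theta, params$slopes)
          calc <- calc_of(F2_of(par), par)
          as.numeric(observed$I - calc$I)
        }, error = function(e) rep(big, length(observed$I)))
        if (cfg$weighting == "inverse-intensity")
          r <- r * as.numeric(sqrt(1 / pmax(observed$I,
                                            1e-6 * max(observed$I))))
        r[!is.finite(r)] <- big
        r
      }
      minpack.lm::nls.lm(theta0, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$optim_maxit))$par
    }
  }

  # Non-monotone cycles with best-state memory: the search may pass through
  # worse states, but only improvements enter the best state (and the
  # reported trace, which is therefore non-increasing).
  for (cycle in seq_len(cfg$max_cycles)) {
    theta1 <- opt_params(params_to_theta(params))
    params_cand <- theta_to_params(theta1, params$slopes)
    F2_cand <- tryCatch(F2_of(params_cand), error = function(e) NULL)
    if (!is.null(F2_cand) &&
        cost_of(F2_cand, params_cand) <= cost_of(F2_of(params), params)) {
      params <- params_cand
      F2 <- F2_cand
    } else {
      F2 <- F2_of(params)
    }
    psi_cur <- cost_of(F2, params)
    if (!is.finite(psi_cur)) abort_numeric("non-finite cost; fit diverged")
    n_cycles <- cycle
    improvement <- (psi_best - psi_cur) / max(psi_best,
                                              .Machine$double.xmin)
    if (psi_cur < psi_best) {
      best <- list(F2 = F2, params = params)
      psi_best <- psi_cur
    } else {
      no_improve <- no_improve + 1L
    }
    trace <- c(trace, psi_best)
    if ((improvement >= 0 && improvement < cfg$cost_rel_tol) ||
        psi_best <= 1e-24 * psi_scale) {
      converged <- TRUE
      break
    }
    if (no_improve >= 2L) break
  }
  F2 <- best$F2
  params <- best$params
  psi <- psi_best

  # final moduli at the accepted parameters
  sys <- build_P_system(reps, params, p_geom, full = full)
  F2_fin <- suppressWarnings(solve_moduli(sys$P, Iobs, clamp = TRUE))
  psi_fin <- cost_of(F2_fin, params)
  if (psi_fin <= psi) {
    F2 <- F2_fin
    psi <- psi_fin
  }
  calc <- calc_of(F2, params)
  rf <- r_factors(observed, calc, weighting = cfg$weighting)
  reps$refl$F2 <- F2

  # cond is the condition number of the analytically evaluated P at the
  # final parameters (the matrix build_P defines); cond_solve describes the
  # sampling-consistent system actually solved when p_mode = "interpolated".
  P_exact <- build_P_system(reps, params, NULL, full = full)$P
  out <- list(reflections = reps, params = params,
              r_p = rf$r_p, r_wp = rf$r_wp,
              cond = condition_number(P_exact),
              cond_solve = condition_number(sys$P),
              n_cycles = max(n_cycles, 1L), cost_trace = trace,
              converged = converged, cost = psi)
  if (!is.null(reference)) {
    ref <- match_reference(reps, reference)
    s2 <- (1 / (2 * reps$refl$d))^2
    wf <- wilson_fit(F2, ref$F2, s2)
    out$wilson <- wf
    out$F2_scaled <- wilson_apply(F2, s2, wf)
    weak_thr <- cfg$weak_exclusion_fraction * stats::median(sqrt(ref$F2))
    out$reflections$refl$weak <- sqrt(ref$F2) < weak_thr
  }
  class(out) <- "fit_result"
  out
}

# Align a reference reflection set with the representatives by (h, k),
# reducing the reference through the same orbit convention if needed.
match_reference <- function(reps, reference) {
  stopifnot(inherits(reference, "reflection_set"))
  ref <- quadrant_reduce(reference)
  idx <- match(paste(reps$refl$h, reps$refl$k),
               paste(ref$refl$h, ref$refl$k))
  if (any(is.na(idx)))
    abort_invalid("reference does not cover all fitted reflections")
  list(F2 = ref$refl$F2[idx])
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> %d reflections, %d cycle(s)%s\n",
                     "  R_p = %.4g, R_wp = %.4g, cond(P) = %.4f\n"),
              nrow(x$reflections$refl), x$n_cycles,
              if (x$converged) " (converged)" else "",
              x$r_p, x$r_wp, x$cond))
  print(x$params)
  invisible(x)
}

#' Neighbour-overlap decomposition around one reflection
#'
#' Splits the fitted model around the `k`-th reflection into its own peak
#' term and the combined contribution of all other Bragg peaks, sampled on
#' circles of increasing radius about the Bragg position. Only sample points
#' whose total model intensity exceeds 2% of the peak's model maximum enter
#' the sums; the returned percentage is
#' `100 * sum(neighbour terms) / sum(total model)` per radius.
#'
#' @param refl a `"reflection_set"` (representatives; expanded internally).
#' @param params fitted [peak_params()].
#' @param F2 extracted squared moduli, one per representative.
#' @param k index of the reflection of interest (into the representatives).
#' @param radii radial distances in 1/Å, within `(0, a*/2]`.
#' @param n_theta sample points per circle.
#' @param intensity_floor fraction of the reflection's peak intensity below
#'   which sample points are discarded (default 0.02).
#' @param peak_intensity the reflection's peak intensity used as the floor
#'   reference; defaults to the analytic model maximum at the Bragg
#'   position. Pass the observed peak intensity (the quantity entering the
#'   linear system) to anchor the floor in the merged data instead.
#' @return a data frame with columns `radius`, `percent`, `n_points`.
#' @export
overlap_decomposition <- function(refl, params, F2, k, radii, n_theta = 72L,
                                  intensity_floor = 0.02,
                                  peak_intensity = NULL) {
  reps <- quadrant_reduce(refl)
  if (k < 1 || k > nrow(reps$refl)) abort_invalid("reflection index out of range")
  if (length(F2) != nrow(reps$refl))
    abort_invalid("F2 must have one value per representative")
  full <- symmetry_expand(reps)
  F2full <- F2[full$refl$orbit]
  own <- which(full$refl$h == reps$refl$h[k] & full$refl$k == reps$refl$k[k])
  qk <- c(reps$refl$qx[k], reps$refl$qy[k])

  model_terms <- function(pts) {
    qmag <- sqrt(full$refl$qx^2 + full$refl$qy^2)
    total <- numeric(nrow(pts)); own_t <- numeric(nrow(pts))
    for (i in seq_len(nrow(full$refl))) {
      wx <- widths_at(params, "x", qmag[i])
      wy <- widths_at(params, "y", qmag[i])
      v <- F2full[i] * pv1d(pts[, 1L] - full$refl$qx[i], params$eta_x,
                            wx$g, wx$l) *
        pv1d(pts[, 2L] - full$refl$qy[i], params$eta_y, wy$g, wy$l)
      total <- total + v
      if (i == own) own_t <- own_t + v
    }
    list(total = total, own = own_t)
  }

  peak_max <- peak_intensity %||% model_terms(matrix(qk, 1L))$total
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  out <- data.frame(radius = radii, percent = NA_real_,
                    n_points = NA_integer_)
  for (ri in seq_along(radii)) {
    pts <- cbind(qk[1L] + radii[ri] * cos(theta),
                 qk[2L] + radii[ri] * sin(theta))
    mt <- model_terms(pts)
    keep <- mt$total > intensity_floor * peak_max
    out$n_points[ri] <- sum(keep)
    if (any(keep)) {
      out$percent[ri] <- 100 * sum(mt$total[keep] - mt$own[keep]) /
        sum(mt$total[keep])
    }
  }
  out
}
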