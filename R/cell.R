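# Unit-cell model, reflection enumeration, 4/m symmetry, continuous unit-cell
# transform, reference structure factors, Wilson statistics and fixture cells.

#' Construct a unit cell
#'
#' Cell lengths are in ångström. The supported Laue classes are `"4/m"`
#' (tetragonal, in-plane fourfold plus Friedel symmetry, requiring `a == b`)
#' and `"1"` (Friedel symmetry only). The diffraction geometry throughout the
#' package is the (hk0) reciprocal-lattice plane, with the scattering-vector
#' convention |q| = 1/d, so the Bragg position of reflection (h, k, 0) is
#' q = (h/a, k/b) in inverse ångström.
#'
#' @param a,b,c cell edge lengths in Å; `b` and `c` default to `a`.
#' @param laue_class `"4/m"` or `"1"`.
#' @return an object of class `"unit_cell"`.
#' @examples
#' unit_cell(79.959, c = 90.419)
#' @export
unit_cell <- function(a, b = a, c = a, laue_class = c("4/m", "1")) {
  laue_class <- match.arg(laue_class)
  if (!all(is.finite(c(a, b, c))) || any(c(a, b, c) <= 0))
    abort_invalid("cell lengths must be finite and positive")
  if (laue_class == "4/m" && abs(a - b) > 1e-9 * a)
    abort_invalid("Laue class 4/m requires a == b")
  structure(list(a = a, b = b, c = c, laue_class = laue_class),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a = %.4f, b = %.4f, c = %.4f Angstrom, Laue %s\n",
              x$a, x$b, x$c, x$laue_class))
  invisible(x)
}

#' Construct a table of atom sites
#'
#' Atoms are point scatterers at fractional coordinates with a scalar
#' scattering strength (electrons), an isotropic Debye-Waller factor B (Å²)
#' and an occupancy in (0, 1]. The Debye-Waller attenuation is applied to the
#' amplitude as exp(-B |q|^2 / 4) under the |q| = 1/d convention (equivalent
#' to the usual exp(-B sin^2(theta)/lambda^2)).
#'
#' @param x,y,z fractional coordinates, wrapped into `[0, 1)`.
#' @param strength scattering amplitudes (electrons); recycled.
#' @param b_iso isotropic B factors in Å², `>= 0`; recycled.
#' @param occupancy occupancies in (0, 1]; recycled.
#' @return a data frame of class `"atom_sites"`.
#' @export
atom_sites <- function(x, y, z = 0, strength = 1, b_iso = 0, occupancy = 1) {
  n <- length(x)
  if (n < 1L) abort_invalid("at least one atom site is required")
  df <- data.frame(x = x %% 1, y = y %% 1, z = rep_len(z, n) %% 1,
                   strength = rep_len(strength, n),
                   b_iso = rep_len(b_iso, n),
                   occupancy = rep_len(occupancy, n))
  if (any(!is.finite(as.matrix(df))))
    abort_invalid("atom site fields must be finite")
  if (any(df$b_iso < 0)) abort_invalid("b_iso must be >= 0")
  if (any(df$occupancy <= 0 | df$occupancy > 1))
    abort_invalid("occupancy must lie in (0, 1]")
  class(df) <- c("atom_sites", "data.frame")
  df
}

# One 4/m orbit generator step: (h, k) -> (-k, h).
rot90_hk <- function(hk) cbind(-hk[, 2L], hk[, 1L])

# Full orbit of (h, k) under the cell's Laue class (including Friedel).
hk_orbit <- function(h, k, laue_class) {
  if (laue_class == "4/m") {
    m <- matrix(c(h, k, -k, h, -h, -k, k, -h), ncol = 2L, byrow = TRUE)
  } else {
    m <- matrix(c(h, k, -h, -k), ncol = 2L, byrow = TRUE)
  }
  unique(m)
}

# Canonical orbit representative. For 4/m the half-open quadrant h >= 1,
# k >= 0 contains exactly one member of every non-origin orbit; for Laue 1
# the representative is the Friedel mate with (h > 0) or (h == 0, k > 0).
hk_representative <- function(h, k, laue_class) {
  orb <- hk_orbit(h, k, laue_class)
  if (laue_class == "4/m") {
    sel <- orb[, 1L] >= 1L & orb[, 2L] >= 0L
  } else {
    sel <- orb[, 1L] > 0L | (orb[, 1L] == 0L & orb[, 2L] > 0L)
  }
  orb[which(sel)[1L], ]
}

new_reflection_set <- function(cell, refl, symmetry_applied) {
  rownames(refl) <- NULL
  structure(list(cell = cell, refl = refl,
                 symmetry_applied = symmetry_applied),
            class = "reflection_set")
}

#' Enumerate Bragg reflections of the (hk0) plane
#'
#' Generates every in-plane reflection (h, k) != (0, 0) reachable at the
#' requested resolution, ordered deterministically by (|q|, h, k). With
#' `quadrant_only = TRUE` the set is reduced to one canonical representative
#' per Laue orbit (for 4/m: the member with h >= 1, k >= 0).
#'
#' @param cell a [unit_cell()].
#' @param d_min resolution limit in Å (`> 0`).
#' @param quadrant_only reduce to one representative per symmetry orbit?
#' @param domain `"circle"` keeps reflections with d = 1/|q| >= d_min;
#'   `"square"` keeps all reflections inside the square grid that spans
#'   `|q_x|, |q_y| <= 1/d_min` (the full field of view of a square detector
#'   array, including its corners).
#' @return a `"reflection_set"`: the cell plus a data frame with columns
#'   `h, k, qx, qy, d, F2, weak`.
#' @export
enumerate_reflections <- function(cell, d_min, quadrant_only = FALSE,
                                  domain = c("circle", "square")) {
  domain <- match.arg(domain)
  if (!is.finite(d_min) || d_min <= 0)
    abort_invalid("d_min must be a positive resolution in Angstrom")
  q_lim <- 1 / d_min
  hmax <- floor(cell$a * q_lim)
  kmax <- floor(cell$b * q_lim)
  g <- expand.grid(h = seq.int(-hmax, hmax), k = seq.int(-kmax, kmax))
  g <- g[!(g$h == 0L & g$k == 0L), , drop = FALSE]
  qx <- g$h / cell$a
  qy <- g$k / cell$b
  qmag <- sqrt(qx^2 + qy^2)
  keep <- if (domain == "circle") qmag <= q_lim + 1e-12 else rep(TRUE, nrow(g))
  refl <- data.frame(h = as.integer(g$h[keep]), k = as.integer(g$k[keep]),
                     qx = qx[keep], qy = qy[keep], d = 1 / qmag[keep],
                     F2 = rep(NA_real_, sum(keep)),
                     weak = rep(FALSE, sum(keep)))
  if (quadrant_only && nrow(refl) > 0L) {
    reps <- t(mapply(hk_representative, refl$h, refl$k,
                     MoreArgs = list(laue_class = cell$laue_class)))
    keep <- refl$h == reps[, 1L] & refl$k == reps[, 2L]
    refl <- refl[keep, , drop = FALSE]
  }
  ord <- order(1 / refl$d, refl$h, refl$k)
  new_reflection_set(cell, refl[ord, , drop = FALSE], quadrant_only)
}

#' Expand a quadrant-reduced reflection set to the full plane
#'
#' Each orbit representative is replicated over its full Laue orbit; the
#' column `orbit` in the result maps every expanded reflection back to the
#' row index of its representative, and `F2` is copied orbit-wide.
#'
#' @param rs a `"reflection_set"`.
#' @return a full-plane `"reflection_set"` whose `refl` carries an `orbit`
#'   column; if `rs` is already full-plane it is returned with `orbit` set to
#'   the row index.
#' @export
symmetry_expand <- function(rs) {
  stopifnot(inherits(rs, "reflection_set"))
  if (!rs$symmetry_applied) {
    rs$refl$orbit <- seq_len(nrow(rs$refl))
    return(rs)
  }
  cell <- rs$cell
  pieces <- lapply(seq_len(nrow(rs$refl)), function(i) {
    r <- rs$refl[i, ]
    orb <- hk_orbit(r$h, r$k, cell$laue_class)
    data.frame(h = as.integer(orb[, 1L]), k = as.integer(orb[, 2L]),
               qx = orb[, 1L] / cell$a, qy = orb[, 2L] / cell$b,
               d = r$d, F2 = r$F2, weak = r$weak, orbit = i)
  })
  refl <- do.call(rbind, pieces)
  ord <- order(1 / refl$d, refl$h, refl$k)
  out <- new_reflection_set(cell, refl[ord, , drop = FALSE], FALSE)
  out
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections%s, d range [%.3f, %.3f] A\n",
              nrow(x$refl),
              if (x$symmetry_applied) " (orbit representatives)" else "",
              min(x$refl$d), max(x$refl$d)))
  invisible(x)
}

#' Continuous unit-cell scattering transform
#'
#' Evaluates the complex unit-cell scattering amplitude
#' F(q) = sum_j f_j o_j exp(-B_j |q|^2/4) exp(2 pi i (q_x a x_j + q_y b y_j))
#' at arbitrary (continuous) points of the (hk0) reciprocal plane, not only
#' at Bragg positions.
#'
#' @param atoms an [atom_sites()] table.
#' @param cell a [unit_cell()].
#' @param q numeric 2-vector or an n-by-2 matrix of (q_x, q_y) in 1/Å.
#' @return complex amplitude(s), one per row of `q`.
#' @export
unit_cell_transform <- function(atoms, cell, q) {
  if (!inherits(atoms, "atom_sites") || nrow(atoms) < 1L)
    abort_invalid("atoms must be a non-empty atom_sites table")
  if (is.null(dim(q))) q <- matrix(q, ncol = 2L)
  q2 <- q[, 1L]^2 + q[, 2L]^2
  amp <- complex(length.out = nrow(q))
  for (j in seq_len(nrow(atoms))) {
    w <- atoms$strength[j] * atoms$occupancy[j] *
      exp(-atoms$b_iso[j] * q2 / 4)
    phase <- 2 * pi * (q[, 1L] * cell$a * atoms$x[j] +
                       q[, 2L] * cell$b * atoms$y[j])
    amp <- amp + w * complex(modulus = 1, argument = phase)
  }
  amp
}

# |F(q)|^2 over a full grid, exploiting separability of both the phase and
# the Debye-Waller factor along the two grid axes: the amplitude grid is a
# single complex matrix product over atoms.
uc_transform_grid <- function(atoms, cell, geom) {
  qx <- q_axis(geom)
  qy <- qx
  n <- geom$n
  J <- nrow(atoms)
  Ex <- matrix(0 + 0i, n, J)
  Ey <- matrix(0 + 0i, n, J)
  for (j in seq_len(J)) {
    Ex[, j] <- exp(-atoms$b_iso[j] * qx^2 / 4) *
      complex(modulus = 1, argument = 2 * pi * qx * cell$a * atoms$x[j])
    Ey[, j] <- complex(modulus = 1, argument = 2 * pi * qy * cell$b * atoms$y[j])
  }
  w <- atoms$strength * atoms$occupancy
  amp <- sweep(Ex, 2L, w, "*") %*%
    t(Ey * exp(-outer(qy^2, atoms$b_iso) / 4))
  Mod(amp)^2
}

#' Reference structure factors at Bragg positions
#'
#' Fills the `F2` column of a reflection set with |F(q_k)|^2 computed from an
#' explicit atomic model via [unit_cell_transform()]. These are the ground
#' truth against which extracted moduli are benchmarked.
#'
#' @inheritParams unit_cell_transform
#' @param rs a `"reflection_set"`.
#' @param use_b apply the Debye-Waller factors? Set `FALSE` to obtain the
#'   static-lattice moduli.
#' @return `rs` with `F2` filled.
#' @export
reference_structure_factors <- function(atoms, cell, rs, use_b = TRUE) {
  stopifnot(inherits(rs, "reflection_set"))
  a2 <- atoms
  if (!use_b) a2$b_iso <- 0
  amp <- unit_cell_transform(a2, cell, cbind(rs$refl$qx, rs$refl$qy))
  rs$refl$F2 <- Mod(amp)^2
  rs
}

#' Wilson scale and thermal-factor fit
#'
#' Least-squares fit of log(F2_ref) = log(k) + log(F2_est) - 2 B s2 over
#' reflections with positive values on both sides, where s2 = (|q|/2)^2 in
#' 1/Å². The recovered `(k, B)` rescale extracted intensities onto the
#' reference scale: `F2_corrected = k * F2_est * exp(-2 B s2)`.
#'
#' @param F2_est extracted squared moduli (or integrated intensities).
#' @param F2_ref reference squared moduli (or a mean-f² curve).
#' @param s2 per-reflection (|q|/2)^2 in 1/Å².
#' @return a list with elements `k`, `B`, `n_used`.
#' @export
wilson_fit <- function(F2_est, F2_ref, s2) {
  ok <- is.finite(F2_est) & is.finite(F2_ref) & is.finite(s2) &
    F2_est > 0 & F2_ref > 0
  if (sum(ok) < 3L)
    abort_numeric("degenerate Wilson fit: fewer than 3 usable reflections")
  s2u <- s2[ok]
  if (max(s2u) - min(s2u) < 1e-12)
    abort_numeric("degenerate Wilson fit: all s2 identical, B unidentifiable")
  y <- log(F2_ref[ok]) - log(F2_est[ok])
  fit <- stats::lm.fit(cbind(1, s2u), y)
  list(k = exp(fit$coefficients[[1L]]), B = -fit$coefficients[[2L]] / 2,
       n_used = sum(ok))
}

#' Apply a Wilson correction
#'
#' @param F2_est extracted squared moduli.
#' @param s2 per-reflection (|q|/2)^2.
#' @param fit result of [wilson_fit()].
#' @return corrected squared moduli `k * F2_est * exp(-2 B s2)`.
#' @export
wilson_apply <- function(F2_est, s2, fit) {
  fit$k * F2_est * exp(-2 * fit$B * s2)
}

#' Deterministic synthetic unit-cell fixture
#'
#' Generates a pseudo-random set of point scatterers standing in for a real
#' protein unit cell in simulation studies. With `symmetrize = TRUE` each
#' generated site is replicated over the in-plane fourfold orbit
#' (x, y) -> (-y, x) -> (-x, -y) -> (y, -x) so that the structure factors obey
#' the cell's 4/m quadrant symmetry exactly. Scattering strengths and B
#' factors are drawn in ranges typical of residue-scale scatterers.
#'
#' @param seed integer RNG seed; the same seed yields identical atoms.
#' @param n_atoms requested number of sites (rounded up to a multiple of the
#'   orbit size when `symmetrize = TRUE`).
#' @param cell a [unit_cell()].
#' @param symmetrize replicate sites over the fourfold orbit?
#' @return an [atom_sites()] table.
#' @export
make_test_cell <- function(seed, n_atoms, cell, symmetrize = TRUE) {
  if (n_atoms < 1L) abort_invalid("n_atoms must be >= 1")
  with_seed(seed, {
    n_base <- if (symmetrize) ceiling(n_atoms / 4) else n_atoms
    x <- stats::runif(n_base)
    y <- stats::runif(n_base)
    z <- stats::runif(n_base)
    f <- stats::runif(n_base, 5, 30)
    b <- stats::runif(n_base, 5, 25)
    if (symmetrize) {
      xs <- c(x, (-y) %% 1, (-x) %% 1, y %% 1)
      ys <- c(y, x %% 1, (-y) %% 1, (-x) %% 1)
      atom_sites(xs, ys, rep(z, 4L), rep(f, 4L), rep(b, 4L))
    } else {
      atom_sites(x, y, z, f, b)
    }
  })
}

#' Read a PDB coordinate file as atom sites
#'
#' Optional reader for standard PDB-format files (ATOM/HETATM records) via
#' the bio3d parser. Orthogonal coordinates are fractionalized with the given
#' cell (axes assumed aligned with the cell edges, as for tetragonal cells);
#' occupancies and B-factor columns are honoured, and scattering strengths
#' default to the element's electron count.
#'
#' @param path path to a PDB file.
#' @param cell a [unit_cell()] used to fractionalize coordinates.
#' @param strengths named numeric vector mapping element symbols to
#'   scattering strengths; defaults to electron counts for common elements.
#' @return an [atom_sites()] table.
#' @export
read_pdb_cell <- function(path, cell, strengths = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort_config("the bio3d package is required to read PDB files")
  if (!file.exists(path)) abort_config(paste("PDB file not found:", path))
  z_table <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34,
               MG = 12, MN = 25, FE = 26, ZN = 30, CA = 20, NA. = 11,
               K = 19, CL = 17)
  if (!is.null(strengths)) z_table[names(strengths)] <- strengths
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  elem[elem == "NA"] <- "NA."
  f <- z_table[elem]
  f[is.na(f)] <- 6  # unknown elements treated as carbon-weight scatterers
  occ <- at$o
  occ[!is.finite(occ) | occ <= 0] <- 1
  occ[occ > 1] <- 1
  b <- at$b
  b[!is.finite(b) | b < 0] <- 0
  out <- atom_sites(at$x / cell$a, at$y / cell$b, at$z / cell$c,
                    strength = as.numeric(f), b_iso = b, occupancy = occ)
  attr(out, "element") <- elem
  out
}

# Four-Gaussian atomic form-factor coefficients (a1..a4, b1..b4, c), with
# f(s) = sum a_i exp(-b_i s^2) + c at s = |q|/2 in 1/A. Covers the elements
# that dominate protein crystals; other elements keep their constant
# electron-count strength.
cromer_mann <- list(
  H = c(0.489918, 0.262003, 0.196767, 0.049879,
        20.6593, 7.74039, 49.5519, 2.20159, 0.001305),
  C = c(2.31000, 1.02000, 1.58860, 0.865000,
        20.8439, 10.2075, 0.568700, 51.6512, 0.215600),
  N = c(12.2126, 3.13220, 2.01250, 1.16630,
        0.005700, 9.89330, 28.9975, 0.582600, -11.529),
  O = c(3.04850, 2.28680, 1.54630, 0.867000,
        13.2771, 5.70110, 0.323900, 32.9089, 0.250800),
  P = c(6.43450, 4.17910, 1.78000, 1.49080,
        1.90670, 27.1570, 0.526000, 68.1645, 1.11490),
  S = c(6.90530, 5.20340, 1.43790, 1.58630,
        1.46790, 22.2151, 0.253600, 56.1720, 0.866900),
  SE = c(17.0006, 5.81960, 3.97310, 4.35430,
         2.40980, 0.272600, 15.2372, 43.8163, 2.84090))

#' Expand atoms into form-factor components
#'
#' Replaces each atom that has a tabulated four-Gaussian form factor with
#' five point scatterers: one per Gaussian term, with strength `a_i` and an
#' isotropic B increased by `b_i` (a Gaussian in `s = |q|/2` is exactly a
#' Debye-Waller factor under this q convention), plus the constant term.
#' The expanded list evaluates the q-dependent scattering factor through
#' the unchanged point-scatterer transform. Atoms without a tabulated
#' element (or inputs from [make_test_cell()]) pass through unchanged.
#'
#' @param atoms an [atom_sites()] table, typically from [read_pdb_cell()]
#'   (which records the element of each site).
#' @return an [atom_sites()] table of expanded point scatterers.
#' @export
expand_form_factors <- function(atoms) {
  elem <- attr(atoms, "element")
  if (is.null(elem)) return(atoms)
  rows <- lapply(seq_len(nrow(atoms)), function(j) {
    cm <- cromer_mann[[elem[j]]]
    if (is.null(cm)) return(atoms[j, , drop = FALSE])
    data.frame(x = atoms$x[j], y = atoms$y[j], z = atoms$z[j],
               strength = c(cm[1:4], cm[9]),
               b_iso = atoms$b_iso[j] + c(cm[5:8], 0),
               occupancy = atoms$occupancy[j])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("atom_sites", "data.frame")
  out
}

#' Write a reflection list as hkl-style text
#'
#' Whitespace-delimited columns `h k l |F| sigma` (l is always 0 in the
#' (hk0) plane) preceded by a commented header naming the unit cell.
#'
#' @param rs a `"reflection_set"` with `F2` filled.
#' @param path output file path.
#' @param sigma per-reflection uncertainties (default 0).
#' @return `path`, invisibly.
#' @export
write_hkl <- function(rs, path, sigma = 0) {
  stopifnot(inherits(rs, "reflection_set"))
  f <- sqrt(pmax(rs$refl$F2, 0))
  sg <- rep_len(sigma, nrow(rs$refl))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell %.17g %.17g %.17g %s", rs$cell$a, rs$cell$b,
                       rs$cell$c, rs$cell$laue_class),
               sprintf("# symmetry_applied %d", as.integer(rs$symmetry_applied)),
               "#   h   k   l            F        sigma"), con)
  writeLines(sprintf("%5d %5d %5d %.17g %.17g",
                     rs$refl$h, rs$refl$k, 0L, f, sg), con)
  invisible(path)
}

#' Read an hkl-style reflection list
#'
#' @param path file written by [write_hkl()] (or any whitespace-delimited
#'   `h k l F sigma` table with the same header).
#' @return a `"reflection_set"` with `F2 = F^2`; the attribute `"sigma"` on
#'   the `refl` data frame carries the sigma column.
#' @export
read_hkl <- function(path) {
  if (!file.exists(path)) abort_config(paste("hkl file not found:", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cl <- strsplit(trimws(sub("^#\\s*cell\\s*", "", hdr[grep("^#\\s*cell", hdr)[1L]])),
                 "\\s+")[[1L]]
  cell <- unit_cell(as.numeric(cl[1L]), as.numeric(cl[2L]), as.numeric(cl[3L]),
                    laue_class = cl[4L])
  sym_line <- grep("^#\\s*symmetry_applied", hdr)
  sym <- length(sym_line) > 0 &&
    as.integer(sub("^#\\s*symmetry_applied\\s*", "", hdr[sym_line[1L]])) == 1L
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  qx <- m[, 1L] / cell$a
  qy <- m[, 2L] / cell$b
  refl <- data.frame(h = as.integer(m[, 1L]), k = as.integer(m[, 2L]),
                     qx = qx, qy = qy, d = 1 / sqrt(qx^2 + qy^2),
                     F2 = m[, 4L]^2, weak = FALSE)
  attr(refl, "sigma") <- m[, 5L]
  new_reflection_set(cell, refl, sym)
}
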