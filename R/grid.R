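# Reciprocal-space grid geometry, the Pattern container and its file formats.

#' Square reciprocal-space grid geometry
#'
#' An n-by-n pixel grid spanning `[-q_max, q_max)` along both reciprocal
#' axes. Pixel `(i, j)` (0-based) has its center at
#' `q = ((i - n/2) dq, (j - n/2) dq)` with `dq = 2 q_max / n`; in R's 1-based
#' indexing, matrix row `i` corresponds to `q_x = (i - 1 - n/2) dq`.
#'
#' @param n pixels per side (`>= 16`, even).
#' @param q_max resolution edge in 1/Å (`1/d_min`).
#' @return an object of class `"grid_geometry"` with fields `n`, `q_max`,
#'   `dq`.
#' @export
grid_geometry <- function(n, q_max) {
  if (!is.finite(n) || n < 16 || n != round(n))
    abort_invalid("n must be an integer >= 16")
  if (n %% 2 != 0) abort_invalid("n must be even")
  if (!is.finite(q_max) || q_max <= 0) abort_invalid("q_max must be > 0")
  structure(list(n = as.integer(n), q_max = q_max, dq = 2 * q_max / n),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d, q_max = %.6g 1/A, dq = %.6g 1/A\n",
              x$n, x$n, x$q_max, x$dq))
  invisible(x)
}

#' Axis of pixel-center q values
#'
#' @param geom a [grid_geometry()].
#' @return numeric vector of length `n` with the q coordinate of each pixel
#'   center along one axis.
#' @export
q_axis <- function(geom) {
  (seq_len(geom$n) - 1 - geom$n / 2) * geom$dq
}

# Fractional (1-based) matrix index of a continuous q coordinate.
q_to_index <- function(geom, q) q / geom$dq + geom$n / 2 + 1

same_geometry <- function(g1, g2) {
  g1$n == g2$n && isTRUE(all.equal(g1$q_max, g2$q_max, tolerance = 1e-12))
}

#' Construct a diffraction Pattern
#'
#' A Pattern couples a 2D non-negative intensity grid (arbitrary units) in
#' the (hk0) reciprocal plane with its [grid_geometry()] and a provenance
#' list (seed, ensemble parameters, ...).
#'
#' @param geom a [grid_geometry()].
#' @param I an `n x n` numeric matrix of intensities, all `>= 0`.
#' @param meta named list of provenance entries.
#' @return an object of class `"pattern"`.
#' @export
pattern <- function(geom, I, meta = list()) {
  stopifnot(inherits(geom, "grid_geometry"))
  if (!is.matrix(I) || nrow(I) != geom$n || ncol(I) != geom$n)
    abort_invalid("I must be an n x n matrix matching the grid geometry")
  if (any(!is.finite(I))) abort_invalid("intensities must be finite")
  if (min(I) < -1e-9 * max(abs(I)))
    abort_invalid("intensities must be non-negative")
  I[I < 0] <- 0
  structure(list(geom = geom, I = I, meta = meta), class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat(sprintf("<pattern> %d x %d, q_max = %.6g 1/A, max I = %.6g\n",
              x$geom$n, x$geom$n, x$geom$q_max, max(x$I)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

# meta is restricted to scalar numeric/character entries for the file formats.
flatten_meta <- function(meta) {
  meta <- meta[vapply(meta, function(v) length(v) == 1L &&
                        (is.numeric(v) || is.character(v)), logical(1L))]
  meta
}

#' Write a pattern as plain text
#'
#' A self-describing text matrix: commented header (`n`, `q_max`, scalar meta
#' entries), then one whitespace-delimited row of the intensity matrix per
#' line. Doubles are printed with 17 significant digits so the round trip
#' through [read_pattern_text()] is bit-exact.
#'
#' @param pat a [pattern()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern_text <- function(pat, path) {
  stopifnot(inherits(pat, "pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wpfx-pattern 1"), con)
  writeLines(sprintf("# n %d", pat$geom$n), con)
  writeLines(sprintf("# q_max %.17g", pat$geom$q_max), con)
  meta <- flatten_meta(pat$meta)
  for (nm in names(meta)) {
    v <- meta[[nm]]
    writeLines(if (is.numeric(v)) sprintf("# meta %s num %.17g", nm, v)
               else sprintf("# meta %s chr %s", nm, v), con)
  }
  apply(pat$I, 1L, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con))
  invisible(path)
}

#' Read a pattern written by [write_pattern_text()]
#'
#' @param path input path.
#' @return a [pattern()].
#' @export
read_pattern_text <- function(path) {
  if (!file.exists(path)) abort_config(paste("pattern file not found:", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!grepl("^# wpfx-pattern", hdr[1L]))
    abort_config("not a wpfx text pattern file")
  get1 <- function(key) {
    ln <- hdr[grep(paste0("^# ", key, " "), hdr)[1L]]
    sub(paste0("^# ", key, " "), "", ln)
  }
  n <- as.integer(get1("n"))
  q_max <- as.numeric(get1("q_max"))
  meta <- list()
  for (ln in hdr[grepl("^# meta ", hdr)]) {
    parts <- strsplit(sub("^# meta ", "", ln), " ")[[1L]]
    val <- paste(parts[-(1:2)], collapse = " ")
    meta[[parts[1L]]] <- if (parts[2L] == "num") as.numeric(val) else val
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  I <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  pattern(grid_geometry(n, q_max), I, meta)
}

#' Write a pattern as a self-describing binary container
#'
#' Compact little-endian binary layout: magic string, grid size, `q_max`,
#' a serialized provenance list and the intensity doubles. Round trips
#' through [read_pattern_bin()] bit-exactly.
#'
#' @inheritParams write_pattern_text
#' @return `path`, invisibly.
#' @export
write_pattern_bin <- function(pat, path) {
  stopifnot(inherits(pat, "pattern"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("WPFXPAT1"), con)
  writeBin(as.integer(pat$geom$n), con, size = 4L, endian = "little")
  writeBin(as.numeric(pat$geom$q_max), con, size = 8L, endian = "little")
  meta_raw <- serialize(pat$meta, NULL)
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(as.numeric(pat$I), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a pattern written by [write_pattern_bin()]
#'
#' @param path input path.
#' @return a [pattern()].
#' @export
read_pattern_bin <- function(path) {
  if (!file.exists(path)) abort_config(paste("pattern file not found:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "WPFXPAT1") abort_config("not a wpfx binary pattern file")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  q_max <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- unserialize(readBin(con, "raw", mlen))
  I <- matrix(readBin(con, "numeric", n * n, size = 8L, endian = "little"),
              n, n)
  pattern(grid_geometry(n, q_max), I, meta)
}
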