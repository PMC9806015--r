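# Internal helpers shared across modules.

# Coordinate convention: positions are real-valued, 0-based, origin at the
# top-left pixel centre; x indexes columns, y indexes rows. A matrix cell
# [r, c] (1-based) has centre (x, y) = (c - 1, r - 1).

# Nearest pixel (row, col) for real-valued positions; clamped to the frame.
position_to_pixel <- function(x, y, dim) {
  r <- pmin(pmax(as.integer(round(y)) + 1L, 1L), dim[1L])
  c <- pmin(pmax(as.integer(round(x)) + 1L, 1L), dim[2L])
  cbind(row = r, col = c)
}

# Split semicolon-joined marker strings into a list of character vectors.
split_markers <- function(markers) {
  out <- strsplit(as.character(markers), ";", fixed = TRUE)
  lapply(out, function(m) m[nzchar(m)])
}

join_markers <- function(marker_list) {
  vapply(marker_list, paste, character(1), collapse = ";")
}

# Draw derived sub-stream seeds from one user-facing seed without touching
# the global RNG state more than once per call site.
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Disc rasterisation: pixel (row, col) offsets within radius r of the origin.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Stamp value v on a matrix at disc around (row0, col0); returns indices used.
disc_indices <- function(dim, row0, col0, offsets) {
  rr <- row0 + offsets[, 1L]
  cc <- col0 + offsets[, 2L]
  keep <- rr >= 1L & rr <= dim[1L] & cc >= 1L & cc <= dim[2L]
  cbind(rr[keep], cc[keep])
}
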