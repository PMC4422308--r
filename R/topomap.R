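# 24-channel prefrontal probe montage: a 4x4 grid of optodes with 3.0 cm
# spacing, sources and detectors alternating in a checkerboard. Each
# adjacent source-detector pair is a measurement channel whose position is
# the pair midpoint: 12 horizontal + 12 vertical pairs = 24 channels. The
# lowest optode row sits on the Fp1-Fp2 line (y = 0); y increases upward.
# Channels are numbered row-major from the top-left of the montage as seen
# facing the participant.

#' Build the default 24-channel probe layout
#'
#' @param spacing Inter-optode distance in cm (default 3.0).
#' @return Object of class \code{probe_layout}: \code{optodes} (data.frame
#'   x, y, role), \code{channels} (data.frame channel, x, y, optode indices),
#'   \code{spacing}.
#' @export
build_default_layout <- function(spacing = 3.0) {
  # optode grid: rows indexed top (row 1, y max) to bottom (row 4, y = 0)
  grid <- expand.grid(col = 0:3, row = 0:3)
  optodes <- data.frame(
    x = grid$col * spacing,
    y = (3 - grid$row) * spacing,
    role = ifelse((grid$col + grid$row) %% 2 == 0, "source", "detector"))
  idx <- function(row, col) row * 4 + col + 1   # 0-based row/col
  chans <- list()
  for (row in 0:3) {
    # horizontal pairs in this optode row
    for (col in 0:2)
      chans[[length(chans) + 1L]] <- c(idx(row, col), idx(row, col + 1))
    # vertical pairs between this row and the next
    if (row < 3) for (col in 0:3)
      chans[[length(chans) + 1L]] <- c(idx(row, col), idx(row + 1, col))
  }
  ch <- do.call(rbind, chans)
  channels <- data.frame(
    channel = seq_len(nrow(ch)),
    a = ch[, 1], b = ch[, 2],
    x = (optodes$x[ch[, 1]] + optodes$x[ch[, 2]]) / 2,
    y = (optodes$y[ch[, 1]] + optodes$y[ch[, 2]]) / 2)
  structure(list(optodes = optodes, channels = channels, spacing = spacing),
            class = "probe_layout")
}

#' Source-detector separation per channel
#' @param layout A \code{probe_layout}.
#' @return Numeric vector of pair distances in cm.
#' @export
channel_distances <- function(layout) {
  o <- layout$optodes; ch <- layout$channels
  sqrt((o$x[ch$a] - o$x[ch$b])^2 + (o$y[ch$a] - o$y[ch$b])^2)
}

# The 24 channel positions form a diamond lattice: in units of spacing/2
# they are the integer points (u, v), u,v in 0..6, with u+v odd. Rotating
# 45 degrees maps them onto a 6x6 square grid minus its four 3-point
# corners, which yields a natural triangulation (two triangles per full
# cell, one per corner cell) for exact piecewise-linear interpolation.
rotated_coords <- function(x, y, spacing) {
  u <- 2 * x / spacing
  v <- 2 * y / spacing
  list(i = (u + v - 1) / 2, j = (u - v + 5) / 2)
}

#' Topographic interpolation of channel t-values
#'
#' Piecewise-linear interpolation of one value per channel over a regular
#' grid covering the montage bounding box, using a fixed triangulation of
#' the channel positions. The interpolant is exact at channel positions;
#' grid points outside the convex hull of the channels are NA.
#'
#' @param t_values Numeric vector, one value per channel.
#' @param layout A \code{probe_layout}.
#' @param resolution Grid points per cm (default 4).
#' @return Object of class \code{topographic_map}: \code{x}, \code{y} grid
#'   axes (cm), \code{z} matrix (rows = y, cols = x), and the display
#'   \code{levels} when df is supplied via \code{attr}.
#' @export
interpolate_tmap <- function(t_values, layout = build_default_layout(),
                             resolution = 4) {
  nch <- nrow(layout$channels)
  if (length(t_values) != nch)
    stop(sprintf("expected %d channel values, got %d", nch, length(t_values)))
  sp <- layout$spacing
  # channel value lookup on the rotated 6x6 grid
  rc <- rotated_coords(layout$channels$x, layout$channels$y, sp)
  val <- matrix(NA_real_, 6, 6)
  val[cbind(round(rc$i) + 1, round(rc$j) + 1)] <- t_values
  xs <- seq(min(layout$channels$x), max(layout$channels$x),
            by = 1 / resolution)
  ys <- seq(min(layout$channels$y), max(layout$channels$y),
            by = 1 / resolution)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  g <- rotated_coords(gx, gy, sp)
  eps <- 1e-9
  ci <- pmin(pmax(floor(g$i + eps), 0), 4)
  cj <- pmin(pmax(floor(g$j + eps), 0), 4)
  r <- g$i - ci
  s <- g$j - cj
  look <- function(di, dj) val[cbind(ci + di + 1, cj + dj + 1)]
  v00 <- look(0, 0); v10 <- look(1, 0); v01 <- look(0, 1); v11 <- look(1, 1)
  lower <- r + s <= 1 + eps
  # barycentric sum; a corner with (numerically) zero weight contributes
  # nothing even when it is a masked lattice hole
  term <- function(w, v) ifelse(abs(w) < 1e-9, 0, w * v)
  z <- ifelse(lower,
              term(1 - r - s, v00) + term(r, v10) + term(s, v01),
              term(r + s - 1, v11) + term(1 - s, v10) + term(1 - r, v01))
  # outside the rotated grid entirely -> outside the hull
  out <- g$i < -eps | g$i > 5 + eps | g$j < -eps | g$j > 5 + eps
  z[out] <- NA_real_
  zmat <- matrix(z, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  structure(list(x = xs, y = ys, z = zmat, resolution = resolution),
            class = "topographic_map")
}

#' Display thresholds for a topographic t-map
#'
#' Two-tailed critical t values at the 5% and 1% significance levels for
#' the given degrees of freedom, used to annotate the map color scale.
#'
#' @param df Degrees of freedom (for two groups of 10, df = 18).
#' @return Named numeric vector \code{c(level_5pct, level_1pct)}.
#' @export
threshold_levels <- function(df) {
  c(level_5pct = critical_t(df, 0.05), level_1pct = critical_t(df, 0.01))
}

#' Write a topographic map grid to CSV
#' @param map A \code{topographic_map}.
#' @param path Output path. Rows are y (descending), columns x.
#' @return \code{path}, invisibly.
#' @export
write_tmap <- function(map, path) {
  df <- as.data.frame(map$z[rev(seq_along(map$y)), , drop = FALSE])
  names(df) <- sprintf("x_%g", map$x)
  df <- cbind(y = rev(map$y), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
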