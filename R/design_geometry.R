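#' Construct a game-board specification
#'
#' The default board is the 13-row by 9-column grid (117 cells) used
#' throughout the piece-counting experiments: 390 x 507 pixels at scale 1,
#' with 21-pixel game pieces. Scaling multiplies every pixel dimension and
#' rounds to whole pixels.
#'
#' @param rows,cols grid dimensions (rows x cols cells).
#' @param scale multiplicative scale factor. The experiments use 1, 0.75 and
#'   0.5; other positive values are accepted with a warning.
#' @param base_cell_px base (scale 1) cell width and height in pixels.
#' @param base_piece_px base piece diameter in pixels.
#' @return an object of class `board_spec` with fields `rows`, `cols`,
#'   `board_px` (width, height), `cell_px` (width, height, unrounded),
#'   `piece_px` and `scale`.
#' @examples
#' b <- make_board()
#' b$rows * b$cols  # 117 cells
#' @export
make_board <- function(rows = 13L, cols = 9L, scale = 1,
                       base_cell_px = c(390 / 9, 507 / 13),
                       base_piece_px = 21) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols)) {
    stop("`rows` and `cols` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a positive number", call. = FALSE)
  }
  if (!scale %in% c(1, 0.75, 0.5)) {
    warning("`scale` outside the standard menu {1, 0.75, 0.5}")
  }
  cell_px <- scale * base_cell_px
  board <- structure(list(
    rows = as.integer(rows),
    cols = as.integer(cols),
    board_px = c(width = round(cols * cell_px[1]), height = round(rows * cell_px[2])),
    cell_px = c(width = cell_px[1], height = cell_px[2]),
    piece_px = round(scale * base_piece_px),
    scale = scale
  ), class = "board_spec")
  stopifnot(all(board$board_px > 0), board$piece_px > 0)
  board
}

#' @export
print.board_spec <- function(x, ...) {
  cat(sprintf("<board_spec> %d x %d cells (%d total), %d x %d px, piece %d px, scale %g\n",
              x$rows, x$cols, x$rows * x$cols,
              x$board_px[1], x$board_px[2], x$piece_px, x$scale))
  invisible(x)
}

#' Construct a mesh occluder with round holes
#'
#' A mesh occluder is a 280 x 407 pixel (at scale 1) rectangle perforated by
#' 12 round holes, six of a small and six of a large diameter. The published
#' occluder menus are identified by the (small, large) diameter pair, e.g.
#' (40, 60). The exact hole coordinates were never published, so this
#' implementation places holes on a fixed 3-column x 4-row lattice centred in
#' the footprint, with the two size classes alternating in a checker pattern;
#' the layout is mirror-symmetric about the occluder's vertical midline.
#' `pattern_id = 2` is the top-bottom flip of pattern 1 (so the two variants
#' differ while obeying the same constraints).
#'
#' @param small_d,large_d hole diameters in pixels, `0 < small_d < large_d`.
#' @param pattern_id 1 or 2, selecting one of the two layout variants.
#' @param scale multiplicative scale factor applied to all pixel dimensions.
#' @param base_occluder_px footprint (width, height) at scale 1.
#' @return an object of class `occluder_spec` with `kind = "mesh"`,
#'   `occluder_px`, `hole_diams`, a `hole_centers` data frame (x, y, class,
#'   diam) and `pattern_id`.
#' @examples
#' occ <- make_mesh_occluder(40, 60)
#' nrow(occ$hole_centers)  # 12 holes
#' @export
make_mesh_occluder <- function(small_d, large_d, pattern_id = 1L, scale = 1,
                               base_occluder_px = c(280, 407)) {
  if (!(is.numeric(small_d) && is.numeric(large_d) && small_d > 0 && large_d > small_d)) {
    stop("need 0 < small_d < large_d", call. = FALSE)
  }
  if (!pattern_id %in% c(1L, 2L)) stop("`pattern_id` must be 1 or 2", call. = FALSE)
  ow <- scale * base_occluder_px[1]
  oh <- scale * base_occluder_px[2]
  ncol_h <- 3L
  nrow_h <- 4L
  cx <- ow * (seq_len(ncol_h) - 0.5) / ncol_h
  cy <- oh * (seq_len(nrow_h) - 0.5) / nrow_h
  grid <- expand.grid(col = seq_len(ncol_h), row = seq_len(nrow_h))
  if (pattern_id == 2L) grid$row <- nrow_h + 1L - grid$row
  size_class <- ifelse((grid$row + grid$col) %% 2L == 0L, "small", "large")
  centers <- data.frame(
    x = cx[grid$col],
    y = cy[grid$row],
    class = size_class,
    diam = scale * ifelse(size_class == "small", small_d, large_d),
    stringsAsFactors = FALSE
  )
  # geometric feasibility: holes inside the footprint and pairwise disjoint
  r <- centers$diam / 2
  if (any(centers$x - r < 0 | centers$x + r > ow | centers$y - r < 0 | centers$y + r > oh)) {
    stop("hole extends outside the occluder footprint", call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(centers[, c("x", "y")]))
  rsum <- outer(r, r, "+")
  diag(dmat) <- Inf
  if (any(dmat < rsum)) stop("holes overlap for these diameters", call. = FALSE)
  structure(list(
    kind = "mesh",
    occluder_px = c(width = ow, height = oh),
    hole_diams = c(small = scale * small_d, large = scale * large_d),
    hole_centers = centers,
    pattern_id = as.integer(pattern_id),
    scale = scale
  ), class = "occluder_spec")
}

#' Construct a bar occluder
#'
#' Bar occluders consist of two opaque bars spanning the full board: two
#' vertical bars each covering two columns, or two horizontal bars each
#' covering three rows. Bar positions (columns 3-4 and 6-7, rows 4-6 and
#' 8-10, 1-based) are symmetric and keep visible cells on both sides; only
#' the covered-line counts enter the expected-hidden arithmetic.
#'
#' @param orientation `"vertical"` or `"horizontal"`.
#' @return an `occluder_spec` with `kind` `"vertical_bars"` or
#'   `"horizontal_bars"` and `bar_extent`, a list of covered column (or row)
#'   index vectors.
#' @examples
#' make_bar_occluder("vertical")$bar_extent  # columns 3-4 and 6-7
#' @export
make_bar_occluder <- function(orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (orientation == "vertical") {
    structure(list(
      kind = "vertical_bars",
      bar_extent = list(3:4, 6:7),
      scale = 1
    ), class = "occluder_spec")
  } else {
    structure(list(
      kind = "horizontal_bars",
      bar_extent = list(4:6, 8:10),
      scale = 1
    ), class = "occluder_spec")
  }
}

#' @export
print.occluder_spec <- function(x, ...) {
  if (x$kind == "mesh") {
    cat(sprintf("<occluder_spec> mesh %g x %g px, 12 holes (d = %g/%g), pattern %d\n",
                x$occluder_px[1], x$occluder_px[2],
                x$hole_diams[1], x$hole_diams[2], x$pattern_id))
  } else {
    cat(sprintf("<occluder_spec> %s covering lines %s\n", x$kind,
                paste(vapply(x$bar_extent, function(b) paste(range(b), collapse = "-"), ""),
                      collapse = ", ")))
  }
  invisible(x)
}

# Rasterize the occluder as a logical material mask over the board's pixel
# grid (rows = y, cols = x; TRUE = opaque). The occluder is centred on the
# board. NULL means no occluder.
occluder_mask <- function(board, occluder = NULL) {
  w <- as.integer(board$board_px[1])
  h <- as.integer(board$board_px[2])
  mask <- matrix(FALSE, nrow = h, ncol = w)
  if (is.null(occluder)) return(mask)
  px <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)   # pixel centre x
  py <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)  # pixel centre y
  if (occluder$kind == "mesh") {
    x0 <- (w - occluder$occluder_px[1]) / 2
    y0 <- (h - occluder$occluder_px[2]) / 2
    inside <- px >= x0 & px <= x0 + occluder$occluder_px[1] &
              py >= y0 & py <= y0 + occluder$occluder_px[2]
    in_hole <- matrix(FALSE, nrow = h, ncol = w)
    hc <- occluder$hole_centers
    for (k in seq_len(nrow(hc))) {
      in_hole <- in_hole |
        ((px - (x0 + hc$x[k]))^2 + (py - (y0 + hc$y[k]))^2 <= (hc$diam[k] / 2)^2)
    }
    mask <- inside & !in_hole
  } else if (occluder$kind == "vertical_bars") {
    cw <- board$cell_px[1]
    for (bar in occluder$bar_extent) {
      mask <- mask | (px >= (min(bar) - 1) * cw & px <= max(bar) * cw)
    }
  } else if (occluder$kind == "horizontal_bars") {
    ch <- board$cell_px[2]
    for (bar in occluder$bar_extent) {
      mask <- mask | (py >= (min(bar) - 1) * ch & py <= max(bar) * ch)
    }
  } else {
    stop("unknown occluder kind: ", occluder$kind, call. = FALSE)
  }
  mask
}

# Is a piece centred on cell (row, col) completely under occluder material?
# Evaluated on the rasterized mask: every pixel whose centre lies within the
# piece disk must be opaque.
cell_hidden <- function(board, mask, row, col) {
  cw <- board$cell_px[1]; ch <- board$cell_px[2]
  cx <- (col - 0.5) * cw
  cy <- (row - 0.5) * ch
  r <- board$piece_px / 2
  xs <- max(1L, floor(cx - r)):min(ncol(mask), ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(nrow(mask), ceiling(cy + r))
  sub <- mask[ys, xs, drop = FALSE]
  dx <- outer(rep(1, length(ys)), xs - 0.5 - cx)
  dy <- outer(ys - 0.5 - cy, rep(1, length(xs)))
  disk <- dx^2 + dy^2 <= r^2
  all(sub[disk])
}

#' Visible/hidden cell geometry for a board-occluder pair
#'
#' Counts, for an occluder centred on the board, the grid cells where a piece
#' would be completely hidden (every pixel of a piece disk centred in the
#' cell lies under occluder material) versus at least partly visible. Under
#' this package's convention the visible and hidden areas are the cell
#' counts themselves (S_v = N_v, S_h = N_h).
#'
#' @param board a `board_spec`.
#' @param occluder an `occluder_spec`, or NULL for no occlusion.
#' @return an object of class `occlusion_geometry` with fields `N_v`, `N_h`,
#'   `S_v`, `S_h`, `ratio` (= S_h / S_v) and a logical `hidden` matrix
#'   (rows x cols).
#' @examples
#' g <- occlusion_geometry(make_board(), make_bar_occluder("vertical"))
#' g$ratio  # 52 hidden / 65 visible = 0.8
#' @export
occlusion_geometry <- function(board, occluder = NULL) {
  stopifnot(inherits(board, "board_spec"))
  mask <- occluder_mask(board, occluder)
  hidden <- matrix(FALSE, nrow = board$rows, ncol = board$cols)
  for (r in seq_len(board$rows)) {
    for (c in seq_len(board$cols)) {
      hidden[r, c] <- cell_hidden(board, mask, r, c)
    }
  }
  n_h <- sum(hidden)
  n_v <- board$rows * board$cols - n_h
  structure(list(
    N_v = n_v, N_h = n_h,
    S_v = n_v, S_h = n_h,
    ratio = if (n_v > 0) n_h / n_v else Inf,
    hidden = hidden,
    board = board, occluder = occluder
  ), class = "occlusion_geometry")
}

#' @export
print.occlusion_geometry <- function(x, ...) {
  cat(sprintf("<occlusion_geometry> N_v = %d, N_h = %d, S_h/S_v = %.4g\n",
              x$N_v, x$N_h, x$ratio))
  invisible(x)
}

#' Expected number of hidden objects by density extrapolation
#'
#' Assuming a homogeneous object density, the number of hidden objects is the
#' density of visible objects (n_v / S_v) extrapolated to the hidden area:
#' n_h = n_v * S_h / S_v.
#'
#' @param n_v number of visible objects (vectorised).
#' @param geom an `occlusion_geometry`, or directly the area ratio S_h / S_v
#'   (useful when the ratio comes from a published menu rather than a
#'   constructed geometry).
#' @return expected hidden count(s), real-valued.
#' @examples
#' expected_hidden(10, 0.27)  # 2.7
#' @export
expected_hidden <- function(n_v, geom) {
  if (any(n_v < 0)) stop("`n_v` must be non-negative", call. = FALSE)
  ratio <- if (inherits(geom, "occlusion_geometry")) {
    if (geom$S_v <= 0) stop("visible area S_v is zero; expected hidden count undefined", call. = FALSE)
    geom$S_h / geom$S_v
  } else if (is.numeric(geom) && length(geom) == 1L && geom >= 0) {
    geom
  } else {
    stop("`geom` must be an occlusion_geometry or a non-negative ratio", call. = FALSE)
  }
  n_v * ratio
}
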