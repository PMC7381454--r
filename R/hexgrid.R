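#' Width and height of a flat-topped hexagonal cell
#'
#' For a flat-topped hexagon of circumradius `cell_size` (the distance from
#' the cell center to any corner), the bounding width is `2 * cell_size` and
#' the height is `sqrt(3) * cell_size`.
#'
#' @param cell_size Circumradius of one hexagonal cell, in cm. Must be a
#'   single positive number.
#' @return Named numeric vector `c(width, height)` in cm.
#' @examples
#' cell_dimensions(1.5)  # c(width = 3, height = 2.598...)
#' @export
cell_dimensions <- function(cell_size) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0) {
    stop("'cell_size' must be a single positive finite number", call. = FALSE)
  }
  c(width = 2 * cell_size, height = sqrt(3) * cell_size)
}

#' Specification of a flat-topped hexagonal grid board
#'
#' Describes the physical board: cell size, board rectangle, and the physical
#' origin. Physical coordinates place the origin at the board's lower-left
#' corner with x rightward and y upward, in cm.
#'
#' @param cell_size Hexagon circumradius in cm (default 1.5).
#' @param board_width,board_height Board rectangle dimensions in cm
#'   (defaults 94 x 61).
#' @param origin Length-2 numeric, physical coordinate of the board's
#'   lower-left corner (default `c(0, 0)`).
#' @return An object of class `hex_grid_spec`.
#' @export
hex_grid_spec <- function(cell_size = 1.5, board_width = 94,
                          board_height = 61, origin = c(0, 0)) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L,
            is.numeric(board_width), is.numeric(board_height),
            is.numeric(origin), length(origin) == 2L)
  if (cell_size <= 0) stop("'cell_size' must be > 0", call. = FALSE)
  if (board_width <= 0 || board_height <= 0) {
    stop("board dimensions must be > 0", call. = FALSE)
  }
  structure(
    list(cell_size = cell_size, board_width = board_width,
         board_height = board_height, orientation = "flat_top",
         origin = as.numeric(origin)),
    class = "hex_grid_spec"
  )
}

#' @export
print.hex_grid_spec <- function(x, ...) {
  wh <- cell_dimensions(x$cell_size)
  cat(sprintf(
    "hex_grid_spec: flat-top cells, size %.3g cm (w %.3g, h %.4g), board %g x %g cm\n",
    x$cell_size, wh[["width"]], wh[["height"]], x$board_width, x$board_height))
  invisible(x)
}

# Lattice constants for a flat-top grid: columns step 3/4 * w horizontally,
# odd columns are shifted down... (here: up, y increases upward) by h/2.
# All six neighbor center distances equal h = sqrt(3) * cell_size.
hex_lattice_constants <- function(spec) {
  wh <- cell_dimensions(spec$cell_size)
  list(w = wh[["width"]], h = wh[["height"]],
       dx = 0.75 * wh[["width"]], spacing = wh[["height"]])
}

# Center of axial cell (q, r) relative to the board origin, in cm.
hex_axial_center <- function(q, r, spec) {
  k <- hex_lattice_constants(spec)
  x <- spec$origin[1] + k$w / 2 + q * k$dx
  y <- spec$origin[2] + k$h / 2 + r * k$h + ifelse(q %% 2L == 1L, k$h / 2, 0)
  cbind(x = x, y = y)
}

#' Generate the hexagonal grid covering a board
#'
#' Enumerates every flat-topped hexagonal cell whose center lies strictly
#' inside the board rectangle. Cells carry axial indices `(q, r)` (`q` the
#' column, odd columns vertically offset by half a cell height) and physical
#' centers in cm. Generation is deterministic: equal specs give identical
#' grids.
#'
#' @param spec A [hex_grid_spec()].
#' @return An object of class `hex_grid`: a list with `spec`, `cells` (a
#'   data.frame with columns `q`, `r`, `x_cm`, `y_cm`, ordered by `(r, q)`),
#'   and `neighbors` (list of integer row-index vectors, one per cell).
#' @examples
#' g <- hex_grid(hex_grid_spec(cell_size = 1.5, board_width = 20, board_height = 15))
#' nrow(g$cells)
#' @export
hex_grid <- function(spec) {
  stopifnot(inherits(spec, "hex_grid_spec"))
  k <- hex_lattice_constants(spec)
  x0 <- spec$origin[1]; y0 <- spec$origin[2]
  q_max <- ceiling(spec$board_width / k$dx) + 1L
  r_max <- ceiling(spec$board_height / k$h) + 1L
  cand <- expand.grid(q = 0:q_max, r = 0:r_max, KEEP.OUT.ATTRS = FALSE)
  ctr <- hex_axial_center(cand$q, cand$r, spec)
  inside <- ctr[, 1] > x0 & ctr[, 1] < x0 + spec$board_width &
            ctr[, 2] > y0 & ctr[, 2] < y0 + spec$board_height
  if (!any(inside)) {
    stop("board smaller than one cell: no cell center fits inside", call. = FALSE)
  }
  cells <- data.frame(q = cand$q[inside], r = cand$r[inside],
                      x_cm = ctr[inside, 1], y_cm = ctr[inside, 2])
  cells <- cells[order(cells$r, cells$q), , drop = FALSE]
  rownames(cells) <- NULL
  grid <- structure(list(spec = spec, cells = cells, neighbors = NULL),
                    class = "hex_grid")
  grid$neighbors <- compute_neighbor_lists(grid)
  grid
}

# Precompute, for each cell, the row indices of cells at exactly one lattice
# spacing (within 1e-9 relative tolerance).
compute_neighbor_lists <- function(grid) {
  k <- hex_lattice_constants(grid$spec)
  x <- grid$cells$x_cm; y <- grid$cells$y_cm
  n <- length(x)
  tol <- 1e-9 * k$spacing
  lapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    which(abs(d - k$spacing) <= tol)
  })
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("hex_grid: %d cells on a %g x %g cm board (cell size %g cm)\n",
              nrow(x$cells), x$spec$board_width, x$spec$board_height,
              x$spec$cell_size))
  invisible(x)
}

#' Nearest grid cell to a physical point
#'
#' Finds, for each query point, the cell whose center minimizes Euclidean
#' distance. Exact ties are broken by the smallest `(r, q)` in lexicographic
#' order (which is the cells' storage order).
#'
#' @param grid A [hex_grid()].
#' @param points Numeric matrix (or length-2 vector) of query points in cm,
#'   one row per point, columns x and y.
#' @return Integer vector of row indices into `grid$cells`, one per point.
#' @export
nearest_cell <- function(grid, points) {
  stopifnot(inherits(grid, "hex_grid"))
  if (nrow(grid$cells) == 0L) stop("empty grid", call. = FALSE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  cx <- grid$cells$x_cm; cy <- grid$cells$y_cm
  vapply(seq_len(nrow(points)), function(i) {
    d2 <- (cx - points[i, 1])^2 + (cy - points[i, 2])^2
    # which.min returns the first minimum; cells are stored in (r, q) order,
    # so this realizes the lexicographic tie-break. Guard against floating
    # near-ties at exact midpoints by snapping within 1e-12 of the minimum.
    m <- min(d2)
    which(d2 <= m + 1e-12 * max(m, 1))[1L]
  }, integer(1))
}

#' Neighbors of a grid cell
#'
#' Returns the row indices of all cells at exactly one lattice spacing from
#' the given cell. Interior cells have 6 neighbors; boundary cells 2-5.
#'
#' @param grid A [hex_grid()].
#' @param cell Integer row index into `grid$cells`.
#' @return Integer vector of neighbor row indices (length at most 6).
#' @export
hex_neighbors <- function(grid, cell) {
  stopifnot(inherits(grid, "hex_grid"))
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 1L || cell > nrow(grid$cells)) {
    stop("'cell' is not a row index of a cell in the grid", call. = FALSE)
  }
  grid$neighbors[[cell]]
}

#' Find a cell's row index from its axial coordinates
#'
#' @param grid A [hex_grid()].
#' @param q,r Axial column and row indices.
#' @return Integer row index, or `NA` if no such cell.
#' @export
cell_index <- function(grid, q, r) {
  i <- which(grid$cells$q == q & grid$cells$r == r)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Export a grid to JSON
#'
#' Serializes the spec fields plus the cell list `{q, r, x_cm, y_cm}`.
#'
#' @param grid A [hex_grid()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
grid_to_json <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "hex_grid"))
  obj <- list(
    spec = list(cell_size = grid$spec$cell_size,
                board_width = grid$spec$board_width,
                board_height = grid$spec$board_height,
                orientation = grid$spec$orientation,
                origin = grid$spec$origin),
    cells = grid$cells
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Import a grid from JSON written by [grid_to_json()]
#'
#' The grid is regenerated from the spec and verified cell-for-cell against
#' the serialized cell list.
#'
#' @param x JSON string or path to a JSON file.
#' @return A [hex_grid()].
#' @export
grid_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  spec <- hex_grid_spec(cell_size = obj$spec$cell_size,
                        board_width = obj$spec$board_width,
                        board_height = obj$spec$board_height,
                        origin = obj$spec$origin)
  grid <- hex_grid(spec)
  got <- grid$cells[, c("q", "r")]
  want <- obj$cells[, c("q", "r")]
  if (nrow(got) != nrow(want) || any(got != want)) {
    stop("serialized cell list does not match the grid implied by its spec",
         call. = FALSE)
  }
  grid
}
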