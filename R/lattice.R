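#' Create a regular raster lattice
#'
#' A lattice is the shared grid geometry of every raster layer in the
#' pipeline: a regular `n_rows` by `n_cols` grid of square cells of side
#' `cell_size` kilometres, indexed in row-major order (cell 1 is the
#' top-left corner).  Rook (4-neighbour) adjacency between cells carries the
#' spatial structure used by the conditional autoregressive (CAR) random
#' effect of the envenoming model.
#'
#' @param n_rows,n_cols Number of rows and columns; both must be at least 3
#'   so that the lattice has interior cells and the CAR effect is
#'   meaningful.
#' @param cell_size Cell side length in kilometres (default 1).
#' @param origin Numeric length-2 vector: projected coordinates of the
#'   lower-left corner of the grid.
#' @param crs_label Free-text label for the (synthetic) coordinate system.
#'
#' @return An object of class `env_lattice`: a list with the grid
#'   dimensions, cell size, origin, CRS label, the rook adjacency list
#'   (`adjacency[[i]]` holds the neighbours of cell `i`), and the unique
#'   edge list as a two-column matrix.
#'
#' @examples
#' lat <- make_lattice(5, 5)
#' lattice_cells(lat)
#' @export
make_lattice <- function(n_rows, n_cols, cell_size = 1,
                         origin = c(0, 0), crs_label = "synthetic-grid") {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 3 || n_cols < 3 || n_rows != round(n_rows) ||
      n_cols != round(n_cols)) {
    abort_invalid("`n_rows` and `n_cols` must be whole numbers >= 3.")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    abort_invalid("`cell_size` must be a positive number (km).")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols

  # row-major cell ids; rook neighbours via index arithmetic
  cell <- seq_len(n)
  row <- ((cell - 1L) %/% n_cols) + 1L
  col <- ((cell - 1L) %% n_cols) + 1L

  edges <- rbind(
    cbind(cell[col < n_cols], cell[col < n_cols] + 1L),     # east
    cbind(cell[row < n_rows], cell[row < n_rows] + n_cols)  # south
  )
  adjacency <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    adjacency[[i]] <- c(adjacency[[i]], j)
    adjacency[[j]] <- c(adjacency[[j]], i)
  }

  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, n_cells = n,
      cell_size = cell_size, origin = as.numeric(origin),
      crs_label = crs_label,
      adjacency = adjacency, edges = edges
    ),
    class = "env_lattice"
  )
}

#' @export
print.env_lattice <- function(x, ...) {
  cat(sprintf("<env_lattice> %d x %d cells of %.3g km (%d cells, %d rook edges)\n",
              x$n_rows, x$n_cols, x$cell_size, x$n_cells, nrow(x$edges)))
  invisible(x)
}

#' Cell table of a lattice
#'
#' @param lattice An [make_lattice()] object.
#' @return A tibble with one row per cell: `cell`, `row`, `col` and the
#'   projected centre coordinates `x`, `y` (km).
#' @export
lattice_cells <- function(lattice) {
  stopifnot(inherits(lattice, "env_lattice"))
  n <- lattice$n_cells
  cell <- seq_len(n)
  row <- ((cell - 1L) %/% lattice$n_cols) + 1L
  col <- ((cell - 1L) %% lattice$n_cols) + 1L
  tibble::tibble(
    cell = cell, row = row, col = col,
    x = lattice$origin[1] + (col - 0.5) * lattice$cell_size,
    y = lattice$origin[2] + (lattice$n_rows - row + 0.5) * lattice$cell_size
  )
}

#' Rook adjacency as a sparse matrix
#'
#' @param lattice An [make_lattice()] object.
#' @return A symmetric sparse 0/1 `Matrix` with zero diagonal.
#' @export
lattice_adjacency_matrix <- function(lattice) {
  stopifnot(inherits(lattice, "env_lattice"))
  e <- lattice$edges
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
    x = 1, dims = c(lattice$n_cells, lattice$n_cells)
  )
}

#' Map projected coordinates to cell ids
#'
#' Points outside the lattice extent get `NA`.
#'
#' @param lattice An [make_lattice()] object.
#' @param x,y Numeric vectors of projected coordinates (km).
#' @return Integer vector of cell ids (row-major).
#' @export
coords_to_cell <- function(lattice, x, y) {
  stopifnot(inherits(lattice, "env_lattice"))
  col <- floor((x - lattice$origin[1]) / lattice$cell_size) + 1
  row_from_bottom <- floor((y - lattice$origin[2]) / lattice$cell_size) + 1
  row <- lattice$n_rows - row_from_bottom + 1
  ok <- col >= 1 & col <= lattice$n_cols & row >= 1 & row <= lattice$n_rows
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((row[ok] - 1) * lattice$n_cols + col[ok])
  out
}

# --- internal helpers ------------------------------------------------------

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "envenomr_invalid_argument", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "envenomr_io_error", ...)
}

# pull a per-cell value column out of a layer tibble, checked against the
# lattice size and (unless allow_na) finiteness
layer_values <- function(layer, lattice, col = "value", allow_na = FALSE) {
  if (!is.data.frame(layer) || !all(c("cell", col) %in% names(layer))) {
    abort_invalid(sprintf("expected a layer tibble with columns `cell` and `%s`.", col))
  }
  if (nrow(layer) != lattice$n_cells || !identical(sort(layer$cell), seq_len(lattice$n_cells))) {
    abort_invalid("layer does not cover the lattice exactly once per cell.")
  }
  v <- layer[[col]][order(layer$cell)]
  if (!allow_na && any(!is.finite(v))) {
    abort_invalid(sprintf("non-finite values in layer column `%s`.", col))
  }
  v
}

layer_tbl <- function(lattice, value, name = "value") {
  out <- tibble::tibble(cell = seq_len(lattice$n_cells))
  out[[name]] <- value
  out
}

#' Plot a per-cell layer as a raster map
#'
#' @param layer A tibble with columns `cell` and the value column.
#' @param lattice The [make_lattice()] geometry of the layer.
#' @param value Name of the value column (default `"value"`).
#' @return A ggplot object.
#' @export
plot_layer <- function(layer, lattice, value = "value") {
  cells <- lattice_cells(lattice)
  df <- dplyr::left_join(cells, layer, by = "cell")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}
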