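#' The 32-location search grid
#'
#' Targets appear on a 6 x 6 grid whose four corner cells are left empty,
#' leaving 32 usable locations.  Rows and columns are 0-based (0..5); cells
#' are identified by a 0-based `cell_index` assigned in row-major order over
#' the retained cells.
#'
#' @return A tibble with columns `cell_index` (0..31), `row` and `col`.
#' @examples
#' g <- make_grid()
#' nrow(g)  # 32
#' @export
make_grid <- function() {
  cells <- expand.grid(col = 0:5, row = 0:5)
  corner <- cells$row %in% c(0L, 5L) & cells$col %in% c(0L, 5L)
  cells <- cells[!corner, ]
  tibble::tibble(
    cell_index = seq_len(nrow(cells)) - 1L,
    row = as.integer(cells$row),
    col = as.integer(cells$col)
  )
}

# Internal: row/col lookup vectors indexed by cell_index + 1.
grid_rows <- function(grid = make_grid()) grid$row[order(grid$cell_index)]
grid_cols <- function(grid = make_grid()) grid$col[order(grid$cell_index)]

#' Are two grid locations neighbors?
#'
#' Adjacency uses the 8-neighborhood (orthogonal and diagonal): two distinct
#' cells are adjacent iff their row and column indices both differ by at most
#' one.  This is the strictest reading of the constraint that consecutive
#' targets within a mini-block may not appear in neighboring screen
#' locations.
#'
#' @param a,b Cell indices (0..31), vectorized.
#' @param grid A grid as returned by [make_grid()].
#' @return Logical vector.
#' @export
is_adjacent <- function(a, b, grid = make_grid()) {
  if (any(a == b)) {
    stop("is_adjacent() is undefined for identical locations")
  }
  rows <- grid_rows(grid)
  cols <- grid_cols(grid)
  abs(rows[a + 1L] - rows[b + 1L]) <= 1L & abs(cols[a + 1L] - cols[b + 1L]) <= 1L
}

# Internal: TRUE if any consecutive pair in a location vector is adjacent.
has_adjacent_pair <- function(locs, grid = make_grid()) {
  n <- length(locs)
  if (n < 2L) return(FALSE)
  any(is_adjacent(locs[-n], locs[-1L], grid = grid))
}
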