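#' Display grid geometry
#'
#' Describes the regular 15 x 19 grid of bar stimuli used throughout the
#' package. Slot centres are `spacing` degrees of visual angle apart, both
#' horizontally and vertically, and the fixation point sits
#' `fixation_offset` degrees to the left of the leftmost column's centre, on
#' the same horizontal line as the target row. With the defaults the grid
#' spans 11.25 deg x 14.25 deg (rows x columns, counting a half-spacing
#' margin beyond the extreme slot centres) and the target slot at row 8,
#' column 8 lies at 6 deg eccentricity.
#'
#' @param n_rows,n_cols Grid dimensions (slots).
#' @param spacing Centre-to-centre slot spacing in degrees of visual angle.
#' @param fixation_offset Degrees between fixation and the leftmost column.
#' @param target_row,target_col 1-based position of the tilted target bar.
#' @param tilt_magnitude Absolute target tilt from vertical, in degrees.
#'
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry()
#' slot_position(8, 8, g)   # 6 deg eccentricity
#' @export
grid_geometry <- function(n_rows = 15L, n_cols = 19L, spacing = 0.75,
                          fixation_offset = 0.75, target_row = 8L,
                          target_col = 8L, tilt_magnitude = 5) {
  stopifnot(n_rows >= 1, n_cols >= 1, spacing > 0, fixation_offset >= 0,
            target_row >= 1, target_row <= n_rows,
            target_col >= 1, target_col <= n_cols, tilt_magnitude > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         spacing = spacing, fixation_offset = fixation_offset,
         target_row = as.integer(target_row),
         target_col = as.integer(target_col),
         tilt_magnitude = tilt_magnitude),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d slots, spacing %.3g deg (span %.4g x %.4g deg)\n",
    x$n_rows, x$n_cols, x$spacing, x$n_rows * x$spacing, x$n_cols * x$spacing))
  cat(sprintf("  target at (%d, %d), tilt +/-%g deg, eccentricity %.4g deg\n",
              x$target_row, x$target_col, x$tilt_magnitude,
              target_eccentricity(x)))
  invisible(x)
}

#' Position of a grid slot relative to fixation
#'
#' Returns the slot centre in degrees of visual angle, with fixation at the
#' origin, x increasing rightward and y increasing upward. The fixation
#' point lies on the target row, `fixation_offset` degrees left of the first
#' column, so `slot_position(target_row, 1, g)` is `(fixation_offset, 0)`.
#'
#' @param row,col 1-based slot indices.
#' @param geometry A [grid_geometry()].
#' @return Numeric vector `c(x, y)` in degrees.
#' @export
slot_position <- function(row, col, geometry = grid_geometry()) {
  check_slot(row, col, geometry)
  c(x = geometry$fixation_offset + (col - 1) * geometry$spacing,
    y = (geometry$target_row - row) * geometry$spacing)
}

check_slot <- function(row, col, geometry) {
  if (any(row < 1 | row > geometry$n_rows | row != floor(row)))
    stop("row index out of range [1, ", geometry$n_rows, "]: ", row,
         call. = FALSE)
  if (any(col < 1 | col > geometry$n_cols | col != floor(col)))
    stop("col index out of range [1, ", geometry$n_cols, "]: ", col,
         call. = FALSE)
  invisible(TRUE)
}

#' Centre-to-centre distance from a slot to the target slot
#'
#' @inheritParams slot_position
#' @return Distance in degrees of visual angle (0 for the target slot).
#' @export
distance_to_target <- function(row, col, geometry = grid_geometry()) {
  check_slot(row, col, geometry)
  geometry$spacing *
    sqrt((row - geometry$target_row)^2 + (col - geometry$target_col)^2)
}

#' Eccentricity of the target slot
#'
#' Euclidean distance from fixation to the target slot centre; 6 deg with
#' the default geometry.
#'
#' @param geometry A [grid_geometry()].
#' @export
target_eccentricity <- function(geometry = grid_geometry()) {
  p <- slot_position(geometry$target_row, geometry$target_col, geometry)
  sqrt(sum(p^2))
}

# 15 x 19 matrix of distances to the target, in degrees
distance_matrix <- function(geometry) {
  rows <- matrix(seq_len(geometry$n_rows), geometry$n_rows, geometry$n_cols)
  cols <- matrix(seq_len(geometry$n_cols), geometry$n_rows, geometry$n_cols,
                 byrow = TRUE)
  geometry$spacing *
    sqrt((rows - geometry$target_row)^2 + (cols - geometry$target_col)^2)
}

#' Table of all slots with their positions
#'
#' @param geometry A [grid_geometry()].
#' @return A tibble with one row per slot: `row`, `col`, `x_deg`, `y_deg`,
#'   `dist_deg` (distance to the target slot) and `is_target`.
#' @export
slot_table <- function(geometry = grid_geometry()) {
  grid <- expand.grid(row = seq_len(geometry$n_rows),
                      col = seq_len(geometry$n_cols))
  tibble::tibble(
    row = grid$row, col = grid$col,
    x_deg = geometry$fixation_offset + (grid$col - 1) * geometry$spacing,
    y_deg = (geometry$target_row - grid$row) * geometry$spacing,
    dist_deg = geometry$spacing * sqrt((grid$row - geometry$target_row)^2 +
                                         (grid$col - geometry$target_col)^2),
    is_target = grid$row == geometry$target_row &
      grid$col == geometry$target_col)
}
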