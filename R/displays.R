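#' Generate a dense display (binary flanker genome)
#'
#' A dense display is the GA genome: every non-target slot of the grid holds
#' either a vertical or a horizontal flanking bar, and the target slot holds
#' a bar tilted `tilt_magnitude` degrees left or right of vertical. Each of
#' the 284 flanker slots is drawn independently vertical with probability
#' `p_vertical` from the current RNG stream.
#'
#' @param p_vertical Probability that a flanker slot is vertical.
#' @param target_sign `+1` (right tilt), `-1` (left tilt), or `NULL` to draw
#'   a fair coin.
#' @param geometry A [grid_geometry()].
#' @return An object of class `dense_display`: a list with `geometry`,
#'   `vertical` (an `n_rows x n_cols` logical matrix, `NA` at the target
#'   slot) and `target_sign`.
#' @examples
#' set.seed(1)
#' d <- make_dense_display(0.3)
#' n_flanker_slots(d)        # 284
#' vertical_count(d) / 284   # about 0.3
#' @export
make_dense_display <- function(p_vertical, target_sign = NULL,
                               geometry = grid_geometry()) {
  if (!is.numeric(p_vertical) || length(p_vertical) != 1 ||
      is.na(p_vertical) || p_vertical < 0 || p_vertical > 1)
    stop("p_vertical must be a probability in [0, 1]", call. = FALSE)
  target_sign <- resolve_sign(target_sign)
  v <- matrix(stats::runif(geometry$n_rows * geometry$n_cols) < p_vertical,
              geometry$n_rows, geometry$n_cols)
  v[geometry$target_row, geometry$target_col] <- NA
  new_dense_display(geometry, v, target_sign)
}

new_dense_display <- function(geometry, vertical, target_sign) {
  structure(list(geometry = geometry, vertical = vertical,
                 target_sign = as.integer(target_sign)),
            class = "dense_display")
}

resolve_sign <- function(target_sign) {
  if (is.null(target_sign))
    return(if (stats::runif(1) < 0.5) 1L else -1L)
  if (!target_sign %in% c(-1, 1))
    stop("target_sign must be +1 or -1", call. = FALSE)
  as.integer(target_sign)
}

#' Generate a sparse display
#'
#' The classical Bouma's-law configuration: the target bar at its usual
#' 6 deg position, surrounded by exactly four flankers of a single
#' orientation class at the four cardinal offsets (`(+/-distance, 0)` and
#' `(0, +/-distance)` relative to the target).
#'
#' @param distance Centre-to-centre target-flanker distance in degrees
#'   (must be positive).
#' @param flanker_class `"vertical"` or `"horizontal"`.
#' @param target_sign `+1`, `-1`, or `NULL` for a fair coin.
#' @param geometry A [grid_geometry()] (target position and tilt are taken
#'   from it).
#' @return An object of class `sparse_display`.
#' @export
make_sparse_display <- function(distance, flanker_class = c("vertical", "horizontal"),
                                target_sign = NULL,
                                geometry = grid_geometry()) {
  if (!is.numeric(distance) || length(distance) != 1 || is.na(distance) ||
      distance <= 0)
    stop("distance must be a positive number of degrees", call. = FALSE)
  flanker_class <- match.arg(flanker_class)
  structure(list(geometry = geometry, distance = distance,
                 flanker_class = flanker_class,
                 n_flankers = 4L,
                 target_sign = resolve_sign(target_sign)),
            class = "sparse_display")
}

#' Generate an unflanked display (target alone)
#'
#' Baseline condition for the sparse-display measure: the target bar with
#' no flankers at all.
#'
#' @inheritParams make_sparse_display
#' @return An object of class `unflanked_display`.
#' @export
make_unflanked_display <- function(target_sign = NULL,
                                   geometry = grid_geometry()) {
  structure(list(geometry = geometry, target_sign = resolve_sign(target_sign)),
            class = "unflanked_display")
}

#' Number of flanker slots in a display
#' @param display A display object.
#' @export
n_flanker_slots <- function(display) {
  UseMethod("n_flanker_slots")
}

#' @export
n_flanker_slots.dense_display <- function(display) {
  sum(!is.na(display$vertical))
}

#' @export
n_flanker_slots.sparse_display <- function(display) display$n_flankers

#' @export
n_flanker_slots.unflanked_display <- function(display) 0L

#' Number of vertical flankers in a dense display
#' @param display A `dense_display`.
#' @export
vertical_count <- function(display) {
  stopifnot(inherits(display, "dense_display"))
  sum(display$vertical, na.rm = TRUE)
}

#' Element table of a display
#'
#' Flattens a display into one row per bar with its position relative to
#' fixation, its orientation (0 = vertical, positive clockwise, period
#' 180 deg) and its distance to the target. This is the representation the
#' observer models consume.
#'
#' @param display A display object.
#' @return A tibble with columns `x_deg`, `y_deg`, `orientation_deg`,
#'   `dist_deg`, `is_target` and (for dense displays) `row`, `col`.
#' @export
display_elements <- function(display) {
  UseMethod("display_elements")
}

#' @export
display_elements.dense_display <- function(display) {
  g <- display$geometry
  tab <- slot_table(g)
  v <- display$vertical[cbind(tab$row, tab$col)]
  tab$orientation_deg <- ifelse(tab$is_target,
                                display$target_sign * g$tilt_magnitude,
                                ifelse(v, 0, 90))
  tab
}

#' @export
display_elements.sparse_display <- function(display) {
  g <- display$geometry
  tpos <- slot_position(g$target_row, g$target_col, g)
  d <- display$distance
  ori <- if (display$flanker_class == "vertical") 0 else 90
  tibble::tibble(
    x_deg = tpos[["x"]] + c(0, d, 0, -d, 0),
    y_deg = tpos[["y"]] + c(0, 0, d, 0, -d),
    orientation_deg = c(display$target_sign * g$tilt_magnitude, rep(ori, 4)),
    dist_deg = c(0, rep(d, 4)),
    is_target = c(TRUE, rep(FALSE, 4)))
}

#' @export
display_elements.unflanked_display <- function(display) {
  g <- display$geometry
  tpos <- slot_position(g$target_row, g$target_col, g)
  tibble::tibble(x_deg = tpos[["x"]], y_deg = tpos[["y"]],
                 orientation_deg = display$target_sign * g$tilt_magnitude,
                 dist_deg = 0, is_target = TRUE)
}

#' @export
print.dense_display <- function(x, ...) {
  cat(sprintf("<dense_display> %d flankers (%d vertical), target tilt %+d x %g deg\n",
              n_flanker_slots(x), vertical_count(x), x$target_sign,
              x$geometry$tilt_magnitude))
  invisible(x)
}

#' @export
print.sparse_display <- function(x, ...) {
  cat(sprintf("<sparse_display> 4 %s flankers at %.3g deg, target tilt %+d x %g deg\n",
              x$flanker_class, x$distance, x$target_sign,
              x$geometry$tilt_magnitude))
  invisible(x)
}

#' @export
as.data.frame.dense_display <- function(x, ...) {
  tab <- display_elements(x)
  tab$class <- ifelse(tab$is_target, "target",
                      ifelse(tab$orientation_deg == 0, "vertical", "horizontal"))
  as.data.frame(tab[, c("row", "col", "x_deg", "y_deg", "class")])
}

## ---- text serialization -------------------------------------------------
## Format: one header line
##   crowdga-display rows=15 cols=19 spacing=0.75 offset=0.75
##     target=8,8 tilt=5 sign=+1
## then n_rows lines of n_cols characters from {V, H, T}.

#' Serialize a dense display to text
#'
#' Encodes the genome as a header line followed by an `n_rows`-line block of
#' `V`/`H`/`T` characters (target slot = `T`). [parse_display()] inverts it
#' exactly for every genome.
#'
#' @param display A `dense_display`.
#' @return Character vector of lines.
#' @seealso [write_display()], [parse_display()]
#' @export
format_display <- function(display) {
  stopifnot(inherits(display, "dense_display"))
  g <- display$geometry
  header <- sprintf(
    "crowdga-display rows=%d cols=%d spacing=%.17g offset=%.17g target=%d,%d tilt=%.17g sign=%+d",
    g$n_rows, g$n_cols, g$spacing, g$fixation_offset,
    g$target_row, g$target_col, g$tilt_magnitude, display$target_sign)
  chars <- ifelse(is.na(display$vertical), "T",
                  ifelse(display$vertical, "V", "H"))
  c(header, apply(chars, 1, paste0, collapse = ""))
}

#' Parse a dense display from its text form
#'
#' @param lines Character vector as produced by [format_display()].
#' @return A `dense_display`.
#' @export
parse_display <- function(lines) {
  if (length(lines) < 2 || !startsWith(lines[[1]], "crowdga-display"))
    stop("not a crowdga display record (missing header line)", call. = FALSE)
  fields <- parse_header_fields(lines[[1]])
  tg <- as.integer(strsplit(fields[["target"]], ",")[[1]])
  g <- grid_geometry(n_rows = as.integer(fields[["rows"]]),
                     n_cols = as.integer(fields[["cols"]]),
                     spacing = as.numeric(fields[["spacing"]]),
                     fixation_offset = as.numeric(fields[["offset"]]),
                     target_row = tg[1], target_col = tg[2],
                     tilt_magnitude = as.numeric(fields[["tilt"]]))
  body <- lines[-1]
  if (length(body) != g$n_rows)
    stop(sprintf("expected %d grid rows, found %d", g$n_rows, length(body)),
         call. = FALSE)
  v <- matrix(NA, g$n_rows, g$n_cols)
  for (r in seq_len(g$n_rows)) {
    row_chars <- strsplit(body[[r]], "")[[1]]
    if (length(row_chars) != g$n_cols)
      stop(sprintf("row %d: expected %d columns, found %d",
                   r, g$n_cols, length(row_chars)), call. = FALSE)
    bad <- which(!row_chars %in% c("V", "H", "T"))
    if (length(bad))
      stop(sprintf("row %d, column %d: invalid character '%s'",
                   r, bad[1], row_chars[bad[1]]), call. = FALSE)
    tpos <- which(row_chars == "T")
    if (r == g$target_row) {
      if (!identical(tpos, as.integer(g$target_col)))
        stop(sprintf("row %d: target marker misplaced", r), call. = FALSE)
    } else if (length(tpos)) {
      stop(sprintf("row %d, column %d: unexpected target marker", r, tpos[1]),
           call. = FALSE)
    }
    v[r, ] <- row_chars == "V"
  }
  v[g$target_row, g$target_col] <- NA
  new_dense_display(g, v, as.integer(fields[["sign"]]))
}

parse_header_fields <- function(header) {
  toks <- strsplit(header, "[[:space:]]+")[[1]][-1]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Read or write a dense display as a text file
#'
#' @param display A `dense_display`.
#' @param path File path.
#' @return `write_display()` returns `path` invisibly; `read_display()`
#'   returns the display.
#' @export
write_display <- function(display, path) {
  writeLines(format_display(display), path)
  invisible(path)
}

#' @rdname write_display
#' @export
read_display <- function(path) {
  parse_display(readLines(path))
}

#' JSON round-trip for dense displays
#'
#' Same fields as the text format, as a JSON object (`genome` holds the
#' `V`/`H`/`T` row strings).
#'
#' @param display A `dense_display`.
#' @param json A JSON string as produced by `display_to_json()`.
#' @export
display_to_json <- function(display) {
  lines <- format_display(display)
  g <- display$geometry
  jsonlite::toJSON(list(
    format = "crowdga-display", n_rows = g$n_rows, n_cols = g$n_cols,
    spacing = g$spacing, fixation_offset = g$fixation_offset,
    target_row = g$target_row, target_col = g$target_col,
    tilt_magnitude = g$tilt_magnitude, target_sign = display$target_sign,
    genome = lines[-1]), auto_unbox = TRUE, digits = NA)
}

#' @rdname display_to_json
#' @export
display_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  g <- grid_geometry(obj$n_rows, obj$n_cols, obj$spacing,
                     obj$fixation_offset, obj$target_row, obj$target_col,
                     obj$tilt_magnitude)
  header <- sprintf(
    "crowdga-display rows=%d cols=%d spacing=%.17g offset=%.17g target=%d,%d tilt=%.17g sign=%+d",
    g$n_rows, g$n_cols, g$spacing, g$fixation_offset,
    g$target_row, g$target_col, g$tilt_magnitude, as.integer(obj$target_sign))
  parse_display(c(header, obj$genome))
}

#' Export the slot table of a display to CSV
#'
#' One row per slot: `row`, `col`, `x_deg`, `y_deg`, `class`.
#'
#' @param display A `dense_display`.
#' @param path Output CSV path.
#' @export
write_display_csv <- function(display, path) {
  utils::write.csv(as.data.frame(display), path, row.names = FALSE)
  invisible(path)
}
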