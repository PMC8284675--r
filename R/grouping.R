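#' Perceptual grouping of display elements
#'
#' Elements on the regular grid are parsed into perceptual groups by
#' collinear same-class linking: two bars are linked iff they are nearest
#' neighbours along their shared orientation axis and have the same
#' orientation class - vertical bars stacked in a column link vertically,
#' horizontal bars adjacent within a row link horizontally. The slightly
#' tilted (+/-5 deg) target counts as vertical-class. Groups are the
#' connected components of this link graph. Grouping is deterministic; all
#' stochasticity in the two-stage observer lives in its interference stage.
#'
#' For a sparse display the same rule applies to the five bars: vertical
#' flankers directly above/below the target are its nearest neighbours
#' along the vertical axis and join its group; horizontal flankers never
#' link to the vertical-class target, and no other element lies along their
#' own axis, so they remain singletons.
#'
#' @param display A `dense_display`, `sparse_display` or
#'   `unflanked_display`.
#' @return For dense displays an `n_rows x n_cols` integer matrix of group
#'   ids covering all 285 slots; for sparse displays an integer vector of
#'   length 5 (target first, then the flankers at +x, +y, -x, -y); for
#'   unflanked displays the scalar 1.
#' @examples
#' d <- make_dense_display(1, target_sign = 1)  # all flankers vertical
#' m <- group_components(d)
#' sum(m == m[8, 8])  # the whole 8th column groups with the target: 15
#' @export
group_components <- function(display) {
  UseMethod("group_components")
}

#' @export
group_components.dense_display <- function(display) {
  g <- display$geometry
  nr <- g$n_rows; nc <- g$n_cols
  v <- display$vertical
  v[g$target_row, g$target_col] <- TRUE  # target is vertical-class
  id <- matrix(seq_len(nr * nc), nr, nc)
  # vertical links: same column, adjacent rows, both vertical-class
  vlink <- v[-nr, ] & v[-1, ]
  e_v <- cbind(id[-nr, ][vlink], id[-1, ][vlink])
  # horizontal links: same row, adjacent columns, both horizontal-class
  h <- !v
  hlink <- h[, -nc] & h[, -1]
  e_h <- cbind(id[, -nc][hlink], id[, -1][hlink])
  graph <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  edges <- rbind(e_v, e_h)
  if (nrow(edges))
    graph <- igraph::add_edges(graph, t(edges))
  matrix(igraph::components(graph)$membership, nr, nc)
}

#' @export
group_components.sparse_display <- function(display) {
  # elements ordered as in display_elements(): target, +x, +y, -x, -y
  if (display$flanker_class == "vertical") {
    # flankers above/below the target share its group
    c(1L, 2L, 1L, 3L, 1L)
  } else {
    c(1L, 2L, 3L, 4L, 5L)
  }
}

#' @export
group_components.unflanked_display <- function(display) 1L

#' Flanker slots belonging to the target's perceptual group
#'
#' For a dense display, the target's group is the contiguous run of
#' vertical flankers in the target column (vertical bars only link
#' vertically, so the component containing the vertical-class target cannot
#' leave its column). This closed form is what the two-stage observer uses
#' internally; it agrees exactly with [group_components()].
#'
#' @param display A `dense_display`.
#' @return Logical `n_rows x n_cols` matrix, `TRUE` for flanker slots in
#'   the target's group (the target slot itself is `FALSE`).
#' @export
target_group <- function(display) {
  stopifnot(inherits(display, "dense_display"))
  g <- display$geometry
  v <- display$vertical
  out <- matrix(FALSE, g$n_rows, g$n_cols)
  r <- g$target_row - 1L
  while (r >= 1 && isTRUE(v[r, g$target_col])) {
    out[r, g$target_col] <- TRUE
    r <- r - 1L
  }
  r <- g$target_row + 1L
  while (r <= g$n_rows && isTRUE(v[r, g$target_col])) {
    out[r, g$target_col] <- TRUE
    r <- r + 1L
  }
  out
}

# Per-flanker interference gain for the two-stage observer: 1 inside the
# target's group, out_group_gain outside. Shape matches what the
# interference computations expect (matrix for dense, length-4 vector for
# sparse in +x, +y, -x, -y order).
group_gains <- function(display, out_group_gain) {
  if (inherits(display, "unflanked_display")) return(NULL)
  if (inherits(display, "dense_display")) {
    gains <- matrix(out_group_gain, display$geometry$n_rows,
                    display$geometry$n_cols)
    gains[target_group(display)] <- 1
    return(gains)
  }
  if (display$flanker_class == "vertical")
    c(out_group_gain, 1, out_group_gain, 1)
  else
    rep(out_group_gain, 4)
}
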