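#' Square arena geometry
#'
#' Defines the square virtual environment in which all navigation takes
#' place. Walls lie at coordinate 0 and `side_length` on each axis, so a
#' position's distance to the nearer wall along one axis is
#' `min(c, side_length - c)`.
#'
#' @param side_length Side of the square arena in virtual meters (vm).
#'   Defaults to 160 vm.
#' @return An object of class `arena`.
#' @examples
#' a <- arena()
#' two_wall_distance_sum(c(33, 16), a)  # 49
#' @export
arena <- function(side_length = 160) {
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0) {
    stop("`side_length` must be a single positive number", call. = FALSE)
  }
  structure(list(side_length = as.numeric(side_length)), class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> square, side %g vm (walls at 0 and %g on each axis)\n",
              x$side_length, x$side_length))
  invisible(x)
}

#' Default target-object registry
#'
#' The three target objects and their positions in the 160-vm arena. The
#' trash bin sits closest to the walls (summed two-wall distance 49 vm),
#' followed by the plant (96 vm) and the ball (102 vm).
#'
#' @return A data frame with columns `name`, `x`, `y`.
#' @export
default_targets <- function() {
  data.frame(
    name = c("trash_bin", "plant", "ball"),
    x = c(33, 27, 64),
    y = c(16, 69, 38),
    stringsAsFactors = FALSE
  )
}

# Normalise a position argument to an n x 2 numeric matrix and reject
# coordinates outside [0, L] (walls themselves are legal, distance 0).
as_position_matrix <- function(p, arena, what = "position") {
  if (is.data.frame(p)) {
    stopifnot(all(c("x", "y") %in% names(p)))
    p <- cbind(p$x, p$y)
  } else if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) != 2L) {
      stop("a single position must be a length-2 numeric (x, y)", call. = FALSE)
    }
    p <- matrix(p, ncol = 2L)
  } else {
    p <- as.matrix(p)
  }
  if (ncol(p) != 2L) stop("positions must have two columns (x, y)", call. = FALSE)
  storage.mode(p) <- "double"
  L <- arena$side_length
  for (ax in 1:2) {
    bad <- which(!is.finite(p[, ax]) | p[, ax] < 0 | p[, ax] > L)
    if (length(bad)) {
      stop(sprintf(
        "%s outside arena: %s = %.6g at row %d (must lie in [0, %g])",
        what, c("x", "y")[ax], p[bad[1L], ax], bad[1L], L
      ), call. = FALSE)
    }
  }
  p
}

#' Distance to the nearer wall along one axis
#'
#' For axis coordinate `c` in an arena of side `L`, the distance to the
#' nearer of the two walls perpendicular to that axis is `min(c, L - c)`.
#'
#' @param p A position: length-2 numeric `c(x, y)`, an n x 2 matrix, or a
#'   data frame with `x` and `y` columns.
#' @param arena An [arena()].
#' @param axis `"x"` or `"y"`.
#' @return Numeric vector of distances in vm, in `[0, side_length / 2]`.
#' @export
axis_wall_distance <- function(p, arena = boundnav::arena(), axis = c("x", "y")) {
  axis <- match.arg(axis)
  p <- as_position_matrix(p, arena)
  cc <- p[, if (axis == "x") 1L else 2L]
  pmin(cc, arena$side_length - cc)
}

#' Summed distance to the two closest walls
#'
#' The per-axis nearer-wall distances added over x and y. This is the
#' boundary-distance convention used both for target placement and for the
#' BOLD parametric modulator: for the default targets it evaluates to 49 vm
#' (trash bin), 96 vm (plant) and 102 vm (ball).
#'
#' @inheritParams axis_wall_distance
#' @return Numeric vector in `[0, side_length]`; maximal at the arena center.
#' @export
two_wall_distance_sum <- function(p, arena = boundnav::arena()) {
  p <- as_position_matrix(p, arena)
  L <- arena$side_length
  pmin(p[, 1L], L - p[, 1L]) + pmin(p[, 2L], L - p[, 2L])
}

#' Distance to the single closest wall
#'
#' Minimum over both axes of the per-axis nearer-wall distance; the
#' robustness variant of the boundary-distance measure.
#'
#' @inheritParams axis_wall_distance
#' @return Numeric vector in `[0, side_length / 2]`.
#' @export
nearest_wall_distance <- function(p, arena = boundnav::arena()) {
  p <- as_position_matrix(p, arena)
  L <- arena$side_length
  pmin(p[, 1L], L - p[, 1L], p[, 2L], L - p[, 2L])
}
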