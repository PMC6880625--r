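# Screen geometry and cursor trajectories.

#' Screen geometry for the mouse-movement condition
#'
#' Normalized, centered coordinates: x and y in [-1, 1], origin at the screen
#' center, y increasing upward. The cursor starts at the bottom center
#' (0, -0.8); the two response buttons sit mirror-symmetrically near the top.
#'
#' @param start Cursor start position `c(x, y)`.
#' @param button_left,button_right Button centers `c(x, y)`.
#' @param button_radius Click radius in screen units.
#' @return An object of class `sst_geometry`.
#' @export
sst_geometry <- function(start = c(0, -0.8),
                         button_left = c(-0.6, 0.7),
                         button_right = c(0.6, 0.7),
                         button_radius = 0.12) {
  stopifnot(length(start) == 2L, length(button_left) == 2L,
            length(button_right) == 2L, button_radius > 0)
  if (start[2] >= button_left[2] || start[2] >= button_right[2]) {
    stop("buttons must lie above the start position", call. = FALSE)
  }
  structure(list(start = as.numeric(start),
                 button_left = as.numeric(button_left),
                 button_right = as.numeric(button_right),
                 button_radius = as.numeric(button_radius)),
            class = "sst_geometry")
}

#' Construct a cursor trajectory
#'
#' A trajectory is an ordered sequence of timestamped cursor positions for one
#' trial, with times in ms from stimulus onset.
#'
#' @param t_ms Strictly increasing sample times (ms from onset).
#' @param x,y Cursor coordinates (normalized screen units).
#' @param sample_interval_ms Nominal recording interval (default 16 ms).
#' @return An object of class `sst_trajectory` with fields `t_ms`, `x`, `y`.
#' @export
trajectory <- function(t_ms, x, y, sample_interval_ms = 16) {
  t_ms <- as.numeric(t_ms); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t_ms)
  if (length(x) != n || length(y) != n) {
    stop("t_ms, x and y must have equal length", call. = FALSE)
  }
  if (n > 0 && (any(!is.finite(t_ms)) || any(!is.finite(x)) || any(!is.finite(y)))) {
    stop("trajectory samples must be finite", call. = FALSE)
  }
  if (n > 1 && any(diff(t_ms) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  if (n > 0 && t_ms[1] < 0) {
    stop("trajectory must start at or after stimulus onset", call. = FALSE)
  }
  structure(list(t_ms = t_ms, x = x, y = y,
                 sample_interval_ms = sample_interval_ms),
            class = "sst_trajectory")
}

#' Coerce to a trajectory
#'
#' Accepts an `sst_trajectory`, or a data frame with columns `t_ms`, `x`, `y`.
#'
#' @param x Object to coerce.
#' @return An `sst_trajectory`.
#' @export
as_trajectory <- function(x) {
  if (inherits(x, "sst_trajectory")) return(x)
  if (is.data.frame(x) && all(c("t_ms", "x", "y") %in% names(x))) {
    return(trajectory(x$t_ms, x$x, x$y))
  }
  stop("cannot coerce to trajectory", call. = FALSE)
}

#' @export
print.sst_trajectory <- function(x, ...) {
  n <- length(x$t_ms)
  cat(sprintf("Cursor trajectory: %d samples", n))
  if (n > 0) cat(sprintf(", t in [%g, %g] ms", x$t_ms[1], x$t_ms[n]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sst_trajectory <- function(x, ...) {
  data.frame(t_ms = x$t_ms, x = x$x, y = x$y)
}

#' @export
plot.sst_trajectory <- function(x, ..., geometry = NULL) {
  plot(x$x, x$y, type = "l", xlab = "x (screen units)", ylab = "y (screen units)",
       xlim = c(-1, 1), ylim = c(-1, 1), ...)
  points(x$x[1], x$y[1], pch = 16)
  if (!is.null(geometry)) {
    symbols(c(geometry$button_left[1], geometry$button_right[1]),
            c(geometry$button_left[2], geometry$button_right[2]),
            circles = rep(geometry$button_radius, 2), inches = FALSE, add = TRUE)
  }
  invisible(x)
}
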