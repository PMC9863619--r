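#' @keywords internal
#' @useDynLib pulseroi, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Shared validation and small numeric helpers.

stop_pulseroi <- function(...) stop(..., call. = FALSE)

check_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop_pulseroi(arg, " must be a numeric matrix of intensities")
  if (nrow(frame) < 2L || ncol(frame) < 2L)
    stop_pulseroi(arg, " must be at least 2x2")
  if (!all(is.finite(frame)))
    stop_pulseroi(arg, " contains non-finite intensities")
  invisible(frame)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop_pulseroi(arg, " must be a matrix")
  if (is.logical(mask)) return(invisible(mask))
  if (is.numeric(mask) && all(mask %in% c(0, 1)))
    return(invisible(mask > 0))
  stop_pulseroi(arg, " must be a logical (or 0/1) matrix")
}

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  m <- x > 0.5
  storage.mode(m) <- "logical"
  m
}

## Euclidean disk structuring element: offsets with dx^2 + dy^2 <= r^2.
## EBImage's small "disc" brushes degenerate to boxes, so the kernel is
## constructed explicitly.
disc_kernel <- function(radius) {
  stopifnot(radius >= 0)
  r <- as.integer(radius)
  d <- 2L * r + 1L
  off <- seq(-r, r)
  k <- outer(off^2, off^2, "+") <= radius^2
  matrix(as.integer(k), d, d)
}

## Centered moving average with edge replication, window odd >= 1.
moving_average <- function(x, window) {
  if (window %% 2L != 1L || window < 1L)
    stop_pulseroi("smooth_window must be an odd integer >= 1")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2L))[(h + 1L):(h + n)]
}
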