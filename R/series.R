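## Region-size time series and contraction statistics.
##
## The per-frame mask is reduced to a single number — the percentage of
## frame pixels it covers, a proxy of the organ size — and the resulting
## series is scanned for alternating relaxation maxima and contraction
## minima, from which per-event intensities and a per-ejaculate summary
## (intensity aggregate + events per minute) are computed.

#' Pixel fraction of a mask
#'
#' @param mask Logical mask matrix.
#' @return Percent of frame pixels covered: `100 * pixel_count / (h * w)`.
#' @export
region_fraction <- function(mask) {
  mask <- check_mask(mask)
  100 * sum(mask) / length(mask)
}

#' Build a region-size time series from masks
#'
#' @param masks List of logical masks of a common shape, in frame order.
#' @param fps Frames per second used to derive timestamps (ignored if
#'   `timestamps` is given).
#' @param timestamps Optional explicit per-frame timestamps in seconds.
#' @return Data frame with columns `frame` (1-based index), `timestamp`
#'   (seconds) and `fraction` (percent).
#' @export
build_series <- function(masks, fps = 30, timestamps = NULL) {
  n <- length(masks)
  if (n == 0L)
    return(data.frame(frame = integer(0), timestamp = numeric(0),
                      fraction = numeric(0)))
  dm <- dim(masks[[1L]])
  frac <- vapply(seq_len(n), function(i) {
    m <- check_mask(masks[[i]], sprintf("masks[[%d]]", i))
    if (!identical(dim(m), dm))
      stop_pulseroi("mask ", i, " has shape ",
                    paste(dim(m), collapse = "x"),
                    " but mask 1 has ", paste(dm, collapse = "x"))
    region_fraction(m)
  }, 0)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1L) / fps
  if (length(timestamps) != n || is.unsorted(timestamps, strictly = TRUE))
    stop_pulseroi("timestamps must be strictly increasing, one per mask")
  data.frame(frame = seq_len(n), timestamp = timestamps, fraction = frac)
}

## Local maxima of x (plateau-aware: first index of each plateau that is
## higher than both flanking runs), with topographic prominence.
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_peak <- c(FALSE, r$values[2:(k - 1L)] > r$values[1:(k - 2L)] &
                 r$values[2:(k - 1L)] > r$values[3:k], FALSE)
  starts[is_peak]
}

## Topographic prominence; a side with no strictly higher value imposes no
## constraint, so peaks tied with the global maximum measure their height
## above the global minimum.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    v <- x[i]
    hi_l <- which(x[seq_len(i - 1L)] > v)
    base_l <- if (length(hi_l)) min(x[(max(hi_l) + 1L):(i - 1L)]) else -Inf
    hi_r <- which(x[seq(i + 1L, length(x))] > v)
    base_r <- if (length(hi_r)) min(x[(i + 1L):(i + min(hi_r) - 1L)]) else -Inf
    base <- max(base_l, base_r)
    if (is.infinite(base)) base <- min(x)
    v - base
  }, 0)
}

#' Detect alternating relaxation/contraction frame pairs
#'
#' Smooths the size series with a centered moving average, finds local
#' maxima (relaxation) and minima (contraction) with topographic prominence
#' at least `min_prominence`, enforces strict alternation (keeping the more
#' extreme of consecutive same-type extrema), and pairs each maximum with
#' the following minimum. Returned indices refer to the unsmoothed series:
#' each extremum is moved to the most extreme raw value within half a
#' window of the smoothed location.
#'
#' @param series Data frame from [build_series()], or a numeric vector of
#'   fractions.
#' @param smooth_window Odd moving-average window length in frames.
#' @param min_prominence Minimum prominence in percent units; `NULL` uses
#'   10% of the series range.
#' @return Data frame with columns `relax_frame` and `contract_frame`
#'   (1-based frame indices); zero rows when no pulsation is detected.
#' @export
detect_extrema <- function(series, smooth_window = 5L, min_prominence = NULL) {
  x <- if (is.data.frame(series)) series$fraction else as.numeric(series)
  frames <- if (is.data.frame(series)) series$frame else seq_along(x)
  if (length(x) < smooth_window)
    stop_pulseroi("series length ", length(x),
                  " is shorter than smooth_window ", smooth_window)
  if (is.null(min_prominence)) min_prominence <- 0.1 * diff(range(x))
  if (min_prominence < 0) stop_pulseroi("min_prominence must be >= 0")
  empty <- data.frame(relax_frame = integer(0), contract_frame = integer(0))
  if (diff(range(x)) == 0) return(empty)

  xs <- moving_average(x, smooth_window)
  maxima <- local_maxima(xs)
  maxima <- maxima[peak_prominence(xs, maxima) >= min_prominence]
  minima <- local_maxima(-xs)
  minima <- minima[peak_prominence(-xs, minima) >= min_prominence]
  if (length(maxima) == 0L || length(minima) == 0L) return(empty)

  ext <- rbind(data.frame(i = maxima, type = 1L),
               data.frame(i = minima, type = -1L))
  ext <- ext[order(ext$i), ]
  ## collapse runs of same-type extrema to the most extreme one
  keep <- logical(nrow(ext))
  run_best <- 1L
  for (k in seq_len(nrow(ext))[-1L]) {
    if (ext$type[k] == ext$type[run_best]) {
      if (ext$type[k] * xs[ext$i[k]] > ext$type[k] * xs[ext$i[run_best]])
        run_best <- k
    } else {
      keep[run_best] <- TRUE
      run_best <- k
    }
  }
  keep[run_best] <- TRUE
  ext <- ext[keep, ]

  ## snap each smoothed extremum to the raw extremum within half a window
  h <- (smooth_window - 1L) %/% 2L
  snap <- function(i, type) {
    lo <- max(1L, i - h); hi <- min(length(x), i + h)
    lo - 1L + if (type > 0) which.max(x[lo:hi]) else which.min(x[lo:hi])
  }
  ext$i <- mapply(snap, ext$i, ext$type)

  pairs <- empty
  k <- 1L
  while (k < nrow(ext)) {
    if (ext$type[k] == 1L && ext$type[k + 1L] == -1L) {
      pairs <- rbind(pairs, data.frame(relax_frame = frames[ext$i[k]],
                                       contract_frame = frames[ext$i[k + 1L]]))
      k <- k + 2L
    } else k <- k + 1L
  }
  pairs
}

#' Contraction intensity of one event
#'
#' Percentage change in region size between the frame of full relaxation
#' and the frame of full contraction. `relative` mode expresses the change
#' relative to the relaxed size, `100 * (relax - contract) / relax`;
#' `absolute` mode returns the difference in percentage points of frame
#' area, `relax - contract`.
#'
#' @param size_relax,size_contract Region sizes in percent of frame area.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return Intensity in percent (vectorized over inputs).
#' @export
contraction_intensity <- function(size_relax, size_contract,
                                  mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (any(size_relax <= 0)) stop_pulseroi("size_relax must be > 0")
  if (any(size_contract < 0)) stop_pulseroi("size_contract must be >= 0")
  if (any(size_contract > size_relax))
    stop_pulseroi("size_contract exceeds size_relax: relaxation and ",
                  "contraction frames appear swapped")
  if (mode == "relative") 100 * (size_relax - size_contract) / size_relax
  else size_relax - size_contract
}

#' Contraction frequency
#'
#' @param n_events Number of contraction events.
#' @param total_time Total ejaculation time in minutes.
#' @return Events per minute.
#' @export
contraction_frequency <- function(n_events, total_time) {
  if (any(total_time <= 0)) stop_pulseroi("total_time must be > 0 minutes")
  n_events / total_time
}

#' Build contraction events from a series and frame pairs
#'
#' Pairs may come from [detect_extrema()] or from manual tags (mirroring a
#' hand-tagged workflow).
#'
#' @param series Data frame from [build_series()].
#' @param pairs Data frame with `relax_frame` and `contract_frame` columns,
#'   or a list of `c(relax, contract)` pairs.
#' @param mode Intensity mode, see [contraction_intensity()].
#' @return Data frame with `relax_frame`, `contract_frame`, `size_relax`,
#'   `size_contract`, `intensity`.
#' @export
events_from_pairs <- function(series, pairs, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p)
      data.frame(relax_frame = p[1L], contract_frame = p[2L])))
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(relax_frame = integer(0), contract_frame = integer(0),
                      size_relax = numeric(0), size_contract = numeric(0),
                      intensity = numeric(0)))
  at <- function(f) {
    j <- match(f, series$frame)
    if (anyNA(j)) stop_pulseroi("tagged frame ", f[which(is.na(j))[1L]],
                                " is not in the series")
    series$fraction[j]
  }
  sr <- at(pairs$relax_frame); sc <- at(pairs$contract_frame)
  data.frame(relax_frame = pairs$relax_frame,
             contract_frame = pairs$contract_frame,
             size_relax = sr, size_contract = sc,
             intensity = contraction_intensity(sr, sc, mode))
}

#' Summarize contraction events for one ejaculate
#'
#' @param events Data frame from [events_from_pairs()].
#' @param total_time Total ejaculation time in minutes.
#' @param aggregate How to aggregate per-event intensities: `"mean"`
#'   (default), `"median"` or `"max"`.
#' @param boar_id,ejaculate_id Optional identifiers carried into the record.
#' @return A list of class `ejaculation_record` with fields `boar_id`,
#'   `ejaculate_id`, `total_time`, `events`, `n_events`,
#'   `intensity_summary` (percent; 0 when there are no events) and
#'   `frequency` (events per minute).
#' @export
summarize_ejaculate <- function(events, total_time,
                                aggregate = c("mean", "median", "max"),
                                boar_id = NA_character_,
                                ejaculate_id = NA_character_) {
  aggregate <- match.arg(aggregate)
  if (total_time <= 0) stop_pulseroi("total_time must be > 0 minutes")
  agg_fun <- switch(aggregate, mean = mean, median = stats::median, max = max)
  summary <- if (nrow(events) == 0L) 0 else agg_fun(events$intensity)
  structure(
    list(boar_id = boar_id, ejaculate_id = ejaculate_id,
         total_time = total_time, events = events,
         n_events = nrow(events), intensity_summary = summary,
         aggregate = aggregate,
         frequency = contraction_frequency(nrow(events), total_time)),
    class = "ejaculation_record")
}

#' @export
print.ejaculation_record <- function(x, ...) {
  cat("Ejaculation record", if (!is.na(x$boar_id)) paste0("(", x$boar_id, ")"),
      "\n  events:", x$n_events,
      "\n  intensity (", x$aggregate, "): ",
      sprintf("%.2f%%", x$intensity_summary),
      "\n  frequency: ", sprintf("%.3f events/min", x$frequency),
      "\n  total time: ", sprintf("%.2f min", x$total_time), "\n", sep = "")
  invisible(x)
}
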