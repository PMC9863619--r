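## Scribble-seeded binary graph-cut segmentation.
##
## Energy over binary labelings L (TRUE = foreground):
##   E(L) = sum_p D_p(L_p)
##        + lambda_smooth * sum_{(p,q) adjacent} w_pq * [L_p != L_q]
## D_p is the negative log of a pseudocount-smoothed intensity-histogram
## likelihood built from the seed pixels of each class;
## w_pq = exp(-(I_p - I_q)^2 / (2 sigma_edge^2)).
## Seed pixels are hard-constrained. The global minimum is found exactly by
## a min s-t cut (igraph max_flow) on the standard two-terminal pixel graph.

#' Construct a scribble seed set
#'
#' @param foreground,background Two-column matrices of 1-based `(row, col)`
#'   pixel coordinates.
#' @return An object of class `scribble_set`.
#' @export
scribble_set <- function(foreground, background) {
  fg <- as.matrix(foreground); bg <- as.matrix(background)
  if (ncol(fg) != 2L || ncol(bg) != 2L)
    stop_pulseroi("scribbles must be two-column (row, col) matrices")
  if (nrow(fg) == 0L || nrow(bg) == 0L)
    stop_pulseroi("both foreground and background scribbles must be non-empty")
  storage.mode(fg) <- "integer"; storage.mode(bg) <- "integer"
  colnames(fg) <- colnames(bg) <- c("row", "col")
  structure(list(foreground = fg, background = bg), class = "scribble_set")
}

## Linear (column-major) pixel indices of the seeds; checks bounds and
## disjointness against a frame of dimensions dm = c(nrow, ncol).
seed_indices <- function(seeds, dm) {
  stopifnot(inherits(seeds, "scribble_set"))
  chk <- function(m, what) {
    if (any(m[, 1L] < 1L | m[, 1L] > dm[1L] | m[, 2L] < 1L | m[, 2L] > dm[2L]))
      stop_pulseroi(what, " scribble coordinates fall outside the frame")
    (m[, 2L] - 1L) * dm[1L] + m[, 1L]
  }
  fg <- unique(chk(seeds$foreground, "foreground"))
  bg <- unique(chk(seeds$background, "background"))
  if (length(intersect(fg, bg)) > 0L)
    stop_pulseroi("foreground and background scribbles overlap")
  list(fg = fg, bg = bg)
}

#' Graph-cut parameters
#'
#' @param lambda_smooth Non-negative weight of the smoothness term.
#' @param sigma_edge Contrast scale of the edge weights (intensity units);
#'   `NULL` self-calibrates to the standard deviation of neighbouring-pixel
#'   intensity differences of the frame being segmented.
#' @param hist_bins Number of histogram bins over `[0, 1]` for the data term.
#' @param hist_pseudocount Laplace pseudocount added to every bin.
#' @param connectivity Pixel neighbourhood, 4 or 8.
#' @return An object of class `graph_cut_params`.
#' @export
graph_cut_params <- function(lambda_smooth = 2, sigma_edge = NULL,
                             hist_bins = 32L, hist_pseudocount = 1,
                             connectivity = 4L) {
  if (lambda_smooth < 0) stop_pulseroi("lambda_smooth must be >= 0")
  if (!is.null(sigma_edge) && sigma_edge <= 0)
    stop_pulseroi("sigma_edge must be > 0")
  if (hist_bins < 2L) stop_pulseroi("hist_bins must be >= 2")
  if (hist_pseudocount <= 0) stop_pulseroi("hist_pseudocount must be > 0")
  if (!connectivity %in% c(4L, 8L)) stop_pulseroi("connectivity must be 4 or 8")
  structure(list(lambda_smooth = lambda_smooth, sigma_edge = sigma_edge,
                 hist_bins = as.integer(hist_bins),
                 hist_pseudocount = hist_pseudocount,
                 connectivity = as.integer(connectivity)),
            class = "graph_cut_params")
}

## Histogram bin of each intensity, clamped to [0,1] scale.
intensity_bins <- function(I, bins) {
  pmin(pmax(floor(pmin(pmax(I, 0), 1) * bins) + 1L, 1L), bins)
}

## Negative log-likelihood data terms from seed histograms. An empty seed
## class yields a uniform (pure-pseudocount) histogram.
hist_data_terms <- function(I, fg_idx, bg_idx, bins, pc) {
  bin <- intensity_bins(I, bins)
  nll <- function(idx) {
    counts <- tabulate(bin[idx], nbins = bins)
    p <- (counts + pc) / (length(idx) + pc * bins)
    -log(p)[bin]
  }
  list(D_fg = nll(fg_idx), D_bg = nll(bg_idx))
}

## Adjacent pixel pairs (p < q in column-major order) and their contrast
## weights w_pq for a frame, as parallel vectors.
neighbor_edges <- function(I, connectivity, sigma_edge = NULL) {
  h <- nrow(I); w <- ncol(I)
  id <- matrix(seq_len(h * w), h, w)
  p <- c(id[-h, ], id[, -w])
  q <- c(id[-1L, ], id[, -1L])
  if (connectivity == 8L) {
    p <- c(p, id[-h, -w], id[-1L, -w])
    q <- c(q, id[-1L, -1L], id[-h, -1L])
  }
  d <- I[q] - I[p]
  if (is.null(sigma_edge)) {
    sigma_edge <- stats::sd(d)
    if (!is.finite(sigma_edge) || sigma_edge <= 0) sigma_edge <- 0.1
  }
  list(p = p, q = q, w = exp(-d^2 / (2 * sigma_edge^2)),
       sigma_edge = sigma_edge)
}

#' Segment a frame by scribble-seeded graph cut
#'
#' Finds the global minimum of the segmentation energy (histogram data term
#' plus contrast-weighted boundary term, scribbles hard-constrained) via a
#' minimum s-t cut. Ties between equal-energy labelings are broken towards
#' background at unseeded pixels.
#'
#' @param frame Numeric intensity matrix in `[0, 1]`.
#' @param seeds A [scribble_set()] valid for the frame.
#' @param params A [graph_cut_params()].
#' @return Logical mask matrix, `TRUE` = foreground.
#' @export
segment_graph_cut <- function(frame, seeds, params = graph_cut_params()) {
  check_frame(frame)
  stopifnot(inherits(params, "graph_cut_params"))
  idx <- seed_indices(seeds, dim(frame))
  n <- length(frame)

  D <- hist_data_terms(frame, idx$fg, idx$bg,
                       params$hist_bins, params$hist_pseudocount)
  ne <- neighbor_edges(frame, params$connectivity, params$sigma_edge)
  wsm <- params$lambda_smooth * ne$w

  ## background-preferring infinitesimal tie-break at unseeded pixels
  D_fg <- D$D_fg; D_bg <- D$D_bg
  unseeded <- setdiff(seq_len(n), c(idx$fg, idx$bg))
  D_fg[unseeded] <- D_fg[unseeded] + 1e-9

  ## hard seeds: terminal capacity exceeding every possible finite cut
  K <- 1 + sum(wsm) + sum(pmax(D_fg, 0)) + sum(pmax(D_bg, 0))
  cap_s <- D_bg  # cut when pixel labeled background
  cap_t <- D_fg  # cut when pixel labeled foreground
  cap_s[idx$fg] <- K
  cap_t[idx$bg] <- K

  src <- n + 1L; snk <- n + 2L
  from <- c(rep(src, n), seq_len(n), ne$p)
  to <- c(seq_len(n), rep(snk, n), ne$q)
  cap <- c(cap_s, cap_t, wsm)
  rev_cap <- c(numeric(n), numeric(n), wsm)  # n-links are symmetric
  mf <- .mincut_dinic(n + 2L, from, to, cap, rev_cap, src, snk)
  fg_side <- mf$source_side

  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  mask[fg_side[fg_side <= n]] <- TRUE
  mask
}

#' Energy of a labeling under the graph-cut model
#'
#' Companion to [segment_graph_cut()]: evaluates the same energy for an
#' arbitrary labeling (without the tie-break bias). A labeling that
#' contradicts a seed has infinite energy.
#'
#' @param frame Numeric intensity matrix.
#' @param labeling Logical mask of the same shape.
#' @param seeds A [scribble_set()].
#' @param params A [graph_cut_params()].
#' @return The scalar energy, or `Inf` if the labeling violates a seed.
#' @export
segmentation_energy <- function(frame, labeling, seeds,
                                params = graph_cut_params()) {
  check_frame(frame)
  labeling <- check_mask(labeling, "labeling")
  if (!identical(dim(frame), dim(labeling)))
    stop_pulseroi("labeling shape ", paste(dim(labeling), collapse = "x"),
                  " does not match frame shape ",
                  paste(dim(frame), collapse = "x"))
  idx <- seed_indices(seeds, dim(frame))
  if (any(!labeling[idx$fg]) || any(labeling[idx$bg])) return(Inf)

  D <- hist_data_terms(frame, idx$fg, idx$bg,
                       params$hist_bins, params$hist_pseudocount)
  ne <- neighbor_edges(frame, params$connectivity, params$sigma_edge)
  sum(ifelse(labeling, D$D_fg, D$D_bg)) +
    params$lambda_smooth * sum(ne$w[labeling[ne$p] != labeling[ne$q]])
}
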