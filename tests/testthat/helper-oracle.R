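# Independent brute-force oracle for the graph-cut energy: enumerates every
# labeling of the unseeded pixels and evaluates the energy with its own
# (vectorized) implementation of the histogram data term and contrast
# smoothness term.

oracle_exhaustive <- function(I, fg_rc, bg_rc, lambda, sigma, bins, pc) {
  h <- nrow(I); w <- ncol(I); n <- h * w
  fg_idx <- (fg_rc[, 2L] - 1L) * h + fg_rc[, 1L]
  bg_idx <- (bg_rc[, 2L] - 1L) * h + bg_rc[, 1L]

  bin <- pmin(pmax(floor(pmin(pmax(I, 0), 1) * bins) + 1L, 1L), bins)
  nll <- function(idx) {
    counts <- tabulate(bin[idx], nbins = bins)
    p <- (counts + pc) / (length(idx) + pc * bins)
    -log(p)[bin]
  }
  D_fg <- as.vector(nll(fg_idx)); D_bg <- as.vector(nll(bg_idx))

  id <- matrix(seq_len(n), h, w)
  ep <- c(id[-h, ], id[, -w]); eq <- c(id[-1L, ], id[, -1L])
  wpq <- exp(-(I[eq] - I[ep])^2 / (2 * sigma^2))

  free <- setdiff(seq_len(n), c(fg_idx, bg_idx))
  nf <- length(free)
  vals <- 0:(2^nf - 1)
  L <- matrix(0, length(vals), n)
  L[, fg_idx] <- 1
  if (nf > 0)
    L[, free] <- outer(vals, 0:(nf - 1), function(v, k)
      bitwAnd(bitwShiftR(v, k), 1L))

  e_data <- L %*% D_fg + (1 - L) %*% D_bg
  e_smooth <- abs(L[, ep, drop = FALSE] - L[, eq, drop = FALSE]) %*% wpq
  e <- as.vector(e_data + lambda * e_smooth)
  best <- which.min(e)
  list(min_energy = e[best],
       argmin = matrix(L[best, ] > 0, h, w),
       energies = e)
}

random_cut_instance <- function(seed, h = 4L, w = 5L, n_fg = 2L, n_bg = 2L) {
  withr::with_seed(seed, {
    I <- matrix(stats::runif(h * w), h, w)
    cells <- sample(h * w, n_fg + n_bg)
    rc <- cbind((cells - 1L) %% h + 1L, (cells - 1L) %/% h + 1L)
    list(I = I,
         seeds = scribble_set(rc[seq_len(n_fg), , drop = FALSE],
                              rc[n_fg + seq_len(n_bg), , drop = FALSE]),
         params = graph_cut_params(
           lambda_smooth = sample(c(0.5, 1, 2), 1L),
           sigma_edge = 0.2,
           hist_bins = sample(c(2L, 4L, 8L), 1L),
           hist_pseudocount = 1))
  })
}

iou <- function(a, b) sum(a & b) / sum(a | b)
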