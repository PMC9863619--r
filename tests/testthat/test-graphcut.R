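# Graph-cut segmentation: hard seeds, exact optimality, energy accounting.

test_that("seeded pixels always carry their seeded label", {
  for (s in 1:20) {
    inst <- random_cut_instance(s, h = 6L, w = 6L, n_fg = 3L, n_bg = 3L)
    m <- segment_graph_cut(inst$I, inst$seeds, inst$params)
    expect_true(all(m[inst$seeds$foreground]))
    expect_false(any(m[inst$seeds$background]))
  }
})

test_that("two-region image is cut along the contrast boundary optimally", {
  I <- cbind(matrix(1, 4, 2), matrix(0, 4, 2))
  seeds <- scribble_set(foreground = rbind(c(1, 1)),
                        background = rbind(c(1, 4)))
  params <- graph_cut_params(lambda_smooth = 1, sigma_edge = 0.2,
                             hist_bins = 2L)
  m <- segment_graph_cut(I, seeds, params)
  expect_identical(m, cbind(matrix(TRUE, 4, 2), matrix(FALSE, 4, 2)))
  oracle <- oracle_exhaustive(I, seeds$foreground, seeds$background,
                              lambda = 1, sigma = 0.2, bins = 2L, pc = 1)
  expect_equal(segmentation_energy(I, m, seeds, params), oracle$min_energy,
               tolerance = 1e-10)
})

test_that("a fully seeded frame reproduces the seeds exactly", {
  I <- matrix(runif(12, 0.4, 0.6), 3, 4)
  all_px <- as.matrix(expand.grid(row = 1:3, col = 1:4))
  bg <- rbind(c(2, 2))
  fg <- all_px[!(all_px[, 1] == 2 & all_px[, 2] == 2), ]
  m <- segment_graph_cut(I, scribble_set(fg, bg), graph_cut_params())
  expect_identical(sum(!m), 1L)
  expect_false(m[2, 2])
})

test_that("solver energy equals the exhaustive minimum on random instances", {
  for (s in 1:10) {
    inst <- random_cut_instance(s)
    m <- segment_graph_cut(inst$I, inst$seeds, inst$params)
    oracle <- oracle_exhaustive(inst$I, inst$seeds$foreground,
                                inst$seeds$background,
                                inst$params$lambda_smooth,
                                inst$params$sigma_edge,
                                inst$params$hist_bins,
                                inst$params$hist_pseudocount)
    e <- segmentation_energy(inst$I, m, inst$seeds, inst$params)
    expect_equal(e, oracle$min_energy, tolerance = 1e-9)
  }
})

test_that("min-cut value agrees with an independent igraph max-flow", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    inst <- random_cut_instance(s, h = 5L, w = 5L)
    m <- segment_graph_cut(inst$I, inst$seeds, inst$params)
    # rebuild the same two-terminal graph and cut it with igraph
    I <- inst$I; n <- length(I)
    idx <- pulseroi:::seed_indices(inst$seeds, dim(I))
    D <- pulseroi:::hist_data_terms(I, idx$fg, idx$bg,
                                    inst$params$hist_bins,
                                    inst$params$hist_pseudocount)
    ne <- pulseroi:::neighbor_edges(I, 4L, inst$params$sigma_edge)
    lam <- inst$params$lambda_smooth
    K <- 1 + sum(lam * ne$w) + sum(D$D_fg) + sum(D$D_bg)
    cap_s <- D$D_bg; cap_t <- D$D_fg
    cap_s[idx$fg] <- K; cap_t[idx$bg] <- K
    edges <- rbind(cbind(n + 1L, seq_len(n)), cbind(seq_len(n), n + 2L),
                   cbind(ne$p, ne$q), cbind(ne$q, ne$p))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    mf <- igraph::max_flow(g, n + 1L, n + 2L,
                           capacity = c(cap_s, cap_t, lam * ne$w, lam * ne$w))
    e_ours <- segmentation_energy(I, m, inst$seeds, inst$params)
    expect_equal(e_ours, mf$value, tolerance = 1e-8)
  }
})

test_that("energy matches a hand computation on a tiny fully seeded frame", {
  # 2x2 frame, hist_bins = 2, pseudocount = 1. Three FG seeds in the high
  # bin, one BG seed in the low bin; labeling equals the seeding.
  I <- matrix(c(0.8, 0.9, 0.1, 0.7), 2, 2)  # column-major
  seeds <- scribble_set(foreground = rbind(c(1, 1), c(2, 1), c(2, 2)),
                        background = rbind(c(1, 2)))
  params <- graph_cut_params(lambda_smooth = 0.5, sigma_edge = 0.5,
                             hist_bins = 2L, hist_pseudocount = 1)
  L <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  # FG histogram: 3 seeds all in bin 2 -> p = (0+1)/5, (3+1)/5
  # BG histogram: 1 seed in bin 1 -> p = (1+1)/3, (0+1)/3
  D_fg <- -log(c(0.2, 0.8)); D_bg <- -log(c(2 / 3, 1 / 3))
  data_term <- D_fg[2] + D_fg[2] + D_bg[1] + D_fg[2]
  w <- function(a, b) exp(-(a - b)^2 / (2 * 0.5^2))
  # label-discontinuous edges: (1,1)-(1,2) and (1,2)-(2,2)
  smooth_term <- 0.5 * (w(0.8, 0.1) + w(0.1, 0.7))
  expect_equal(segmentation_energy(I, L, seeds, params),
               data_term + smooth_term, tolerance = 1e-12)
})

test_that("energy is infinite for seed-violating labelings and checks shape", {
  I <- matrix(runif(9), 3, 3)
  seeds <- scribble_set(rbind(c(1, 1)), rbind(c(3, 3)))
  bad <- matrix(FALSE, 3, 3)  # violates the FG seed
  expect_identical(segmentation_energy(I, bad, seeds), Inf)
  expect_error(segmentation_energy(I, matrix(FALSE, 2, 2), seeds),
               "does not match")
})

test_that("boundary length is non-increasing in the smoothness weight", {
  inst <- withr::with_seed(21L, {
    I <- matrix(runif(16 * 16, 0, 1), 16, 16)
    I[5:12, 5:12] <- I[5:12, 5:12] * 0.3 + 0.7
    list(I = I,
         seeds = scribble_set(rbind(c(8, 8), c(9, 9)),
                              rbind(c(1, 1), c(16, 16))))
  })
  boundary_len <- function(m) {
    sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
  }
  lens <- vapply(c(0.25, 0.5, 1, 2, 4, 8), function(lam) {
    m <- segment_graph_cut(inst$I, inst$seeds,
                           graph_cut_params(lambda_smooth = lam,
                                            sigma_edge = 0.3))
    boundary_len(m)
  }, 0)
  expect_true(all(diff(lens) <= 0))
})

test_that("scribble sets are validated", {
  expect_error(scribble_set(matrix(numeric(0), 0, 2), rbind(c(1, 1))),
               "non-empty")
  I <- matrix(runif(9), 3, 3)
  expect_error(segment_graph_cut(I, scribble_set(rbind(c(1, 1)),
                                                 rbind(c(1, 1)))),
               "overlap")
  expect_error(segment_graph_cut(I, scribble_set(rbind(c(1, 5)),
                                                 rbind(c(3, 3)))),
               "outside")
  I[2, 2] <- NaN
  expect_error(segment_graph_cut(I, scribble_set(rbind(c(1, 1)),
                                                 rbind(c(3, 3)))),
               "non-finite")
})
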