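# Mixed-effects fits and the correlation screen.

test_that("a noiseless table reproduces the generating line exactly", {
  tab <- generate_semen_table(semen_sim_spec(n_boars = 5L,
                                             ejaculates_per_boar = 2L,
                                             beta0 = 1, beta1 = 2,
                                             sd_intercept = 0, sd_slope = 0,
                                             sd_noise = 0))
  res <- fit_lmm(tab, "response", "intensity")
  expect_equal(res$slope, 2, tolerance = 1e-6)
  expect_equal(res$r_squared, 1, tolerance = 1e-6)
  expect_equal(res$n_obs, 10L)
  expect_equal(res$n_groups, 5L)
})

test_that("a response identical to the predictor has unit slope", {
  tab <- generate_semen_table(semen_sim_spec(seed = 4L))
  tab$copy <- tab$intensity
  res <- fit_lmm(tab, "copy", "intensity")
  expect_equal(res$slope, 1, tolerance = 1e-6)
  expect_equal(res$r_squared, 1, tolerance = 1e-6)
})

test_that("slope recovery is within two standard errors of the truth", {
  tab <- generate_semen_table(semen_sim_spec(n_boars = 40L,
                                             ejaculates_per_boar = 2L,
                                             beta1 = 0.5, sd_intercept = 1,
                                             sd_slope = 0.05, sd_noise = 0.5,
                                             seed = 17L))
  res <- fit_lmm(tab, "response", "intensity")
  se <- (res$ci_high - res$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(res$slope - 0.5), 2 * se)
  expect_true(res$ci_low <= res$slope && res$slope <= res$ci_high)
})

test_that("slope is equivariant under predictor scaling and response shift", {
  tab <- generate_semen_table(semen_sim_spec(n_boars = 30L, sd_slope = 0.3,
                                             sd_noise = 1, seed = 8L))
  base <- fit_lmm(tab, "response", "intensity")
  tab$x10 <- tab$intensity * 10
  scaled <- fit_lmm(tab, "response", "x10")
  expect_equal(scaled$slope, base$slope / 10, tolerance = 1e-2)
  expect_equal(scaled$ci_low, base$ci_low / 10, tolerance = 1e-2)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-2)
  tab$y_shift <- tab$response + 100
  shifted <- fit_lmm(tab, "y_shift", "intensity")
  expect_equal(shifted$slope, base$slope, tolerance = 1e-6)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-4)
})

test_that("R-squared does not decrease as residual noise decreases", {
  r2 <- vapply(c(8, 2, 0.5, 0.1), function(sdn) {
    tab <- generate_semen_table(semen_sim_spec(n_boars = 20L, beta1 = 0.5,
                                               sd_noise = sdn, seed = 31L))
    fit_lmm(tab, "response", "intensity")$r_squared
  }, 0)
  expect_true(all(diff(r2) >= -1e-6))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("degenerate inputs are rejected", {
  tab <- generate_semen_table(semen_sim_spec(seed = 2L))
  tab$const <- 5
  expect_error(fit_lmm(tab, "response", "const"), "zero variance")
  expect_error(fit_lmm(tab, "response", "missing_col"), "not found")
  tab$one_group <- factor("a")
  expect_error(fit_lmm(tab, "response", "intensity", group = "one_group"),
               ">= 2 groups")
})

test_that("the screen returns one row per response in input order", {
  tab <- generate_screen_table(n_boars = 10L, seed = 5L)
  responses <- semen_variable_names()
  res <- correlation_screen(tab, "intensity", responses)
  expect_equal(nrow(res), 26L)
  expect_equal(res$response, responses)
  expect_true(all(c("slope", "ci_low", "ci_high", "p_value", "r_squared",
                    "r2_marginal", "r2_conditional", "n_obs", "n_groups",
                    "converged") %in% names(res)))
  expect_equal(nrow(correlation_screen(tab, "intensity", character(0))), 0L)
})

test_that("an injected association attains the smallest screen p-value", {
  tab <- generate_screen_table(n_boars = 20L, injected = "vap", beta1 = 1,
                               sd_noise = 0.5, seed = 12L)
  res <- correlation_screen(tab, "intensity", semen_variable_names())
  expect_equal(res$response[which.min(res$p_value)], "vap")
})

test_that("constant responses are omitted with a notice", {
  tab <- generate_semen_table(semen_sim_spec(seed = 3L))
  tab$dna_fragmentation <- 0.5
  expect_message(
    res <- correlation_screen(tab, "intensity",
                              c("response", "dna_fragmentation")),
    "constant")
  expect_equal(res$response, "response")
})

test_that("format_screen flags p < alpha and marks non-converged rows", {
  res <- rbind(
    data.frame(predictor = "intensity", response = "vap", slope = 0.574,
               ci_low = 0.024, ci_high = 1.024, p_value = 0.043,
               r_squared = 0.591, r2_marginal = 0.3, r2_conditional = 0.5,
               n_obs = 10L, n_groups = 5L, converged = TRUE,
               random_slope_dropped = FALSE),
    data.frame(predictor = "intensity", response = "vcl", slope = -0.2,
               ci_low = -1.3, ci_high = 0.9, p_value = 0.679,
               r_squared = 0.784, r2_marginal = 0.1, r2_conditional = 0.6,
               n_obs = 10L, n_groups = 5L, converged = TRUE,
               random_slope_dropped = FALSE),
    data.frame(predictor = "intensity", response = "bad", slope = NA,
               ci_low = NA, ci_high = NA, p_value = NA, r_squared = NA,
               r2_marginal = NA, r2_conditional = NA, n_obs = 10L,
               n_groups = NA, converged = FALSE, random_slope_dropped = NA))
  rep <- format_screen(res, alpha = 0.05)
  expect_identical(rep$significant, c(TRUE, FALSE, NA))
  expect_identical(rep$note, c("", "", "not converged"))
  expect_error(format_screen(res, alpha = 1.2), "alpha")
  # empty screen -> header-only outputs
  empty <- format_screen(res[0, ])
  expect_equal(nrow(empty), 0L)
  md <- screen_markdown(format_screen(res))
  expect_length(md, 5L)
  expect_match(md[3], "\\*")   # significant row starred
  expect_match(md[5], "!")     # non-converged row marked
  expect_length(screen_markdown(empty), 2L)
})

test_that("BH adjustment is available behind the fdr flag", {
  res <- data.frame(predictor = "x", response = letters[1:3],
                    slope = 1, ci_low = 0, ci_high = 2,
                    p_value = c(0.001, 0.03, 0.04),
                    r_squared = 0.5, r2_marginal = 0.3, r2_conditional = 0.4,
                    n_obs = 10L, n_groups = 5L, converged = TRUE,
                    random_slope_dropped = FALSE)
  rep <- format_screen(res, alpha = 0.05, fdr = TRUE)
  expect_equal(rep$p_adjusted, p.adjust(res$p_value, "BH"))
  expect_identical(rep$significant, c(TRUE, TRUE, TRUE))
  rep2 <- format_screen(res, alpha = 0.01, fdr = TRUE)
  expect_identical(rep2$significant, c(TRUE, FALSE, FALSE))
})
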