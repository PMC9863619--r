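## Linear mixed-effects correlation screen.
##
## Each (predictor, response) pair is fitted as
##   y = beta0 + beta1 * x + b0_g + b1_g * x + eps,   g = boar,
## with uncorrelated random intercept and slope (diagonal random-effect
## covariance), estimated by maximum likelihood. Inference on the fixed
## slope uses the Wald normal approximation (estimate, 95% CI, two-sided
## p). The headline R^2 is the ordinary R^2 of the conditional fitted
## values (fixed + predicted random effects) against the observations;
## marginal and conditional pseudo-R^2 are also reported.

#' Fit the random-intercept / random-slope model for one pair
#'
#' @param table Data frame with the predictor, response and grouping
#'   columns; no missing values in the fitted columns.
#' @param response,predictor Column names.
#' @param group Grouping column name (default `"boar_id"`).
#' @return One-row data frame with `predictor`, `response`, `slope`,
#'   `ci_low`, `ci_high`, `p_value`, `r_squared`, `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `n_groups`, `converged` and
#'   `random_slope_dropped`. When the random-slope variance is estimated at
#'   the zero boundary the model is refitted with a random intercept only
#'   and `random_slope_dropped` is `TRUE`.
#' @export
fit_lmm <- function(table, response, predictor, group = "boar_id") {
  for (col in c(response, predictor, group))
    if (!col %in% names(table))
      stop_pulseroi("column '", col, "' not found in table")
  d <- data.frame(y = table[[response]], x = table[[predictor]],
                  g = factor(table[[group]]))
  if (anyNA(d)) stop_pulseroi("missing values in '", response, "' / '",
                              predictor, "' / '", group, "'")
  if (nlevels(d$g) < 2L) stop_pulseroi("need >= 2 groups in '", group, "'")
  if (stats::var(d$x) == 0) stop_pulseroi("predictor '", predictor,
                                          "' has zero variance")
  if (stats::var(d$y) == 0) stop_pulseroi("response '", response,
                                          "' has zero variance")

  fit_quiet <- function(formula) {
    warned <- FALSE
    fit <- withCallingHandlers(
      suppressMessages(lme4::lmer(formula, data = d, REML = FALSE)),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warned = warned)
  }

  res <- fit_quiet(y ~ x + (1 | g) + (0 + x | g))
  vc <- as.data.frame(lme4::VarCorr(res$fit))
  slope_var <- vc$vcov[vc$var1 == "x" & !is.na(vc$var1)][1]
  dropped <- FALSE
  if (!is.na(slope_var) && slope_var <= 1e-10 * max(stats::var(d$y), 1e-12)) {
    res <- fit_quiet(y ~ x + (1 | g))
    dropped <- TRUE
  }
  fit <- res$fit

  beta <- lme4::fixef(fit)
  ## vcov can fail numerically on exactly collinear (zero-residual) data;
  ## fall back to the OLS-style SE with the (near-zero) residual sigma
  se <- suppressWarnings(
    tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
             error = function(e) NA_real_))
  if (anyNA(se) || any(!is.finite(se))) {
    X <- cbind(1, d$x)
    se <- stats::sigma(fit) * sqrt(diag(solve(crossprod(X))))
  }
  slope <- unname(beta[2L]); slope_se <- unname(se[2L])
  z <- stats::qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(slope / slope_se))

  y <- d$y
  fitted_cond <- stats::fitted(fit)
  fitted_marg <- as.numeric(cbind(1, d$x) %*% beta)
  r2 <- 1 - sum((y - fitted_cond)^2) / sum((y - mean(y))^2)
  var_f <- stats::var(fitted_marg)
  var_r <- stats::var(fitted_cond - fitted_marg)
  var_e <- stats::sigma(fit)^2
  conv_code <- fit@optinfo$conv$opt

  data.frame(
    predictor = predictor, response = response,
    slope = slope, ci_low = slope - z * slope_se,
    ci_high = slope + z * slope_se, p_value = p,
    r_squared = max(0, min(1, r2)),
    r2_marginal = var_f / (var_f + var_r + var_e),
    r2_conditional = (var_f + var_r) / (var_f + var_r + var_e),
    n_obs = nrow(d), n_groups = nlevels(d$g),
    converged = (conv_code == 0) && !res$warned,
    random_slope_dropped = dropped,
    stringsAsFactors = FALSE)
}

#' Screen many responses against one predictor
#'
#' Fits [fit_lmm()] for each response against the fixed predictor.
#' Per-response failures become non-converged rows with `NA` estimates
#' rather than aborting the screen; responses with zero variance are
#' omitted with a message. No multiple-testing adjustment is applied here
#' (see [format_screen()] for the optional Benjamini-Hochberg flag).
#'
#' @param table Observation data frame.
#' @param predictor Predictor column name (the contraction-intensity
#'   variable in the standard screen).
#' @param responses Character vector of response column names.
#' @param group Grouping column name.
#' @return Data frame with one [fit_lmm()] row per (non-constant) response,
#'   in input order.
#' @export
correlation_screen <- function(table, predictor, responses,
                               group = "boar_id") {
  rows <- lapply(responses, function(resp) {
    if (resp %in% names(table) && stats::var(table[[resp]]) == 0) {
      message("omitting constant response '", resp, "' from the screen")
      return(NULL)
    }
    tryCatch(fit_lmm(table, resp, predictor, group),
             error = function(e)
               data.frame(predictor = predictor, response = resp,
                          slope = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          r_squared = NA_real_, r2_marginal = NA_real_,
                          r2_conditional = NA_real_,
                          n_obs = nrow(table), n_groups = NA_integer_,
                          converged = FALSE, random_slope_dropped = NA,
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- fit_lmm_empty()
  rownames(out) <- NULL
  out
}

fit_lmm_empty <- function() {
  data.frame(predictor = character(0), response = character(0),
             slope = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
             p_value = numeric(0), r_squared = numeric(0),
             r2_marginal = numeric(0), r2_conditional = numeric(0),
             n_obs = integer(0), n_groups = integer(0),
             converged = logical(0), random_slope_dropped = logical(0),
             stringsAsFactors = FALSE)
}

#' Format a correlation screen as a report table
#'
#' Adds a significance flag at level `alpha` (optionally on
#' Benjamini-Hochberg adjusted p-values) and a warning marker for
#' non-converged rows. Column order is fixed.
#'
#' @param results Data frame from [correlation_screen()].
#' @param alpha Significance level in `(0, 1)`.
#' @param fdr If `TRUE`, flag on Benjamini-Hochberg adjusted p-values.
#' @return Data frame with the screen columns plus `p_adjusted` (when
#'   `fdr`), `significant` (logical, `NA` for non-converged rows) and
#'   `note` (`"not converged"` marker or empty).
#' @export
format_screen <- function(results, alpha = 0.05, fdr = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_pulseroi("alpha must be in (0, 1)")
  out <- results[, intersect(
    c("predictor", "response", "slope", "ci_low", "ci_high", "p_value",
      "r_squared", "r2_marginal", "r2_conditional", "n_obs", "n_groups",
      "converged", "random_slope_dropped"), names(results)), drop = FALSE]
  p_flag <- out$p_value
  if (fdr) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    p_flag <- out$p_adjusted
  }
  out$significant <- ifelse(out$converged %in% TRUE, p_flag < alpha, NA)
  out$note <- ifelse(out$converged %in% TRUE, "", "not converged")
  out
}

#' Render a screen report as markdown
#'
#' @param report Data frame from [format_screen()].
#' @return Character vector of markdown lines.
#' @export
screen_markdown <- function(report) {
  num <- function(x) ifelse(is.na(x), "--", sprintf("%.3f", x))
  header <- paste("| Response | Slope | 95% CI | p | R2 | Significant |")
  sep <- "|---|---|---|---|---|---|"
  if (nrow(report) == 0L) return(c(header, sep))
  rows <- sprintf("| %s | %s | [%s, %s] | %s | %s | %s |",
                  report$response, num(report$slope), num(report$ci_low),
                  num(report$ci_high), num(report$p_value),
                  num(report$r_squared),
                  ifelse(is.na(report$significant), "!",
                         ifelse(report$significant, "*", "")))
  c(header, sep, rows)
}
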