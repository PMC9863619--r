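## Grouped semen-variable simulator: the data-generating process of the
## mixed-effects correlation screen, with known fixed slope and random-effect
## variances, used for parameter-recovery and calibration studies.

#' Specify a grouped semen-variable simulation
#'
#' Describes the generating model of the correlation screen: for boar `i`,
#' ejaculate `j`,
#' \deqn{y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) x_{ij} +
#'   \varepsilon_{ij},}
#' with independent \eqn{b_{0i} \sim N(0, \sigma_0^2)},
#' \eqn{b_{1i} \sim N(0, \sigma_1^2)},
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma_e^2)} and contraction intensity
#' `x` drawn uniformly on `intensity_range`.
#'
#' @param n_boars Number of groups (boars); must be at least 2.
#' @param ejaculates_per_boar Observations per group.
#' @param beta0,beta1 Fixed intercept and slope (response units, response
#'   units per percent intensity).
#' @param sd_intercept,sd_slope Random-effect standard deviations.
#' @param sd_noise Residual standard deviation.
#' @param intensity_range `(lo, hi)` percent intensity range.
#' @param seed Integer seed.
#' @return An object of class `semen_sim_spec`.
#' @export
semen_sim_spec <- function(n_boars = 5L, ejaculates_per_boar = 2L,
                           beta0 = 50, beta1 = 0.5,
                           sd_intercept = 1, sd_slope = 0.05, sd_noise = 0.5,
                           intensity_range = c(10, 40), seed = 1L) {
  if (n_boars < 2L)
    stop_pulseroi("n_boars must be >= 2 (grouping is degenerate otherwise)")
  if (any(c(sd_intercept, sd_slope, sd_noise) < 0))
    stop_pulseroi("standard deviations must be >= 0")
  if (intensity_range[1] >= intensity_range[2])
    stop_pulseroi("intensity_range must satisfy lo < hi")
  structure(
    list(n_boars = as.integer(n_boars),
         ejaculates_per_boar = as.integer(ejaculates_per_boar),
         beta0 = beta0, beta1 = beta1, sd_intercept = sd_intercept,
         sd_slope = sd_slope, sd_noise = sd_noise,
         intensity_range = as.numeric(intensity_range),
         seed = as.integer(seed)),
    class = "semen_sim_spec")
}

#' Simulate a grouped (boar x ejaculate) observation table
#'
#' @param spec A [semen_sim_spec()].
#' @return A data frame with one row per ejaculate and columns `boar_id`
#'   (factor), `ejaculate_id`, `intensity` (percent) and `response`.
#' @export
generate_semen_table <- function(spec) {
  stopifnot(inherits(spec, "semen_sim_spec"))
  nb <- spec$n_boars; ne <- spec$ejaculates_per_boar
  withr::with_seed(spec$seed, {
    b0 <- stats::rnorm(nb, 0, spec$sd_intercept)
    b1 <- stats::rnorm(nb, 0, spec$sd_slope)
    boar <- rep(seq_len(nb), each = ne)
    x <- stats::runif(nb * ne, spec$intensity_range[1], spec$intensity_range[2])
    eps <- stats::rnorm(nb * ne, 0, spec$sd_noise)
    y <- (spec$beta0 + b0[boar]) + (spec$beta1 + b1[boar]) * x + eps
    data.frame(
      boar_id = factor(sprintf("boar_%02d", boar)),
      ejaculate_id = rep(seq_len(ne), times = nb),
      intensity = x,
      response = y)
  })
}

#' Names of the semen-quality screen variables
#'
#' The standard per-ejaculate response panel: CASA motility and kinematics,
#' morphology classes, viability, membrane integrity (HOS test), ejaculate
#' volume and total ejaculation time.
#'
#' @return Character vector of 26 column names.
#' @export
semen_variable_names <- function() {
  c("total_motility", "progressive_motility", "non_progressive_motility",
    "immotile", "rapid", "medium", "slow",
    "vcl", "vsl", "vap", "lin", "str", "wob", "alh", "bcf",
    "normal_morphology", "abnormal_morphology", "head_abnormalities",
    "midpiece_abnormalities", "tail_abnormalities", "cytoplasmic_droplets",
    "viability", "hyperactivated", "hos_positive", "volume_ml",
    "total_time_min")
}

## Plausible per-variable location/scale used for the null responses.
screen_variable_scales <- function() {
  nm <- semen_variable_names()
  mean <- c(85, 70, 15, 15, 45, 20, 10,
            100, 45, 60, 45, 75, 60, 2.5, 30,
            80, 20, 5, 5, 8, 8,
            85, 5, 70, 200, 6)
  sd <- c(5, 8, 5, 5, 8, 5, 3,
          10, 6, 6, 6, 6, 6, 0.4, 4,
          5, 5, 2, 2, 2.5, 2.5,
          5, 2, 8, 40, 1.5)
  data.frame(variable = nm, mean = mean, sd = sd)
}

#' Simulate a full correlation-screen table with one injected association
#'
#' Builds a per-ejaculate table with the 26 response variables of
#' [semen_variable_names()], each with a per-boar random intercept and
#' residual noise on a plausible scale, plus a contraction-intensity
#' predictor. Exactly one response (`injected`) depends linearly on the
#' intensity with slope `beta1`; all other responses are independent of it.
#'
#' @param n_boars,ejaculates_per_boar Design size.
#' @param injected Name of the response carrying the true association.
#' @param beta1 Injected slope (response units per percent intensity).
#' @param sd_noise Residual SD of the injected response.
#' @param intensity_range `(lo, hi)` percent intensity range.
#' @param seed Integer seed.
#' @return Data frame with `boar_id`, `ejaculate_id`, `intensity` and the
#'   26 response columns.
#' @export
generate_screen_table <- function(n_boars = 40L, ejaculates_per_boar = 2L,
                                  injected = "vap", beta1 = 1,
                                  sd_noise = 0.5,
                                  intensity_range = c(10, 40), seed = 1L) {
  scales <- screen_variable_scales()
  if (!injected %in% scales$variable)
    stop_pulseroi("unknown injected variable: ", injected)
  nb <- as.integer(n_boars); ne <- as.integer(ejaculates_per_boar)
  if (nb < 2L) stop_pulseroi("n_boars must be >= 2")
  withr::with_seed(seed, {
    boar <- rep(seq_len(nb), each = ne)
    n <- nb * ne
    x <- stats::runif(n, intensity_range[1], intensity_range[2])
    tab <- data.frame(
      boar_id = factor(sprintf("boar_%02d", boar)),
      ejaculate_id = rep(seq_len(ne), times = nb),
      intensity = x)
    for (k in seq_len(nrow(scales))) {
      v <- scales$variable[k]
      b0 <- stats::rnorm(nb, 0, scales$sd[k] / 2)
      if (v == injected) {
        tab[[v]] <- scales$mean[k] + beta1 * (x - mean(intensity_range)) +
          b0[boar] + stats::rnorm(n, 0, sd_noise)
      } else {
        tab[[v]] <- scales$mean[k] + b0[boar] +
          stats::rnorm(n, 0, scales$sd[k] / 2)
      }
    }
    tab
  })
}
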