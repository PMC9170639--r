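# Analytic and numerical bias of weighted two-component RT mixtures.
#
# Pooling congruent and incongruent RTs before taking a central tendency
# computes the central tendency of a weighted mixture of the two condition
# distributions. Its deviation from the unweighted midpoint of the two
# component centers is the cell-level bias.
#
# Sign convention throughout: bias = (weighted central) - (unweighted
# midpoint). With congruent the faster condition, a congruent surplus
# (prop_congruent > 0.5) pulls the weighted central tendency down, so the
# cell-level bias is negative; PES-level bias combines the post-error and
# baseline cell biases with opposite signs.

#' Analytic mean bias of a weighted congruency mixture
#'
#' For a cell whose congruent proportion deviates from 50%, the pooled mean
#' differs from the unweighted mean of the two condition means by a bias
#' that is linear in both the interference effect and the imbalance:
#' \deqn{bias = -(\bar{RT}_{incon} - \bar{RT}_{con}) \times (p_{con} - 0.5)}
#' i.e. interference-per-100-ms times the percentage-point deviation from
#' 50%, signed negative for a congruent surplus. The bias does not depend on
#' the component SDs.
#'
#' @param interference_ms mean incongruent RT minus mean congruent RT (ms).
#' @param prop_congruent congruent proportion of the cell, in `[0, 1]`.
#' @return Signed bias in ms (vectorized). `abs()` gives the magnitude form
#'   interference/100 x deviation-in-percentage-points.
#' @export
#' @examples
#' mean_bias(100, 0.70)       # -20: congruent surplus pulls the mean down
#' abs(mean_bias(100, 0.70))  # 20 ms bias magnitude
mean_bias <- function(interference_ms, prop_congruent) {
  stopifnot(is.finite(interference_ms), is.finite(prop_congruent))
  -interference_ms * (prop_congruent - 0.5)
}

#' Specification of a two-component normal RT mixture
#'
#' @param interference_ms difference of component means,
#'   incongruent minus congruent (ms).
#' @param sd_ms common SD of both components (ms, non-negative).
#' @param prop_congruent mixture weight of the congruent (faster) component.
#' @param central `"mean"` or `"median"`.
#' @param mu_con_ms mean of the congruent component (default 0; only the
#'   bias, not the location, depends on it).
#' @return A list of class `pes_mixture_spec`.
#' @export
mixture_spec <- function(interference_ms, sd_ms, prop_congruent,
                         central = c("mean", "median"), mu_con_ms = 0) {
  central <- match.arg(central)
  if (sd_ms < 0) {
    abort("sd_ms must be non-negative.", class = "pesbias_contract_error")
  }
  stopifnot(prop_congruent >= 0, prop_congruent <= 1)
  structure(
    list(interference_ms = interference_ms, sd_ms = sd_ms,
         prop_congruent = prop_congruent, central = central,
         mu_con_ms = mu_con_ms),
    class = "pes_mixture_spec"
  )
}

#' Central tendency of a weighted normal mixture
#'
#' The mean variant is the closed-form weighted mean of the component means.
#' The median variant solves
#' \eqn{w\,\Phi((m-\mu_{con})/\sigma) + (1-w)\,\Phi((m-\mu_{incon})/\sigma) = 1/2}
#' for `m` by bracketed root search (the mixture CDF is strictly increasing)
#' to within 0.01 ms. For the degenerate \eqn{\sigma = 0} the step-CDF
#' median is the component mean holding the majority weight, and the
#' midpoint at `w = 0.5`.
#'
#' @param spec a [mixture_spec()].
#' @return Central value in ms.
#' @export
#' @examples
#' mixture_central(mixture_spec(200, 50, 0.5, "median"))  # midpoint: 100
mixture_central <- function(spec) {
  stopifnot(inherits(spec, "pes_mixture_spec"))
  w <- spec$prop_congruent
  mu1 <- spec$mu_con_ms
  mu2 <- spec$mu_con_ms + spec$interference_ms
  if (spec$central == "mean") {
    return(w * mu1 + (1 - w) * mu2)
  }
  sigma <- spec$sd_ms
  if (sigma == 0 || mu1 == mu2) {
    if (w > 0.5) return(mu1)
    if (w < 0.5) return(mu2)
    return((mu1 + mu2) / 2)
  }
  lower <- min(mu1, mu2) - 10 * sigma
  upper <- max(mu1, mu2) + 10 * sigma
  f <- function(m) {
    w * pnorm((m - mu1) / sigma) + (1 - w) * pnorm((m - mu2) / sigma) - 0.5
  }
  uniroot(f, lower = lower, upper = upper, tol = 1e-8)$root
}

#' Bias of a weighted mixture's central tendency
#'
#' [mixture_central()] minus the unweighted midpoint of the two component
#' means; zero for a balanced mixture, negative for a congruent surplus.
#'
#' @inheritParams mixture_central
#' @return Signed bias in ms.
#' @export
mixture_bias <- function(spec) {
  mixture_central(spec) -
    (spec$mu_con_ms + (spec$mu_con_ms + spec$interference_ms)) / 2
}

#' Bias surface over interference, imbalance and SD
#'
#' Evaluates [mixture_bias()] on the Cartesian grid of interference effects,
#' congruent proportions, component SDs and central tendencies, as a tidy
#' table. For the mean the bias is independent of the SD; for the median it
#' is at least as strong as the mean bias (same sign) and grows non-linearly
#' with interference and with smaller SDs.
#'
#' @param interference_ms grid of interference effects (ms); default 0-200
#'   in 5-ms steps.
#' @param prop_congruent grid of congruent proportions; default 0.55-0.70 in
#'   0.05 steps.
#' @param sd_ms grid of component SDs; default 50 and 100 ms.
#' @param central central tendencies; default both.
#' @return A tibble with columns `interference_ms`, `prop_congruent`,
#'   `sd_ms`, `central`, `bias_ms`.
#' @export
bias_grid <- function(interference_ms = seq(0, 200, by = 5),
                      prop_congruent = seq(0.55, 0.70, by = 0.05),
                      sd_ms = c(50, 100),
                      central = c("mean", "median")) {
  if (length(interference_ms) == 0 || length(prop_congruent) == 0 ||
      length(sd_ms) == 0 || length(central) == 0) {
    abort("All grid axes must be non-empty.", class = "pesbias_contract_error")
  }
  grid <- tidyr::expand_grid(
    interference_ms = interference_ms,
    prop_congruent = prop_congruent,
    sd_ms = sd_ms,
    central = central
  )
  grid$bias_ms <- vapply(seq_len(nrow(grid)), function(i) {
    mixture_bias(mixture_spec(grid$interference_ms[i], grid$sd_ms[i],
                              grid$prop_congruent[i], grid$central[i]))
  }, numeric(1))
  grid
}
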