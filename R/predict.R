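#' Predict dry weight with uncertainty
#'
#' Turns a fitted hierarchical model (or a registry equation) into per-record
#' body-size estimates. For an `itd_glmm`, the ln-scale linear predictor is
#' evaluated per posterior draw and exponentiated per draw; the point
#' estimate is the posterior median on the mg scale (invariant to the exp
#' transform). The SE and interval are posterior *predictive* for a new
#' specimen: each draw adds a residual Normal(0, sigma) perturbation before
#' exponentiating, so a nominal 90% interval is calibrated to contain the
#' measured dry weight of a fresh specimen about 90% of the time, not just
#' its ln-scale mean. No smearing correction is needed because the
#' back-transform is applied to draws, not to a mean.
#'
#' Records of species unseen during fitting get their species effect
#' integrated over its posterior population distribution (a fresh
#' Normal(0, sd_species) draw per posterior draw); unseen regions likewise,
#' with a warning. The integration draws use R's RNG, so call `set.seed()`
#' first if bitwise reproducibility is required.
#'
#' For an [allometric_equation()], the power law is evaluated exactly; if
#' the equation has a ln-scale residual SD the interval comes from the
#' ln-normal error model, otherwise the result is point-only.
#'
#' @param model An `itd_glmm` fit or an `allometric_equation`.
#' @param newdata Data frame with `itd_mm` and whatever covariates the model
#'   requires (`sex`, `group`, `region`, `species`).
#' @param level Interval coverage, default 0.90.
#' @return Data frame, one row per input record: `point_mg`, `se_mg`,
#'   `lo90`, `hi90` (bounds of the requested `level` interval) and `flags`.
#' @export
predict_dry_weight <- function(model, newdata, level = 0.90) {
  if (level <= 0 || level >= 1) ps_stop("level must be in (0, 1)", "pollisize_validation_error")
  if (inherits(model, "allometric_equation")) {
    if (model$response != "dry_weight_mg")
      ps_stop("equation does not predict dry_weight_mg", "pollisize_validation_error")
    x <- newdata$itd_mm
    if (is.null(x) || any(is.na(x)) || any(x <= 0))
      ps_stop("itd_mm must be present and positive", "pollisize_validation_error")
    mu <- model$alpha_ln + model$beta * log(x)
    if (!is.null(model$sigma_resid_ln)) {
      s <- model$sigma_resid_ln
      z <- qnorm(1 - (1 - level) / 2)
      out <- data.frame(point_mg = exp(mu),
                        se_mg = sqrt((exp(s^2) - 1) * exp(2 * mu + s^2)),
                        lo90 = exp(mu - z * s), hi90 = exp(mu + z * s),
                        flags = "")
    } else {
      out <- data.frame(point_mg = exp(mu), se_mg = NA_real_,
                        lo90 = NA_real_, hi90 = NA_real_, flags = "point_only")
    }
    return(out)
  }
  if (!inherits(model, "itd_glmm"))
    ps_stop("model must be an itd_glmm or allometric_equation", "pollisize_validation_error")

  des <- build_design_for_predict(model, newdata)
  draws <- model$draws
  ndraw <- nrow(draws)
  eta <- des$X %*% t(draws[, model$coef_names, drop = FALSE])  # n x ndraw
  n <- nrow(eta)
  flags <- character(n)
  if (!is.null(model$region_levels)) {
    if (is.null(newdata$region) || any(is.na(newdata$region)))
      ps_stop("missing required covariate 'region'", "pollisize_validation_error")
    if (is.null(newdata$species) || any(is.na(newdata$species)))
      ps_stop("missing required covariate 'species'", "pollisize_validation_error")
    sd_r <- draws[, "sd_region"]; sd_s <- draws[, "sd_species"]
    seen_region <- des$region %in% model$region_levels
    if (any(!seen_region))
      warning(sprintf(
        "%d record(s) from region(s) unseen in fitting; region effect integrated over its population distribution",
        sum(!seen_region)), call. = FALSE)
    for (i in seq_len(n)) {
      u <- if (seen_region[i]) draws[, paste0("u:", des$region[i])]
           else rnorm(ndraw, 0, sd_r)
      vcol <- paste0("v:", des$key[i])
      if (vcol %in% colnames(draws)) {
        v <- draws[, vcol]
      } else {
        v <- rnorm(ndraw, 0, sd_s)
        flags[i] <- paste0(flags[i], "new_species;")
      }
      if (!seen_region[i]) flags[i] <- paste0(flags[i], "new_region;")
      eta[i, ] <- eta[i, ] + u + v
    }
  }
  # point: noise-free posterior median; spread: posterior predictive draws
  sigma <- draws[, "sigma"]
  noise <- matrix(rnorm(length(eta), 0, rep(sigma, each = n)), n, ndraw)
  w_pred <- exp(eta + noise)
  a <- (1 - level) / 2
  data.frame(point_mg = exp(apply(eta, 1, median)),
             se_mg = apply(w_pred, 1, sd),
             lo90 = apply(w_pred, 1, quantile, a),
             hi90 = apply(w_pred, 1, quantile, 1 - a),
             flags = sub(";$", "", flags))
}
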