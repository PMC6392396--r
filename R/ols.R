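#' Ordinary least squares fit of a power law on ln-ln axes
#'
#' Fits `ln(y) = alpha_ln + beta * ln(x)` by OLS. This is the workhorse
#' behind predictor comparison and the per-species intraspecific
#' diagnostics.
#'
#' @param x Positive predictor values (e.g. ITD, mm).
#' @param y Positive response values (e.g. dry weight, mg).
#' @return An object of class `ols_loglog`: a list with `alpha_ln`,
#'   `alpha_se`, `beta`, `beta_se`, `f_stat`, `df1`, `df2`, `r2`, `adj_r2`,
#'   `p_value`, `n`, and the underlying `lm` fit.
#' @export
fit_ols_loglog <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) ps_stop("need at least 3 complete (x, y) pairs", "pollisize_validation_error")
  if (any(x <= 0) || any(y <= 0))
    ps_stop("x and y must be positive for a ln-ln fit", "pollisize_validation_error")
  if (var(log(x)) == 0) ps_stop("zero variance in ln(x)", "pollisize_validation_error")
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    alpha_ln = unname(co[1, 1]), alpha_se = unname(co[1, 2]),
    beta = unname(co[2, 1]), beta_se = unname(co[2, 2]),
    f_stat = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)),
    n = length(x), lm = fit), class = "ols_loglog")
}

#' @export
print.ols_loglog <- function(x, ...) {
  cat(sprintf(
    "ln-ln OLS (n = %d): ln(y) = %.3f (+/- %.3f) + %.3f (+/- %.3f) ln(x)\n",
    x$n, x$alpha_ln, x$alpha_se, x$beta, x$beta_se))
  cat(sprintf("  F(%d, %d) = %.3f, adj R2 = %.3f, p = %.3g\n",
              x$df1, x$df2, x$f_stat, x$adj_r2, x$p_value))
  invisible(x)
}

#' Compare ITD and body length as body-size predictors
#'
#' For species with both measurements, computes Pearson's r between each
#' candidate predictor and dry weight on species-mean ln values, and the
#' adjusted R-squared of the corresponding species-mean ln-ln OLS fit. The
#' comparison that motivates using the ITD: it is at least as predictive as
#' body length and far less ambiguous to measure.
#'
#' @param df Specimen data frame with `itd_mm`, `body_length_mm` and
#'   `dry_weight_mg`.
#' @return Data frame with one row per predictor (`itd_mm`,
#'   `body_length_mm`): `pearson_r` and `ols_r2` on species means, and
#'   `n_species`.
#' @export
compare_predictors <- function(df) {
  ok <- is.finite(df$itd_mm) & is.finite(df$body_length_mm) & is.finite(df$dry_weight_mg)
  d <- df[ok, , drop = FALSE]
  means <- aggregate_species_means(d)
  if (nrow(means) < 3)
    ps_stop("need both predictors and dry weight for at least 3 species",
            "pollisize_validation_error")
  one <- function(col) {
    r <- stats::cor(log(means[[col]]), log(means$dry_weight_mg))
    f <- fit_ols_loglog(means[[col]], means$dry_weight_mg)
    data.frame(predictor = col, pearson_r = r, ols_r2 = f$r2,
               adj_r2 = f$adj_r2, n_species = nrow(means))
  }
  rbind(one("itd_mm"), one("body_length_mm"))
}

# Species-mean table of the three measurement columns (geometric-friendly:
# arithmetic means of the raw mm/mg values, as used for predictor screening).
aggregate_species_means <- function(df) {
  sp <- unique(df$species)
  out <- data.frame(species = sp,
                    itd_mm = NA_real_, body_length_mm = NA_real_,
                    dry_weight_mg = NA_real_)
  for (i in seq_along(sp)) {
    sub <- df[df$species == sp[i], ]
    out$itd_mm[i] <- mean(sub$itd_mm)
    out$body_length_mm[i] <- mean(sub$body_length_mm)
    out$dry_weight_mg[i] <- mean(sub$dry_weight_mg)
  }
  out
}
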