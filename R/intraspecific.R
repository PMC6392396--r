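#' Intraspecific dry weight ~ ITD regression
#'
#' Within a single species and sex, fits ln(dry weight) on ln(ITD) by OLS.
#' Unlike the interspecific hierarchy, within-species allometry is often weak
#' and sample-size sensitive, so these per-species fits are diagnostics
#' rather than prediction tools. At least 4 specimens are required: below
#' that the residual degrees of freedom (n - 2) make the F test meaningless.
#'
#' @param df Specimen data frame.
#' @param species Species binomial to subset.
#' @param sex `"female"` or `"male"`.
#' @return An `ols_loglog` fit (see [fit_ols_loglog()]) with `species` and
#'   `sex` fields added.
#' @export
intraspecific_fit <- function(df, species, sex) {
  sub <- df[df$species == species & df$sex == sex &
              is.finite(df$itd_mm) & is.finite(df$dry_weight_mg), , drop = FALSE]
  if (nrow(sub) < 4)
    ps_stop(sprintf("only %d usable specimens of %s %s (need >= 4)",
                    nrow(sub), sex, species), "pollisize_validation_error")
  if (var(log(sub$itd_mm)) == 0)
    ps_stop(sprintf("all ITD values identical for %s %s", sex, species),
            "pollisize_validation_error")
  fit <- fit_ols_loglog(sub$itd_mm, sub$dry_weight_mg)
  fit$species <- species
  fit$sex <- sex
  fit$region <- paste(sort(unique(sub$region)), collapse = "/")
  fit$group <- paste(sort(unique(sub$group)), collapse = "/")
  fit
}

#' Intraspecific summary table
#'
#' Runs [intraspecific_fit()] for a set of (species, sex) targets and lays
#' the results out as one row per fit: region, taxon, species, F(df1, df2),
#' ln-scale intercept +/- SE, exponent +/- SE, adjusted R-squared and p.
#'
#' @param df Specimen data frame.
#' @param targets Data frame with columns `species` and `sex`.
#' @return Data frame, one row per target.
#' @export
intraspecific_table <- function(df, targets) {
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    f <- intraspecific_fit(df, targets$species[i], targets$sex[i])
    data.frame(region = f$region, group = f$group, species = f$species,
               sex = f$sex, n = f$n,
               f_stat = f$f_stat, df1 = f$df1, df2 = f$df2,
               alpha_ln = f$alpha_ln, alpha_se = f$alpha_se,
               beta = f$beta, beta_se = f$beta_se,
               adj_r2 = f$adj_r2, p_value = f$p_value)
  })
  do.call(rbind, rows)
}

#' Sample-size adequacy by resampling
#'
#' How many specimens are needed for a stable species mean? For each
#' subsample size n in 1..N the trait mean of a random subsample (without
#' replacement) is averaged over `replicates` draws; the adequate sample
#' size is the smallest n from which this resampled-mean curve stays inside
#' the t-based 95% confidence band of the full-sample mean for every larger
#' n as well (stability, not a single crossing).
#'
#' Stability is judged on the spread of the resampled means, not their
#' average: because a subsample mean is unbiased, its replicate average sits
#' near the full-sample mean at every n and would declare any sample size
#' adequate. Instead the 2.5%/97.5% envelope of the replicate means at each
#' n must lie inside the full-sample confidence band from `adequate_n`
#' onwards -- the sample size at which one more specimen no longer moves
#' the mean outside its final confidence limits.
#'
#' @param values Numeric trait measurements (e.g. ITD of one species), N >= 3.
#' @param replicates Subsamples drawn per n; default 100.
#' @param seed Integer seed; the curve is reproducible given the seed.
#' @return An object of class `adequacy_curve`: list with `n_grid`,
#'   `mean_per_n` (replicate-averaged mean per n), `envelope_lo`,
#'   `envelope_hi` (replicate 2.5%/97.5% quantiles), `band` (lo, hi),
#'   `full_mean`, `adequate_n`, `seed`, `replicates`.
#' @export
adequacy_curve <- function(values, replicates = 100, seed = 1) {
  values <- values[is.finite(values)]
  N <- length(values)
  if (N < 3) ps_stop("need at least 3 measurements", "pollisize_validation_error")
  full_mean <- mean(values)
  half <- stats::qt(0.975, N - 1) * stats::sd(values) / sqrt(N)
  band <- c(lo = full_mean - half, hi = full_mean + half)
  set.seed(substream_seed(seed, "adequacy"))
  reps <- vapply(seq_len(N), function(n) {
    vapply(seq_len(replicates), function(r) mean(values[sample.int(N, n)]),
           numeric(1))
  }, numeric(replicates))                       # replicates x N
  mean_per_n <- colMeans(reps)
  env_lo <- apply(reps, 2, quantile, 0.025)
  env_hi <- apply(reps, 2, quantile, 0.975)
  eps <- 1e-12 * max(1, abs(full_mean))
  inside <- env_lo >= band["lo"] - eps & env_hi <= band["hi"] + eps
  # smallest n such that the envelope stays inside the band from n through N
  stays <- rev(cumprod(rev(inside))) > 0
  adequate_n <- if (any(stays)) min(which(stays)) else N
  structure(list(n_grid = seq_len(N), mean_per_n = mean_per_n,
                 envelope_lo = env_lo, envelope_hi = env_hi, band = band,
                 full_mean = full_mean, adequate_n = adequate_n,
                 seed = seed, replicates = replicates),
            class = "adequacy_curve")
}

#' @export
print.adequacy_curve <- function(x, ...) {
  cat(sprintf(
    "adequacy curve over n = 1..%d (%d replicates): full mean %.4g, 95%% band [%.4g, %.4g]\n",
    max(x$n_grid), x$replicates, x$full_mean, x$band["lo"], x$band["hi"]))
  cat(sprintf("  adequate sample size: %d\n", x$adequate_n))
  invisible(x)
}

#' Export an adequacy curve as a data frame
#'
#' @param x An `adequacy_curve`.
#' @param ... Unused.
#' @return Data frame with columns `n`, `mean`, `band_lo`, `band_hi`.
#' @export
as.data.frame.adequacy_curve <- function(x, ...) {
  data.frame(n = x$n_grid, mean = x$mean_per_n,
             band_lo = unname(x$band["lo"]), band_hi = unname(x$band["hi"]))
}
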