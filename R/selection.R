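#' Bayesian R-squared
#'
#' Per posterior draw, the variance of the fitted ln-scale values over the
#' training records divided by that variance plus the draw's residual
#' variance — a draw-wise proportion of explained variance that is always
#' in \[0, 1\]. Summarized over draws by the mean and the 5%/95% quantiles.
#'
#' @param fit An `itd_glmm`.
#' @param data The training data the model was fitted on (fingerprint is
#'   checked).
#' @return List with `mean`, `q5`, `q95` and the per-draw vector `draws`.
#' @export
bayes_r2 <- function(fit, data) {
  fp <- fingerprint_data(
    data[, intersect(c("species", "region", "group", "sex", "itd_mm", "dry_weight_mg"),
                     names(data)), drop = FALSE])
  if (!identical(fp, fit$data_fingerprint))
    ps_stop("data fingerprint does not match the fit's training data",
            "pollisize_validation_error")
  eta <- linpred_draws(fit, data)
  var_fit <- apply(eta, 2, var)
  if (all(var_fit == 0))
    ps_stop("zero variance in fitted values", "pollisize_validation_error")
  sigma2 <- fit$draws[, "sigma"]^2
  r2 <- var_fit / (var_fit + sigma2)
  list(mean = mean(r2), q5 = unname(quantile(r2, 0.05)),
       q95 = unname(quantile(r2, 0.95)), draws = r2)
}

#' Species-grouped K-fold assignment
#'
#' Partitions the species (not the specimens) of a table into k folds of
#' near-equal species counts (sizes differ by at most 1): the species list
#' is sorted, permuted under the seed and dealt round-robin. Every specimen
#' of a species shares its fold, so a held-out species is entirely unseen
#' by the training folds. The assignment depends only on the species set
#' and the seed, not on record order.
#'
#' @param data Specimen data frame (or anything with the group column).
#' @param k Number of folds, default 10; must not exceed the number of
#'   distinct groups.
#' @param group Grouping column, default `"species"`.
#' @param seed Integer seed.
#' @return Named integer vector (group -> fold), class `kfold_assignment`,
#'   with attributes `k`, `seed`, `group`.
#' @export
grouped_kfold_split <- function(data, k = 10, group = "species", seed = 1) {
  groups <- sort(unique(data[[group]]))
  if (k < 2) ps_stop("k must be >= 2", "pollisize_validation_error")
  if (k > length(groups))
    ps_stop(sprintf("k = %d exceeds the %d distinct %s", k, length(groups), group),
            "pollisize_validation_error")
  set.seed(substream_seed(seed, "kfold"))
  perm <- sample(groups)
  fold <- setNames(rep(seq_len(k), length.out = length(perm)), perm)
  fold <- fold[order(names(fold))]
  structure(fold, k = as.integer(k), seed = as.integer(seed), group = group,
            class = "kfold_assignment")
}

#' Root-mean-square error on the response scale
#'
#' `sqrt(mean((observed - predicted)^2))`, computed on the mg scale so the
#' error is in the units of the response.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A single number (mg when the inputs are mg).
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    ps_stop("observed and predicted must have equal length", "pollisize_validation_error")
  if (!length(observed)) ps_stop("need at least one pair", "pollisize_validation_error")
  sqrt(mean((observed - predicted)^2))
}

#' Species-grouped K-fold cross-validation
#'
#' For each fold, refits the model on the other k-1 folds and scores the
#' held-out specimens by their log posterior-predictive density. Held-out
#' species are unseen by construction, so their random intercept is
#' integrated out: for the taxonomic model the normal integral over
#' Normal(0, sd_species) is taken analytically within each posterior draw;
#' for the phylogenetic model the held-out species' effect is conditioned
#' on the training species' effects through the tree covariance (Gaussian
#' conditional), which is what lets phylogenetic information help predict
#' unseen relatives. The reported score is `-2 * sum(log predictive
#' density)` (deviance scale, lower is better), totalled over folds.
#'
#' @param spec A [model_spec()].
#' @param data Specimen data frame.
#' @param folds A [grouped_kfold_split()] assignment covering the data's
#'   species.
#' @param settings [mcmc_settings()] used for each refit.
#' @param priors Prior configuration.
#' @param tree Required when `spec$phylo`; the phylogeny covering all
#'   species.
#' @return Object of class `cv_result`: `k`, `fold_scores`, `total_score`,
#'   `seed`, `fold_assignment`, `fold_converged`, `reliable` (FALSE if any
#'   fold's refit failed the convergence gate).
#' @export
kfold_cv <- function(spec, data, folds, settings = mcmc_settings(),
                     priors = default_priors(), tree = NULL) {
  k <- attr(folds, "k")
  if (is.null(k) || k < 2) ps_stop("folds must come from grouped_kfold_split (k >= 2)",
                                   "pollisize_validation_error")
  sp_all <- unique(data$species)
  if (!all(sp_all %in% names(folds)))
    ps_stop("fold assignment does not cover all species in data", "pollisize_validation_error")
  if (isTRUE(spec$phylo) && is.null(tree))
    ps_stop("phylogenetic spec needs the tree", "pollisize_validation_error")
  Cfull <- NULL
  if (isTRUE(spec$phylo)) {
    keep <- gsub(" ", "_", sp_all)
    tr <- ape::keep.tip(tree, intersect(tree$tip.label, keep))
    Cfull <- stats::cov2cor(ape::vcv.phylo(tr))
  }
  fold_of <- folds[data$species]
  fold_scores <- numeric(k)
  fold_converged <- logical(k)
  for (f in seq_len(k)) {
    train <- data[fold_of != f, , drop = FALSE]
    test <- data[fold_of == f, , drop = FALSE]
    if (!nrow(test)) { fold_scores[f] <- 0; fold_converged[f] <- TRUE; next }
    fit <- withCallingHandlers(
      if (isTRUE(spec$phylo))
        fit_interspecific_phylo(train, spec, tree, settings, priors)
      else fit_interspecific(train, spec, settings, priors),
      warning = function(w) invokeRestart("muffleWarning"))
    fold_converged[f] <- fit$converged
    fold_scores[f] <- -2 * sum(heldout_lpd(fit, test, Cfull))
  }
  reliable <- all(fold_converged)
  if (!reliable)
    warning("one or more fold refits failed the convergence gate; total score marked unreliable",
            call. = FALSE)
  structure(list(k = k, fold_scores = fold_scores,
                 total_score = sum(fold_scores),
                 seed = attr(folds, "seed"), fold_assignment = folds,
                 fold_converged = fold_converged, reliable = reliable),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("K-fold CV (k = %d, seed = %d): total = %.1f%s\n",
              x$k, x$seed, x$total_score,
              if (x$reliable) "" else "  [UNRELIABLE: non-converged folds]"))
  cat("  fold scores:", paste(sprintf("%.1f", x$fold_scores), collapse = ", "), "\n")
  invisible(x)
}

# Log posterior-predictive density of held-out rows whose species are unseen.
# Marginalizes the species effect per draw: analytically for the i.i.d. model,
# via the Gaussian conditional on training species for the phylogenetic one.
heldout_lpd <- function(fit, test, Cfull = NULL) {
  des <- build_design_for_predict(fit, test)
  draws <- fit$draws
  ndraw <- nrow(draws)
  eta <- des$X %*% t(draws[, fit$coef_names, drop = FALSE])  # n x ndraw
  sigma2 <- draws[, "sigma"]^2
  n <- nrow(eta)
  y <- log(test$dry_weight_mg)
  if (is.null(fit$region_levels)) {
    ld <- dnorm(y, eta, matrix(sqrt(sigma2), n, ndraw, byrow = TRUE), log = TRUE)
    return(apply(ld, 1, logmeanexp))
  }
  sd_r <- draws[, "sd_region"]; sd_s <- draws[, "sd_species"]
  mean_adj <- matrix(0, n, ndraw)
  var_mult <- rep(1, n)          # multiplier on sd_species^2
  if (isTRUE(fit$phylo) && !is.null(Cfull)) {
    tr <- fit$species_keys
    te_sp <- unique(des$key)
    A <- Cfull[te_sp, tr, drop = FALSE] %*% solve(Cfull[tr, tr])
    condvar <- pmax(0, diag(Cfull)[te_sp] - rowSums(A * Cfull[te_sp, tr, drop = FALSE]))
    v_tr <- t(draws[, paste0("v:", tr), drop = FALSE])        # S_tr x ndraw
    cond_mean <- A %*% v_tr                                   # S_te x ndraw
    idx <- match(des$key, te_sp)
    mean_adj <- cond_mean[idx, , drop = FALSE]
    var_mult <- condvar[idx]
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- eta[i, ] + mean_adj[i, ]
    v <- sigma2 + var_mult[i] * sd_s^2
    if (des$region[i] %in% fit$region_levels) {
      m <- m + draws[, paste0("u:", des$region[i])]
    } else {
      v <- v + sd_r^2
    }
    out[i] <- logmeanexp(dnorm(y[i], m, sqrt(v), log = TRUE))
  }
  out
}

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Model-selection comparison table
#'
#' Lays out a set of fitted models as one row each: Bayesian R-squared,
#' species-grouped K-fold CV score, Delta (difference to the best, i.e.
#' lowest, CV score) and RMSE of the posterior-median mg-scale predictions
#' on the training data. Rows are sorted by the CV score ascending, so the
#' first row is the selected model. All fits must have been trained on the
#' same table (fingerprints are compared).
#'
#' @param fits List of `itd_glmm` fits.
#' @param data The shared training data.
#' @param folds A [grouped_kfold_split()] assignment.
#' @param tree Phylogeny, needed if any fit is phylogenetic.
#' @param settings Optional [mcmc_settings()] for the CV refits; defaults to
#'   each fit's own settings.
#' @return Data frame with columns `model`, `bayes_r2`, `kcv`, `delta_kcv`,
#'   `rmse_mg`, `cv_reliable`.
#' @export
compare_models <- function(fits, data, folds, tree = NULL, settings = NULL) {
  fps <- vapply(fits, `[[`, character(1), "data_fingerprint")
  if (length(unique(fps)) != 1)
    ps_stop("fits were trained on different data (mixed fingerprints)",
            "pollisize_validation_error")
  fp <- fingerprint_data(
    data[, intersect(c("species", "region", "group", "sex", "itd_mm", "dry_weight_mg"),
                     names(data)), drop = FALSE])
  if (!identical(fp, fps[[1]]))
    ps_stop("data does not match the fits' training data", "pollisize_validation_error")
  rows <- lapply(fits, function(fit) {
    r2 <- bayes_r2(fit, data)$mean
    cv <- kfold_cv(fit$spec, data, folds,
                   settings = settings %||% fit$settings,
                   priors = fit$priors, tree = tree)
    pred <- apply(exp(linpred_draws(fit, data)), 1, median)
    data.frame(model = format_model_spec(fit$spec),
               bayes_r2 = r2, kcv = cv$total_score,
               rmse_mg = rmse(data$dry_weight_mg, pred),
               cv_reliable = cv$reliable)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$kcv), , drop = FALSE]
  out$delta_kcv <- out$kcv - min(out$kcv)
  rownames(out) <- NULL
  out[, c("model", "bayes_r2", "kcv", "delta_kcv", "rmse_mg", "cv_reliable")]
}

#' Write a comparison table to CSV or Markdown
#'
#' @param comparison Output of [compare_models()].
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(comparison, path, row.names = FALSE)
  } else {
    hdr <- "| Model | R2 | K-CV | Delta | RMSE (mg) |"
    sep <- "|---|---|---|---|---|"
    rows <- sprintf("| %s | %.3f | %.1f | %.1f | %.3f |",
                    comparison$model, comparison$bayes_r2, comparison$kcv,
                    comparison$delta_kcv, comparison$rmse_mg)
    writeLines(c(hdr, sep, rows), path)
  }
  invisible(path)
}
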