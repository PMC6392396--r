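#' Specify an interspecific allometric model
#'
#' Describes the fixed and random structure of the hierarchical ln-ln model
#' `ln(dry weight) = ln(alpha) + beta * ln(ITD) + ...`. Fixed co-variate
#' terms come from `{"group", "sex", "group:ln_itd", "sex:ln_itd"}` (group
#' is the bee family or hoverfly subfamily); an interaction requires its
#' main effect. The random structure is species nested within biogeographic
#' region (`"region/species"`), or `NULL` for a fixed-effects-only model.
#'
#' @param fixed Character vector of co-variate terms (may be empty).
#' @param random `"region/species"` or `NULL`.
#' @param itd_slope Include the ln(ITD) slope; default TRUE. Setting FALSE
#'   gives an intercept-only model, useful for degenerate checks.
#' @param phylo Constrain the species effect by a phylogeny (set by
#'   [fit_interspecific_phylo()]; users normally leave this alone).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(fixed = character(), random = "region/species",
                       itd_slope = TRUE, phylo = FALSE) {
  allowed <- c("group", "sex", "group:ln_itd", "sex:ln_itd")
  bad <- setdiff(fixed, allowed)
  if (length(bad))
    ps_stop(sprintf("unknown fixed terms: %s (allowed: %s)",
                    paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
            "pollisize_validation_error")
  if ("group:ln_itd" %in% fixed && !"group" %in% fixed)
    ps_stop("group:ln_itd requires the group main effect", "pollisize_validation_error")
  if ("sex:ln_itd" %in% fixed && !"sex" %in% fixed)
    ps_stop("sex:ln_itd requires the sex main effect", "pollisize_validation_error")
  if (!is.null(random) && !identical(random, "region/species"))
    ps_stop('random must be "region/species" or NULL', "pollisize_validation_error")
  if (any(c("group:ln_itd", "sex:ln_itd") %in% fixed) && !itd_slope)
    ps_stop("ITD interactions require the ITD slope", "pollisize_validation_error")
  structure(list(fixed = fixed, random = random, itd_slope = itd_slope,
                 phylo = phylo), class = "model_spec")
}

#' Human-readable model formula
#' @param spec A `model_spec`.
#' @return A single string in the field's mixed-model notation.
#' @export
format_model_spec <- function(spec) {
  rhs <- c(if (spec$itd_slope) "ln(ITD)",
           if ("group" %in% spec$fixed) "Group",
           if ("sex" %in% spec$fixed) "Sex",
           if ("group:ln_itd" %in% spec$fixed) "Group:ln(ITD)",
           if ("sex:ln_itd" %in% spec$fixed) "Sex:ln(ITD)")
  if (!length(rhs)) rhs <- "1"
  f <- paste("ln(Dry weight) ~", paste(rhs, collapse = " + "))
  if (!is.null(spec$random)) f <- paste0(f, " + (1 | Region/Species)")
  if (spec$phylo) f <- paste0(f, " [phylo]")
  f
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format_model_spec(x), "\n")
  invisible(x)
}

#' MCMC sampler settings
#'
#' `iterations` counts total iterations per chain including warmup
#' (`burn_in`), matching the convention in which a 2000-iteration run with a
#' burn-in of 1000 keeps 1000 draws per chain. `adapt_delta` and
#' `max_tree_depth` are accepted and recorded for interoperability with
#' Hamiltonian samplers, but the Gibbs sampler used here has no equivalent
#' tuning knobs and they do not influence sampling.
#'
#' @param iterations Total iterations per chain (including warmup).
#' @param burn_in Warmup iterations discarded per chain; must be <
#'   `iterations`.
#' @param chains Number of chains (>= 2 so split-R-hat is defined).
#' @param adapt_delta Recorded acceptance target in (0, 1); inert here.
#' @param max_tree_depth Recorded integer; inert here.
#' @param seed Integer seed; drives all chain RNGs.
#' @return Object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 2000, burn_in = 1000, chains = 4,
                          adapt_delta = 0.99, max_tree_depth = 10, seed = 1) {
  if (burn_in >= iterations) ps_stop("burn_in must be < iterations", "pollisize_validation_error")
  if (adapt_delta <= 0 || adapt_delta >= 1) ps_stop("adapt_delta must be in (0, 1)", "pollisize_validation_error")
  if (chains < 1) ps_stop("need at least 1 chain", "pollisize_validation_error")
  structure(list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
                 chains = as.integer(chains), adapt_delta = adapt_delta,
                 max_tree_depth = as.integer(max_tree_depth),
                 seed = as.integer(seed)), class = "mcmc_settings")
}

#' Weakly informative default priors
#'
#' Normal(0, 5) on the ln-scale intercept, Normal(0, 2) on slopes and
#' offsets, half-Normal(0, 1) on all standard deviations (residual and
#' random-effect). On the ln scale these are broad relative to any plausible
#' insect allometry (an exponent prior SD of 2 covers isometry through
#' strong positive allometry several times over).
#'
#' @param intercept_sd,slope_sd,sd_sd Prior SDs; override to taste.
#' @return Named list of prior SDs.
#' @export
default_priors <- function(intercept_sd = 5, slope_sd = 2, sd_sd = 1) {
  if (any(c(intercept_sd, slope_sd, sd_sd) <= 0))
    ps_stop("prior SDs must be positive", "pollisize_validation_error")
  list(intercept_sd = intercept_sd, slope_sd = slope_sd, sd_sd = sd_sd)
}

# ---- internal: design construction ------------------------------------------

# Builds response, fixed-effect design matrix and grouping indices from a
# specimen table under a model_spec. Stores factor levels for prediction.
build_design <- function(data, spec) {
  need <- c("species", "region", "itd_mm", "dry_weight_mg")
  if ("group" %in% spec$fixed) need <- c(need, "group")
  if ("sex" %in% spec$fixed) need <- c(need, "sex")
  for (col in need) {
    if (!col %in% names(data) || any(is.na(data[[col]])))
      ps_stop(sprintf("all records must have non-missing '%s'", col),
              "pollisize_validation_error")
  }
  if (any(data$itd_mm <= 0) || any(data$dry_weight_mg <= 0))
    ps_stop("itd_mm and dry_weight_mg must be positive", "pollisize_validation_error")
  if (length(unique(data$species)) < 2)
    ps_stop("need at least 2 species", "pollisize_validation_error")
  md <- data.frame(ln_itd = log(data$itd_mm))
  levels_used <- list()
  for (fac in c("group", "sex")) {
    if (fac %in% spec$fixed) {
      lv <- sort(unique(data[[fac]]))
      if (length(lv) < 2)
        ps_stop(sprintf(
          "singular design: '%s' term requested but only one level present (%s)",
          fac, lv), "pollisize_singular_error")
      md[[fac]] <- factor(data[[fac]], levels = lv)
      levels_used[[fac]] <- lv
    }
  }
  rhs <- c(if (spec$itd_slope) "ln_itd",
           if ("group" %in% spec$fixed) "group",
           if ("sex" %in% spec$fixed) "sex",
           if ("group:ln_itd" %in% spec$fixed) "group:ln_itd",
           if ("sex:ln_itd" %in% spec$fixed) "sex:ln_itd")
  form <- stats::as.formula(paste("~", if (length(rhs)) paste(rhs, collapse = "+") else "1"))
  X <- stats::model.matrix(form, md)
  list(y = log(data$dry_weight_mg), X = X, formula = form,
       levels = levels_used,
       region = data$region, species = gsub(" ", "_", data$species))
}

# ---- internal: JAGS machinery ----------------------------------------------

# The sampled parameterization is hierarchically centered (species intercepts
# centered on their region's, regions on the global intercept) with centered
# covariate columns: both are exact reparameterizations that decorrelate the
# Gibbs updates. Draws are transformed back to the user-facing basis
# (global intercept + zero-mean region/species offsets, uncentered covariates)
# before anything downstream sees them.
jags_model_string <- function(has_random, phylo, has_slopes) {
  slope_term <- if (has_slopes) "inprod(Xs[i,], gs[])" else NULL
  mu <- if (!has_random) {
    paste(c("g1", slope_term), collapse = " + ")
  } else if (phylo) {
    # species effect centered on its home region's intercept; the explicit
    # u difference covers specimens observed away from the home region
    paste(c(slope_term, "v[sp[i]]", "u[region[i]] - u[regof[sp[i]]]"),
          collapse = " + ")
  } else {
    paste(c(slope_term, "v[sp[i]]"), collapse = " + ")
  }
  lines <- c(
    "model {",
    "  for (i in 1:N) {",
    sprintf("    mu[i] <- %s", mu),
    "    y[i] ~ dnorm(mu[i], tau)",
    "  }",
    if (has_random) c(
      if (phylo) c(
        "  for (k in 1:S) { mu_v[k] <- u[regof[k]] }",
        "  v[1:S] ~ dmnorm(mu_v[], Omega[,])",
        "  for (a in 1:S) { for (b in 1:S) { Omega[a,b] <- tau_species * Vinv[a,b] } }"
      ) else
        "  for (k in 1:S) { v[k] ~ dnorm(u[regof[k]], tau_species) }",
      "  tau_species <- pow(sd_species, -2)",
      "  for (j in 1:R) { u[j] ~ dnorm(g1, tau_region) }",
      "  sd_region ~ dnorm(0, prec_sd) T(0,)",
      "  sd_species ~ dnorm(0, prec_sd) T(0,)",
      "  tau_region <- pow(sd_region, -2)"
    ),
    "  g1 ~ dnorm(0, prec_intercept)",
    if (has_slopes) "  for (p in 1:P) { gs[p] ~ dnorm(0, prec_slope) }",
    "  sigma ~ dnorm(0, prec_sd) T(0,)",
    "  tau <- pow(sigma, -2)",
    "}")
  paste(unlist(lines), collapse = "\n")
}

# Split-R-hat (Gelman-Rubin on half-chains) for a list of draw matrices.
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    if (n < 4) return(rep(NA_real_, ncol(chains[[1]])))
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    xs <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    s2 <- vapply(halves, function(h) var(h[, j]), numeric(1))
    W <- mean(s2); B <- n * var(xs)
    if (W == 0) return(ifelse(B == 0, 1, Inf))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

run_jags <- function(dat, model_str, monitors, settings) {
  inits <- lapply(seq_len(settings$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(settings$seed, paste0("chain", i)))
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          n.chains = settings$chains,
                          inits = inits, quiet = TRUE,
                          n.adapt = min(500L, settings$burn_in))
  stats::update(jm, settings$burn_in, progress.bar = "none")
  keep <- settings$iterations - settings$burn_in
  rjags::coda.samples(jm, monitors, keep, progress.bar = "none")
}

# ---- fitting ----------------------------------------------------------------

#' Fit the hierarchical interspecific allometric model
#'
#' Fits `ln(dry weight) ~ ln(ITD) (+ co-variates) + (1 | Region/Species)` by
#' MCMC (JAGS Gibbs sampling). Random intercepts are nested: one per region
#' and one per species-within-region combination, each with its own
#' half-Normal-prior standard deviation, plus a ln-scale residual SD. All
#' posterior draws of every fixed coefficient, random-effect SD and random
#' intercept are retained in the fit object, so predictions propagate full
#' posterior uncertainty.
#'
#' Convergence is assessed by split-R-hat over chains; a fit with any R-hat
#' above 1.05 is returned but flagged non-converged with a warning, never
#' silently. Given a seed, the fit is exactly reproducible.
#'
#' @param data Specimen data frame (all rows need species, region, positive
#'   `itd_mm` and `dry_weight_mg`; plus `group`/`sex` when those terms are in
#'   the spec).
#' @param spec A [model_spec()].
#' @param settings An [mcmc_settings()].
#' @param priors A [default_priors()] list.
#' @return Object of class `itd_glmm` holding posterior draws, parameter
#'   maps, factor levels, diagnostics (per-parameter R-hat; the Gibbs
#'   sampler has no divergent transitions so that count is structurally 0)
#'   and the training-data fingerprint.
#' @export
fit_interspecific <- function(data, spec = model_spec(),
                              settings = mcmc_settings(),
                              priors = default_priors()) {
  if (isTRUE(spec$phylo))
    ps_stop("phylo spec requires fit_interspecific_phylo()", "pollisize_validation_error")
  fit_glmm_impl(data, spec, settings, priors, C_species = NULL)
}

#' Fit the phylogenetically constrained interspecific model
#'
#' As [fit_interspecific()], but the species random effect is constrained by
#' a phylogeny: effects are jointly multivariate normal with covariance
#' `sd_species^2 * C`, where `C` is the tree's shared-path-length matrix
#' rescaled to unit diagonal (see [phylo_covariance()]). One effect is
#' estimated per species (the tree has one tip per species); the region
#' intercept stays i.i.d. On a star phylogeny with equal tip lengths `C` is
#' the identity and the model coincides with the taxonomic one.
#'
#' @inheritParams fit_interspecific
#' @param tree A `phylo` object whose tips cover every species in `data`
#'   (spaces in species names match underscores in tip labels). Species
#'   missing from the tree are an error that names them, so the caller can
#'   exclude them explicitly.
#' @return An `itd_glmm` with `phylo = TRUE`.
#' @export
fit_interspecific_phylo <- function(data, spec = model_spec(), tree,
                                    settings = mcmc_settings(),
                                    priors = default_priors()) {
  validate_tree(tree)
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    ps_stop("tree must have positive branch lengths", "pollisize_validation_error")
  if (is.null(spec$random))
    ps_stop("phylogenetic model requires the region/species random term",
            "pollisize_validation_error")
  sp <- unique(gsub(" ", "_", data$species))
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp))
    ps_stop(sprintf("species missing from tree (%d): %s",
                    length(missing_sp), paste(missing_sp, collapse = ", ")),
            "pollisize_validation_error", species = missing_sp)
  extra <- setdiff(tree$tip.label, sp)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  C <- stats::cov2cor(ape::vcv.phylo(tree))
  spec$phylo <- TRUE
  fit_glmm_impl(data, spec, settings, priors, C_species = C)
}

fit_glmm_impl <- function(data, spec, settings, priors, C_species = NULL) {
  des <- build_design(data, spec)
  has_random <- !is.null(spec$random)
  phylo <- !is.null(C_species)
  N <- length(des$y); P <- ncol(des$X)
  has_slopes <- P > 1
  ctr <- if (has_slopes) colMeans(des$X[, -1, drop = FALSE]) else numeric()
  dat <- list(N = N, y = des$y,
              prec_intercept = 1 / priors$intercept_sd^2,
              prec_sd = 1 / priors$sd_sd^2)
  if (has_slopes) {
    dat$Xs <- sweep(des$X[, -1, drop = FALSE], 2, ctr)
    dat$P <- P - 1L
    dat$prec_slope <- 1 / priors$slope_sd^2
  }
  monitors <- c("g1", if (has_slopes) "gs", "sigma")
  region_levels <- species_keys <- NULL
  if (has_random) {
    region_levels <- sort(unique(des$region))
    if (phylo) {
      species_keys <- rownames(C_species)
      sp_idx <- match(des$species, species_keys)
      dat$Vinv <- solve(C_species)
      dat$region <- match(des$region, region_levels)
      # home (modal) region of each species, for hierarchical centering
      dat$regof <- vapply(species_keys, function(s) {
        r <- des$region[des$species == s]
        match(names(sort(-table(r)))[1], region_levels)
      }, integer(1))
    } else {
      species_keys <- sort(unique(paste(des$region, des$species, sep = "|")))
      sp_idx <- match(paste(des$region, des$species, sep = "|"), species_keys)
      dat$regof <- match(sub("\\|.*", "", species_keys), region_levels)
    }
    dat$sp <- sp_idx
    dat$R <- length(region_levels)
    dat$S <- length(species_keys)
    monitors <- c(monitors, "u", "v", "sd_region", "sd_species")
  }
  model_str <- jags_model_string(has_random, phylo, has_slopes)
  samples <- run_jags(dat, model_str, monitors, settings)

  # per chain: transform the hierarchically centered draws back to the
  # user-facing basis (intercept + zero-mean offsets, uncentered covariates)
  coef_names <- colnames(des$X)
  col_of <- function(m, base, idx, n_all) {
    # JAGS drops the index brackets for length-1 vectors
    if (n_all == 1) m[, base] else m[, sprintf("%s[%d]", base, idx)]
  }
  chains <- lapply(samples, function(s) {
    m <- as.matrix(s)
    ndr <- nrow(m)
    gs <- if (has_slopes)
      vapply(seq_len(P - 1), function(p) col_of(m, "gs", p, P - 1), numeric(ndr))
    else matrix(0, ndr, 0)
    g1 <- m[, "g1"]
    intercept <- g1 - if (has_slopes) as.vector(gs %*% ctr) else 0
    out <- cbind(intercept, gs)
    colnames(out) <- coef_names
    if (has_random) {
      R <- length(region_levels); S <- length(species_keys)
      u <- vapply(seq_len(R), function(j) col_of(m, "u", j, R), numeric(ndr))
      v <- vapply(seq_len(S), function(k) col_of(m, "v", k, S), numeric(ndr))
      u_off <- u - g1
      v_off <- v - u[, dat$regof, drop = FALSE]
      colnames(u_off) <- paste0("u:", region_levels)
      colnames(v_off) <- paste0("v:", species_keys)
      out <- cbind(out, u_off, v_off,
                   sd_region = m[, "sd_region"], sd_species = m[, "sd_species"])
    }
    cbind(out, sigma = m[, "sigma"])
  })
  draws <- do.call(rbind, chains)
  nm <- colnames(draws)

  rhat <- split_rhat(chains)
  names(rhat) <- nm
  # deterministic nodes of a phylo fit (v) can be perfectly recovered from z;
  # R-hat on them is still meaningful, keep all.
  converged <- all(rhat <= 1.05, na.rm = TRUE)
  fit <- structure(list(
    spec = spec, draws = draws, n_chains = settings$chains,
    n_kept = settings$iterations - settings$burn_in,
    coef_names = coef_names, formula = des$formula, levels = des$levels,
    region_levels = region_levels, species_keys = species_keys,
    phylo = phylo, C_species = C_species,
    settings = settings, priors = priors,
    diagnostics = list(rhat = rhat, n_divergent = 0L,
                       max_rhat = suppressWarnings(max(rhat, na.rm = TRUE))),
    converged = converged,
    data_fingerprint = fingerprint_data(
      data[, intersect(c("species", "region", "group", "sex", "itd_mm", "dry_weight_mg"),
                       names(data)), drop = FALSE])
  ), class = "itd_glmm")
  if (!converged)
    warning(sprintf("fit flagged as non-converged: max split-R-hat = %.3f (threshold 1.05)",
                    fit$diagnostics$max_rhat), call. = FALSE)
  fit
}

#' @export
print.itd_glmm <- function(x, ...) {
  cat("<itd_glmm>", format_model_spec(x$spec), "\n")
  cat(sprintf("  %d chains x %d kept draws; max split-R-hat %.3f (%s)\n",
              x$n_chains, x$n_kept, x$diagnostics$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  s <- summary(x)
  print(s, digits = 3)
  invisible(x)
}

#' Posterior summary of the fixed effects and SDs
#' @param object An `itd_glmm`.
#' @param ... Unused.
#' @return Data frame of posterior median, mean, SD and 90% interval per
#'   fixed coefficient and variance-component SD.
#' @export
summary.itd_glmm <- function(object, ...) {
  keep <- c(object$coef_names, "sigma",
            if (!is.null(object$region_levels)) c("sd_region", "sd_species"))
  d <- object$draws[, keep, drop = FALSE]
  data.frame(parameter = keep,
             median = apply(d, 2, median),
             mean = colMeans(d),
             sd = apply(d, 2, sd),
             lo90 = apply(d, 2, quantile, 0.05),
             hi90 = apply(d, 2, quantile, 0.95),
             rhat = object$diagnostics$rhat[keep],
             row.names = NULL)
}

# Linear-predictor draws for rows of `data` under a fit, using the stored
# random-intercept draws (training levels must cover the data). Returns an
# N x ndraw matrix.
linpred_draws <- function(fit, data) {
  des <- build_design_for_predict(fit, data)
  eta <- des$X %*% t(fit$draws[, fit$coef_names, drop = FALSE])
  if (!is.null(fit$region_levels)) {
    u_cols <- paste0("u:", des$region)
    v_cols <- paste0("v:", des$key)
    if (any(!u_cols %in% colnames(fit$draws)))
      ps_stop("data contains regions unseen by the fit", "pollisize_validation_error")
    if (any(!v_cols %in% colnames(fit$draws)))
      ps_stop("data contains species unseen by the fit", "pollisize_validation_error")
    eta <- eta + t(fit$draws[, u_cols, drop = FALSE]) + t(fit$draws[, v_cols, drop = FALSE])
  }
  eta
}

# Rebuild the fixed design for new rows using the training factor levels.
build_design_for_predict <- function(fit, data) {
  if (any(data$itd_mm <= 0) || any(is.na(data$itd_mm)))
    ps_stop("itd_mm must be present and positive", "pollisize_validation_error")
  md <- data.frame(ln_itd = log(data$itd_mm))
  for (fac in names(fit$levels)) {
    if (!fac %in% names(data) || any(is.na(data[[fac]])))
      ps_stop(sprintf("missing required covariate '%s'", fac), "pollisize_validation_error")
    unseen <- setdiff(unique(data[[fac]]), fit$levels[[fac]])
    if (length(unseen))
      ps_stop(sprintf("unseen %s level(s): %s", fac, paste(unseen, collapse = ", ")),
              "pollisize_validation_error")
    md[[fac]] <- factor(data[[fac]], levels = fit$levels[[fac]])
  }
  X <- stats::model.matrix(fit$formula, md)
  sp <- gsub(" ", "_", data$species %||% rep(NA_character_, nrow(data)))
  key <- if (isTRUE(fit$phylo)) sp else paste(data$region, sp, sep = "|")
  list(X = X, region = data$region, species = sp, key = key)
}
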