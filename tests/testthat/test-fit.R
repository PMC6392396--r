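test_that("model_spec enforces its term grammar", {
  expect_error(model_spec("sex:ln_itd"), "requires the sex main effect")
  expect_error(model_spec("group:ln_itd"), "requires the group main effect")
  expect_error(model_spec("colour"), "unknown fixed terms")
  expect_error(model_spec(random = "site"), "region/species")
  expect_match(format_model_spec(model_spec(c("group", "sex", "group:ln_itd", "sex:ln_itd"))),
               "Group:ln\\(ITD\\).*\\(1 \\| Region/Species\\)")
})

test_that("mcmc_settings validates its invariants", {
  expect_error(mcmc_settings(iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_settings(adapt_delta = 1.2), "adapt_delta")
  s <- mcmc_settings()
  expect_equal(s$iterations, 2000L)
  expect_equal(s$burn_in, 1000L)
  expect_equal(s$chains, 4L)
})

test_that("a near-constant response with an intercept-only model concentrates at it", {
  df <- small_specimens(seed = 2)
  set.seed(1)
  df$dry_weight_mg <- exp(1.7 + rnorm(nrow(df), 0, 0.005))
  spec <- model_spec(character(), random = NULL, itd_slope = FALSE)
  fit <- suppressWarnings(fit_interspecific(df, spec, quick_settings(seed = 5)))
  s <- summary(fit)
  expect_lt(abs(s$median[s$parameter == "(Intercept)"] - 1.7), 0.01)
  expect_lt(s$median[s$parameter == "sigma"], 0.02)
})

test_that("a sex term with single-sex data is a singular-design error", {
  df <- small_specimens(seed = 3)
  df <- df[df$sex == "female", ]
  err <- tryCatch(fit_interspecific(df, model_spec("sex"), quick_settings()),
                  error = identity)
  expect_s3_class(err, "pollisize_singular_error")
  expect_match(conditionMessage(err), "sex")
})

test_that("records missing the response or predictor are refused", {
  df <- small_specimens(seed = 3)
  df$dry_weight_mg[5] <- NA
  expect_error(fit_interspecific(df, model_spec(), quick_settings()),
               "dry_weight_mg")
})

test_that("the fit is exactly reproducible given the seed", {
  df <- small_specimens(seed = 6, species_per_group = 10)
  f1 <- suppressWarnings(fit_interspecific(df, model_spec("sex"), quick_settings(seed = 21)))
  f2 <- suppressWarnings(fit_interspecific(df, model_spec("sex"), quick_settings(seed = 21)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_interspecific(df, model_spec("sex"), quick_settings(seed = 22)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the posterior recovers the generative slope and sex offset", {
  sim <- generate_specimens(generator_truth(seed = 17))
  fit <- suppressWarnings(
    fit_interspecific(sim$specimens, model_spec("sex"), quick_settings(seed = 17)))
  s <- summary(fit)
  beta_row <- s[s$parameter == "ln_itd", ]
  expect_lt(abs(beta_row$median - 2.6), 4 * beta_row$sd)
  sex_row <- s[s$parameter == "sexmale", ]
  expect_lt(abs(sex_row$median - (-0.3)), 4 * sex_row$sd)
  # residual SD is well identified
  expect_lt(abs(s$median[s$parameter == "sigma"] - 0.3), 0.05)
})

test_that("every sampled parameter carries an R-hat and variance draws are positive", {
  df <- small_specimens(seed = 8, species_per_group = 8)
  fit <- suppressWarnings(fit_interspecific(df, model_spec(), quick_settings(seed = 2)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_length(fit$diagnostics$rhat, ncol(fit$draws))
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_true(all(fit$draws[, "sd_region"] >= 0))
  expect_true(all(fit$draws[, "sd_species"] >= 0))
  expect_identical(fit$diagnostics$n_divergent, 0L)
})

test_that("registry equations give closed-form predictions", {
  eq <- allometric_equation("fx", "dry_weight_mg", "itd_mm",
                            alpha_ln = 1, beta = 2,
                            scope = list(taxon = "Apoidea"))
  got <- predict_dry_weight(eq, data.frame(itd_mm = c(1, 2)))
  expect_equal(got$point_mg, c(exp(1), exp(1 + 2 * log(2))), tolerance = 1e-12)
  expect_equal(got$point_mg[2], exp(1) * 4, tolerance = 1e-12)
})

test_that("ln point prediction of a fixed-effects-only equation is affine in ln ITD", {
  eq <- allometric_equation("fx", "dry_weight_mg", "itd_mm", 0.7, 2.2,
                            scope = list(taxon = "Apoidea"))
  grid <- exp(seq(log(0.5), log(8), length.out = 9))
  p <- predict_dry_weight(eq, data.frame(itd_mm = grid))$point_mg
  second_diff <- diff(diff(log(p)))
  expect_true(all(abs(second_diff) < 1e-10))
})

test_that("GLMM point predictions are monotone in ITD and near-affine on the ln scale", {
  df <- small_specimens(seed = 12)
  fit <- suppressWarnings(fit_interspecific(df, model_spec(), quick_settings(seed = 3)))
  grid <- data.frame(itd_mm = exp(seq(log(0.8), log(6), length.out = 12)),
                     species = df$species[1], region = df$region[1])
  p <- predict_dry_weight(fit, grid)$point_mg
  expect_true(all(diff(p) > 0))
  # exact per draw, approximately affine after taking the posterior median
  second_diff <- diff(diff(log(p)))
  expect_true(all(abs(second_diff) < 0.02))
})

test_that("unseen species and regions are integrated, with flags and a warning", {
  df <- small_specimens(seed = 13, n_regions = 3)  # South America stays unseen
  fit <- suppressWarnings(fit_interspecific(df, model_spec(), quick_settings(seed = 4)))
  nd <- data.frame(itd_mm = 2.5,
                   species = c(df$species[1], "Xylocopa nova"),
                   region = df$region[1])
  set.seed(1)
  p <- predict_dry_weight(fit, nd)
  expect_equal(p$flags, c("", "new_species"))
  expect_gt(p$se_mg[2], p$se_mg[1])  # integrating widens the uncertainty
  nd2 <- data.frame(itd_mm = 2.5, species = "Xylocopa nova", region = "South America")
  expect_warning(p2 <- predict_dry_weight(fit, nd2), "unseen")
  expect_match(p2$flags, "new_region")
  expect_true(p2$lo90 <= p2$point_mg && p2$point_mg <= p2$hi90)
})

test_that("missing covariates and non-positive ITD are prediction errors", {
  df <- small_specimens(seed = 13)
  fit <- suppressWarnings(fit_interspecific(df, model_spec("sex"), quick_settings(seed = 4)))
  expect_error(predict_dry_weight(fit, data.frame(itd_mm = 2, species = "x", region = "Europe")),
               "sex")
  expect_error(predict_dry_weight(fit, data.frame(itd_mm = -2, sex = "female",
                                                  species = "x", region = "Europe")),
               "positive")
})

test_that("phylogenetic fit refuses species missing from the tree, naming them", {
  df <- small_specimens(seed = 14, species_per_group = 8)
  tree <- star_tree(df[df$species != unique(df$species)[1], ])
  err <- tryCatch(
    fit_interspecific_phylo(df, model_spec(), tree, quick_settings()),
    error = identity)
  expect_s3_class(err, "pollisize_validation_error")
  expect_match(conditionMessage(err), gsub(" ", "_", unique(df$species)[1]))
})

test_that("a star phylogeny reproduces the i.i.d. species model", {
  df <- small_specimens(seed = 3)
  st <- quick_settings(seed = 15, iterations = 1500, burn_in = 500)
  f_iid <- suppressWarnings(fit_interspecific(df, model_spec("sex"), st))
  f_star <- suppressWarnings(
    fit_interspecific_phylo(df, model_spec("sex"), star_tree(df), st))
  s1 <- summary(f_iid); s2 <- summary(f_star)
  for (par in c("ln_itd", "sexmale", "sigma", "sd_species")) {
    mc_err <- 3 * sqrt(s1$sd[s1$parameter == par]^2 + s2$sd[s2$parameter == par]^2) /
      sqrt(st$chains * (st$iterations - st$burn_in) / 10)  # generous ESS guess
    expect_lt(abs(s1$median[s1$parameter == par] - s2$median[s2$parameter == par]),
              max(mc_err, 0.05), label = par)
  }
})

test_that("serialize and load round-trip a fit for identical predictions", {
  df <- small_specimens(seed = 19, species_per_group = 6)
  fit <- suppressWarnings(fit_interspecific(df, model_spec("sex"), quick_settings(seed = 6)))
  dir <- tempfile()
  serialize_fit(fit, dir)
  fit2 <- load_fit(dir)
  nd <- df[1:4, ]
  set.seed(99)  # predictive intervals draw residual noise
  p1 <- predict_dry_weight(fit, nd)
  set.seed(99)
  p2 <- predict_dry_weight(fit2, nd)
  expect_equal(p1$point_mg, p2$point_mg, tolerance = 1e-12)
  expect_equal(p1$lo90, p2$lo90, tolerance = 1e-12)
  expect_identical(fit2$data_fingerprint, fit$data_fingerprint)
})
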