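#' Define the generative truth for synthetic specimen tables
#'
#' Parameters of the synthetic study the generator emulates: per-(group,
#' sex) power-law coefficients, region and species-within-region random
#' intercept SDs, ln-scale residual noise, and a lognormal ITD distribution
#' per species. Defaults describe one taxonomic group sampled across the
#' four biogeographic regions, 40 species with 5 specimens per sex
#' (10 per species), exponent 2.6 with a female-biased sex offset of -0.3
#' on the ln intercept, random-effect SDs 0.2 (region) and 0.4 (species)
#' and residual SD 0.3 — curvature and dispersion in the range observed for
#' real bees, but synthetic values, not estimates.
#'
#' @param n_regions Regions used (1..4, labels from the controlled
#'   vocabulary).
#' @param n_groups Taxonomic groups (families); default 1.
#' @param species_per_group Species per group; default 40.
#' @param specimens_per_species_sex Specimens per species and sex; default 5.
#' @param lnalpha Baseline ln-scale intercept (first group, female).
#' @param beta Allometric exponent (first group); default 2.6.
#' @param group_lnalpha_offsets,group_beta_offsets Per-group deviations from
#'   the baseline (length `n_groups`, first entry 0).
#' @param sex_offset Additive ln-intercept offset for males; default -0.3.
#' @param sex_slope_offset Additive exponent offset for males; default 0.
#' @param region_sd,species_sd,resid_sd Random-intercept and residual SDs on
#'   the ln scale.
#' @param itd_median_mm,itd_lnsd Lognormal ITD distribution of species
#'   medians; default median 2 mm, ln-SD 0.5.
#' @param itd_jitter_lnsd Within-species ln-scale ITD jitter; default 0.1.
#' @param seed Integer seed.
#' @return List of class `generator_truth`.
#' @export
generator_truth <- function(n_regions = 4, n_groups = 1, species_per_group = 40,
                            specimens_per_species_sex = 5,
                            lnalpha = 1.0, beta = 2.6,
                            group_lnalpha_offsets = rep(0, n_groups),
                            group_beta_offsets = rep(0, n_groups),
                            sex_offset = -0.3, sex_slope_offset = 0,
                            region_sd = 0.2, species_sd = 0.4, resid_sd = 0.3,
                            itd_median_mm = 2, itd_lnsd = 0.5,
                            itd_jitter_lnsd = 0.1, seed = 1) {
  if (any(c(n_regions, n_groups, species_per_group, specimens_per_species_sex) < 1))
    ps_stop("counts must be >= 1", "pollisize_validation_error")
  if (n_regions > length(REGIONS))
    ps_stop(sprintf("at most %d regions available", length(REGIONS)), "pollisize_validation_error")
  if (any(c(region_sd, species_sd, resid_sd, itd_lnsd, itd_jitter_lnsd) < 0))
    ps_stop("SDs must be >= 0", "pollisize_validation_error")
  if (length(group_lnalpha_offsets) != n_groups || length(group_beta_offsets) != n_groups)
    ps_stop("group offset vectors must have length n_groups", "pollisize_validation_error")
  structure(as.list(environment()), class = "generator_truth")
}

#' Generate a synthetic specimen table with known truth
#'
#' Draws a specimen table from the hierarchical model the package fits:
#' `ln(weight) = lnalpha(group, sex) + beta(group, sex) * ln(ITD) + region
#' effect + species effect + Normal(0, resid_sd)`, with species ITD medians
#' lognormal and per-specimen lognormal jitter. Separate named random
#' substreams (ITD, effects, noise) are derived from the seed, so adding a
#' field to the generator never perturbs existing draws. Deterministic
#' given the seed, and the output always passes [validate_specimens()].
#'
#' @param truth A [generator_truth()].
#' @return List with `specimens` (data frame in the canonical specimen
#'   schema) and `truth` (the input truth plus the realized region and
#'   species effects and assignments, for parameter-recovery checks).
#' @export
generate_specimens <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  t <- truth
  regions <- REGIONS[seq_len(t$n_regions)]
  groups <- paste0("Family", LETTERS[seq_len(t$n_groups)])
  n_species <- t$n_groups * t$species_per_group
  species <- sprintf("Genus%02d sp%02d",
                     rep(seq_len(n_species)), rep(1L, n_species))
  # one genus per species keeps the genus->species map trivial for trees
  genus <- sprintf("Genus%02d", seq_len(n_species))
  sp_group <- rep(groups, each = t$species_per_group)

  set.seed(substream_seed(t$seed, "effects"))
  region_eff <- setNames(rnorm(t$n_regions, 0, t$region_sd), regions)
  sp_region <- setNames(sample(regions, n_species, replace = TRUE), species)
  species_eff <- setNames(rnorm(n_species, 0, t$species_sd), species)

  set.seed(substream_seed(t$seed, "itd"))
  sp_itd_median <- setNames(rlnorm(n_species, log(t$itd_median_mm), t$itd_lnsd), species)

  per <- t$specimens_per_species_sex
  n_rows <- n_species * 2L * per
  idx_sp <- rep(seq_len(n_species), each = 2L * per)
  sex <- rep(rep(SEXES, each = per), times = n_species)

  set.seed(substream_seed(t$seed, "itd_jitter"))
  itd <- sp_itd_median[idx_sp] * exp(rnorm(n_rows, 0, t$itd_jitter_lnsd))

  g_idx <- match(sp_group[idx_sp], groups)
  lnalpha_i <- t$lnalpha + t$group_lnalpha_offsets[g_idx] +
    ifelse(sex == "male", t$sex_offset, 0)
  beta_i <- t$beta + t$group_beta_offsets[g_idx] +
    ifelse(sex == "male", t$sex_slope_offset, 0)

  set.seed(substream_seed(t$seed, "noise"))
  eps <- rnorm(n_rows, 0, t$resid_sd)
  ln_w <- lnalpha_i + beta_i * log(itd) +
    region_eff[sp_region[idx_sp]] + species_eff[idx_sp] + eps

  df <- data.frame(
    specimen_id = sprintf("S%05d", seq_len(n_rows)),
    species = species[idx_sp],
    genus = genus[idx_sp],
    group = sp_group[idx_sp],
    sex = sex,
    region = unname(sp_region[idx_sp]),
    itd_mm = unname(itd),
    dry_weight_mg = exp(ln_w),
    body_length_mm = NA_real_, pin_type = NA_character_,
    latitude = NA_real_, longitude = NA_real_,
    stringsAsFactors = FALSE)
  t$region_effects <- region_eff
  t$species_effects <- species_eff
  t$species_region <- sp_region
  t$species_group <- setNames(sp_group, species)
  t$species_itd_median <- sp_itd_median
  list(specimens = df, truth = t)
}

#' Generate a random grafted phylogeny
#'
#' Simulates an ultrametric genus backbone (coalescent topology, depth
#' rescaled to 1) and grafts `species_per_genus` species tips onto each
#' genus as equal-length polytomies via [graft_species_polytomies()].
#' Species tips are labelled `Genus01_sp01`, ...
#'
#' @param n_genera Number of backbone genera (>= 2).
#' @param species_per_genus Species per genus (scalar or length `n_genera`).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object.
#' @export
generate_tree <- function(n_genera, species_per_genus = 1, seed = 1) {
  if (n_genera < 2) ps_stop("need at least 2 genera", "pollisize_validation_error")
  per <- rep(species_per_genus, length.out = n_genera)
  if (any(per < 1)) ps_stop("species_per_genus must be >= 1", "pollisize_validation_error")
  set.seed(substream_seed(seed, "tree"))
  backbone <- ape::rcoal(n_genera, tip.label = sprintf("Genus%02d", seq_len(n_genera)))
  backbone$edge.length <- backbone$edge.length /
    max(ape::node.depth.edgelength(backbone))
  map <- do.call(rbind, lapply(seq_len(n_genera), function(i) {
    data.frame(species = sprintf("Genus%02d_sp%02d", i, seq_len(per[i])),
               genus = sprintf("Genus%02d", i))
  }))
  graft_species_polytomies(backbone, map)$tree
}

#' Simulate a trait with tunable phylogenetic signal
#'
#' Draws one value per tip from a multivariate normal whose covariance is
#' the tree's shared-path-length matrix with off-diagonals scaled by
#' `lambda_true` (Pagel's lambda transform): `lambda_true = 1` is Brownian
#' motion, `0` is independent tips.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian rate; default 1.
#' @param lambda_true Signal strength in \[0, 1\].
#' @param seed Integer seed.
#' @return Named numeric vector (tip label -> trait value).
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, lambda_true = 1, seed = 1) {
  if (lambda_true < 0 || lambda_true > 1)
    ps_stop("lambda_true must be in [0, 1]", "pollisize_validation_error")
  C <- ape::vcv.phylo(tree)
  V <- lambda_true * C
  diag(V) <- diag(C)
  set.seed(substream_seed(seed, "bm_trait"))
  x <- drop(rmvnorm_chol(1, rep(0, nrow(V)), sigma2 * V))
  setNames(x, rownames(C))
}
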