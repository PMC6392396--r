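# Shared fixtures and reduced sampler settings for the test suite. The
# sampler settings keep each JAGS run around a second; recovery-style checks
# that need stable posteriors use slightly longer runs.

quick_settings <- function(seed = 1, chains = 2, iterations = 800, burn_in = 400) {
  mcmc_settings(iterations = iterations, burn_in = burn_in, chains = chains,
                seed = seed)
}

# A small synthetic study: 20 species x 4 regions x (4+4) specimens.
small_truth <- function(seed = 1, species_per_group = 20,
                        specimens_per_species_sex = 4, ...) {
  generator_truth(species_per_group = species_per_group,
                  specimens_per_species_sex = specimens_per_species_sex,
                  seed = seed, ...)
}

small_specimens <- function(seed = 1, ...) {
  generate_specimens(small_truth(seed = seed, ...))$specimens
}

# A minimal hand-built specimen table (3 valid rows).
tiny_specimens <- function() {
  data.frame(
    specimen_id = c("S1", "S2", "S3"),
    species = c("Apis mellifera", "Apis mellifera", "Bombus terrestris"),
    genus = c("Apis", "Apis", "Bombus"),
    group = "Apidae",
    sex = c("female", "male", "female"),
    region = c("Europe", "Europe", "Europe"),
    itd_mm = c(3.1, 2.9, 4.4),
    dry_weight_mg = c(35.2, 28.4, 110.5),
    body_length_mm = NA_real_, pin_type = NA_character_,
    latitude = NA_real_, longitude = NA_real_,
    stringsAsFactors = FALSE)
}

write_tmp_csv <- function(df) {
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(df, tf, row.names = FALSE, na = "")
  tf
}

# Star phylogeny over the species of a specimen table (unit tip lengths).
star_tree <- function(data) {
  sp <- gsub(" ", "_", sort(unique(data$species)))
  ape::read.tree(text = paste0("(", paste0(sp, ":1", collapse = ","), ");"))
}

expect_no_issues <- function(df) {
  testthat::expect_identical(nrow(validate_specimens(df)), 0L)
}
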