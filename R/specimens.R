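#' Read a specimen table
#'
#' Reads a CSV of measured specimens into a validated data frame. One row is
#' one pinned insect with its taxonomy, sex, biogeographic region of origin,
#' intertegular distance (ITD, mm) and optional dry weight (mg), body length
#' (mm), pin type and coordinates.
#'
#' Mandatory columns (after mapping): `specimen_id`, `species`, `genus`,
#' `group` (bee family or hoverfly subfamily), `sex` (`female`/`male`),
#' `region` (one of Australia, Europe, North America, South America) and
#' `itd_mm`. Optional: `dry_weight_mg`, `body_length_mm`, `pin_type`,
#' `latitude`, `longitude`. Files with other headers are loaded by supplying
#' `mapping`, a named character vector `c(canonical = "file_column")`.
#'
#' Validation is collect-then-report: every offending row is listed in the
#' error (and available via the condition's `issues` data frame), rather than
#' failing on the first bad row, so a whole curation pass can be fixed at
#' once.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param mapping Optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return A `data.frame` of validated specimen records with canonical
#'   column names and types.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(specimen_id = "S1", species = "Apis mellifera",
#'                      genus = "Apis", group = "Apidae", sex = "female",
#'                      region = "Europe", itd_mm = 3.1,
#'                      dry_weight_mg = 35.2), tf, row.names = FALSE)
#' spec <- read_specimens(tf)
#' @export
read_specimens <- function(path, mapping = NULL) {
  if (!file.exists(path)) ps_stop(sprintf("file not found: %s", path), "pollisize_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(df))
    if (length(missing_src))
      ps_stop(sprintf("mapped columns absent from file: %s",
                      paste(missing_src, collapse = ", ")), "pollisize_io_error")
    for (canon in names(mapping)) names(df)[names(df) == mapping[[canon]]] <- canon
  }
  mandatory <- c("specimen_id", "species", "genus", "group", "sex", "region", "itd_mm")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    ps_stop(sprintf("mandatory columns missing: %s", paste(missing_cols, collapse = ", ")),
            "pollisize_io_error")
  optional <- c("dry_weight_mg", "body_length_mm", "pin_type", "latitude", "longitude")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA
  for (col in c("itd_mm", "dry_weight_mg", "body_length_mm", "latitude", "longitude"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("specimen_id", "species", "genus", "group", "sex", "region", "pin_type")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!nzchar(trimws(df[[col]] %||% ""))] <- NA_character_
  }
  df <- df[, c(mandatory, optional)]
  issues <- validate_specimens(df)
  if (nrow(issues)) {
    msg <- paste0(
      "specimen table failed validation (", nrow(issues), " problem",
      if (nrow(issues) > 1) "s" else "", "):\n",
      paste(sprintf("  row %d [%s]: %s", issues$row, issues$field, issues$problem),
            collapse = "\n"))
    ps_stop(msg, "pollisize_validation_error", issues = issues)
  }
  df
}

#' Validate specimen records
#'
#' Checks every row of a specimen table against the record invariants
#' (positive measurements, controlled sex/region vocabularies, one genus per
#' species) and returns all problems found.
#'
#' @param df A specimen data frame as produced by [read_specimens()] or
#'   [generate_specimens()].
#' @return A data frame with columns `row`, `field`, `problem`; zero rows if
#'   the table is valid.
#' @export
validate_specimens <- function(df) {
  issues <- list()
  add <- function(rows, field, problem) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(row = rows, field = field,
                                                   problem = problem)
  }
  n <- nrow(df)
  rows <- seq_len(n)
  for (field in c("specimen_id", "species", "genus", "group", "sex", "region")) {
    add(rows[is.na(df[[field]])], field, "missing value")
  }
  add(rows[!is.na(df$sex) & !df$sex %in% SEXES], "sex",
      sprintf("not one of {%s}", paste(SEXES, collapse = ", ")))
  add(rows[!is.na(df$region) & !df$region %in% REGIONS], "region",
      sprintf("not one of {%s}", paste(REGIONS, collapse = ", ")))
  add(rows[is.na(df$itd_mm)], "itd_mm", "missing or non-numeric")
  add(rows[!is.na(df$itd_mm) & df$itd_mm <= 0], "itd_mm", "must be > 0")
  add(rows[!is.na(df$dry_weight_mg) & df$dry_weight_mg <= 0], "dry_weight_mg", "must be > 0")
  add(rows[!is.na(df$body_length_mm) & df$body_length_mm <= 0], "body_length_mm", "must be > 0")
  # species must imply a unique genus within one table
  ok <- !is.na(df$species) & !is.na(df$genus)
  if (any(ok)) {
    tab <- unique(data.frame(species = df$species[ok], genus = df$genus[ok]))
    dup_sp <- tab$species[duplicated(tab$species)]
    add(rows[ok & df$species %in% dup_sp], "genus",
        "species mapped to more than one genus in this table")
  }
  if (!length(issues))
    return(data.frame(row = integer(), field = character(), problem = character()))
  out <- do.call(rbind, issues)
  out[order(out$row), , drop = FALSE]
}

#' Write a specimen table
#'
#' Writes specimens back to CSV with full numeric precision, so that a write
#' followed by [read_specimens()] reproduces every field bit-identically.
#'
#' @param df Specimen data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(df, path) {
  out <- df
  for (col in names(out)) if (is.numeric(out[[col]])) out[[col]] <- fmt_full(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a pin-weight table
#'
#' Pinned specimens are weighed together with their pin; the mean weight of a
#' sample of pins of each type is later subtracted. The table has columns
#' `pin_type`, `mean_mg`, `se_mg`, `n`.
#'
#' @param path CSV path.
#' @return Data frame with columns `pin_type`, `mean_mg`, `se_mg`, `n`.
#' @export
read_pin_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("pin_type", "mean_mg", "se_mg", "n")
  if (!all(req %in% names(df)))
    ps_stop(sprintf("pin table must have columns %s", paste(req, collapse = ", ")),
            "pollisize_io_error")
  if (any(df$mean_mg < 0, na.rm = TRUE)) ps_stop("pin mean_mg must be >= 0", "pollisize_validation_error")
  if (any(df$n < 1, na.rm = TRUE)) ps_stop("pin n must be >= 1", "pollisize_validation_error")
  if (anyDuplicated(df$pin_type)) ps_stop("duplicate pin_type in pin table", "pollisize_validation_error")
  df
}

#' Subtract pin weight from measured dry weight
#'
#' For specimens weighed on their pin, subtracts the mean weight of the
#' specimen's pin type from `dry_weight_mg`. Rows without a `pin_type` are
#' left untouched. Provenance is recorded in two audit columns:
#' `pin_corrected` (logical) and `pin_mean_subtracted_mg`, and a table that
#' has already been corrected refuses a second pass (the operation is not
#' idempotent for nonzero pin weights).
#'
#' @param df Specimen data frame.
#' @param pins Pin table from [read_pin_table()] (or a data frame with the
#'   same columns).
#' @return The data frame with corrected weights and audit columns.
#' @export
apply_pin_correction <- function(df, pins) {
  if (isTRUE(any(df$pin_corrected)))
    ps_stop("table already pin-corrected (pin_corrected == TRUE present); refusing to subtract twice",
            "pollisize_validation_error")
  needs <- !is.na(df$pin_type)
  unknown <- setdiff(unique(df$pin_type[needs]), pins$pin_type)
  if (length(unknown))
    ps_stop(sprintf("pin types absent from pin table: %s", paste(unknown, collapse = ", ")),
            "pollisize_validation_error")
  no_weight <- needs & is.na(df$dry_weight_mg)
  if (any(no_weight))
    ps_stop(sprintf("rows with pin_type but no dry weight: %s",
                    paste(which(no_weight), collapse = ", ")),
            "pollisize_validation_error")
  pin_mean <- setNames(pins$mean_mg, pins$pin_type)
  sub <- ifelse(needs, pin_mean[df$pin_type], 0)
  corrected <- df$dry_weight_mg - ifelse(is.na(sub), 0, sub)
  bad <- needs & !is.na(corrected) & corrected <= 0
  if (any(bad))
    ps_stop(sprintf(
      "pin correction yields non-positive dry weight (implausible pin assignment) in rows: %s",
      paste(which(bad), collapse = ", ")),
      "pollisize_validation_error", rows = which(bad))
  df$dry_weight_mg <- corrected
  df$pin_corrected <- needs
  df$pin_mean_subtracted_mg <- ifelse(needs, sub, 0)
  df
}

#' Introduced-range exclusion rules
#'
#' The default list removes specimens of five bee species from regions where
#' they are introduced rather than native, so the fitted allometry reflects
#' native-range variation: *Andrena wilkella*, *Halictus rubicundus*,
#' *Lasioglossum leucozonium* and *Anthidium manicatum* from North America,
#' and *Apis mellifera* from Australia.
#'
#' @return Data frame with columns `species`, `excluded_region`.
#' @export
default_exclusion_rules <- function() {
  data.frame(
    species = c("Andrena wilkella", "Halictus rubicundus",
                "Lasioglossum leucozonium", "Anthidium manicatum",
                "Apis mellifera"),
    excluded_region = c("North America", "North America", "North America",
                        "North America", "Australia"),
    stringsAsFactors = FALSE
  )
}

#' Remove specimens from their introduced ranges
#'
#' Splits a specimen table into records kept and records removed by the
#' exclusion rules: a record is removed iff its (species, region) pair
#' matches a rule. Order is preserved in both parts.
#'
#' @param df Specimen data frame.
#' @param rules Data frame with columns `species`, `excluded_region`;
#'   defaults to [default_exclusion_rules()].
#' @return A list with elements `kept` and `removed`.
#' @export
apply_exclusions <- function(df, rules = default_exclusion_rules()) {
  if (!nrow(rules)) return(list(kept = df, removed = df[0, , drop = FALSE]))
  bad_region <- setdiff(rules$excluded_region, REGIONS)
  if (length(bad_region))
    ps_stop(sprintf("exclusion rule region not in vocabulary: %s",
                    paste(bad_region, collapse = ", ")), "pollisize_validation_error")
  key <- paste(df$species, df$region, sep = "\r")
  rule_key <- paste(rules$species, rules$excluded_region, sep = "\r")
  hit <- key %in% rule_key
  list(kept = df[!hit, , drop = FALSE], removed = df[hit, , drop = FALSE])
}
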