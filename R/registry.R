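#' Construct an allometric equation
#'
#' A registered power-law conversion `y = alpha * x^beta`, stored in the
#' canonical ln-scale form `ln(y) = alpha_ln + beta * ln(x)`. Equations
#' published on the natural scale are converted at transcription time
#' (`alpha_ln = ln(alpha)`), so prediction code handles a single form.
#'
#' @param eq_id Unique identifier within a registry.
#' @param response One of `dry_weight_mg`, `foraging_distance_km`,
#'   `tongue_length_mm`, `wing_loading`, `nectar_load_mg`.
#' @param predictor One of `itd_mm`, `body_length_mm`, `head_width_mm`,
#'   `body_length_x_width`.
#' @param alpha_ln ln-scale intercept.
#' @param beta Allometric exponent; must be finite.
#' @param sigma_resid_ln Optional ln-scale residual SD of the source fit,
#'   used to propagate uncertainty in [derived_trait()].
#' @param scope Named list of applicability labels, keys from
#'   `taxon`, `sex`, `region`; an empty vector for a key means the equation
#'   is not restricted on it. At least one key must be non-empty.
#' @param source Citation string for the transcribed coefficients.
#' @return An object of class `allometric_equation`.
#' @export
allometric_equation <- function(eq_id, response, predictor, alpha_ln, beta,
                                sigma_resid_ln = NULL,
                                scope = list(taxon = character()),
                                source = "") {
  responses <- c("dry_weight_mg", "foraging_distance_km", "tongue_length_mm",
                 "wing_loading", "nectar_load_mg")
  predictors <- c("itd_mm", "body_length_mm", "head_width_mm", "body_length_x_width")
  if (!response %in% responses)
    ps_stop(sprintf("unknown response '%s'", response), "pollisize_validation_error")
  if (!predictor %in% predictors)
    ps_stop(sprintf("unknown predictor '%s'", predictor), "pollisize_validation_error")
  if (!is.finite(beta)) ps_stop("beta must be finite", "pollisize_validation_error")
  scope <- scope[vapply(scope, length, 1L) > 0]
  if (!length(scope))
    ps_stop("equation scope must be non-empty", "pollisize_validation_error")
  structure(list(eq_id = eq_id, response = response, predictor = predictor,
                 alpha_ln = alpha_ln, beta = beta,
                 sigma_resid_ln = sigma_resid_ln, scope = scope,
                 source = source),
            class = "allometric_equation")
}

#' @export
print.allometric_equation <- function(x, ...) {
  cat(sprintf("<allometric_equation %s>\n  ln(%s) = %.4g + %.4g * ln(%s)\n",
              x$eq_id, x$response, x$alpha_ln, x$beta, x$predictor))
  scp <- paste(vapply(names(x$scope), function(k)
    paste0(k, ": ", paste(x$scope[[k]], collapse = "/")), character(1)),
    collapse = "; ")
  cat("  scope:", scp, "\n")
  if (!is.null(x$sigma_resid_ln))
    cat(sprintf("  ln-scale residual SD: %.4g\n", x$sigma_resid_ln))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Load an equation registry
#'
#' Reads a registry of allometric equations either from JSON (one object per
#' equation, the canonical format) or from CSV (columns `eq_id`, `response`,
#' `predictor`, `alpha_ln`, `beta`, `sigma_resid_ln`, `taxon`, `sex`,
#' `region`, `source`; multi-valued scope entries separated by `;`).
#'
#' The starter registry shipped with the package is at
#' `system.file("extdata", "equation_registry.json", package = "pollisize")`.
#'
#' @param path Path to a `.json` or `.csv` registry file.
#' @return A list of [allometric_equation()] objects, class
#'   `equation_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) ps_stop(sprintf("file not found: %s", path), "pollisize_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    eqs <- lapply(raw, function(e) {
      allometric_equation(
        eq_id = e$eq_id, response = e$response, predictor = e$predictor,
        alpha_ln = as.numeric(e$alpha_ln), beta = as.numeric(e$beta),
        sigma_resid_ln = if (is.null(e$sigma_resid_ln)) NULL else as.numeric(e$sigma_resid_ln),
        scope = lapply(e$scope, function(v) unlist(v) %||% character()),
        source = e$source %||% "")
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    split_scope <- function(s) if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";")[[1]]
    eqs <- lapply(seq_len(nrow(df)), function(i) {
      allometric_equation(
        eq_id = df$eq_id[i], response = df$response[i], predictor = df$predictor[i],
        alpha_ln = df$alpha_ln[i], beta = df$beta[i],
        sigma_resid_ln = if (is.na(df$sigma_resid_ln[i])) NULL else df$sigma_resid_ln[i],
        scope = list(taxon = split_scope(df$taxon[i]), sex = split_scope(df$sex[i]),
                     region = split_scope(df$region[i])),
        source = df$source[i] %||% "")
    })
  }
  ids <- vapply(eqs, `[[`, character(1), "eq_id")
  if (anyDuplicated(ids))
    ps_stop(sprintf("duplicate eq_id in registry: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "pollisize_validation_error")
  structure(eqs, class = "equation_registry")
}

#' Find applicable equations in a registry
#'
#' Returns every equation whose response, predictor and scope cover the
#' query, most specific first. An equation covers a scope query key if it is
#' unrestricted on that key or its label set contains the queried value;
#' specificity is the number of scope keys on which the equation is both
#' restricted and matched. Labels are opaque: no taxonomic synonymy or
#' rank expansion is attempted.
#'
#' @param registry An `equation_registry` from [load_registry()], or a list
#'   of [allometric_equation()] objects.
#' @param response Response label, or `NULL` to match any.
#' @param predictor Predictor label, or `NULL` to match any.
#' @param scope Named list of query labels, e.g.
#'   `list(taxon = "Apidae", sex = "female")`.
#' @return A list of matching equations, ordered most specific first.
#' @export
find_equations <- function(registry, response = NULL, predictor = NULL,
                           scope = list()) {
  keep <- list(); specificity <- numeric()
  for (eq in registry) {
    if (!is.null(response) && eq$response != response) next
    if (!is.null(predictor) && eq$predictor != predictor) next
    spec_n <- 0L; ok <- TRUE
    for (key in names(scope)) {
      labels <- eq$scope[[key]] %||% character()
      if (!length(labels)) next               # unrestricted on this key
      if (scope[[key]] %in% labels) spec_n <- spec_n + 1L else { ok <- FALSE; break }
    }
    if (ok) { keep[[length(keep) + 1L]] <- eq; specificity <- c(specificity, spec_n) }
  }
  keep[order(-specificity)]
}

#' Estimate a derived trait from a registry equation
#'
#' Evaluates a registered power law for traits that scale with body size:
#' bee foraging distance, tongue length, wing loading or nectar load. When
#' the source equation carries an ln-scale residual SD, prediction
#' uncertainty is propagated through the ln-normal error model (the point
#' estimate is the ln-normal median, the SE its SD, and the 90% interval its
#' 5%/95% quantiles); otherwise only the point value is returned and the
#' result is flagged `point_only`.
#'
#' @param registry An `equation_registry`.
#' @param trait One of `foraging_distance`, `tongue_length`, `wing_loading`,
#'   `nectar_load`, `dry_weight`.
#' @param value Positive predictor value(s) (e.g. ITD in mm).
#' @param scope Scope query, as in [find_equations()].
#' @param predictor Predictor label, default `itd_mm`.
#' @param level Interval coverage, default 0.90.
#' @return A data frame with one row per input value: `point`, `se`, `lo`,
#'   `hi`, `flags`, `eq_id`, plus the response units in `response`.
#' @export
derived_trait <- function(registry, trait, value, scope = list(),
                          predictor = "itd_mm", level = 0.90) {
  trait_response <- c(foraging_distance = "foraging_distance_km",
                      tongue_length = "tongue_length_mm",
                      wing_loading = "wing_loading",
                      nectar_load = "nectar_load_mg",
                      dry_weight = "dry_weight_mg")
  if (!trait %in% names(trait_response))
    ps_stop(sprintf("unknown trait '%s'", trait), "pollisize_validation_error")
  if (any(value <= 0)) ps_stop("predictor values must be positive", "pollisize_validation_error")
  hits <- find_equations(registry, response = trait_response[[trait]],
                         predictor = predictor, scope = scope)
  if (!length(hits)) {
    scp <- if (length(scope))
      paste(names(scope), unlist(scope), sep = "=", collapse = ", ") else "any scope"
    ps_stop(sprintf("no %s equation with predictor %s for %s in this registry",
                    trait, predictor, scp), "pollisize_no_equation_error")
  }
  eq <- hits[[1L]]
  mu <- eq$alpha_ln + eq$beta * log(value)
  if (!is.null(eq$sigma_resid_ln)) {
    s <- eq$sigma_resid_ln
    z <- qnorm(1 - (1 - level) / 2)
    out <- data.frame(point = exp(mu),
                      se = sqrt((exp(s^2) - 1) * exp(2 * mu + s^2)),
                      lo = exp(mu - z * s), hi = exp(mu + z * s),
                      flags = "", stringsAsFactors = FALSE)
  } else {
    out <- data.frame(point = exp(mu), se = NA_real_, lo = NA_real_,
                      hi = NA_real_, flags = "point_only", stringsAsFactors = FALSE)
  }
  out$eq_id <- eq$eq_id
  out$response <- eq$response
  out
}
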