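# Internal helpers shared across modules.

# Controlled vocabularies for specimen tables.
REGIONS <- c("Australia", "Europe", "North America", "South America")
SEXES <- c("female", "male")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
ps_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pollisize_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Canonical fingerprint of a data frame
#'
#' md5 of a canonical CSV rendering (sorted column order, full numeric
#' precision). Used to detect that two fitted models were trained on the same
#' table before they are compared; not a cryptographic commitment.
#' @noRd
fingerprint_data <- function(df) {
  df <- df[, order(names(df)), drop = FALSE]
  if (nrow(df) > 1) {
    ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
    df <- df[ord, , drop = FALSE]
  }
  txt <- vapply(df, function(col) {
    if (is.numeric(col)) paste(sprintf("%.17g", col), collapse = ",")
    else paste(as.character(col), collapse = ",")
  }, character(1))
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(c(names(df), txt), tmp)
  unname(tools::md5sum(tmp))
}

# Derive a reproducible sub-seed for a named random substream, so adding a new
# draw stage never perturbs the draws of existing stages. Kept below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

# Multivariate normal draws via Cholesky; Sigma must be symmetric PSD.
# Returns n x d matrix.
rmvnorm_chol <- function(n, mu, Sigma) {
  d <- length(mu)
  L <- chol(Sigma + diag(1e-12 * mean(diag(Sigma)), d))
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% L, 2, mu, "+")
}

# Format a numeric for lossless CSV round-trip.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}
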