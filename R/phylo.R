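#' Read and write Newick trees
#'
#' Thin wrappers around ape's Newick parser that enforce the package's tree
#' invariants: unique tip labels, a single root, nonnegative branch lengths.
#' Round-tripping preserves topology and branch lengths to stored precision.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object (ape).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) ps_stop(sprintf("file not found: %s", path), "pollisize_io_error")
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) ps_stop(paste("malformed Newick:", conditionMessage(e)),
                                               "pollisize_io_error"))
  if (is.null(tree)) ps_stop("malformed Newick: parser returned nothing", "pollisize_io_error")
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) ps_stop("not a phylo object", "pollisize_validation_error")
  if (anyDuplicated(tree$tip.label))
    ps_stop(sprintf("duplicate tip labels: %s",
                    paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")),
            "pollisize_validation_error")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    ps_stop("negative branch lengths", "pollisize_validation_error")
  invisible(tree)
}

#' Is a tree ultrametric (to relative tolerance)?
#'
#' All root-to-tip depths must agree within `tol` times the tree depth.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tol Relative tolerance, default 1e-6.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol * max(depths)
}

#' Prune a genus backbone to represented genera
#'
#' Keeps only the given genera, collapsing the induced degree-2 internal
#' nodes and summing their branch lengths, so path lengths between retained
#' tips are preserved.
#'
#' @param backbone A `phylo` object whose tips are genus labels.
#' @param genera Character vector of genera to keep; must be a subset of the
#'   backbone's tips.
#' @return The pruned `phylo` object.
#' @export
prune_to_genera <- function(backbone, genera) {
  validate_tree(backbone)
  genera <- unique(genera)
  unknown <- setdiff(genera, backbone$tip.label)
  if (length(unknown))
    ps_stop(sprintf("genera absent from backbone: %s", paste(unknown, collapse = ", ")),
            "pollisize_validation_error")
  if (!length(genera))
    ps_stop("no genera to keep", "pollisize_validation_error")
  if (length(genera) == length(backbone$tip.label)) return(backbone)
  ape::keep.tip(backbone, genera)
}

#' Graft species onto a genus backbone as polytomies
#'
#' Each genus tip that has species assigned becomes a polytomy: the genus
#' terminal edge of length e is split into a stem of `(1 - fraction) * e`
#' and S species tips each of length `fraction * e`, so every root-to-tip
#' depth of the original genus lineage is preserved exactly and all
#' congeners sit at equal pairwise distance. A genus with a single species
#' is simply relabeled. Species whose genus is not a backbone tip are
#' returned in `excluded`, not treated as errors, mirroring how taxa missing
#' from a published backbone are dropped from phylogenetic analyses.
#'
#' Because the infrageneric polytomies are artificial, downstream
#' phylogenetic statements should be read at and above the genus level.
#'
#' @param backbone A `phylo` object with genus tip labels.
#' @param species_to_genus Data frame with columns `species`, `genus`.
#' @param fraction Fraction of the genus terminal edge given to each species
#'   tip, in (0, 1); default 0.5.
#' @return List with `tree` (the grafted `phylo`) and `excluded` (character
#'   vector of species whose genus was absent).
#' @export
graft_species_polytomies <- function(backbone, species_to_genus, fraction = 0.5) {
  validate_tree(backbone)
  if (!nrow(species_to_genus)) ps_stop("empty species-to-genus mapping", "pollisize_validation_error")
  if (fraction <= 0 || fraction >= 1) ps_stop("fraction must be in (0, 1)", "pollisize_validation_error")
  map <- species_to_genus
  map$species <- gsub(" ", "_", map$species)
  excluded <- map$species[!map$genus %in% backbone$tip.label]
  map <- map[map$genus %in% backbone$tip.label, , drop = FALSE]
  if (!nrow(map))
    ps_stop("no species left to graft: no genus matches the backbone", "pollisize_validation_error")

  ntip <- length(backbone$tip.label)
  elen <- numeric(max(backbone$edge))
  elen[backbone$edge[, 2]] <- backbone$edge.length
  kids <- split(backbone$edge[, 2], backbone$edge[, 1])
  fmt <- function(x) sprintf("%.15g", x)
  rec <- function(node) {
    if (node <= ntip) {
      g <- backbone$tip.label[node]
      e <- elen[node]
      spp <- map$species[map$genus == g]
      if (!length(spp)) return(paste0(g, ":", fmt(e)))
      if (length(spp) == 1L) return(paste0(spp, ":", fmt(e)))
      tip_len <- fraction * e
      paste0("(", paste0(spp, ":", fmt(tip_len), collapse = ","),
             "):", fmt(e - tip_len))
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], rec, character(1)),
                     collapse = ",")
      if (node == ntip + 1L) paste0("(", inner, ");")
      else paste0("(", inner, "):", fmt(elen[node]))
    }
  }
  tree <- ape::read.tree(text = rec(ntip + 1L))
  validate_tree(tree)
  list(tree = tree, excluded = excluded)
}

#' Penalized-likelihood chronogram (correlated rates)
#'
#' Converts a tree with branch lengths in expected substitutions (or any
#' rate-confounded unit) into an ultrametric chronogram whose depths are in
#' relative time, by Sanderson-style penalized likelihood with a correlated
#' rate model: branch-length likelihood minus `smoothing` times the summed
#' squared rate differences between adjacent edges. Larger smoothing values
#' pull the fit towards a single global clock. The root age is fixed at 1,
#' so depths are relative time.
#'
#' @param tree A `phylo` object with positive branch lengths.
#' @param smoothing Positive smoothing parameter (lambda of the penalty);
#'   default 1.
#' @param model Rate model, only `"correlated"` is supported (the
#'   discrete/relaxed variants are out of scope here).
#' @return An ultrametric `phylo` object carrying attributes `rates` (fitted
#'   per-edge rates) and `ploglik` (final penalized log-likelihood).
#' @export
chronogram_pl <- function(tree, smoothing = 1, model = "correlated") {
  validate_tree(tree)
  model <- match.arg(model, "correlated")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    ps_stop("tree must have strictly positive branch lengths", "pollisize_validation_error")
  ntip <- length(tree$tip.label)
  if (ntip == 2) {
    # any two-tip chronogram is ultrametric; fix root age 1, recover rates
    out <- tree
    rates <- out$edge.length
    out$edge.length <- rep(1, length(out$edge.length))
    attr(out, "rates") <- rates
    attr(out, "ploglik") <- 0
    return(out)
  }
  res <- tryCatch(
    suppressWarnings(suppressMessages(
      ape::chronos(tree, lambda = smoothing,
                   model = "correlated",
                   quiet = TRUE,
                   calibration = ape::makeChronosCalib(tree),
                   control = ape::chronos.control())
    )),
    error = function(e) ps_stop(paste("chronogram optimization failed:", conditionMessage(e)),
                                "pollisize_convergence_error"))
  out <- res
  class(out) <- "phylo"
  attr(out, "ploglik") <- attr(res, "ploglik")
  attr(out, "rates") <- attr(res, "rates")
  if (!is_ultrametric_tree(out, tol = 1e-5))
    ps_stop("chronogram is not ultrametric: optimizer did not converge", "pollisize_convergence_error")
  out
}

#' Phylogenetic covariance (shared path lengths)
#'
#' Entry (i, j) is the root-to-MRCA shared path length of tips i and j; the
#' diagonal holds the tip depths. Under Brownian trait evolution this is the
#' trait covariance up to a rate constant, and it is the matrix the
#' phylogenetic GLMM uses for its species effect.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric positive-semidefinite matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of Pagel's lambda in \[0, 1\]: the trait is
#' modeled as multivariate normal with covariance `sigma2 * C(lambda)`,
#' where `C(lambda)` scales the off-diagonal shared path lengths by lambda
#' and keeps the diagonal. The ancestral mean and rate `sigma2` are profiled
#' out analytically (GLS mean, ML variance), leaving a 1-D optimization by
#' Brent's method on \[0, 1\]. Significance is a likelihood-ratio test
#' against lambda = 0 on chi-squared(1); because lambda = 0 sits on the
#' boundary, a 50:50 boundary-mixture p-value is available via
#' `boundary_mixture = TRUE` (it halves the chi-squared tail).
#'
#' The tree must be ultrametric (a chronogram): on a non-ultrametric tree
#' the diagonal of C confounds depth differences with signal, so the
#' function refuses rather than warns.
#'
#' @param tree Ultrametric `phylo` object.
#' @param trait Named numeric vector, names are tip labels (species). Every
#'   trait species must be a tip; tips without trait values are pruned.
#' @param boundary_mixture Use the boundary-corrected p-value; default FALSE.
#' @return An object of class `lambda_result`: list with `lambda_hat`,
#'   `sigma2_hat`, `loglik_at_hat`, `loglik_at_zero`, `lr_stat`,
#'   `lr_pvalue`, `n_tips`.
#' @export
pagels_lambda <- function(tree, trait, boundary_mixture = FALSE) {
  validate_tree(tree)
  if (!is_ultrametric_tree(tree))
    ps_stop("tree must be ultrametric (fit a chronogram first)", "pollisize_validation_error")
  if (is.null(names(trait))) ps_stop("trait must be a named vector", "pollisize_validation_error")
  names(trait) <- gsub(" ", "_", names(trait))
  missing_tips <- setdiff(names(trait), tree$tip.label)
  if (length(missing_tips))
    ps_stop(sprintf("trait species not in tree: %s", paste(missing_tips, collapse = ", ")),
            "pollisize_validation_error")
  if (length(trait) < 4)
    ps_stop("need at least 4 species with trait values", "pollisize_validation_error")
  extra <- setdiff(tree$tip.label, names(trait))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  C <- ape::vcv.phylo(tree)
  x <- trait[rownames(C)]
  n <- length(x)
  ones <- rep(1, n)
  profile_ll <- function(lambda) {
    V <- lambda * C
    diag(V) <- diag(C)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Vi1 <- backsolve(ch, forwardsolve(t(ch), ones))
    mu <- sum(Vi1 * x) / sum(Vi1 * ones)
    r <- x - mu
    Vir <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * Vir) / n
    if (s2 <= 0) return(-Inf)
    -0.5 * (n * log(2 * pi * s2) + logdet + n)
  }
  opt <- stats::optimize(profile_ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  ll0 <- profile_ll(0)
  ll1 <- profile_ll(1)
  # guard the interior optimum against the boundary values
  cand <- rbind(c(0, ll0), c(opt$maximum, opt$objective), c(1, ll1))
  best <- cand[which.max(cand[, 2]), ]
  lambda_hat <- best[1]; ll_hat <- best[2]
  lr <- max(0, 2 * (ll_hat - ll0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p <- p / 2
  # recover sigma2 at the optimum
  V <- lambda_hat * C; diag(V) <- diag(C)
  ch <- chol(V)
  Vi1 <- backsolve(ch, forwardsolve(t(ch), ones))
  mu <- sum(Vi1 * x) / sum(Vi1 * ones)
  r <- x - mu
  s2 <- sum(r * backsolve(ch, forwardsolve(t(ch), r))) / n
  structure(list(lambda_hat = unname(lambda_hat), sigma2_hat = s2,
                 ancestral_mean = mu,
                 loglik_at_hat = unname(ll_hat), loglik_at_zero = ll0,
                 lr_stat = lr, lr_pvalue = p, n_tips = n,
                 boundary_mixture = boundary_mixture),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.3f (n = %d tips)\n", x$lambda_hat, x$n_tips))
  cat(sprintf("  logL(lambda_hat) = %.3f, logL(0) = %.3f, LR = %.3f, p = %.3g%s\n",
              x$loglik_at_hat, x$loglik_at_zero, x$lr_stat, x$lr_pvalue,
              if (x$boundary_mixture) " (boundary mixture)" else ""))
  invisible(x)
}
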