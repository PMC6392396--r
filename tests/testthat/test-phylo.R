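test_that("Newick I/O parses lengths and rejects duplicates", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", tf)
  tree <- read_newick(tf)
  expect_equal(length(tree$tip.label), 2L)
  expect_equal(sort(tree$edge.length), c(1, 1))
  writeLines("(A:1,A:2);", tf)
  expect_error(read_newick(tf), "duplicate tip")
  writeLines("(A:1,B:1", tf)
  expect_error(read_newick(tf), "malformed|duplicate")
})

test_that("Newick round-trip preserves topology (RF = 0) and lengths", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  tree <- ape::rtree(50)
  tf <- tempfile(fileext = ".nwk")
  write_newick(tree, tf)
  got <- read_newick(tf)
  expect_equal(phangorn::RF.dist(tree, got), 0)
  expect_equal(sort(got$edge.length), sort(tree$edge.length), tolerance = 1e-12)
})

test_that("pruning to genera preserves pairwise path lengths", {
  set.seed(5)
  backbone <- ape::rtree(5)
  expect_identical(prune_to_genera(backbone, backbone$tip.label), backbone)
  keep <- backbone$tip.label[c(1, 4)]
  pruned <- prune_to_genera(backbone, keep)
  expect_setequal(pruned$tip.label, keep)
  d_full <- ape::cophenetic.phylo(backbone)[keep, keep]
  d_sub <- ape::cophenetic.phylo(pruned)[keep, keep]
  expect_equal(d_sub, d_full, tolerance = 1e-10)
  expect_error(prune_to_genera(backbone, character()), "no genera")
  expect_error(prune_to_genera(backbone, "NotAGenus"), "absent")
})

test_that("grafting splits the genus edge at the configured fraction", {
  backbone <- ape::read.tree(text = "((Apis:10,Bombus:6):2,Andrena:12);")
  map <- data.frame(species = c("Apis a", "Apis b", "Apis c", "Bombus x"),
                    genus = c("Apis", "Apis", "Apis", "Bombus"))
  out <- graft_species_polytomies(backbone, map)
  tree <- out$tree
  expect_length(out$excluded, 0L)
  # single species: relabel only
  expect_true("Bombus_x" %in% tree$tip.label)
  d <- ape::node.depth.edgelength(tree)
  names(d) <- c(tree$tip.label, rep(NA, tree$Nnode))
  # depths preserved: Apis species at depth 12, Bombus at 8, Andrena at 12
  expect_equal(unname(d["Apis_a"]), 12, tolerance = 1e-12)
  expect_equal(unname(d["Bombus_x"]), 8, tolerance = 1e-12)
  # polytomy: three tips of edge 5 below a stem of 5
  apis_edges <- tree$edge.length[tree$edge[, 2] %in%
                                   which(tree$tip.label %in% c("Apis_a", "Apis_b", "Apis_c"))]
  expect_equal(apis_edges, rep(5, 3), tolerance = 1e-12)
  # congeners sit at equal pairwise distances
  dm <- ape::cophenetic.phylo(tree)[c("Apis_a", "Apis_b", "Apis_c"),
                                    c("Apis_a", "Apis_b", "Apis_c")]
  offd <- dm[upper.tri(dm)]
  expect_equal(offd, rep(10, 3), tolerance = 1e-12)
})

test_that("species of genera absent from the backbone are excluded, not fatal", {
  backbone <- ape::read.tree(text = "(Apis:1,Bombus:1);")
  map <- data.frame(species = c("Apis a", "Flavipanurgus venustus"),
                    genus = c("Apis", "Flavipanurgus"))
  out <- graft_species_polytomies(backbone, map)
  expect_equal(out$excluded, "Flavipanurgus_venustus")
  expect_error(graft_species_polytomies(backbone, map[0, ]), "empty")
})

test_that("grafting preserves every root-to-tip depth to 1e-9 relative", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    backbone <- ape::rcoal(n, tip.label = paste0("G", seq_len(n)))
    per <- sample(1:4, n, replace = TRUE)
    map <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(species = paste0("G", i, "_s", seq_len(per[i])),
                 genus = paste0("G", i))))
    frac <- runif(1, 0.1, 0.9)
    tree <- graft_species_polytomies(backbone, map, fraction = frac)$tree
    depth_in <- max(ape::node.depth.edgelength(backbone))
    d_out <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    expect_true(all(abs(d_out - depth_in) <= 1e-9 * depth_in))
  }
})

test_that("phylo covariance reads shared path lengths off the tree", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unname(phylo_covariance(star)), diag(3), tolerance = 1e-12)
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tree)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)
})

test_that("phylo covariance is PSD across 100 random trees", {
  set.seed(33)
  for (rep in 1:100) {
    tree <- ape::rtree(sample(3:40, 1))
    C <- phylo_covariance(tree)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
    expect_equal(C, t(C), tolerance = 1e-12)
  }
})

test_that("grafted congeners share identical off-diagonal covariance", {
  tree <- generate_tree(6, 4, seed = 8)
  C <- phylo_covariance(tree)
  for (g in sprintf("Genus%02d", 1:6)) {
    tips <- grep(paste0("^", g, "_"), rownames(C), value = TRUE)
    offd <- C[tips, tips][upper.tri(diag(length(tips)))]
    expect_lt(diff(range(offd)), 1e-10)
  }
})

test_that("a 2-tip chronogram is ultrametric by construction", {
  tree <- ape::read.tree(text = "(A:4,B:1);")
  chrono <- chronogram_pl(tree)
  expect_true(is_ultrametric_tree(chrono))
  d <- ape::node.depth.edgelength(chrono)[1:2]
  expect_equal(d[1], d[2], tolerance = 1e-12)
})

test_that("a clock-like tree passes through the chronogram almost unchanged", {
  set.seed(3)
  tree <- ape::rcoal(12)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  # scale to substitutions under a strict clock with rate 2
  subst <- tree
  subst$edge.length <- subst$edge.length * 2
  chrono <- chronogram_pl(subst, smoothing = 1)
  expect_true(is_ultrametric_tree(chrono))
  # depths proportional to the original relative times
  d_in <- ape::cophenetic.phylo(tree)
  d_out <- ape::cophenetic.phylo(chrono)[rownames(d_in), colnames(d_in)]
  ratio <- d_out[upper.tri(d_out)] / d_in[upper.tri(d_in)]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
  rates <- attr(chrono, "rates")
  expect_lt(sd(rates) / mean(rates), 0.1)
})

test_that("strong smoothing pulls fitted rates towards a global clock", {
  set.seed(9)
  tree <- ape::rtree(12)
  cv_of <- function(smoothing) {
    rates <- attr(chronogram_pl(tree, smoothing = smoothing), "rates")
    sd(rates) / mean(rates)
  }
  cv_lo <- cv_of(0.1); cv_hi <- cv_of(1e5)
  expect_lt(cv_hi, 0.3)
  expect_lt(cv_hi, cv_lo - 0.05)
  expect_true(is_ultrametric_tree(chronogram_pl(tree, smoothing = 1e5)))
})

test_that("Pagel's lambda recovers strong and absent signal", {
  lam_bm <- numeric(10); lam_null <- numeric(10)
  for (r in 1:10) {
    tree <- generate_tree(20, 5, seed = 100 + r)   # 100 tips
    trait <- simulate_bm_trait(tree, sigma2 = 1, lambda_true = 1, seed = 200 + r)
    lam_bm[r] <- pagels_lambda(tree, trait)$lambda_hat
    shuffled <- setNames(sample(trait), names(trait))
    lam_null[r] <- pagels_lambda(tree, shuffled)$lambda_hat
  }
  expect_gte(median(lam_bm), 0.9)
  expect_lte(median(lam_null), 0.2)
})

test_that("the likelihood-ratio test separates signal from shuffle", {
  tree <- generate_tree(20, 5, seed = 42)
  trait <- simulate_bm_trait(tree, lambda_true = 1, seed = 7)
  sig <- pagels_lambda(tree, trait)
  expect_lt(sig$lr_pvalue, 1e-6)
  expect_gte(sig$loglik_at_hat, sig$loglik_at_zero)
  set.seed(8)
  shuf <- pagels_lambda(tree, setNames(sample(trait), names(trait)))
  expect_gt(shuf$lr_pvalue, 0.01)
  # boundary mixture halves the chi-squared tail
  both <- pagels_lambda(tree, trait, boundary_mixture = TRUE)
  expect_equal(both$lr_pvalue, sig$lr_pvalue / 2)
})

test_that("lambda is invariant to affine transforms of the trait", {
  tree <- generate_tree(15, 4, seed = 5)
  trait <- simulate_bm_trait(tree, lambda_true = 0.7, seed = 9)
  a <- pagels_lambda(tree, trait)
  b <- pagels_lambda(tree, 3.2 * trait + 17)
  expect_equal(a$lambda_hat, b$lambda_hat, tolerance = 1e-5)
  expect_equal(a$lr_stat, b$lr_stat, tolerance = 1e-5)
})

test_that("lambda agrees with an independent maximum-likelihood implementation", {
  skip_if_not_installed("phytools")
  tree <- generate_tree(12, 3, seed = 77)
  trait <- simulate_bm_trait(tree, lambda_true = 0.8, seed = 13)
  ours <- pagels_lambda(tree, trait)
  ref <- phytools::phylosig(tree, trait[tree$tip.label], method = "lambda", test = TRUE)
  expect_equal(ours$lambda_hat, unname(ref$lambda), tolerance = 1e-3)
  expect_equal(ours$loglik_at_hat, unname(ref$logL), tolerance = 1e-4)
  expect_equal(ours$loglik_at_zero, unname(ref$logL0), tolerance = 1e-4)
})

test_that("lambda refuses non-ultrametric trees and tiny samples", {
  set.seed(2)
  tree <- ape::rtree(10)  # not ultrametric
  trait <- setNames(rnorm(10), tree$tip.label)
  expect_error(pagels_lambda(tree, trait), "ultrametric")
  small <- generate_tree(3, 1, seed = 1)
  expect_error(pagels_lambda(small, setNames(rnorm(3), small$tip.label)),
               "at least 4")
})
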