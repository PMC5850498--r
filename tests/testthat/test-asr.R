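test_that("pruning to non-C4 tips conserves path lengths", {
  meta <- data.frame(species_id = c("C4a", "C3a", "C3b"),
                     type = c("C4", "nonC4", "nonC4"),
                     origin_id = c("o1", NA, NA), stringsAsFactors = FALSE)
  pr <- prune_to_nonc4(read_newick("((C4a:1,C3a:1):1,C3b:2);"), meta)
  expect_setequal(pr$tip.label, c("C3a", "C3b"))
  expect_equal(unname(diag(vcv_matrix(pr))), c(2, 2))

  # no C4 tips: unchanged
  meta2 <- meta; meta2$type <- "nonC4"; meta2$origin_id <- NA
  tr <- read_newick("((C4a:1,C3a:1):1,C3b:2);")
  expect_true(ape::all.equal.phylo(prune_to_nonc4(tr, meta2), tr))

  # fewer than 2 non-C4 tips is an error
  meta3 <- meta; meta3$type <- c("C4", "C4", "nonC4")
  meta3$origin_id <- c("o1", "o2", NA)
  expect_error(prune_to_nonc4(tr, meta3), "at least 2")
})

test_that("pruning a simulated tree preserves surviving tip depths", {
  sim <- simulate_dataset(sim_config(), seed = 3)
  pr <- prune_to_nonc4(sim$tree, sim$meta)
  expect_equal(length(pr$tip.label), sum(sim$meta$type == "nonC4"))
  d_full <- diag(vcv_matrix(sim$tree))
  d_pruned <- diag(vcv_matrix(pr))
  expect_equal(d_pruned, d_full[names(d_pruned)], tolerance = 1e-9)
})

test_that("fit_bm closed forms: symmetric two-tip tree", {
  fit <- fit_bm(read_newick("(A:1,B:1);"), c(A = 0, B = 2))
  expect_equal(fit$root_state, 1)
  expect_equal(fit$sigma2, 1)  # (x - mu)' C^-1 (x - mu) / n = 2/2
  expect_equal(fit$loglik,
               -0.5 * (2 * log(2 * pi * 1) + 0 + 2))  # log det I = 0
})

test_that("fit_bm flags constant traits and singular inputs", {
  tr <- read_newick("(A:1,B:1);")
  fit <- fit_bm(tr, c(A = 3, B = 3))
  expect_true(fit$constant)
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$root_state, 3)
  expect_error(fit_bm(read_newick("(A:0,B:1);"), c(A = 1, B = 2)),
               "zero-length terminal")
  expect_error(fit_bm(tr, c(A = 1)), "missing tip")
})

test_that("fit_bm matches a brute-force likelihood optimizer", {
  tr <- simulate_tree(30, seed = 5)
  set.seed(6)
  x <- setNames(rnorm(30, 5, 2), tr$tip.label)
  fit <- fit_bm(tr, x)

  C <- vcv_matrix(tr)
  negll <- function(par) {  # independent MVN log-likelihood
    mu <- par[1]; s2 <- exp(par[2])
    d <- x[rownames(C)] - mu
    0.5 * (30 * log(2 * pi * s2) +
             determinant(C, logarithm = TRUE)$modulus +
             drop(d %*% solve(C, d)) / s2)
  }
  opt <- optim(c(mean(x), 0), negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(fit$root_state, opt$par[1], tolerance = 1e-6)
  expect_equal(fit$sigma2, exp(opt$par[2]), tolerance = 1e-6)
  expect_equal(-fit$loglik, opt$value, tolerance = 1e-8)
})

test_that("ancestral states: star tree root is the arithmetic mean", {
  a <- ancestral_states(read_newick("(A:1,B:1,C:1,D:1);"),
                        c(A = 1, B = 2, C = 3, D = 6))
  expect_equal(a$nodes$estimate, 3)
  expect_equal(a$root_state, 3)
})

test_that("ancestral states: two-tip precision-weighted closed form", {
  a <- ancestral_states(read_newick("(A:1,B:3);"), c(A = 0, B = 4))
  expect_equal(a$nodes$estimate, (0 / 1 + 4 / 3) / (1 / 1 + 1 / 3))
})

test_that("joint-ML states match a brute-force optimizer and ace", {
  tr <- simulate_tree(30, seed = 8)
  set.seed(9)
  x <- phytools::fastBM(tr, a = 2, sig2 = 0.5)[tr$tip.label]
  a <- ancestral_states(tr, x)

  nll <- joint_bm_negloglik(tr, x, a$sigma2)
  opt <- optim(rep(mean(x), tr$Nnode), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  expect_equal(a$nodes$estimate, opt$par, tolerance = 1e-5)
  expect_gte(nll(a$nodes$estimate) + 1e-9, opt$value)

  # independent cross-check against ape's ML reconstruction
  ace <- ape::ace(x, tr, type = "continuous", method = "ML", model = "BM")
  expect_equal(a$nodes$estimate, unname(ace$ace), tolerance = 1e-4)
})

test_that("likelihood at the optimum beats random perturbations", {
  tr <- simulate_tree(15, seed = 12)
  set.seed(13)
  x <- setNames(rnorm(15), tr$tip.label)
  a <- ancestral_states(tr, x)
  nll <- joint_bm_negloglik(tr, x, a$sigma2)
  best <- nll(a$nodes$estimate)
  for (i in 1:100) {
    expect_gte(nll(a$nodes$estimate + rnorm(tr$Nnode, 0, 0.3)) + 1e-12,
               best)
  }
})

test_that("root estimate is a convex combination of tip values", {
  set.seed(21)
  for (s in 1:10) {
    tr <- simulate_tree(sample(4:30, 1), seed = 100 + s)
    x <- setNames(rnorm(length(tr$tip.label), 10, 4), tr$tip.label)
    a <- ancestral_states(tr, x)
    expect_gte(a$nodes$estimate[1], min(x) - 1e-9)
    expect_lte(a$nodes$estimate[1], max(x) + 1e-9)
    expect_true(all(a$nodes$ci_lo <= a$nodes$estimate + 1e-12 &
                      a$nodes$estimate <= a$nodes$ci_hi + 1e-12))
    expect_equal(a$nodes$estimate[1], a$root_state, tolerance = 1e-9)
  }
})

test_that("BM parameter recovery shows the known ML rate bias", {
  tr <- simulate_tree(50, seed = 40)
  n <- 50; mu <- 3; s2 <- 2
  set.seed(41)
  fits <- replicate(200, {
    x <- phytools::fastBM(tr, a = mu, sig2 = s2)[tr$tip.label]
    f <- fit_bm(tr, x)
    c(f$root_state, f$sigma2)
  })
  mu_hat <- fits[1, ]; s2_hat <- fits[2, ]
  expect_lt(abs(mean(mu_hat) - mu), 3 * sd(mu_hat) / sqrt(200))
  # E[sigma2_hat] = sigma2 * (n - 1) / n for the ML (divide-by-n) estimate
  expect_lt(abs(mean(s2_hat) - s2 * (n - 1) / n),
            3 * sd(s2_hat) / sqrt(200))
})

test_that("the non-C4 mean proxy averages correctly", {
  meta <- data.frame(species_id = c("c4", "c3x", "c3y"),
                     type = c("C4", "nonC4", "nonC4"),
                     origin_id = c("o1", NA, NA), stringsAsFactors = FALSE)
  expr <- expr_from_values(data.frame(
    lineage_id = "g", species_id = c("c4", "c3x", "c3y"),
    tissue = "leaf", rpkm = c(900, 10, 30), stringsAsFactors = FALSE))
  expect_equal(c3_mean_proxy(expr, meta, "g"), 20)
  expect_equal(c3_mean_proxy(expr[expr$species_id != "c3y", ], meta, "g"),
               10)
  expect_true(is.na(c3_mean_proxy(expr, meta, "absent")))
})

test_that("tree-based roots track non-C4 means across lineages", {
  sim <- simulate_dataset(sim_config(), seed = 23)
  expr <- build_expression_matrix(sim$counts, sim$lineages,
                                  sim$libraries, sim$totals)
  meta <- species_metadata(sim$libraries)
  asr <- reconstruct_ancestral_traits(expr, meta, sim$lineages, sim$tree)
  roots <- asr$root_estimate[asr$trait == "leaf_rpkm"]
  means <- vapply(sim$lineages$lineage_id, function(g)
    c3_mean_proxy(expr, meta, g), numeric(1))
  expect_gt(cor(roots, means)^2, 0.9)
})
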