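test_that("simulated trees are ultrametric, unit depth, deterministic", {
  tr <- simulate_tree(5, seed = 2)
  expect_equal(length(tr$tip.label), 5)
  expect_equal(tr$Nnode, 4)
  depths <- diag(vcv_matrix(tr))
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(write_newick(simulate_tree(5, seed = 2)),
                   write_newick(tr))
  expect_error(simulate_tree(2), "at least 3")
})

test_that("origin placement yields disjoint monophyletic C4 groups", {
  tr <- simulate_tree(25, seed = 4)
  meta <- assign_origins(tr, 10, c(2, 2, 2, rep(1, 7)), seed = 5)
  expect_equal(sum(meta$type == "C4"), 13)
  expect_equal(sum(meta$type == "nonC4"), 12)
  expect_equal(length(unique(na.omit(meta$origin_id))), 10)
  # monophyly and disjointness: each origin's tips form a clade whose MRCA
  # descendants are exactly those tips
  for (o in unique(na.omit(meta$origin_id))) {
    sp <- meta$species_id[!is.na(meta$origin_id) & meta$origin_id == o]
    if (length(sp) > 1) {
      mrca <- ape::getMRCA(tr, sp)
      desc <- ape::extract.clade(tr, mrca)$tip.label
      expect_setequal(desc, sp)
    }
  }
  expect_identical(assign_origins(tr, 10, c(2, 2, 2, rep(1, 7)), seed = 5),
                   meta)
  expect_error(assign_origins(tr, 2, c(20, 20)), "fewer than 2 non-C4")
})

test_that("BM expression simulation has the right moments and structure", {
  cfg <- sim_config()
  tr <- simulate_tree(10, seed = 6)

  # zero rate: every node carries the root value
  cfg0 <- sim_config(sigma2_leaf = 0, sigma2_ratio = 0)
  es0 <- simulate_expression(tr, cfg0, seed = 7)
  expect_true(all(abs(es0$leaf_log - es0$leaf_log[, "root"]) < 1e-12))

  # tip variance about the root value scales as sigma2 * depth (1000 BM
  # realisations pooled across lineages; unit-depth tree)
  es <- simulate_expression(tr, sim_config(family_sizes = rep(1, 1000)),
                            seed = 8)
  dev <- es$leaf_log[, tr$tip.label[1]] - es$leaf_log[, "root"]
  expect_lt(abs(var(dev) - sim_config()$sigma2_leaf),
            0.1 * sim_config()$sigma2_leaf)

  # sister tips correlate more than distant tips
  V <- vcv_matrix(tr)
  off <- V; diag(off) <- NA
  pair_max <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pair_min <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  d <- sweep(es$leaf_log[, tr$tip.label], 1, es$leaf_log[, "root"])
  expect_gt(cor(d[, pair_max[1]], d[, pair_max[2]]),
            cor(d[, pair_min[1]], d[, pair_min[2]]))
})

test_that("co-option choice follows the softmax in beta", {
  lineages <- data.frame(lineage_id = paste0("f_g", 1:4), family_id = "f",
                         stringsAsFactors = FALSE)
  anc <- setNames(c(0, 1, 2, 3), lineages$lineage_id)
  meta <- data.frame(species_id = c("a", "b", "c"),
                     type = c("C4", "nonC4", "nonC4"),
                     origin_id = c("o1", NA, NA), stringsAsFactors = FALSE)

  # beta = 0: uniform choice across the family
  cfg0 <- sim_config(beta = 0, event_prob = 1)
  set.seed(29)
  picks <- replicate(2500, {
    co <- simulate_cooption(anc, meta, lineages, cfg0)
    co$events$lineage_id
  })
  freq <- table(factor(picks, levels = lineages$lineage_id)) / 2500
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 2500)))

  # beta -> infinity: the most abundant lineage is always chosen
  cfg50 <- sim_config(beta = 50, event_prob = 1)
  set.seed(30)
  picks <- replicate(50, simulate_cooption(anc, meta, lineages,
                                           cfg50)$events$lineage_id)
  expect_true(all(picks == "f_g4"))

  # events always pick a lineage of their own family
  cfg <- sim_config()
  sim <- simulate_dataset(cfg, seed = 11)
  fam_of <- setNames(sim$lineages$family_id, sim$lineages$lineage_id)
  expect_true(all(fam_of[sim$truth$events$lineage_id] ==
                    sim$truth$events$family_id))
})

test_that("noise-free count emission inverts the rpkm formula", {
  cfg <- sim_config(noise_sdlog = 0, n_replicates = 1)
  sim <- simulate_dataset(cfg, seed = 14)
  expr <- build_expression_matrix(sim$counts, sim$lineages,
                                  sim$libraries, sim$totals)
  truth <- sim$truth$true_rpkm
  m <- merge(expr, truth, by = c("lineage_id", "species_id", "tissue"),
             suffixes = c("", "_true"))
  big <- m$rpkm_true >= 10
  expect_true(any(big))
  expect_lt(max(abs(m$rpkm[big] - m$rpkm_true[big]) / m$rpkm_true[big]),
            0.01)
})

test_that("replicate means beat single replicates under noise", {
  cfg <- sim_config(noise_sdlog = 0.4, n_replicates = 2)
  sim <- simulate_dataset(cfg, seed = 15)
  inputs <- list(sim$counts, sim$lineages, sim$libraries, sim$totals)
  expr <- do.call(build_expression_matrix, inputs)
  # recompute per-replicate rpkm for leaf libraries
  grid <- merge(sim$counts, sim$libraries, by = "library_id")
  grid <- merge(grid, sim$totals, by = "library_id")
  grid <- merge(grid, sim$lineages, by = "lineage_id")
  grid$rpkm <- compute_rpkm(grid$count, grid$effective_length_bp,
                            grid$cleaned_reads)
  m <- merge(grid, sim$truth$true_rpkm,
             by = c("lineage_id", "species_id", "tissue"),
             suffixes = c("", "_true"))
  m <- m[m$rpkm_true >= 10, ]
  e_single <- abs(log(m$rpkm + 1) - log(m$rpkm_true + 1))
  mm <- merge(expr, sim$truth$true_rpkm,
              by = c("lineage_id", "species_id", "tissue"),
              suffixes = c("", "_true"))
  mm <- mm[mm$rpkm_true >= 10, ]
  e_mean <- abs(log(mm$rpkm + 1) - log(mm$rpkm_true + 1))
  expect_lt(mean(e_mean), mean(e_single))
})

test_that("datasets are deterministic per seed and internally consistent", {
  s1 <- simulate_dataset(sim_config(), seed = 16)
  s2 <- simulate_dataset(sim_config(), seed = 16)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))

  # mapped fraction bounded: sum of count/total <= 1 per library
  frac <- tapply(s1$counts$count, s1$counts$library_id, sum) /
    s1$totals$cleaned_reads[match(names(tapply(s1$counts$count,
                                               s1$counts$library_id, sum)),
                                  s1$totals$library_id)]
  expect_true(all(frac <= 1))
})

test_that("emitted files parse cleanly by the corresponding readers", {
  sim <- simulate_dataset(sim_config(), seed = 18)
  dir <- tempfile("simdata")
  write_dataset(sim, dir)
  expect_warning(
    inp <- read_expression_inputs(file.path(dir, "counts.tsv"),
                                  file.path(dir, "lineages.tsv"),
                                  file.path(dir, "libraries.tsv"),
                                  file.path(dir, "totals.tsv")),
    regexp = NA)
  expect_warning(tr <- read_newick(file = file.path(dir, "tree.nwk")),
                 regexp = NA)
  expect_setequal(tr$tip.label, sim$meta$species_id)
  expect_identical(dim(inp$counts), dim(sim$counts))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$seed, 18)
  unlink(dir, recursive = TRUE)
})
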