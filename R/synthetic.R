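## Synthetic-data generator.  Emulates a grass-like clade: ~10 independent
## C4 origins among ~25 species, 14 gene families of 1-8 lineages, leaf
## abundances evolving under Brownian motion on the tree, co-option events
## biased toward ancestrally abundant lineages, co-opted genes upregulated
## by large fold changes, and log-normal replicate noise.  Every stage of
## the pipeline can be exercised against the recorded truth table.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the dimensions of the empirical study design: 25
#' species, 10 independent C4 origins totalling 13 C4 species, 14 gene
#' families holding 58 lineages (sizes 1-8), co-option fold changes of
#' 10-480x, two biological replicates. BM traits are simulated on the
#' log10 scale.
#'
#' @param n_species Number of species (tips).
#' @param n_origins Number of independent C4 origins.
#' @param origin_sizes Integer vector of C4 tips per origin
#'   (`sum <= n_species - 2`).
#' @param family_sizes Integer vector of lineages per gene family.
#' @param root_log_mean,root_log_sd Distribution of the ancestral (root)
#'   leaf abundance, log10 rpkm.
#' @param sigma2_leaf,sigma2_ratio BM rates (log10 units^2 per unit tree
#'   depth) for leaf abundance and leaf/root ratio.
#' @param ratio_log_mean,ratio_log_sd Distribution of the ancestral
#'   leaf/root log10 ratio.
#' @param beta Co-option bias strength: within a family a lineage is
#'   chosen with probability proportional to
#'   `exp(beta * z)`, `z` its standardized ancestral leaf log-abundance.
#'   `beta = 0` is the uniform null.
#' @param event_prob Probability that a given (origin, family) pair
#'   experiences a co-option event.
#' @param fold_change_range Leaf upregulation of the co-opted lineage in
#'   the origin's C4 tips, drawn log-uniformly (default 10-480x).
#' @param c4_target_range Minimum functional leaf abundance (rpkm) a
#'   co-opted gene reaches in C4 tips, drawn log-uniformly per event
#'   (default 1000-10000). A weak C4 cycle demands high catalytic flux,
#'   so upregulation saturates at a functional level rather than a pure
#'   multiple: the boosted value is `max(fold * ancestral, target)`.
#' @param specificity_boost_range Leaf/root-ratio boost of co-opted
#'   lineages, drawn log-uniformly.
#' @param n_replicates Biological replicates per (species, tissue).
#' @param noise_sdlog SD of the multiplicative log-normal replicate noise
#'   (natural-log scale).
#' @param depth_range Cleaned-read totals per library, drawn uniformly.
#' @param length_range Effective lineage lengths in bp, drawn uniformly.
#' @param mapped_cap Upper bound on the expected fraction of a library's
#'   reads mapping to the simulated gene families (default 0.9). Reads
#'   compete for sequencing depth, so a library whose boosted transcripts
#'   would demand more than this is renormalized; the truth table records
#'   the post-saturation relative abundances.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 25,
                       n_origins = 10,
                       origin_sizes = c(2, 2, 2, rep(1, 7)),
                       family_sizes = c(8, 5, 5, 5, 5, 5, 5, 4, 4, 4, 4,
                                        2, 1, 1),
                       root_log_mean = 1.0,
                       root_log_sd = 0.45,
                       sigma2_leaf = 0.1,
                       sigma2_ratio = 0.15,
                       ratio_log_mean = 0,
                       ratio_log_sd = 0.4,
                       beta = 3,
                       event_prob = 0.6,
                       fold_change_range = c(10, 480),
                       c4_target_range = c(1000, 10000),
                       specificity_boost_range = c(10, 1000),
                       n_replicates = 2,
                       noise_sdlog = 0.25,
                       depth_range = c(5e6, 2e7),
                       length_range = c(500, 5000),
                       mapped_cap = 0.9) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_origins >= 1,
            length(cfg$origin_sizes) == cfg$n_origins,
            all(cfg$origin_sizes >= 1),
            sum(cfg$origin_sizes) <= cfg$n_species - 2,
            all(cfg$family_sizes >= 1),
            cfg$beta >= 0,
            cfg$event_prob > 0, cfg$event_prob <= 1,
            all(cfg$fold_change_range > 0),
            diff(cfg$fold_change_range) >= 0,
            all(cfg$c4_target_range > 0),
            all(cfg$specificity_boost_range > 0),
            cfg$n_replicates >= 1,
            cfg$noise_sdlog >= 0,
            all(cfg$depth_range > 0), all(cfg$length_range > 0),
            cfg$mapped_cap > 0, cfg$mapped_cap <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule (pure-birth) tree rescaled to unit root-to-tip depth. The
#' topology is a stand-in: only the BM covariance structure matters for
#' the analyses this package performs.
#'
#' @param n_species Number of tips (>= 3).
#' @param seed Optional integer seed.
#' @return A `phylo` object, tips labelled `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 3) stop("need at least 3 species")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Place independent C4 origins on a tree
#'
#' Chooses `n_origins` pairwise disjoint, non-nested monophyletic groups
#' of tips as C4 origins (clades for sizes > 1, single tips for size 1);
#' all remaining tips are non-C4. At least 2 non-C4 tips are guaranteed.
#'
#' @param tree A `phylo` object.
#' @param n_origins Number of origins.
#' @param origin_sizes Tips per origin.
#' @param seed Optional integer seed.
#' @return Species-level metadata data.frame: `species_id`, `type`,
#'   `origin_id` (`origin01`, ... for C4, `NA` otherwise).
#' @export
assign_origins <- function(tree, n_origins, origin_sizes, seed = NULL) {
  stopifnot(length(origin_sizes) == n_origins)
  n <- length(tree$tip.label)
  if (sum(origin_sizes) > n - 2)
    stop("origins leave fewer than 2 non-C4 tips; use smaller sizes")
  clade_tips <- lapply((n + 1):(n + tree$Nnode), function(nd)
    tree$tip.label[unlist(ape::prop.part(tree)[[nd - n]])])
  with_seed(seed, {
    for (attempt in 1:200) {
      taken <- character(0)
      groups <- vector("list", n_origins)
      ord <- order(-origin_sizes)
      ok <- TRUE
      for (i in ord) {
        s <- origin_sizes[i]
        if (s == 1) {
          pool <- setdiff(tree$tip.label, taken)
          if (!length(pool)) { ok <- FALSE; break }
          groups[[i]] <- sample(pool, 1)
        } else {
          cand <- Filter(function(tp) length(tp) == s &&
                           !any(tp %in% taken), clade_tips)
          if (!length(cand)) { ok <- FALSE; break }
          groups[[i]] <- cand[[sample.int(length(cand), 1)]]
        }
        taken <- c(taken, groups[[i]])
      }
      if (ok && length(setdiff(tree$tip.label, taken)) >= 2) {
        meta <- data.frame(species_id = tree$tip.label, type = "nonC4",
                           origin_id = NA_character_,
                           stringsAsFactors = FALSE)
        for (i in seq_len(n_origins)) {
          idx <- match(groups[[i]], meta$species_id)
          meta$type[idx] <- "C4"
          meta$origin_id[idx] <- sprintf("origin%02d", i)
        }
        return(meta)
      }
    }
    stop("cannot place ", n_origins, " disjoint origins of sizes ",
         paste(origin_sizes, collapse = ","),
         " on this tree; try smaller sizes")
  })
}

## lineage/family table implied by a config
sim_lineages <- function(config) {
  fam <- sprintf("fam%02d", seq_along(config$family_sizes))
  data.frame(
    lineage_id = unlist(lapply(seq_along(fam), function(i)
      sprintf("%s_g%d", fam[i], seq_len(config$family_sizes[i])))),
    family_id = rep(fam, config$family_sizes),
    stringsAsFactors = FALSE)
}

#' Simulate expression traits under Brownian motion
#'
#' For each gene lineage, the leaf log10 abundance and the leaf/root
#' log10 ratio evolve independently by Brownian motion along the tree from
#' a root value drawn from the configured distribution. Values at internal
#' nodes are retained so ancestral-state reconstructions can be checked
#' against the truth.
#'
#' @param tree A `phylo` object (unit depth assumed for the rate units).
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @return List with `leaf_log` and `ratio_log` (matrices lineage x node,
#'   columns = tips then internal nodes in ape order; root column named
#'   `root`), and `lineages` (the lineage/family table).
#' @export
simulate_expression <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  lineages <- sim_lineages(config)
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  cols <- c(tree$tip.label,
            ifelse(seq.int(n + 1, n_all) == n + 1, "root",
                   paste0("node", seq.int(n + 1, n_all))))
  sim_trait <- function(root_vals, sig2) {
    m <- t(vapply(root_vals, function(a)
      bm_on_tree(tree, a, sig2), numeric(n_all)))
    dimnames(m) <- list(lineages$lineage_id, cols)
    m
  }
  with_seed(seed, {
    roots_leaf <- stats::rnorm(nrow(lineages), config$root_log_mean,
                               config$root_log_sd)
    roots_ratio <- stats::rnorm(nrow(lineages), config$ratio_log_mean,
                                config$ratio_log_sd)
    list(leaf_log = sim_trait(roots_leaf, config$sigma2_leaf),
         ratio_log = sim_trait(roots_ratio, config$sigma2_ratio),
         lineages = lineages)
  })
}

## one BM realisation on the tree, all node values in ape order
bm_on_tree <- function(tree, root_value, sig2) {
  if (sig2 == 0) {
    return(rep(root_value, length(tree$tip.label) + tree$Nnode))
  }
  v <- phytools::fastBM(tree, a = root_value, sig2 = sig2, internal = TRUE)
  ## fastBM returns tips (named) then internal nodes; map into ape order
  n <- length(tree$tip.label)
  out <- numeric(n + tree$Nnode)
  out[seq_len(n)] <- v[tree$tip.label]
  out[(n + 1):(n + tree$Nnode)] <- v[as.character((n + 1):(n + tree$Nnode))]
  out
}

#' Simulate biased co-option events
#'
#' Each (origin, family) pair experiences a co-option event with
#' probability `event_prob`; when it does, one lineage of the family is
#' chosen with probability proportional to `exp(beta * z)` where `z` is
#' the lineage's standardized ancestral leaf log-abundance (`beta = 0`
#' gives the uniform null). Chosen lineages get a leaf fold change, a
#' functional target abundance and a leaf/root specificity boost drawn
#' log-uniformly from the configured ranges; in that origin's C4 tips the
#' leaf value becomes `max(fold * value, target)` and the ratio is
#' multiplied by the boost.
#'
#' @param ancestral Named numeric vector of true ancestral (root) leaf
#'   log10 abundances, one per lineage.
#' @param meta Species-level metadata with C4 origins (see
#'   [assign_origins()]).
#' @param lineages Lineage/family table.
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @return List with `events` (data.frame `origin_id`, `family_id`,
#'   `lineage_id`, `fold_leaf`, `c4_target`, `fold_ratio`) and `beta`.
#' @export
simulate_cooption <- function(ancestral, meta, lineages, config,
                              seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  miss <- setdiff(lineages$lineage_id, names(ancestral))
  if (length(miss))
    stop("no ancestral value for lineage(s): ", paste(miss, collapse = ", "))
  fams <- split(lineages$lineage_id, lineages$family_id)
  if (any(lengths(fams) == 0)) stop("empty family")
  z_all <- as.numeric(scale(ancestral[lineages$lineage_id]))
  if (anyNA(z_all)) z_all <- rep(0, nrow(lineages))  # constant abundances
  names(z_all) <- lineages$lineage_id
  origins <- sort(unique(meta$origin_id[meta$type == "C4"]))
  lo <- log(config$fold_change_range)
  lt <- log(config$c4_target_range)
  ls <- log(config$specificity_boost_range)
  with_seed(seed, {
    rows <- list()
    for (o in origins) {
      for (f in names(fams)) {
        if (stats::runif(1) > config$event_prob) next
        g <- fams[[f]]
        w <- exp(config$beta * z_all[g])
        pick <- if (length(g) == 1) g else
          sample(g, 1, prob = w / sum(w))
        rows[[length(rows) + 1]] <- data.frame(
          origin_id = o, family_id = f, lineage_id = pick,
          fold_leaf = exp(stats::runif(1, lo[1], lo[2])),
          c4_target = exp(stats::runif(1, lt[1], lt[2])),
          fold_ratio = exp(stats::runif(1, ls[1], ls[2])),
          stringsAsFactors = FALSE)
      }
    }
    events <- if (length(rows)) do.call(rbind, rows) else
      data.frame(origin_id = character(0), family_id = character(0),
                 lineage_id = character(0), fold_leaf = numeric(0),
                 fold_ratio = numeric(0))
    list(events = events, beta = config$beta)
  })
}

#' Emit replicate-level count tables from true expression
#'
#' Builds the four input tables the expression module consumes. Per
#' library, the expected count inverts the rpkm formula
#' (`rpkm * length/1000 * total/1e6`) applied to the true tip rpkm with
#' multiplicative log-normal replicate noise, rounded to an integer.
#' Co-opted lineages have their leaf rpkm multiplied by the event's fold
#' change and their leaf/root ratio multiplied by the specificity boost
#' (root rpkm = boosted leaf / boosted ratio) in that origin's C4 tips.
#'
#' @param expr_sim Output of [simulate_expression()].
#' @param events Truth events from [simulate_cooption()].
#' @param meta Species-level metadata.
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @return List of data.frames: `counts`, `lineages` (with
#'   `effective_length_bp`), `libraries`, `totals`, plus `true_rpkm`
#'   (long data.frame `lineage_id`, `species_id`, `tissue`, `rpkm` of the
#'   noise-free truth).
#' @export
emit_counts <- function(expr_sim, events, meta, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  lineages <- expr_sim$lineages
  species <- meta$species_id
  nL <- nrow(lineages); nS <- length(species)

  leaf <- 10^expr_sim$leaf_log[, species, drop = FALSE]
  ratio <- 10^expr_sim$ratio_log[, species, drop = FALSE]
  ## apply co-option boosts in the origin's C4 tips
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      sp <- meta$species_id[!is.na(meta$origin_id) &
                              meta$origin_id == events$origin_id[i]]
      g <- events$lineage_id[i]
      leaf[g, sp] <- pmax(leaf[g, sp] * events$fold_leaf[i],
                          events$c4_target[i])
      ratio[g, sp] <- ratio[g, sp] * events$fold_ratio[i]
    }
  }
  root <- leaf / ratio

  libraries <- expand.grid(species_id = species,
                           tissue = c("leaf", "root"),
                           replicate = seq_len(config$n_replicates),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  libraries$library_id <- sprintf("%s_%s_r%d", libraries$species_id,
                                  libraries$tissue, libraries$replicate)
  libraries <- merge(libraries, meta, by = "species_id")
  libraries <- libraries[order(libraries$library_id),
                         c("library_id", "species_id", "tissue",
                           "replicate", "type", "origin_id")]
  rownames(libraries) <- NULL

  with_seed(seed, {
    len <- round(stats::runif(nL, config$length_range[1],
                              config$length_range[2]))
    ## library saturation: reads compete for depth, so the expected
    ## mapped fraction sum(rpkm * len/1000 / 1e6) cannot exceed the cap;
    ## saturated columns are renormalized and the truth records the
    ## post-saturation relative abundances
    saturate <- function(mat) {
      S <- colSums(mat * (len / 1000) / 1e6)
      sweep(mat, 2, pmin(1, config$mapped_cap / S), "*")
    }
    leaf <- saturate(leaf)
    root <- saturate(root)
    totals <- data.frame(
      library_id = libraries$library_id,
      cleaned_reads = round(stats::runif(nrow(libraries),
                                         config$depth_range[1],
                                         config$depth_range[2])),
      stringsAsFactors = FALSE)
    counts <- do.call(rbind, lapply(seq_len(nrow(libraries)), function(i) {
      lib <- libraries[i, ]
      tru <- if (lib$tissue == "leaf") leaf[, lib$species_id] else
        root[, lib$species_id]
      noise <- if (config$noise_sdlog > 0)
        exp(stats::rnorm(nL, 0, config$noise_sdlog)) else 1
      f <- tru * noise * (len / 1000) / 1e6
      f <- f * min(1, config$mapped_cap / sum(f))  # noise can re-saturate
      tot <- totals$cleaned_reads[i]
      data.frame(library_id = lib$library_id,
                 lineage_id = lineages$lineage_id,
                 count = round(f * tot),
                 stringsAsFactors = FALSE)
    }))
    rownames(counts) <- NULL
    true_rpkm <- rbind(
      data.frame(lineage_id = rep(lineages$lineage_id, nS),
                 species_id = rep(species, each = nL), tissue = "leaf",
                 rpkm = as.vector(leaf), stringsAsFactors = FALSE),
      data.frame(lineage_id = rep(lineages$lineage_id, nS),
                 species_id = rep(species, each = nL), tissue = "root",
                 rpkm = as.vector(root), stringsAsFactors = FALSE))
    list(counts = counts,
         lineages = cbind(lineages, effective_length_bp = len),
         libraries = libraries, totals = totals, true_rpkm = true_rpkm)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs tree simulation, origin placement, BM expression evolution,
#' biased co-option and count emission in sequence under a single seeded
#' RNG stream, returning everything the pipeline consumes plus the truth
#' table.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (default 1).
#' @return Object of class `coopt_sim`: list with `tree`, `meta`,
#'   `counts`, `lineages`, `libraries`, `totals`, `config`, `seed` and
#'   `truth` (list: `events`, `beta`, `ancestral_leaf_log`,
#'   `ancestral_ratio_log`, `leaf_log`, `ratio_log`, `true_rpkm`).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    tree <- simulate_tree(config$n_species)
    meta <- assign_origins(tree, config$n_origins, config$origin_sizes)
    es <- simulate_expression(tree, config)
    co <- simulate_cooption(es$leaf_log[, "root"], meta, es$lineages,
                            config)
    emitted <- emit_counts(es, co$events, meta, config)
    structure(
      list(tree = tree, meta = meta, counts = emitted$counts,
           lineages = emitted$lineages, libraries = emitted$libraries,
           totals = emitted$totals, config = config, seed = seed,
           truth = list(events = co$events, beta = co$beta,
                        ancestral_leaf_log = es$leaf_log[, "root"],
                        ancestral_ratio_log = es$ratio_log[, "root"],
                        leaf_log = es$leaf_log,
                        ratio_log = es$ratio_log,
                        true_rpkm = emitted$true_rpkm)),
      class = "coopt_sim")
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits the exact TSV dialects the expression module reads
#' (`counts.tsv`, `lineages.tsv`, `libraries.tsv`, `totals.tsv`), the tree
#' (`tree.nwk`), the truth events (`truth_events.tsv`) and the
#' configuration echo (`config.yaml`, including the seed).
#'
#' @param sim A `coopt_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "coopt_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$counts, "counts.tsv")
  wt(sim$lineages, "lineages.tsv")
  wt(sim$libraries, "libraries.tsv")
  wt(sim$totals, "totals.tsv")
  wt(sim$truth$events, "truth_events.tsv")
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  cfg <- unclass(sim$config)
  cfg$seed <- sim$seed
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.coopt_sim <- function(x, ...) {
  cat("Synthetic C4 co-option dataset (seed", x$seed, ")\n")
  cat(sprintf("  %d species (%d C4 in %d origins), %d lineages in %d families\n",
              nrow(x$meta), sum(x$meta$type == "C4"),
              length(unique(stats::na.omit(x$meta$origin_id))),
              nrow(x$lineages), length(unique(x$lineages$family_id))))
  cat(sprintf("  %d true co-option events, beta = %g\n",
              nrow(x$truth$events), x$truth$beta))
  invisible(x)
}
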