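# Builders for small in-code fixtures shared across test files.

# Two species (one C4 with an origin, one non-C4), both tissues, `reps`
# replicates, a single two-lineage family; counts chosen so rpkm values
# are round numbers.
tiny_inputs <- function(reps = 2) {
  species <- data.frame(
    species_id = c("c4sp", "c3sp"), type = c("C4", "nonC4"),
    origin_id = c("o1", NA), stringsAsFactors = FALSE)
  libraries <- expand.grid(
    species_id = species$species_id, tissue = c("leaf", "root"),
    replicate = seq_len(reps), KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE)
  libraries <- merge(libraries, species, by = "species_id")
  libraries$library_id <- sprintf("%s_%s_r%d", libraries$species_id,
                                  libraries$tissue, libraries$replicate)
  lineages <- data.frame(lineage_id = c("famA_g1", "famA_g2"),
                         family_id = "famA",
                         effective_length_bp = c(1000, 2000),
                         stringsAsFactors = FALSE)
  totals <- data.frame(library_id = libraries$library_id,
                       cleaned_reads = 1e6, stringsAsFactors = FALSE)
  counts <- expand.grid(library_id = libraries$library_id,
                        lineage_id = lineages$lineage_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts$count <- 100
  list(counts = counts, lineages = lineages, libraries = libraries,
       totals = totals, species = species)
}

# Long-format expression matrix straight from (lineage, species, tissue,
# rpkm) triples, bypassing count emission.
expr_from_values <- function(df) {
  df$n_replicates <- 1L
  class(df) <- c("expression_matrix", "data.frame")
  df
}

# Independent brute-force shared-path matrix: per pair, sum branch lengths
# along the intersection of root paths.
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  elen <- function(node) tree$edge.length[tree$edge[, 2] == node]
  root <- n + 1
  path_edges <- function(tip) {
    nodes <- integer(0)
    node <- tip
    while (length(p <- parent(node))) {
      nodes <- c(nodes, node)
      node <- p
    }
    nodes
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(vapply(shared, elen, numeric(1)))
  }
  V
}

# Negative log of the joint BM likelihood over all node states (internal
# states free, tips fixed), used as the independent ancestral-state oracle.
joint_bm_negloglik <- function(tree, x, sigma2) {
  n <- length(tree$tip.label)
  function(y) {  # y: internal states, ape order n+1 ..
    states <- c(x[tree$tip.label], y)
    d <- states[tree$edge[, 2]] - states[tree$edge[, 1]]
    v <- sigma2 * tree$edge.length
    sum(d^2 / (2 * v) + 0.5 * log(2 * pi * v))
  }
}
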