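## Maximum-likelihood ancestral-state reconstruction under Brownian motion.
##
## Model: tip values x ~ N(mu * 1, sigma2 * C), C the shared-path-length
## matrix of the tree.  mu-hat is the GLS mean, sigma2-hat the ML estimate
## (divide by n).  Joint-ML internal states maximize the full BM likelihood
## over all internal node values; on the tree graph this is harmonic
## interpolation with edge weights 1/branch-length, so the estimates and
## their curvature-based variances come from the weighted graph Laplacian.

#' Restrict a phylogeny to its non-C4 tips
#'
#' Ancestral reconstructions of expression are run on non-C4 species only,
#' to avoid the upregulated levels of C4 taxa biasing the inferred
#' ancestral condition. Unary nodes left by the pruning are suppressed with
#' their branch lengths summed, so root-to-tip path lengths of the
#' surviving species are preserved.
#'
#' @param tree A `phylo` object.
#' @param meta Species-level metadata (`species_id`, `type`) or library
#'   metadata.
#' @return The pruned `phylo` object.
#' @export
prune_to_nonc4 <- function(tree, meta) {
  validate_phylogeny(tree, warn_zero_internal = FALSE)
  if ("library_id" %in% names(meta)) meta <- species_metadata(meta)
  required_cols(meta, c("species_id", "type"), "meta")
  keep <- intersect(tree$tip.label,
                    meta$species_id[meta$type == "nonC4"])
  if (length(keep) < 2)
    stop("need at least 2 non-C4 tips, got ", length(keep))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Fit a Brownian-motion model to tip values
#'
#' Maximum-likelihood fit of `x ~ N(mu * 1, sigma2 * C)` where `C` is the
#' Brownian covariance of the tree ([vcv_matrix()]): `mu` is the GLS mean
#' (which is also the ML root-state estimate) and `sigma2` the ML rate
#' estimate dividing by `n` (not `n - 1`).
#'
#' @param tree A `phylo` object with strictly positive terminal branch
#'   lengths.
#' @param x Named numeric vector of tip values (names = tip labels), one
#'   finite value per tip.
#' @return Object of class `bm_fit`: list with `sigma2`, `root_state`,
#'   `loglik`, `n`, `constant` (TRUE when all tip values are identical, in
#'   which case `sigma2` is 0 and `loglik` is `NA`).
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' fit_bm(tr, c(A = 0, B = 2))  # root 1, sigma2 1
#' @export
fit_bm <- function(tree, x) {
  validate_phylogeny(tree, warn_zero_internal = FALSE)
  n <- length(tree$tip.label)
  term <- tree$edge[, 2] <= n
  if (any(tree$edge.length[term] == 0))
    stop("zero-length terminal branch makes the BM covariance singular: ",
         paste(tree$tip.label[tree$edge[term, 2][
           tree$edge.length[term] == 0]], collapse = ", "))
  if (is.null(names(x))) stop("x must be named by tip label")
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("missing tip value(s): ", paste(miss, collapse = ", "))
  x <- x[tree$tip.label]
  if (any(!is.finite(x))) stop("non-finite tip values")

  C <- vcv_matrix(tree)
  R <- chol(C)
  z <- backsolve(R, x, transpose = TRUE)       # R'z = x
  o <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  q <- sum((z - mu * o)^2)                      # (x-mu)' C^-1 (x-mu)
  sigma2 <- q / n
  constant <- isTRUE(all.equal(max(x), min(x)))
  loglik <- if (constant || sigma2 <= 0) NA_real_ else
    -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + n)
  structure(list(sigma2 = if (constant) 0 else sigma2, root_state = mu,
                 loglik = loglik, n = n, constant = constant),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("BM fit: n = %d, root = %.6g, sigma2 = %.6g, logLik = %.6g\n",
              x$n, x$root_state, x$sigma2, x$loglik))
  invisible(x)
}

## Weighted graph Laplacian of the tree (weights 1/branch length),
## rows/cols in ape node order (tips 1..n, internals n+1..n+Nnode).
tree_laplacian <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  L <- matrix(0, n_all, n_all)
  w <- 1 / tree$edge.length
  if (any(!is.finite(w)))
    stop("zero-length branch in tree; cannot form BM precision matrix")
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    L[p, p] <- L[p, p] + w[i]
    L[c, c] <- L[c, c] + w[i]
    L[p, c] <- L[p, c] - w[i]
    L[c, p] <- L[c, p] - w[i]
  }
  L
}

#' Joint-ML ancestral states under Brownian motion
#'
#' Internal-node values that maximize the full Brownian likelihood jointly
#' over all internal nodes (root included), given the ML rate from
#' [fit_bm()]. These coincide with the conditional means of the Gaussian
#' model given the tips; the root estimate equals the GLS mean. The 95%
#' interval at each node is `estimate +/- 1.96 * sqrt(v)` with `v` the
#' curvature-based variance `sigma2_hat * [L_yy^-1]_jj` from the joint
#' likelihood (`L_yy` the internal-node block of the tree's weighted
#' Laplacian).
#'
#' @inheritParams fit_bm
#' @return Object of class `ancestral_estimate`: list with `nodes`
#'   (data.frame `node`, `estimate`, `ci_lo`, `ci_hi`, `var`; node numbers
#'   in ape convention, root first), `sigma2`, `root_state`, `loglik`,
#'   `n_tips`, `fit` (the `bm_fit`).
#' @examples
#' tr <- read_newick("(A:1,B:1,C:1,D:1);")
#' ancestral_states(tr, c(A = 1, B = 2, C = 3, D = 6))$nodes$estimate  # 3
#' @export
ancestral_states <- function(tree, x) {
  fit <- fit_bm(tree, x)
  x <- x[tree$tip.label]
  n <- length(tree$tip.label)
  internal <- (n + 1):(n + tree$Nnode)
  L <- tree_laplacian(tree)
  Lyy <- L[internal, internal, drop = FALSE]
  Lyx <- L[internal, seq_len(n), drop = FALSE]
  Lyy_inv <- solve(Lyy)
  est <- drop(Lyy_inv %*% (-Lyx %*% x))
  v <- fit$sigma2 * diag(Lyy_inv)
  half <- stats::qnorm(0.975) * sqrt(pmax(v, 0))
  nodes <- data.frame(node = internal, estimate = est,
                      ci_lo = est - half, ci_hi = est + half, var = v)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, sigma2 = fit$sigma2,
                 root_state = fit$root_state, loglik = fit$loglik,
                 n_tips = n, fit = fit),
            class = "ancestral_estimate")
}

#' @export
print.ancestral_estimate <- function(x, ...) {
  cat(sprintf(
    "BM ancestral states: %d tips, sigma2 = %.6g, root = %.6g [%.6g, %.6g]\n",
    x$n_tips, x$sigma2, x$nodes$estimate[1], x$nodes$ci_lo[1],
    x$nodes$ci_hi[1]))
  invisible(x)
}

## Precomputed root-reconstruction machinery for one tree, reused across
## lineages sharing the same tip set: returns function(x) giving the ML
## root state, its 95% CI and sigma2-hat without re-factorizing the tree.
bm_root_machinery <- function(tree) {
  n <- length(tree$tip.label)
  term <- tree$edge[, 2] <= n
  if (any(tree$edge.length[term] == 0))
    stop("zero-length terminal branch makes the BM covariance singular")
  R <- chol(vcv_matrix(tree))
  o <- backsolve(R, rep(1, n), transpose = TRUE)
  oo <- sum(o * o)
  internal <- (n + 1):(n + tree$Nnode)
  L <- tree_laplacian(tree)
  Lyy_inv <- solve(L[internal, internal, drop = FALSE])
  w_root <- drop(Lyy_inv[1, , drop = FALSE] %*%
                   (-L[internal, seq_len(n), drop = FALSE]))
  v_root <- Lyy_inv[1, 1]
  z95 <- stats::qnorm(0.975)
  function(x) {
    x <- x[tree$tip.label]
    z <- backsolve(R, x, transpose = TRUE)
    mu <- sum(o * z) / oo
    sigma2 <- if (isTRUE(all.equal(max(x), min(x)))) 0 else
      sum((z - mu * o)^2) / n
    est <- sum(w_root * x)
    half <- z95 * sqrt(sigma2 * v_root)
    list(root = est, lo = est - half, hi = est + half, sigma2 = sigma2)
  }
}

#' Average abundance among non-C4 species (tree-free proxy)
#'
#' When no phylogeny is available for a clade the ancestral condition is
#' approximated by the arithmetic mean of the lineage's values among
#' non-C4 species, which tracks the tree-based reconstruction closely when
#' sampling is balanced.
#'
#' @param expr An `expression_matrix`.
#' @param meta Species-level or library metadata.
#' @param lineage Lineage id.
#' @param tissue Tissue to average (default `"leaf"`).
#' @return Mean rpkm, or `NA` if no non-C4 species has a value.
#' @export
c3_mean_proxy <- function(expr, meta, lineage, tissue = "leaf") {
  if ("library_id" %in% names(meta)) meta <- species_metadata(meta)
  sp <- meta$species_id[meta$type == "nonC4"]
  v <- expr$rpkm[expr$lineage_id == lineage & expr$tissue == tissue &
                   expr$species_id %in% sp]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Ancestral expression traits for every lineage
#'
#' Reconstructs, for each gene lineage, the leaf abundance and the
#' leaf/root abundance ratio at the root of the non-C4 phylogeny (the
#' inferred condition before C4 evolved). Each trait is a separate
#' univariate BM analysis. Species missing the needed tissue data are
#' pruned per lineage; lineages with fewer than 2 usable tips get `NA`
#' estimates. With `tree = NULL` the non-C4 mean proxy is used instead and
#' `ci_lo`/`ci_hi`/`sigma2` are `NA`.
#'
#' @param expr An `expression_matrix`.
#' @param meta Species-level or library metadata.
#' @param lineages data.frame `lineage_id`, `family_id`.
#' @param tree A `phylo` covering the species, or `NULL` for the mean
#'   proxy.
#' @param epsilon Pseudocount for the leaf/root ratio (default 1 rpkm).
#' @param log_scale If TRUE, traits are reconstructed on the
#'   `log10(x + 1)` scale (estimates are reported on that scale and
#'   flagged in `scale`).
#' @return data.frame `lineage_id`, `trait` (`leaf_rpkm` or
#'   `leaf_root_ratio`), `root_estimate`, `ci_lo`, `ci_hi`, `sigma2`,
#'   `n_tips`, `scale`, `method`.
#' @export
reconstruct_ancestral_traits <- function(expr, meta, lineages, tree = NULL,
                                         epsilon = 1, log_scale = FALSE) {
  if ("library_id" %in% names(meta)) meta <- species_metadata(meta)
  scale_flag <- if (log_scale) "log10p1" else "raw"
  tf <- if (log_scale) function(v) log10(v + 1) else identity
  ratios <- leaf_root_ratio(expr, epsilon = epsilon)
  nonc4 <- meta$species_id[meta$type == "nonC4"]
  ptree <- if (!is.null(tree)) prune_to_nonc4(tree, meta)
  machinery <- new.env(parent = emptyenv())  # cache keyed by tip set

  one <- function(lineage, trait) {
    vals <- if (trait == "leaf_rpkm") {
      d <- expr[expr$lineage_id == lineage & expr$tissue == "leaf" &
                  expr$species_id %in% nonc4, ]
      stats::setNames(d$rpkm, d$species_id)
    } else {
      d <- ratios[ratios$lineage_id == lineage &
                    ratios$species_id %in% nonc4 & !is.na(ratios$ratio), ]
      stats::setNames(d$ratio, d$species_id)
    }
    vals <- tf(vals)
    na_row <- data.frame(lineage_id = lineage, trait = trait,
                         root_estimate = NA_real_, ci_lo = NA_real_,
                         ci_hi = NA_real_, sigma2 = NA_real_,
                         n_tips = length(vals), scale = scale_flag,
                         method = if (is.null(tree)) "nonC4_mean" else "bm_ml",
                         stringsAsFactors = FALSE)
    if (is.null(tree)) {
      if (!length(vals)) return(na_row)
      na_row$root_estimate <- mean(vals)
      return(na_row)
    }
    sp <- intersect(ptree$tip.label, names(vals))
    if (length(sp) < 2) return(na_row)
    key <- paste(sort(sp), collapse = "\r")
    if (is.null(machinery[[key]])) {
      tr <- if (length(sp) == length(ptree$tip.label)) ptree else
        ape::keep.tip(ptree, sp)
      machinery[[key]] <- bm_root_machinery(tr)
    }
    a <- machinery[[key]](vals[sp])
    data.frame(lineage_id = lineage, trait = trait,
               root_estimate = a$root, ci_lo = a$lo,
               ci_hi = a$hi, sigma2 = a$sigma2,
               n_tips = length(sp), scale = scale_flag, method = "bm_ml",
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(lineages$lineage_id, function(g)
    rbind(one(g, "leaf_rpkm"), one(g, "leaf_root_ratio"))))
  rownames(out) <- NULL
  out
}
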