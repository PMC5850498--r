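## Resampling test for co-option bias.
##
## The null model keeps every observed co-option event attached to its gene
## family and resamples only WHICH lineage within the family was used.  A
## deficit of distinct lineages relative to this null indicates that
## independent C4 origins preferentially re-used the same lineages.

check_bias_config <- function(events, family_sizes) {
  required_cols(events, c("origin_id", "family_id"), "events")
  if (!nrow(events)) stop("no co-option events")
  if (is.null(names(family_sizes)) || any(!nzchar(names(family_sizes))))
    stop("family_sizes must be a named vector")
  if (any(family_sizes < 1)) stop("family sizes must be >= 1")
  unknown <- setdiff(unique(events$family_id), names(family_sizes))
  if (length(unknown))
    stop("event(s) reference unknown family: ",
         paste(unknown, collapse = ", "))
  ## without-replacement groups cannot ask for more lineages than exist
  g <- table(paste(events$origin_id, events$family_id, sep = "\r"))
  fam_of_g <- sub("^.*\r", "", names(g))
  if (any(as.integer(g) > family_sizes[fam_of_g]))
    stop("an origin has more events in a family than the family has lineages")
  invisible(events)
}

#' Resampling null for the number of distinct co-opted lineages
#'
#' For each of `B` resamples every event keeps its (origin, family)
#' identity and picks a lineage uniformly at random within its family —
#' independently across origins, and without replacement among events of
#' the same origin in the same family. The statistic is the number of
#' distinct lineages picked at least once. The one-sided p-value
#' `(#\{null <= observed\} + 1) / (B + 1)` asks whether fewer distinct
#' lineages were co-opted than expected by chance.
#'
#' @param events data.frame with columns `origin_id`, `family_id` and,
#'   unless `observed` is given, `lineage_id` (from which the observed
#'   statistic is computed).
#' @param family_sizes Named vector, family id -> number of lineages.
#' @param B Number of resamples (default 1e5).
#' @param seed Optional integer seed; recorded in the result.
#' @param observed Observed number of distinct co-opted lineages; defaults
#'   to `length(unique(events$lineage_id))`.
#' @return Object of class `bias_test`: list with `observed`, `null`
#'   (integer vector of length `B`), `null_mean`, `null_sd`, `p_value`,
#'   `B`, `seed`.
#' @examples
#' ev <- data.frame(origin_id = c("o1", "o2"), family_id = "f",
#'                  lineage_id = c("g1", "g1"))
#' resample_null(ev, c(f = 2), B = 1000, seed = 1)$p_value
#' @export
resample_null <- function(events, family_sizes, B = 1e5, seed = NULL,
                          observed = NULL) {
  check_bias_config(events, family_sizes)
  if (B < 1) stop("B must be >= 1")
  if (is.null(observed)) {
    if (!"lineage_id" %in% names(events))
      stop("supply 'observed' or a lineage_id column in events")
    observed <- length(unique(events$lineage_id))
  }
  null <- with_seed(seed, sample_distinct_counts(events, family_sizes, B))
  p <- (sum(null <= observed) + 1) / (B + 1)
  structure(list(observed = observed, null = null,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 p_value = p, B = as.integer(B), seed = seed),
            class = "bias_test")
}

## B draws of the distinct-lineage statistic.  Lineages are encoded as
## family-offset + within-family index so distinctness is global.
sample_distinct_counts <- function(events, family_sizes, B) {
  fams <- names(family_sizes)
  offset <- stats::setNames(c(0L, cumsum(family_sizes))[seq_along(fams)], fams)
  grp <- split(seq_len(nrow(events)),
               paste(events$origin_id, events$family_id, sep = "\r"))
  E <- nrow(events)
  M <- matrix(0L, nrow = B, ncol = E)
  for (g in grp) {
    f <- events$family_id[g[1]]
    m <- family_sizes[[f]]
    k <- length(g)
    if (k == 1L) {
      M[, g] <- offset[[f]] + sample.int(m, B, replace = TRUE)
    } else {
      ## without replacement within the (origin, family) group
      draws <- vapply(seq_len(B), function(b) sample.int(m, k),
                      integer(k))
      M[, g] <- offset[[f]] + t(draws)
    }
  }
  vapply(seq_len(B), function(b) length(unique(M[b, ])), integer(1))
}

#' Exact null distribution of the distinct-lineage statistic
#'
#' Enumerates every equiprobable outcome of the within-family resampling
#' null and returns the exact probability mass function of the number of
#' distinct lineages. Families are independent, so the pmf is computed per
#' family and convolved; the refusal guard on the total outcome space is
#' applied before any work.
#'
#' @param events data.frame with `origin_id`, `family_id`.
#' @param family_sizes Named vector, family id -> number of lineages.
#' @param max_outcomes Refuse configurations whose raw outcome space
#'   `prod(m_f^events_f)` exceeds this (default 1e6).
#' @return List with `support` (integer), `prob` (summing to 1), `mean`,
#'   `sd`.
#' @examples
#' ev <- data.frame(origin_id = c("o1", "o2"), family_id = "f")
#' exact_null(ev, c(f = 2))$prob  # 0.5, 0.5 on {1, 2}
#' @export
exact_null <- function(events, family_sizes, max_outcomes = 1e6) {
  check_bias_config(events, family_sizes)
  ev_per_fam <- table(events$family_id)
  space <- prod(family_sizes[names(ev_per_fam)] ^ as.numeric(ev_per_fam))
  if (space > max_outcomes)
    stop("outcome space too large to enumerate (", format(space),
         " > ", format(max_outcomes), ")")

  fam_pmfs <- lapply(names(ev_per_fam), function(f) {
    m <- family_sizes[[f]]
    ks <- as.integer(table(events$origin_id[events$family_id == f]))
    ## per origin-group: all k-subsets of the m lineages, equiprobable
    acc <- stats::setNames(c(1), "0")  # occupancy bitmask (as char) -> prob
    for (k in ks) {
      subs <- utils::combn(m, k)
      sub_masks <- apply(subs, 2, function(s) sum(2^(s - 1)))
      p_each <- 1 / ncol(subs)
      new <- new.env(parent = emptyenv())
      for (i in seq_along(acc)) {
        m0 <- as.numeric(names(acc)[i])
        for (sm in sub_masks) {
          key <- as.character(bitwOr(as.integer(m0), as.integer(sm)))
          prev <- if (is.null(new[[key]])) 0 else new[[key]]
          new[[key]] <- prev + acc[[i]] * p_each
        }
      }
      acc <- unlist(as.list(new))
    }
    distinct <- vapply(as.integer(names(acc)), popcount, integer(1))
    tapply(acc, distinct, sum)
  })

  ## convolve independent family pmfs
  pmf <- c(1)          # index i -> P(total distinct = i - 1)
  for (fp in fam_pmfs) {
    vals <- as.integer(names(fp))
    out <- numeric(length(pmf) + max(vals))
    for (j in seq_along(fp))
      out[seq_along(pmf) + vals[j]] <- out[seq_along(pmf) + vals[j]] +
        pmf * fp[[j]]
    pmf <- out
  }
  support <- which(pmf > 0) - 1L
  prob <- pmf[pmf > 0]
  mu <- sum(support * prob)
  list(support = support, prob = prob, mean = mu,
       sd = sqrt(sum((support - mu)^2 * prob)))
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' @export
print.bias_test <- function(x, ...) {
  cat("Co-option bias resampling test\n")
  cat(sprintf("  observed distinct lineages: %d\n", x$observed))
  cat(sprintf("  null mean %.2f (sd %.2f), B = %d\n",
              x$null_mean, x$null_sd, x$B))
  cat(sprintf("  one-sided P (fewer than expected) = %.4g\n", x$p_value))
  invisible(x)
}

## run code under a temporary seed; NULL seed = use current RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
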