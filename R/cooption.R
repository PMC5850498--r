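#' Call gene lineages as co-opted for C4 per independent origin
#'
#' A lineage is called co-opted in a C4 origin when its leaf abundance
#' (replicate-mean rpkm) reaches `threshold` in at least one sampled C4
#' species of that origin, provided the lineage is not excluded. A lineage
#' is excluded — all calls false — when its leaf abundance reaches the same
#' threshold in at least one non-C4 species, i.e. its high expression is not
#' diagnostic of the C4 pathway (the beta-carbonic-anhydrase situation).
#'
#' @param expr An `expression_matrix` (see [build_expression_matrix()]).
#' @param meta Species-level metadata (`species_id`, `type`, `origin_id`) or
#'   library metadata from which it is derived.
#' @param lineages data.frame `lineage_id`, `family_id` (extra columns
#'   ignored).
#' @param threshold Leaf rpkm threshold for the call (default 500;
#'   common alternatives 300, 1000, 1500).
#' @return An object of class `cooption_calls`: list with `threshold`,
#'   `calls` (data.frame `lineage_id`, `origin_id`, `call`), `excluded`
#'   (data.frame `lineage_id`, `reason`), `counts` (per-lineage table, see
#'   [count_cooptions()]), `origins` (origin ids), `universe` (lineage ids
#'   of families with at least one co-opted lineage).
#' @export
call_cooption <- function(expr, meta, lineages, threshold = 500) {
  stopifnot(is.data.frame(expr), threshold > 0)
  required_cols(lineages, c("lineage_id", "family_id"), "lineages")
  if ("library_id" %in% names(meta)) meta <- species_metadata(meta)
  required_cols(meta, c("species_id", "type", "origin_id"), "meta")
  c4 <- meta[meta$type == "C4", , drop = FALSE]
  if (any(is.na(c4$origin_id)))
    stop("C4 species without origin label: ",
         paste(c4$species_id[is.na(c4$origin_id)], collapse = ", "))
  origins <- sort(unique(as.character(c4$origin_id)))

  leaf <- expr[expr$tissue == "leaf", , drop = FALSE]
  leaf <- merge(leaf, meta, by = "species_id")
  ids <- lineages$lineage_id

  ## exclusion: >= threshold in any non-C4 species
  non_c4_hit <- leaf$type == "nonC4" & leaf$rpkm >= threshold
  excluded_ids <- unique(leaf$lineage_id[non_c4_hit])
  excluded <- data.frame(
    lineage_id = excluded_ids,
    reason = rep(sprintf("leaf rpkm >= %g in non-C4 species", threshold),
                 length(excluded_ids)),
    stringsAsFactors = FALSE)

  ## per (lineage, origin): any C4 species of the origin passing
  hit <- leaf$type == "C4" & leaf$rpkm >= threshold
  calls <- expand.grid(lineage_id = ids, origin_id = origins,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  passed <- unique(data.frame(lineage_id = leaf$lineage_id[hit],
                              origin_id = as.character(leaf$origin_id[hit]),
                              stringsAsFactors = FALSE))
  calls$call <- interaction(calls$lineage_id, calls$origin_id) %in%
    interaction(passed$lineage_id, passed$origin_id)
  calls$call[calls$lineage_id %in% excluded_ids] <- FALSE

  res <- structure(
    list(threshold = threshold, calls = calls, excluded = excluded,
         origins = origins, lineages = lineages[, c("lineage_id", "family_id")]),
    class = "cooption_calls")
  res$counts <- count_cooptions(res)$counts
  cofam <- unique(res$counts$family_id[res$counts$n_cooptions > 0])
  res$universe <- lineages$lineage_id[lineages$family_id %in% cofam]
  res
}

#' Tabulate per-lineage co-option counts
#'
#' Each origin contributes at most one count per lineage regardless of how
#' many of its sampled C4 species pass the threshold.
#'
#' @param calls A `cooption_calls` object (see [call_cooption()]).
#' @return List with `counts` (data.frame `lineage_id`, `family_id`,
#'   `n_cooptions`, `excluded`), `n_distinct` (lineages co-opted at least
#'   once) and `max_count`.
#' @export
count_cooptions <- function(calls) {
  stopifnot(inherits(calls, "cooption_calls"))
  cl <- calls$calls
  n <- tapply(cl$call, cl$lineage_id, sum)
  counts <- data.frame(lineage_id = names(n), n_cooptions = as.integer(n),
                       stringsAsFactors = FALSE)
  counts <- merge(calls$lineages, counts, by = "lineage_id")
  counts$excluded <- counts$lineage_id %in% calls$excluded$lineage_id
  counts <- counts[order(counts$lineage_id), ]
  rownames(counts) <- NULL
  stopifnot(all(counts$n_cooptions <= length(calls$origins)),
            all(counts$n_cooptions[counts$excluded] == 0))
  list(counts = counts,
       n_distinct = sum(counts$n_cooptions > 0),
       max_count = if (nrow(counts)) max(counts$n_cooptions) else 0L)
}

#' Co-option events implied by a call table
#'
#' One event per (origin, called lineage); an origin that co-opted two
#' lineages of the same family therefore contributes two events to that
#' family.
#'
#' @param calls A `cooption_calls` object.
#' @return data.frame `origin_id`, `family_id`, `lineage_id`, one row per
#'   event.
#' @export
cooption_events <- function(calls) {
  stopifnot(inherits(calls, "cooption_calls"))
  ev <- calls$calls[calls$calls$call, c("origin_id", "lineage_id")]
  ev <- merge(ev, calls$lineages, by = "lineage_id")
  ev <- ev[order(ev$origin_id, ev$family_id, ev$lineage_id),
           c("origin_id", "family_id", "lineage_id")]
  rownames(ev) <- NULL
  ev
}

#' Gene-family sizes from a lineage table
#'
#' @param lineages data.frame with `lineage_id`, `family_id`.
#' @param universe Optional lineage ids to restrict to (default all).
#' @return Named integer vector, family id -> number of lineages.
#' @export
family_sizes <- function(lineages, universe = NULL) {
  if (!is.null(universe))
    lineages <- lineages[lineages$lineage_id %in% universe, , drop = FALSE]
  tab <- table(lineages$family_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a per-lineage co-option count table
#'
#' Reader for TSVs with columns `lineage_id`, `family_id`, `n_cooptions`,
#' such as the bundled transcription of published grass co-option counts
#' (`system.file("extdata", "table1_cooption_counts.tsv",
#' package = "c4coopt")`).
#'
#' @param file TSV path.
#' @return data.frame with the three columns, counts as integers.
#' @export
read_cooption_counts <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  required_cols(x, c("lineage_id", "family_id", "n_cooptions"), "counts")
  if (any(x$n_cooptions < 0)) stop("negative co-option count")
  x$n_cooptions <- as.integer(x$n_cooptions)
  x
}

#' @export
print.cooption_calls <- function(x, ...) {
  cc <- count_cooptions(x)
  cat("Co-option calls at threshold", x$threshold, "rpkm\n")
  cat("  origins:", length(x$origins),
      " lineages:", nrow(x$counts),
      " co-opted >=1x:", cc$n_distinct,
      " max count:", cc$max_count, "\n")
  if (nrow(x$excluded))
    cat("  excluded (non-C4 above threshold):",
        paste(x$excluded$lineage_id, collapse = ", "), "\n")
  invisible(x)
}
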