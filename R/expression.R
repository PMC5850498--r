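#' Reads per kilobase per million cleaned reads (rpkm)
#'
#' The transcript-abundance proxy used throughout this package:
#' `count / ((length_bp / 1000) * (library_total / 1e6))`. No pseudocounts
#' and no length-bias or GC correction are applied.
#'
#' @param count Mapped read count(s), non-negative.
#' @param length_bp Effective length of the co-ortholog group in bp, > 0.
#' @param library_total Cleaned-read total of the library, > 0.
#' @return Numeric rpkm value(s); vectorized with recycling.
#' @examples
#' compute_rpkm(1000, 1000, 1e6)  # 1000
#' compute_rpkm(500, 2000, 1e7)   # 25
#' @export
compute_rpkm <- function(count, length_bp, library_total) {
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("effective length must be > 0")
  if (any(!is.finite(library_total)) || any(library_total <= 0))
    stop("library total must be > 0")
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be non-negative")
  count / ((length_bp / 1000) * (library_total / 1e6))
}

## ---- input tables ---------------------------------------------------------

required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Validate library metadata
#'
#' Checks the library-level metadata contract: tissue in {leaf, root},
#' unique (species, tissue, replicate) triples, photosynthetic type in
#' {C4, nonC4} constant within species, and an origin id present iff the
#' species is C4.
#'
#' @param libraries data.frame with columns `library_id`, `species_id`,
#'   `tissue`, `replicate`, `type`, `origin_id` (NA for non-C4).
#' @return The validated data.frame, invisibly.
#' @export
validate_libraries <- function(libraries) {
  required_cols(libraries,
                c("library_id", "species_id", "tissue", "replicate",
                  "type", "origin_id"), "libraries")
  if (anyDuplicated(libraries$library_id))
    stop("duplicate library ids")
  bad <- setdiff(unique(libraries$tissue), c("leaf", "root"))
  if (length(bad)) stop("unknown tissue value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(libraries$type), c("C4", "nonC4"))
  if (length(bad)) stop("unknown type value(s): ", paste(bad, collapse = ", "))
  key <- paste(libraries$species_id, libraries$tissue, libraries$replicate)
  if (anyDuplicated(key))
    stop("duplicate (species, tissue, replicate) triple(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  sp <- unique(libraries[, c("species_id", "type", "origin_id")])
  if (anyDuplicated(sp$species_id))
    stop("species with inconsistent type/origin across libraries: ",
         paste(unique(sp$species_id[duplicated(sp$species_id)]),
               collapse = ", "))
  c4 <- sp$type == "C4"
  if (any(c4 & (is.na(sp$origin_id) | !nzchar(as.character(sp$origin_id)))))
    stop("C4 species without origin label: ",
         paste(sp$species_id[c4 & is.na(sp$origin_id)], collapse = ", "))
  if (any(!c4 & !is.na(sp$origin_id)))
    stop("non-C4 species carries an origin label: ",
         paste(sp$species_id[!c4 & !is.na(sp$origin_id)], collapse = ", "))
  invisible(libraries)
}

#' Species-level metadata from library metadata
#'
#' @param libraries Validated library metadata (see [validate_libraries()]).
#' @return data.frame with one row per species: `species_id`, `type`,
#'   `origin_id`.
#' @export
species_metadata <- function(libraries) {
  validate_libraries(libraries)
  sp <- unique(libraries[, c("species_id", "type", "origin_id")])
  rownames(sp) <- NULL
  sp
}

#' Read the four expression input tables
#'
#' @param counts_file TSV with columns `library_id`, `lineage_id`, `count`.
#' @param lineages_file TSV with columns `lineage_id`, `family_id`,
#'   `effective_length_bp`.
#' @param libraries_file TSV with columns `library_id`, `species_id`,
#'   `tissue`, `replicate`, `type`, `origin_id` (empty for non-C4).
#' @param totals_file TSV with columns `library_id`, `cleaned_reads`.
#' @return Named list `counts`, `lineages`, `libraries`, `totals` of
#'   validated data.frames.
#' @export
read_expression_inputs <- function(counts_file, lineages_file,
                                   libraries_file, totals_file) {
  rd <- function(f) {
    if (!file.exists(f)) stop("input file not found: ", f)
    utils::read.delim(f, stringsAsFactors = FALSE)
  }
  libs <- rd(libraries_file)
  if (!"origin_id" %in% names(libs)) libs$origin_id <- NA
  libs$origin_id[!nzchar(as.character(libs$origin_id))] <- NA
  out <- list(counts = rd(counts_file), lineages = rd(lineages_file),
              libraries = libs, totals = rd(totals_file))
  validate_expression_inputs(out)
  out
}

validate_expression_inputs <- function(x) {
  required_cols(x$counts, c("library_id", "lineage_id", "count"), "counts")
  required_cols(x$lineages,
                c("lineage_id", "family_id", "effective_length_bp"),
                "lineages")
  required_cols(x$totals, c("library_id", "cleaned_reads"), "totals")
  validate_libraries(x$libraries)
  if (any(x$counts$count < 0) || any(x$counts$count %% 1 != 0))
    stop("counts must be non-negative integers")
  if (any(x$lineages$effective_length_bp <= 0))
    stop("effective length must be > 0 for every lineage")
  if (anyDuplicated(x$lineages$lineage_id))
    stop("duplicate lineage ids in lineages table")
  orphan <- setdiff(x$counts$library_id, x$libraries$library_id)
  if (length(orphan))
    stop("library id(s) in counts missing from metadata: ",
         paste(unique(orphan), collapse = ", "))
  orphan <- setdiff(x$counts$lineage_id, x$lineages$lineage_id)
  if (length(orphan))
    stop("lineage id(s) in counts missing from lineages table: ",
         paste(unique(orphan), collapse = ", "))
  orphan <- setdiff(x$libraries$library_id, x$totals$library_id)
  if (length(orphan))
    stop("library id(s) without cleaned-read totals: ",
         paste(unique(orphan), collapse = ", "))
  invisible(x)
}

## ---- expression matrix ----------------------------------------------------

#' Build the species-level expression matrix
#'
#' Computes rpkm per library (missing (library, lineage) count rows are
#' taken as zero), then averages arithmetically across biological
#' replicates of the same (species, tissue). A (lineage, species, tissue)
#' cell exists only if at least one library of that tissue exists for the
#' species; species sampled in one tissue only simply lack the other cells.
#'
#' @param counts data.frame `library_id`, `lineage_id`, `count`.
#' @param lineages data.frame `lineage_id`, `family_id`,
#'   `effective_length_bp`.
#' @param libraries Library metadata (see [validate_libraries()]).
#' @param totals data.frame `library_id`, `cleaned_reads`.
#' @return Long-format data.frame `lineage_id`, `species_id`, `tissue`,
#'   `rpkm`, `n_replicates`, of class `c("expression_matrix", "data.frame")`.
#' @export
build_expression_matrix <- function(counts, lineages, libraries, totals) {
  x <- list(counts = counts, lineages = lineages, libraries = libraries,
            totals = totals)
  validate_expression_inputs(x)

  ## full grid lineage x library, zero-filled
  grid <- expand.grid(lineage_id = lineages$lineage_id,
                      library_id = libraries$library_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- merge(grid, counts, by = c("library_id", "lineage_id"),
                all.x = TRUE)
  grid$count[is.na(grid$count)] <- 0
  grid <- merge(grid, lineages[, c("lineage_id", "effective_length_bp")],
                by = "lineage_id")
  grid <- merge(grid, totals, by = "library_id")
  grid <- merge(grid,
                libraries[, c("library_id", "species_id", "tissue")],
                by = "library_id")
  grid$rpkm <- compute_rpkm(grid$count, grid$effective_length_bp,
                            grid$cleaned_reads)

  key <- list(lineage_id = grid$lineage_id, species_id = grid$species_id,
              tissue = grid$tissue)
  out <- aggregate(grid$rpkm, by = key, FUN = mean)
  names(out)[4] <- "rpkm"
  nrep <- aggregate(grid$rpkm, by = key, FUN = length)
  out$n_replicates <- nrep$x
  out <- out[order(out$lineage_id, out$species_id, out$tissue), ]
  rownames(out) <- NULL
  class(out) <- c("expression_matrix", "data.frame")
  out
}

#' Leaf/root abundance ratio per lineage and species
#'
#' Proxy for leaf specificity of expression:
#' `(leaf + epsilon) / (root + epsilon)`. The pseudocount guards against
#' zero denominators; with `epsilon = 0` the raw ratio is returned. Species
#' lacking either tissue get `NA` rather than an error.
#'
#' @param expr An `expression_matrix` (see [build_expression_matrix()]).
#' @param epsilon Pseudocount in rpkm units added to both tissues
#'   (default 1).
#' @return data.frame `lineage_id`, `species_id`, `leaf`, `root`, `ratio`.
#' @export
leaf_root_ratio <- function(expr, epsilon = 1) {
  stopifnot(is.data.frame(expr))
  if (epsilon < 0) stop("epsilon must be >= 0")
  leaf <- expr[expr$tissue == "leaf", c("lineage_id", "species_id", "rpkm")]
  root <- expr[expr$tissue == "root", c("lineage_id", "species_id", "rpkm")]
  names(leaf)[3] <- "leaf"
  names(root)[3] <- "root"
  out <- merge(leaf, root, by = c("lineage_id", "species_id"), all = TRUE)
  out$ratio <- (out$leaf + epsilon) / (out$root + epsilon)
  out$ratio[is.na(out$leaf) | is.na(out$root)] <- NA_real_
  out[order(out$lineage_id, out$species_id), , drop = FALSE]
}

#' Write an expression matrix as TSV
#' @param expr An `expression_matrix`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_expression_matrix <- function(expr, file) {
  utils::write.table(expr, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
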