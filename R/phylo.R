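#' Read a rooted phylogeny from a newick string or file
#'
#' Parses a single rooted newick statement into an [ape::read.tree()] `phylo`
#' object, with validation suited to downstream comparative analyses: tip
#' labels must be unique and non-empty, branch lengths must be non-negative,
#' and absent branch lengths default to 1 with a warning. Internal node
#' labels (e.g. bootstrap values from tree-inference tools) are accepted and
#' retained, but ignored by all computations in this package.
#'
#' @param text A newick string terminated by `";"`. Exactly one of `text`
#'   and `file` must be given.
#' @param file Path to a file containing a single newick tree.
#' @return A `phylo` object (rooted, with `edge.length`).
#' @examples
#' tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
#' tr$tip.label
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("newick file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("newick parse error: empty string")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')')")
  if (!grepl(";\\s*$", text))
    stop("newick parse error: statement not terminated by ';'")
  if (sum(lengths(regmatches(text, gregexpr(";", text, fixed = TRUE)))) > 1L)
    stop("newick parse error: multiple statements; one tree per input")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: could not parse '",
         substr(text, 1, 40), "'")
  if (is.null(tree$edge.length)) {
    warning("newick input has no branch lengths; defaulting all to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("newick input has branches without lengths; defaulting those to 1")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  validate_phylogeny(tree)
  tree
}

#' Serialize a phylogeny to newick
#'
#' Round-trip stable: `read_newick(write_newick(t))` is isomorphic to `t`
#' with branch lengths preserved to full double precision.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if given the newick string is also written
#'   there (single line, trailing newline).
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(tree, warn_zero_internal = FALSE)
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

## Shared validation for all tree consumers.  Zero-length internal branches
## are legal (soft polytomies) but flagged; negative lengths never are.
validate_phylogeny <- function(tree, warn_zero_internal = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tips <- tree$tip.label
  if (any(!nzchar(tips)) || anyNA(tips))
    stop("tree has empty tip labels")
  if (anyDuplicated(tips))
    stop("duplicate tip labels: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  if (!is.null(tree$edge.length)) {
    if (any(tree$edge.length < 0))
      stop("negative branch lengths are not allowed")
    internal <- tree$edge[, 2] > length(tips)
    if (warn_zero_internal && any(tree$edge.length[internal] == 0))
      warning("tree has zero-length internal branches")
  }
  invisible(tree)
}

#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j, the
#' covariance structure induced by Brownian trait evolution; the diagonal
#' holds root-to-tip path lengths.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tips Character vector ordering the rows/columns; defaults to
#'   `tree$tip.label`.
#' @return A symmetric positive-semidefinite numeric matrix with `tips` as
#'   dimnames.
#' @examples
#' vcv_matrix(read_newick("((A:1,B:1):0.5,C:1.5);"))
#' @export
vcv_matrix <- function(tree, tips = tree$tip.label) {
  validate_phylogeny(tree, warn_zero_internal = FALSE)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  V <- ape::vcv.phylo(tree)
  V[tips, tips, drop = FALSE]
}
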