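#' Aggregate per-locus gene trees into one multi-newick file
#'
#' Collects newick trees from the given files (one or more trees per file,
#' one per line; Windows line endings are normalised), validates each with
#' [ape::read.tree()], optionally checks leaf labels against the species
#' roster, and writes them one per line — the `all.trees` input layout of
#' coalescent species-tree methods such as ASTRAL.
#'
#' The input newick strings are preserved verbatim (after line-ending
#' normalisation), so aggregation is byte-deterministic; ape is used for
#' validation only.
#'
#' @param tree_paths Character vector of newick file paths.
#' @param out_path Optional output path (conventional name `all.trees`).
#' @param roster Optional species roster; leaf labels outside it trigger a
#'   warning (not an error, since gene copies may carry decorated labels).
#' @return An object of class `gene_tree_set` with element `trees`
#'   (character vector of newick strings, input order).
#' @export
aggregate_gene_trees <- function(tree_paths, out_path = NULL, roster = NULL) {
  if (length(tree_paths) == 0L) abort("no tree files given")
  trees <- character(0)
  for (p in tree_paths) {
    if (!file.exists(p)) abort("tree file not found: %s", p)
    lines <- sub("\r$", "", readLines(p))
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) abort("tree file %s contains no trees", p)
    for (ln in lines) {
      tr <- tryCatch(ape::read.tree(text = ln), error = function(e) NULL,
                     warning = function(w) NULL)
      if (is.null(tr))
        abort("unparseable newick in %s: %.60s", p, ln)
      if (!is.null(roster)) {
        unknown <- setdiff(tr$tip.label, roster)
        if (length(unknown))
          warning(sprintf("tree in %s has leaf label(s) outside the roster: %s",
                          p, paste(utils::head(unknown, 3), collapse = ", ")))
      }
      trees <- c(trees, ln)
    }
  }
  if (!is.null(out_path)) writeLines(trees, out_path)
  structure(list(trees = trees), class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("gene_tree_set: %d trees\n", length(x$trees)))
  invisible(x)
}
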