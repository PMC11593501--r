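#' Construct an orthogroup
#'
#' An orthogroup holds, for one putative ancestral gene, the member gene
#' sequences grouped by species. Species with no copy may be omitted from
#' `members` or mapped to an empty vector; both mean "absent".
#'
#' @param og_id Orthogroup identifier (e.g. `"OG0000001"`).
#' @param members Named list mapping species label to a named character vector
#'   of amino-acid sequences (names are gene IDs). Empty vectors are allowed.
#' @return An object of class `orthogroup`.
#' @examples
#' og <- orthogroup("OG1", list(A = c(g1 = "MKV", g2 = "MKL"), B = c(g3 = "MKV")))
#' max_copy_number(og)
#' @export
orthogroup <- function(og_id, members) {
  if (!is_string(og_id) || !nzchar(og_id)) abort("og_id must be a non-empty string")
  if (!is.list(members) || is.null(names(members)) || any(!nzchar(names(members))))
    abort("members must be a named list (species -> gene sequences)")
  ids <- unlist(lapply(members, names), use.names = FALSE)
  n_genes <- sum(lengths(members))
  if (n_genes < 1L) abort("orthogroup '%s' has no genes", og_id)
  if (length(ids) != n_genes || any(!nzchar(ids)))
    abort("orthogroup '%s': every sequence must carry a gene ID", og_id)
  if (anyDuplicated(ids))
    abort("orthogroup '%s': duplicated gene ID '%s'", og_id, ids[duplicated(ids)][1])
  seqs <- unlist(members, use.names = FALSE)
  if (any(!nzchar(seqs))) abort("orthogroup '%s': empty sequence", og_id)
  structure(list(og_id = og_id, members = members), class = "orthogroup")
}

#' Construct an orthogroup set
#'
#' Bundles an ordered species roster (which fixes supermatrix row order and
#' the missing-rate denominator) with an ordered list of orthogroups.
#'
#' @param roster Character vector of unique species labels, in output order.
#' @param orthogroups List of [orthogroup()] objects; input order is preserved.
#' @return An object of class `orthogroup_set`.
#' @export
orthogroup_set <- function(roster, orthogroups) {
  if (!is.character(roster) || length(roster) == 0L || anyDuplicated(roster) ||
      any(!nzchar(roster)))
    abort("roster must be a non-empty character vector of unique species labels")
  if (!all(vapply(orthogroups, inherits, logical(1), "orthogroup")))
    abort("orthogroups must be a list of orthogroup objects")
  ids <- vapply(orthogroups, function(og) og$og_id, character(1))
  if (anyDuplicated(ids)) abort("duplicated og_id '%s'", ids[duplicated(ids)][1])
  for (og in orthogroups) {
    bad <- setdiff(names(og$members), roster)
    if (length(bad))
      abort("orthogroup '%s': species '%s' not in roster", og$og_id, bad[1])
  }
  names(orthogroups) <- ids
  structure(list(roster = roster, orthogroups = orthogroups),
            class = "orthogroup_set")
}

#' @export
print.orthogroup_set <- function(x, ...) {
  cat(sprintf("orthogroup_set: %d orthogroups over %d species\n",
              length(x$orthogroups), length(x$roster)))
  invisible(x)
}

#' @export
print.orthogroup <- function(x, ...) {
  cat(sprintf("orthogroup %s: %d genes in %d species\n", x$og_id,
              sum(lengths(x$members)), sum(lengths(x$members) > 0L)))
  invisible(x)
}

#' Per-species copy counts of an orthogroup
#'
#' @param og An [orthogroup()].
#' @param roster Optional species roster; when given, the result covers every
#'   roster species (absent species count 0) in roster order.
#' @return Named integer vector of copy counts.
#' @export
copy_counts <- function(og, roster = NULL) {
  n <- lengths(og$members)
  if (is.null(roster)) return(n)
  out <- stats::setNames(integer(length(roster)), roster)
  out[names(n)] <- n
  out
}

#' Read a protein FASTA file
#'
#' IDs are the first whitespace-delimited token of each header. Residues are
#' upper-cased and trailing stop codons (`*`) are stripped, so that ORF
#' predictions with terminal stops do not perturb alignment identity.
#'
#' @param path FASTA file path.
#' @param strip_stop Strip trailing `*` characters (default `TRUE`).
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path, strip_stop = TRUE) {
  if (!file.exists(path)) abort("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) abort("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    abort("duplicate sequence ID '%s' in %s", ids[duplicated(ids)][1], path)
  seqs <- toupper(as.character(ss))
  if (strip_stop) seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs)))
    abort("empty sequence for ID '%s' in %s", ids[!nzchar(seqs)][1], path)
  stats::setNames(seqs, ids)
}

#' Write a protein FASTA file
#'
#' @param records Named character vector of residue strings.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) == 0L) abort("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    abort("all records must be named")
  if (anyDuplicated(names(records)))
    abort("duplicate record ID '%s'", names(records)[duplicated(names(records))][1])
  if (any(!nzchar(records))) abort("empty sequence among records")
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    substring(s, seq(1L, nchar(s), width), pmin(seq(width, nchar(s) + width - 1L, width), nchar(s)))
  }
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), wrap(records[[id]]))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

## Read every FASTA in a directory (or one file) into a single gene->sequence
## map. Works for both per-species and per-orthogroup sequence layouts.
load_sequence_source <- function(sequence_source) {
  if (dir.exists(sequence_source)) {
    files <- list.files(sequence_source,
                        pattern = "\\.(fa|faa|fasta|pep)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
      abort("no FASTA files (*.fa, *.faa, *.fasta, *.pep) found in %s", sequence_source)
  } else if (file.exists(sequence_source)) {
    files <- sequence_source
  } else {
    abort("sequence_source '%s' does not exist", sequence_source)
  }
  recs <- lapply(sort(files), read_fasta)
  all <- unlist(recs)
  ## unlist() of length-1 file lists keeps names; re-derive explicitly
  ids <- unlist(lapply(recs, names), use.names = FALSE)
  names(all) <- ids
  if (anyDuplicated(ids))
    abort("gene ID '%s' appears in more than one FASTA record",
          ids[duplicated(ids)][1])
  all
}

#' Read orthogroups in the OrthoFinder table dialect
#'
#' Two table dialects are auto-detected from the header:
#' * wide (`Orthogroups.tsv`): header `Orthogroup<TAB><species...>`, one row
#'   per orthogroup, cells holding `", "`-separated gene IDs (empty cell =
#'   species absent). Species attribution comes from column position only.
#' * long: exactly two columns (orthogroup ID, gene ID); requires
#'   `species_map` to assign each gene to a species.
#'
#' Every listed gene ID must resolve to a FASTA record in `sequence_source`
#' (a single FASTA or a directory of per-species / per-orthogroup FASTAs).
#'
#' @param table_path Path to the orthogroup table.
#' @param sequence_source FASTA file or directory resolving every gene ID.
#' @param species_map For the long dialect: path to a two-column TSV
#'   (`gene_id<TAB>species`) or an equivalent data frame. The roster is the
#'   unique species in map order.
#' @return An [orthogroup_set()].
#' @export
read_orthogroups_tsv <- function(table_path, sequence_source, species_map = NULL) {
  if (!file.exists(table_path)) abort("orthogroup table not found: %s", table_path)
  header <- strsplit(readLines(table_path, n = 1L), "\t", fixed = TRUE)[[1]]
  seqs <- load_sequence_source(sequence_source)
  if (length(header) >= 2L && header[1] == "Orthogroup") {
    read_orthogroups_wide(table_path, seqs)
  } else if (length(header) == 2L) {
    if (is.null(species_map))
      abort("long-format table requires a species_map (gene_id -> species)")
    read_orthogroups_long(table_path, seqs, species_map)
  } else {
    abort("unrecognised orthogroup table header in %s", table_path)
  }
}

read_orthogroups_wide <- function(table_path, seqs) {
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (nrow(tab) == 0L) abort("orthogroup table %s has no rows", table_path)
  roster <- colnames(tab)[-1]
  seen <- character(0)
  ogs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    og_id <- tab[i, 1]
    members <- stats::setNames(vector("list", length(roster)), roster)
    for (sp in roster) {
      cell <- tab[i, sp]
      ids <- if (nzchar(trimws(cell))) trimws(strsplit(cell, ",", fixed = TRUE)[[1]]) else character(0)
      ids <- ids[nzchar(ids)]
      missing <- setdiff(ids, names(seqs))
      if (length(missing))
        abort("no sequence for gene '%s' (orthogroup '%s', species '%s')",
              missing[1], og_id, sp)
      members[[sp]] <- seqs[ids]
    }
    all_ids <- unlist(lapply(members, names), use.names = FALSE)
    dup <- all_ids[all_ids %in% seen]
    if (length(dup))
      abort("gene '%s' listed in more than one orthogroup", dup[1])
    seen <- c(seen, all_ids)
    ogs[[i]] <- orthogroup(og_id, members)
  }
  orthogroup_set(roster, ogs)
}

read_orthogroups_long <- function(table_path, seqs, species_map) {
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) abort("orthogroup table %s has no rows", table_path)
  if (is.character(species_map)) {
    species_map <- utils::read.delim(species_map, header = TRUE, sep = "\t",
                                     quote = "", colClasses = "character")
  }
  if (ncol(species_map) < 2L) abort("species_map needs columns gene_id, species")
  gene2sp <- stats::setNames(species_map[[2]], species_map[[1]])
  roster <- unique(species_map[[2]])
  unknown <- setdiff(tab[[2]], names(gene2sp))
  if (length(unknown)) abort("gene '%s' absent from species_map", unknown[1])
  if (anyDuplicated(tab[[2]]))
    abort("gene '%s' listed in more than one orthogroup",
          tab[[2]][duplicated(tab[[2]])][1])
  og_ids <- unique(tab[[1]])
  ogs <- lapply(og_ids, function(id) {
    g <- tab[[2]][tab[[1]] == id]
    missing <- setdiff(g, names(seqs))
    if (length(missing))
      abort("no sequence for gene '%s' (orthogroup '%s')", missing[1], id)
    members <- lapply(split(g, factor(gene2sp[g], levels = roster)), function(ids) seqs[ids])
    members <- members[lengths(members) > 0L]
    orthogroup(id, members)
  })
  orthogroup_set(roster, ogs)
}

#' Write an orthogroup set as an OrthoFinder-style table plus species FASTAs
#'
#' Emits `Orthogroups.tsv` (wide dialect) and one `<species>.faa` per roster
#' species into `dir`. This is the inverse of [read_orthogroups_tsv()] on the
#' wide dialect.
#'
#' @param set An [orthogroup_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the table path and the FASTA paths.
#' @export
write_orthogroups_tsv <- function(set, dir) {
  stopifnot(inherits(set, "orthogroup_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(dir, "Orthogroups.tsv")
  lines <- c(paste(c("Orthogroup", set$roster), collapse = "\t"))
  for (og in set$orthogroups) {
    cells <- vapply(set$roster, function(sp) {
      ids <- names(og$members[[sp]])
      if (is.null(ids)) "" else paste(ids, collapse = ", ")
    }, character(1))
    lines <- c(lines, paste(c(og$og_id, cells), collapse = "\t"))
  }
  writeLines(lines, tab_path)
  fasta_paths <- character(0)
  for (sp in set$roster) {
    recs <- unlist(lapply(set$orthogroups, function(og) og$members[[sp]]))
    ids <- unlist(lapply(set$orthogroups, function(og) names(og$members[[sp]])),
                  use.names = FALSE)
    if (length(ids) == 0L) next
    names(recs) <- ids
    p <- file.path(dir, paste0(sp, ".faa"))
    write_fasta(recs, p)
    fasta_paths <- c(fasta_paths, p)
  }
  invisible(list(table = tab_path, fastas = fasta_paths))
}
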