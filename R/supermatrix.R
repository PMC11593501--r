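#' Align one merged orthogroup into a locus alignment
#'
#' Builds the per-locus multiple alignment consumed by concatenation or by
#' per-locus gene-tree inference. Two aligners are available:
#' `"builtin_star"` (default) computes a centre-star alignment — the longest
#' sequence is the centre, every other sequence is globally aligned to it,
#' and pairwise gaps are propagated into a common coordinate system — which
#' is effectively exact for the near-identical consensus sequences this
#' pipeline produces; `"external_mafft"` shells out to a MAFFT executable for
#' general-purpose use.
#'
#' @param merged A `merged_orthogroup` (see [process_orthogroup()]) with at
#'   least two retained species; loci with fewer species are skipped with a
#'   warning (`NULL` is returned).
#' @param aligner `"builtin_star"` or `"external_mafft"`.
#' @param align_params An [alignment_params()] (builtin aligner only).
#' @param mafft_path MAFFT executable (default `"mafft"` on `PATH`).
#' @return An object of class `locus_alignment` (`og_id`, `rows` — named
#'   character vector of equal-length gapped strings — and `length`), or
#'   `NULL` for skipped loci.
#' @export
align_locus <- function(merged, aligner = c("builtin_star", "external_mafft"),
                        align_params = alignment_params(),
                        mafft_path = "mafft") {
  aligner <- match.arg(aligner)
  stopifnot(inherits(merged, "merged_orthogroup"))
  seqs <- merged$sequences
  if (length(seqs) < 2L) {
    warning(sprintf("orthogroup '%s': fewer than two species; locus skipped",
                    merged$og_id))
    return(NULL)
  }
  rows <- switch(aligner,
                 builtin_star = star_align(seqs, align_params),
                 external_mafft = mafft_align(seqs, mafft_path))
  locus_alignment(merged$og_id, rows)
}

locus_alignment <- function(og_id, rows) {
  len <- unique(nchar(rows))
  if (length(len) != 1L)
    abort("locus '%s': aligned rows have unequal lengths", og_id)
  structure(list(og_id = og_id, rows = rows, length = len),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment %s: %d species x %d columns\n",
              x$og_id, length(x$rows), x$length))
  invisible(x)
}

## Centre-star multiple alignment. Centre = longest sequence (ties broken by
## smallest name); every pairwise centre-vs-other alignment is merged by
## padding each inter-centre slot to the maximum insertion length seen there.
star_align <- function(seqs, params = alignment_params()) {
  if (length(seqs) == 1L) return(seqs)
  lens <- nchar(seqs)
  center_name <- sort(names(seqs)[lens == max(lens)])[1]
  center <- seqs[[center_name]]
  L <- nchar(center)
  others <- setdiff(names(seqs), center_name)
  ins_max <- integer(L + 1L)             # slot i: insertions before centre pos i
  at <- list(); ins <- list()
  for (nm in others) {
    al <- global_align(center, seqs[[nm]], params)
    ca <- chars(al$aligned_a)
    cb <- chars(al$aligned_b)
    cum <- cumsum(ca != "-")
    slots <- cum[ca == "-"] + 1L
    at[[nm]] <- cb[ca != "-"]
    ins[[nm]] <- split(cb[ca == "-"], factor(slots, levels = seq_len(L + 1L)))
    ins_max <- pmax(ins_max, tabulate(slots, nbins = L + 1L))
  }
  pad <- function(v, n) c(v, rep("-", n - length(v)))
  build <- function(at_chars, ins_list) {
    pieces <- character(0)
    for (i in seq_len(L))
      pieces <- c(pieces, pad(ins_list[[i]], ins_max[i]), at_chars[i])
    paste(c(pieces, pad(ins_list[[L + 1L]], ins_max[L + 1L])), collapse = "")
  }
  center_ins <- split(character(0), factor(integer(0), levels = seq_len(L + 1L)))
  rows <- stats::setNames(character(length(seqs)), names(seqs))
  rows[center_name] <- build(chars(center), center_ins)
  for (nm in others) rows[nm] <- build(at[[nm]], ins[[nm]])
  rows
}

mafft_align <- function(seqs, mafft_path) {
  if (Sys.which(mafft_path) == "" && !file.exists(mafft_path))
    abort(paste0("MAFFT executable '%s' not found; install MAFFT or use ",
                 "aligner = \"builtin_star\""), mafft_path)
  tmp_in <- tempfile(fileext = ".faa")
  on.exit(unlink(tmp_in))
  write_fasta(seqs, tmp_in)
  out <- suppressWarnings(system2(mafft_path, c("--auto", "--quiet", tmp_in),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || length(out) == 0L)
    abort("MAFFT failed with status %d", status)
  tmp_out <- tempfile(fileext = ".faa")
  on.exit(unlink(tmp_out), add = TRUE)
  writeLines(out, tmp_out)
  aligned <- read_fasta(tmp_out, strip_stop = FALSE)
  aligned[names(seqs)]
}

#' Concatenate locus alignments into a supermatrix
#'
#' Loci are concatenated in input order into one row per roster species;
#' species missing from a locus are padded with the fill character across
#' that locus' columns. The partition table records each locus' 1-based
#' inclusive column range.
#'
#' @param loci List of `locus_alignment` objects (`NULL` entries from skipped
#'   loci are tolerated and ignored).
#' @param roster Species roster; fixes row order and the full row set.
#' @param fill Fill character for missing species (default `"-"`).
#' @return An object of class `supermatrix`: `roster`, `matrix` (named
#'   character, one concatenated row per roster species) and `partitions`
#'   (data frame og_id/start/end).
#' @export
concatenate <- function(loci, roster, fill = "-") {
  loci <- Filter(Negate(is.null), loci)
  if (length(loci) == 0L) abort("no loci to concatenate")
  stopifnot(nchar(fill) == 1L)
  for (loc in loci) {
    bad <- setdiff(names(loc$rows), roster)
    if (length(bad))
      abort("locus '%s': species '%s' not in roster", loc$og_id, bad[1])
  }
  lens <- vapply(loci, function(l) l$length, numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  partitions <- data.frame(
    og_id = vapply(loci, function(l) l$og_id, character(1)),
    start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE)
  rows <- vapply(roster, function(sp) {
    paste(vapply(loci, function(l) {
      if (sp %in% names(l$rows)) l$rows[[sp]] else strrep(fill, l$length)
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(roster = roster, matrix = rows, partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d sites (%d partitions)\n",
              length(x$matrix), nchar(x$matrix[[1]]),
              if (is.null(x$partitions)) 0L else nrow(x$partitions)))
  invisible(x)
}

#' Extract one partition from a supermatrix
#'
#' Returns the rows of the given locus, restricted to species with at least
#' one residue there (all-gap rows are the padding of absent species).
#'
#' @param sm A [concatenate()] result.
#' @param og_id Partition (orthogroup) identifier.
#' @return Named character vector of aligned rows.
#' @export
extract_partition <- function(sm, og_id) {
  stopifnot(inherits(sm, "supermatrix"), !is.null(sm$partitions))
  i <- match(og_id, sm$partitions$og_id)
  if (is.na(i)) abort("no partition '%s'", og_id)
  seg <- substring(sm$matrix, sm$partitions$start[i], sm$partitions$end[i])
  names(seg) <- names(sm$matrix)
  seg[gsub("-", "", seg) != ""]
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Header line `"<ntaxa> <nsites>"`, then one `"<name> <sequence>"` line per
#' species in roster order. Relaxed means names are not truncated to 10
#' characters (RAxML and IQ-TREE both accept this), so names must not
#' contain whitespace.
#'
#' @param sm A `supermatrix`.
#' @param path Output path (conventional name `final_OrthologsAlign_GDL.phy`).
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(sm, path = "final_OrthologsAlign_GDL.phy") {
  stopifnot(inherits(sm, "supermatrix"))
  if (length(sm$matrix) == 0L || nchar(sm$matrix[[1]]) == 0L)
    abort("refusing to write an empty supermatrix")
  if (any(grepl("\\s", names(sm$matrix))))
    abort("species names must not contain whitespace in relaxed PHYLIP")
  lines <- c(sprintf("%d %d", length(sm$matrix), nchar(sm$matrix[[1]])),
             sprintf("%s %s", names(sm$matrix), unname(sm$matrix)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' Inverse of [write_phylip()]; the partition table is not stored in PHYLIP
#' and comes back `NULL`.
#'
#' @param path Input path.
#' @return A `supermatrix` (without partitions).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) abort("bad PHYLIP header in %s", path)
  body <- lines[-1]
  if (length(body) != hdr[1]) abort("PHYLIP %s: expected %d taxa, found %d",
                                    path, hdr[1], length(body))
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[`, character(1), 1L)
  sq <- vapply(parts, `[`, character(1), 2L)
  if (any(nchar(sq) != hdr[2])) abort("PHYLIP %s: sequence length mismatch", path)
  structure(list(roster = nm, matrix = stats::setNames(sq, nm),
                 partitions = NULL), class = "supermatrix")
}

#' Write a RAxML-style partition file
#'
#' One line per locus: `PROT, <og_id> = <start>-<end>` with 1-based inclusive
#' coordinates.
#'
#' @param sm A `supermatrix` with a partition table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_partitions <- function(sm, path = "partitions.txt") {
  stopifnot(inherits(sm, "supermatrix"))
  p <- sm$partitions
  if (is.null(p) || nrow(p) == 0L) abort("supermatrix carries no partitions")
  if (any(p$start > p$end) || any(p$start[-1] <= p$end[-nrow(p)]))
    abort("partitions overlap or are out of order")
  writeLines(sprintf("PROT, %s = %d-%d", p$og_id, p$start, p$end), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path Input path.
#' @return Data frame with columns `og_id`, `start`, `end`.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*\\S+,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$", lines))
  if (any(lengths(m) != 4L)) abort("unparseable partition line in %s", path)
  data.frame(og_id = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Write per-locus alignment FASTAs
#'
#' One `<og_id>.fasta` per locus (aligned rows, record IDs = species labels),
#' the input layout expected by per-locus gene-tree inference.
#'
#' @param loci List of `locus_alignment` objects (`NULL` entries ignored).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_locus_fastas <- function(loci, dir) {
  loci <- Filter(Negate(is.null), loci)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(loci, function(l) {
    p <- file.path(dir, paste0(l$og_id, ".fasta"))
    write_fasta(l$rows, p)
    p
  }, character(1))
  invisible(paths)
}

#' Write per-orthogroup merged FASTAs
#'
#' One `<og_id>.merged.faa` per orthogroup with one (unaligned) consensus or
#' pass-through sequence per retained species; record IDs are species labels.
#'
#' @param merged_list List of `merged_orthogroup` objects (rejected ones are
#'   skipped).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_merged_fastas <- function(merged_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in merged_list) {
    if (!is.null(m$rejected) || length(m$sequences) == 0L) next
    p <- file.path(dir, paste0(m$og_id, ".merged.faa"))
    write_fasta(m$sequences, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
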