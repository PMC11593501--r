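#' Merge near-identical same-species copies into a consensus sequence
#'
#' Copies are star-aligned against the longest copy (ties broken by the
#' lexicographically smallest gene ID), giving one residue-or-gap per copy at
#' each reference position; columns where the reference carries a gap
#' (insertions private to non-reference copies) are dropped. Each reference
#' column is then decided by voting over the non-gap residues:
#'
#' * all votes identical: the residue is kept (unanimous site);
#' * a residue holds a strict majority (more than half of the non-gap votes):
#'   that residue is kept (similar site, merged);
#' * otherwise the column is removed (divergent site, trimmed).
#'
#' Gaps never vote, so fragmentary copies cannot create artificial
#' divergence. For a heterozygous allele pair the unanimous sites are exactly
#' the sites where the alleles agree, and the trimmed sites are the
#' heterozygous positions.
#'
#' Callers must gate the copies with [copies_mergeable()] first; this
#' function assumes the copies are near-identical.
#'
#' @param copies Named character vector of `>= 2` same-species sequences
#'   (names are gene IDs).
#' @param params An [alignment_params()].
#' @param species Optional species label recorded in the result.
#' @return An object of class `merge_record`: `species`, `input_gene_ids`,
#'   `consensus`, `n_sites_unanimous`, `n_sites_majority`, `n_sites_trimmed`,
#'   `min_pairwise_identity`.
#' @examples
#' merge_copies(c(a1 = "MKVLD", a2 = "MKALD"))$consensus  # "MKLD"
#' @export
merge_copies <- function(copies, params = alignment_params(), species = NA_character_) {
  if (length(copies) < 2L) abort("merge_copies requires at least two copies")
  if (is.null(names(copies)) || anyDuplicated(names(copies)))
    abort("copies must carry unique gene IDs as names")
  lens <- nchar(copies)
  ref_id <- sort(names(copies)[lens == max(lens)])[1]
  ref <- copies[[ref_id]]
  L <- nchar(ref)
  others <- copies[setdiff(names(copies), ref_id)]
  votes <- matrix("-", nrow = length(copies), ncol = L)
  votes[1L, ] <- chars(ref)
  for (k in seq_along(others)) {
    al <- global_align(ref, others[[k]], params)
    ca <- chars(al$aligned_a)
    cb <- chars(al$aligned_b)
    votes[k + 1L, ] <- cb[ca != "-"]
  }
  consensus <- character(L)
  kind <- character(L)   # "unanimous" | "majority" | "trimmed"
  for (j in seq_len(L)) {
    v <- votes[, j]
    v <- v[v != "-"]
    if (length(v) == 0L) { kind[j] <- "trimmed"; next }
    tab <- table(v)
    if (length(tab) == 1L) {
      consensus[j] <- names(tab); kind[j] <- "unanimous"
    } else if (max(tab) > length(v) / 2) {
      consensus[j] <- names(tab)[which.max(tab)]; kind[j] <- "majority"
    } else {
      kind[j] <- "trimmed"
    }
  }
  pairs <- utils::combn(length(copies), 2L)
  min_id <- min(pairwise_identity_batch(unname(copies[pairs[1L, ]]),
                                        unname(copies[pairs[2L, ]]), params))
  structure(list(
    species = species,
    input_gene_ids = names(copies),
    consensus = paste(consensus[kind != "trimmed"], collapse = ""),
    n_sites_unanimous = sum(kind == "unanimous"),
    n_sites_majority = sum(kind == "majority"),
    n_sites_trimmed = sum(kind == "trimmed"),
    min_pairwise_identity = min_id), class = "merge_record")
}

#' @export
print.merge_record <- function(x, ...) {
  cat(sprintf(
    "merge_record [%s]: %d copies -> %d sites (%d unanimous, %d majority, %d trimmed), min identity %.4f\n",
    x$species, length(x$input_gene_ids), nchar(x$consensus),
    x$n_sites_unanimous, x$n_sites_majority, x$n_sites_trimmed,
    x$min_pairwise_identity))
  invisible(x)
}

#' Reduce one orthogroup to at most one sequence per species
#'
#' Single-copy species pass through unchanged; multi-copy species are gated
#' by [copies_mergeable()] and merged with [merge_copies()]. If any species
#' fails the similarity gate the orthogroup is either rejected outright
#' (`reject_policy = "drop_orthogroup"`, the default) or that species is
#' dropped (`"drop_species"`). Species whose consensus trims to nothing are
#' dropped with a warning.
#'
#' @param og An [orthogroup()] that already passed the structural filters.
#' @param roster Species roster; fixes the order of the output sequences.
#' @param params A [filter_params()] (supplies `min_similarity` and
#'   `reject_policy`).
#' @param align_params An [alignment_params()].
#' @return An object of class `merged_orthogroup`: `og_id`, `sequences`
#'   (named character, one per retained species, roster order),
#'   `merge_records` (one per merged species), `rejected` (`NULL` or
#'   `"fail_similarity"`).
#' @export
process_orthogroup <- function(og, roster, params = filter_params(),
                               align_params = alignment_params()) {
  stopifnot(inherits(og, "orthogroup"))
  seqs <- character(0)
  records <- list()
  for (sp in names(og$members)) {
    copies <- og$members[[sp]]
    if (length(copies) == 0L) next
    if (length(copies) == 1L) {
      seqs[sp] <- unname(copies)
      next
    }
    cm <- copies_mergeable(copies, params$min_similarity, align_params)
    if (!cm$mergeable) {
      if (params$reject_policy == "drop_orthogroup") {
        return(structure(list(og_id = og$og_id, sequences = character(0),
                              merge_records = list(),
                              rejected = "fail_similarity"),
                         class = "merged_orthogroup"))
      }
      next
    }
    rec <- merge_copies(copies, align_params, species = sp)
    if (!nzchar(rec$consensus)) {
      warning(sprintf("orthogroup '%s': consensus for species '%s' trimmed to nothing; species dropped",
                      og$og_id, sp))
      next
    }
    records[[sp]] <- rec
    seqs[sp] <- rec$consensus
  }
  seqs <- seqs[roster[roster %in% names(seqs)]]
  structure(list(og_id = og$og_id, sequences = seqs,
                 merge_records = records, rejected = NULL),
            class = "merged_orthogroup")
}

#' @export
print.merged_orthogroup <- function(x, ...) {
  if (!is.null(x$rejected)) {
    cat(sprintf("merged_orthogroup %s: rejected (%s)\n", x$og_id, x$rejected))
  } else {
    cat(sprintf("merged_orthogroup %s: %d species (%d merged)\n", x$og_id,
                length(x$sequences), length(x$merge_records)))
  }
  invisible(x)
}

#' Write merge provenance as TSV
#'
#' One row per merged species:
#' og_id, species, input gene IDs, minimum pairwise identity and the
#' unanimous/majority/trimmed site counts.
#'
#' @param merged_list List of `merged_orthogroup` objects.
#' @param path Output TSV path.
#' @return Invisibly, the provenance data frame.
#' @export
write_merge_provenance <- function(merged_list, path) {
  rows <- list()
  for (m in merged_list) {
    for (rec in m$merge_records) {
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = m$og_id, species = rec$species,
        input_gene_ids = paste(rec$input_gene_ids, collapse = ","),
        min_identity = rec$min_pairwise_identity,
        n_unanimous = rec$n_sites_unanimous,
        n_majority = rec$n_sites_majority,
        n_trimmed = rec$n_sites_trimmed,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(og_id = character(0), species = character(0),
               input_gene_ids = character(0), min_identity = numeric(0),
               n_unanimous = integer(0), n_majority = integer(0),
               n_trimmed = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
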