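#' Configuration for an end-to-end pipeline run
#'
#' Bundles input paths, thresholds and output choices. The configuration is
#' serialized verbatim into `run_manifest.json` in the output directory so a
#' run can be reproduced exactly.
#'
#' @param orthogroups_tsv Path to the orthogroup table
#'   (see [read_orthogroups_tsv()]).
#' @param sequence_source FASTA file or directory resolving every gene ID.
#' @param out_dir Output directory (created; must not be an existing
#'   non-empty file).
#' @param method `"concat"`, `"coalescent"` or `"both"`.
#' @param filter A [filter_params()].
#' @param align An [alignment_params()].
#' @param aligner `"builtin_star"` or `"external_mafft"`.
#' @param mafft_path MAFFT executable for `aligner = "external_mafft"`.
#' @param species_map Optional gene-to-species map for the long table
#'   dialect.
#' @param gene_tree_paths Optional newick files to aggregate into
#'   `all.trees` (coalescent method).
#' @param fill Fill character for species missing from a locus (default
#'   `"-"`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(orthogroups_tsv, sequence_source, out_dir,
                       method = c("concat", "coalescent", "both"),
                       filter = filter_params(),
                       align = alignment_params(),
                       aligner = c("builtin_star", "external_mafft"),
                       mafft_path = "mafft",
                       species_map = NULL,
                       gene_tree_paths = NULL,
                       fill = "-") {
  structure(list(orthogroups_tsv = orthogroups_tsv,
                 sequence_source = sequence_source,
                 out_dir = out_dir,
                 method = match.arg(method),
                 filter = filter, align = align,
                 aligner = match.arg(aligner),
                 mafft_path = mafft_path,
                 species_map = species_map,
                 gene_tree_paths = gene_tree_paths,
                 fill = fill),
            class = "run_config")
}

#' Run the full orthogroup selection pipeline
#'
#' Reads the orthogroup table, applies the structural and similarity
#' filters, merges multi-copy species into consensus sequences, aligns the
#' retained loci, and writes the outputs for the chosen tree-building route:
#'
#' * `concat`/`both`: `final_OrthologsAlign_GDL.phy` (relaxed PHYLIP
#'   supermatrix) and `partitions.txt`;
#' * `coalescent`/`both`: per-locus alignments under `loci/`, per-orthogroup
#'   merged FASTAs under `merged/`, and `all.trees` if gene trees are
#'   supplied.
#'
#' Every run also writes `filter_report.tsv` / `filter_summary.json`,
#' `merge_provenance.tsv`, `run_manifest.json` and `run.log` (the stage
#' counts: input orthogroups, structural passes, similarity passes, emitted
#' loci). On any hard error the partially written output directory is
#' removed (if this run created it) before the error propagates.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `report` (the `filter_report`), `merged`
#'   (the merged orthogroups), `loci`, `supermatrix` (or `NULL`) and
#'   `counts` (the stage counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  created <- !dir.exists(config$out_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(config$out_dir, recursive = TRUE))

  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  set <- read_orthogroups_tsv(config$orthogroups_tsv, config$sequence_source,
                              config$species_map)
  note("input orthogroups: %d (%d species)", length(set$orthogroups),
       length(set$roster))

  fr <- filter_orthogroups(set, config$filter, config$align,
                           check_similarity = TRUE)
  n_structural <- sum(fr$report$table$outcome %in% c("pass", "fail_similarity"))
  n_pass <- sum(fr$report$table$outcome == "pass")
  note("pass structural filters (missing rate <= %.3g, copies <= %d): %d",
       config$filter$max_missing_rate, config$filter$max_duplication_num,
       n_structural)
  note("pass similarity gate (identity >= %.3g, %s): %d",
       config$filter$min_similarity, config$filter$reject_policy, n_pass)

  merged <- if (is.null(fr$set)) list() else
    lapply(fr$set$orthogroups, process_orthogroup, roster = set$roster,
           params = config$filter, align_params = config$align)
  merged <- Filter(function(m) is.null(m$rejected), merged)

  loci <- list()
  for (m in merged) {
    if (length(m$sequences) < 2L) next
    loci[[m$og_id]] <- align_locus(m, aligner = config$aligner,
                                   align_params = config$align,
                                   mafft_path = config$mafft_path)
  }
  loci <- Filter(Negate(is.null), loci)
  note("emitted loci (>= 2 species after merging): %d", length(loci))

  write_filter_report(fr$report,
                      tsv = file.path(config$out_dir, "filter_report.tsv"),
                      json = file.path(config$out_dir, "filter_summary.json"))
  write_merge_provenance(merged,
                         file.path(config$out_dir, "merge_provenance.tsv"))

  sm <- NULL
  if (config$method %in% c("concat", "both")) {
    if (length(loci) == 0L) abort("no loci survive filtering; nothing to concatenate")
    sm <- concatenate(loci, set$roster, fill = config$fill)
    write_phylip(sm, file.path(config$out_dir, "final_OrthologsAlign_GDL.phy"))
    write_partitions(sm, file.path(config$out_dir, "partitions.txt"))
    note("supermatrix: %d taxa x %d sites in %d partitions",
         length(sm$matrix), nchar(sm$matrix[[1]]), nrow(sm$partitions))
  }
  if (config$method %in% c("coalescent", "both")) {
    write_locus_fastas(loci, file.path(config$out_dir, "loci"))
    write_merged_fastas(merged, file.path(config$out_dir, "merged"))
    if (!is.null(config$gene_tree_paths)) {
      gts <- aggregate_gene_trees(config$gene_tree_paths,
                                  out_path = file.path(config$out_dir, "all.trees"),
                                  roster = set$roster)
      note("aggregated gene trees: %d", length(gts$trees))
    }
  }

  manifest <- unclass(config)
  manifest$filter <- unclass(manifest$filter)
  manifest$align <- unclass(manifest$align)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  ok <- TRUE
  invisible(list(report = fr$report, merged = merged, loci = loci,
                 supermatrix = sm,
                 counts = c(input = length(set$orthogroups),
                            structural_pass = n_structural,
                            similarity_pass = n_pass,
                            loci = length(loci))))
}
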