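#' Filtering thresholds for orthogroup selection
#'
#' The three thresholds the selection pipeline applies, in order: species
#' missing rate, per-species maximum copy number, and minimum pairwise
#' identity among same-species copies. Defaults follow the method's standard
#' setting (missing rate 0.05, 6 copies, 97% identity); the lenient setting
#' used for supermatrix construction on highly duplicated transcriptomes is
#' `filter_params(0.10, 10, 0.95)`.
#'
#' @param max_missing_rate Maximum fraction of roster species allowed to lack
#'   the orthogroup (default 0.05).
#' @param max_duplication_num Maximum copy number of the orthogroup in any
#'   single species (default 6).
#' @param min_similarity Minimum pairwise alignment identity required among
#'   same-species copies before they may be merged (default 0.97). Values
#'   greater than 1 are interpreted as percentages and divided by 100.
#' @param reject_policy What to do when a species' copies fail
#'   `min_similarity`: `"drop_orthogroup"` (default) discards the orthogroup,
#'   `"drop_species"` discards only that species' copies.
#' @param strict Use strict `<` comparisons instead of the default inclusive
#'   `<=` for the missing-rate and copy-number thresholds.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(max_missing_rate = 0.05,
                          max_duplication_num = 6L,
                          min_similarity = 0.97,
                          reject_policy = c("drop_orthogroup", "drop_species"),
                          strict = FALSE) {
  reject_policy <- match.arg(reject_policy)
  if (min_similarity > 1) min_similarity <- min_similarity / 100
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            max_duplication_num >= 1,
            min_similarity >= 0, min_similarity <= 1)
  structure(list(max_missing_rate = max_missing_rate,
                 max_duplication_num = as.integer(max_duplication_num),
                 min_similarity = min_similarity,
                 reject_policy = reject_policy,
                 strict = isTRUE(strict)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("filter_params: missing rate <=%.3g, copies <=%d, identity >=%.3g (%s)\n",
              x$max_missing_rate, x$max_duplication_num, x$min_similarity,
              x$reject_policy))
  invisible(x)
}

#' Species missing rate of an orthogroup
#'
#' The fraction of roster species with zero copies in the orthogroup. Genes
#' belonging to species outside the roster do not count as presence.
#'
#' @param og An [orthogroup()].
#' @param roster Character vector of species labels (the denominator).
#' @return A fraction in `[0, 1]`.
#' @examples
#' og <- orthogroup("OG1", list(A = c(g1 = "MKV")))
#' missing_rate(og, c("A", "B"))  # 0.5
#' @export
missing_rate <- function(og, roster) {
  if (length(roster) == 0L) abort("roster must be non-empty")
  present <- names(og$members)[lengths(og$members) > 0L]
  sum(!(roster %in% present)) / length(roster)
}

#' Maximum per-species copy number of an orthogroup
#'
#' The largest number of copies the orthogroup has in any single species; 1
#' for every species means a one-to-one orthogroup.
#'
#' @param og An [orthogroup()].
#' @return A positive integer.
#' @export
max_copy_number <- function(og) {
  n <- lengths(og$members)
  if (sum(n) < 1L) abort("orthogroup '%s' has no genes", og$og_id)
  max(n)
}

FILTER_OUTCOMES <- c("pass", "fail_missing", "fail_duplication", "fail_similarity")

#' Apply the structural (missing-rate and copy-number) filters
#'
#' Tests the missing rate first, then the maximum copy number. Comparisons are
#' inclusive (`<=`) by default; with `strict = TRUE` in the params they become
#' strict (`<`).
#'
#' @param og An [orthogroup()].
#' @param roster Species roster.
#' @param params A [filter_params()].
#' @return `"pass"`, `"fail_missing"` or `"fail_duplication"`.
#' @export
passes_structural_filters <- function(og, roster, params = filter_params()) {
  mr <- missing_rate(og, roster)
  mc <- max_copy_number(og)
  if (params$strict) {
    if (mr >= params$max_missing_rate) return("fail_missing")
    if (mc >= params$max_duplication_num) return("fail_duplication")
  } else {
    if (mr > params$max_missing_rate) return("fail_missing")
    if (mc > params$max_duplication_num) return("fail_duplication")
  }
  "pass"
}

#' Filter an orthogroup set
#'
#' Applies the structural filters and, for structurally passing orthogroups,
#' the same-species similarity gate (all pairwise identities among a species'
#' copies must reach `min_similarity`; complete linkage). Under
#' `reject_policy = "drop_orthogroup"` a similarity failure discards the
#' orthogroup (`fail_similarity`); under `"drop_species"` only the offending
#' species' copies are removed and the orthogroup still passes. The missing
#' rate is always computed on the original membership, before any
#' similarity-based removal, so outcomes are order-independent.
#'
#' @param set An [orthogroup_set()].
#' @param params A [filter_params()].
#' @param align_params An [alignment_params()] for the identity computation.
#' @param check_similarity Apply the similarity gate (default `TRUE`). With
#'   `FALSE` only the structural filters run (cheaper; merging will re-check).
#' @return A list with `set` (the passing orthogroups, input order preserved,
#'   species-dropped where the policy says so) and `report` (a
#'   `filter_report`).
#' @export
filter_orthogroups <- function(set, params = filter_params(),
                               align_params = alignment_params(),
                               check_similarity = TRUE) {
  stopifnot(inherits(set, "orthogroup_set"))
  n <- length(set$orthogroups)
  outcome <- character(n)
  mr <- numeric(n)
  mc <- integer(n)
  min_id <- rep(NA_real_, n)
  kept <- vector("list", n)
  for (i in seq_len(n)) {
    og <- set$orthogroups[[i]]
    mr[i] <- missing_rate(og, set$roster)
    mc[i] <- max_copy_number(og)
    outcome[i] <- passes_structural_filters(og, set$roster, params)
  }
  ## similarity gate: one batched alignment call over every same-species
  ## copy pair of every structurally passing orthogroup
  if (check_similarity) {
    pair_og <- integer(0); pair_sp <- character(0)
    pa <- character(0); pb <- character(0)
    for (i in which(outcome == "pass")) {
      og <- set$orthogroups[[i]]
      for (sp in names(og$members)) {
        copies <- og$members[[sp]]
        if (length(copies) < 2L) next
        idx <- utils::combn(length(copies), 2L)
        pair_og <- c(pair_og, rep(i, ncol(idx)))
        pair_sp <- c(pair_sp, rep(sp, ncol(idx)))
        pa <- c(pa, unname(copies[idx[1L, ]]))
        pb <- c(pb, unname(copies[idx[2L, ]]))
      }
    }
    ids <- pairwise_identity_batch(pa, pb, align_params)
    for (i in unique(pair_og)) {
      sel <- pair_og == i
      min_id[i] <- min(ids[sel])
      sp_min <- tapply(ids[sel], pair_sp[sel], min)
      bad_species <- names(sp_min)[sp_min < params$min_similarity]
      if (length(bad_species)) {
        if (params$reject_policy == "drop_orthogroup") {
          outcome[i] <- "fail_similarity"
        } else {
          og <- set$orthogroups[[i]]
          members <- og$members[setdiff(names(og$members), bad_species)]
          if (sum(lengths(members)) >= 1L)
            kept[[i]] <- orthogroup(og$og_id, members)
          else outcome[i] <- "fail_similarity"
        }
      }
    }
  }
  for (i in which(outcome == "pass"))
    kept[[i]] <- kept[[i]] %||% set$orthogroups[[i]]
  passing <- Filter(Negate(is.null), kept)
  out_set <- if (length(passing)) orthogroup_set(set$roster, passing) else NULL
  report <- structure(list(
    table = data.frame(
      og_id = vapply(set$orthogroups, function(og) og$og_id, character(1)),
      outcome = outcome, missing_rate = mr, max_copy = mc,
      min_identity = min_id, row.names = NULL, stringsAsFactors = FALSE),
    counts = table(factor(outcome, levels = FILTER_OUTCOMES)),
    params = params), class = "filter_report")
  list(set = out_set, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d orthogroups\n", nrow(x$table)))
  for (o in FILTER_OUTCOMES)
    cat(sprintf("  %-16s %d\n", o, x$counts[[o]]))
  invisible(x)
}

#' Summarise a filter report
#'
#' @param object A `filter_report`.
#' @param ... Unused.
#' @return A list with outcome counts and histograms of missing rates and
#'   maximum copy numbers (both over all input orthogroups).
#' @method summary filter_report
#' @export
summary.filter_report <- function(object, ...) {
  list(counts = as.list(object$counts),
       missing_rate_hist = table(object$table$missing_rate),
       max_copy_hist = table(object$table$max_copy))
}

#' Write a filter report to disk
#'
#' @param report A `filter_report`.
#' @param tsv Optional path for the per-orthogroup TSV
#'   (og_id, outcome, missing_rate, max_copy, min_identity).
#' @param json Optional path for a JSON summary (outcome counts, thresholds,
#'   histograms).
#' @return Invisibly, the report.
#' @export
write_filter_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "filter_report"))
  if (!is.null(tsv)) {
    utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    s <- summary(report)
    jsonlite::write_json(list(
      params = unclass(report$params),
      counts = s$counts,
      missing_rate_hist = as.list(s$missing_rate_hist),
      max_copy_hist = as.list(s$max_copy_hist)), json,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
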