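#' Parameters for a synthetic orthogroup dataset
#'
#' Describes a generative scenario with the statistical structure the filter
#' is designed for: every orthogroup descends from a random ancestral
#' protein; each species carries an independently mutated base copy unless
#' lost; heterozygosity and recent duplication add near-identical extra
#' copies; deep-paralog contamination adds a highly divergent copy (emulating
#' ancient whole-genome duplication remnants swept into the orthogroup).
#'
#' @param n_species Number of species (default 24).
#' @param n_orthogroups Number of orthogroups (default 1000).
#' @param seq_length Ancestral protein length in residues (default 300).
#' @param het_prob Probability a present species contributes a second,
#'   heterozygous allele (default 0.15).
#' @param het_divergence Per-site substitution probability between the two
#'   alleles (default 0.01, i.e. ~99% identity — the heterozygosity peak of
#'   de novo assembled transcriptomes).
#' @param dup_prob Probability of an additional recent duplicate, diverged at
#'   `het_divergence` (default 0.05).
#' @param paralog_prob Probability of injecting a deep paralog (default
#'   0.02) at `paralog_divergence`.
#' @param paralog_divergence Per-site substitution probability of the deep
#'   paralog relative to the species base copy (default 0.40, the
#'   whole-genome-duplication regime).
#' @param loss_prob Per-species probability of absence (default 0.02).
#' @param species_divergence Per-site substitution probability between a
#'   species base copy and the orthogroup ancestor (default 0.05).
#' @param indel_prob Probability that a het/dup extra copy additionally
#'   carries a short deletion (1-3 residues), exercising gap handling
#'   (default 0; with indels the similarity ground truth is not analytic and
#'   is reported as `NA`).
#' @param seed Integer seed; fully determines the dataset.
#' @return An object of class `synth_scenario`.
#' @export
synth_scenario <- function(n_species = 24L, n_orthogroups = 1000L,
                           seq_length = 300L,
                           het_prob = 0.15, het_divergence = 0.01,
                           dup_prob = 0.05,
                           paralog_prob = 0.02, paralog_divergence = 0.40,
                           loss_prob = 0.02, species_divergence = 0.05,
                           indel_prob = 0, seed = 1L) {
  probs <- c(het_prob, het_divergence, dup_prob, paralog_prob,
             paralog_divergence, loss_prob, species_divergence, indel_prob)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (n_species < 1L || n_orthogroups < 1L)
    abort("need at least one species and one orthogroup")
  if (seq_length < 1L) abort("seq_length must be positive")
  structure(list(n_species = as.integer(n_species),
                 n_orthogroups = as.integer(n_orthogroups),
                 seq_length = as.integer(seq_length),
                 het_prob = het_prob, het_divergence = het_divergence,
                 dup_prob = dup_prob, paralog_prob = paralog_prob,
                 paralog_divergence = paralog_divergence,
                 loss_prob = loss_prob,
                 species_divergence = species_divergence,
                 indel_prob = indel_prob, seed = as.integer(seed)),
            class = "synth_scenario")
}

#' Mutate a protein sequence site-by-site
#'
#' Each site is independently substituted with probability `p`; a substituted
#' site takes a uniformly chosen residue different from the original, so the
#' realized number of substitutions is exactly the Hamming distance to the
#' input.
#'
#' @param seq Residue string.
#' @param p Per-site substitution probability.
#' @return The mutated residue string.
#' @export
mutate_seq <- function(seq, p) {
  stopifnot(p >= 0, p <= 1)
  cs <- chars(seq)
  hit <- stats::runif(length(cs)) < p
  if (any(hit)) {
    cs[hit] <- vapply(cs[hit], function(r) sample(setdiff(AA_RESIDUES, r), 1L),
                      character(1))
  }
  paste(cs, collapse = "")
}

random_protein <- function(L) paste(sample(AA_RESIDUES, L, replace = TRUE),
                                    collapse = "")

hamming_identity <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

delete_stretch <- function(seq, max_len = 3L) {
  L <- nchar(seq)
  k <- sample(seq_len(min(max_len, L - 1L)), 1L)
  start <- sample(L - k + 1L, 1L)
  paste0(substr(seq, 1L, start - 1L), substr(seq, start + k, L))
}

#' Generate a synthetic orthogroup dataset with ground truth
#'
#' Realizes the scenario draws, writes the dataset in the OrthoFinder table
#' dialect (`Orthogroups.tsv` + one `<species>.faa` per species) plus a
#' `ground_truth.tsv`, and returns the in-memory orthogroup set together
#' with the ground truth. The truth is computed analytically from the
#' realized draws — realized species absences, realized copy counts, and
#' exact Hamming identities among same-species copies (the sequences are
#' generated without indels by default, so the optimal global alignment is
#' gapless and Hamming identity equals alignment identity) — never by
#' running the filtering pipeline itself.
#'
#' The same seed yields byte-identical files.
#'
#' @param scenario A [synth_scenario()].
#' @param dir Optional output directory; when `NULL` nothing is written.
#' @return A list with `set` (an [orthogroup_set()]), `truth` (a
#'   `synth_truth`: `table` with per-orthogroup realized statistics,
#'   `per_species` with one row per multi-copy species-orthogroup pair and
#'   its minimum copy identity, `ancestral` with the pre-mutation species
#'   base sequences; see [ground_truth_labels()]), and `files` (paths, or
#'   `NULL`).
#' @export
generate_dataset <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "synth_scenario"))
  sc <- scenario
  with_local_seed(sc$seed, {
    species <- sprintf("species_%02d", seq_len(sc$n_species))
    ogs <- vector("list", sc$n_orthogroups)
    truth_rows <- vector("list", sc$n_orthogroups)
    sp_rows <- list()
    ancestral <- vector("list", sc$n_orthogroups)
    for (i in seq_len(sc$n_orthogroups)) {
      og_id <- sprintf("OG%07d", i)
      root <- random_protein(sc$seq_length)
      members <- list()
      anc <- character(0)
      min_id <- NA_real_
      exact_id <- TRUE
      for (sp in species) {
        if (stats::runif(1) < sc$loss_prob) next
        base <- mutate_seq(root, sc$species_divergence)
        anc[sp] <- base
        copies <- c(stats::setNames(base, sprintf("%s_%s_c1", sp, og_id)))
        k <- 1L
        sp_exact <- TRUE
        add_copy <- function(s) {
          k <<- k + 1L
          copies[sprintf("%s_%s_c%d", sp, og_id, k)] <<- s
        }
        if (stats::runif(1) < sc$het_prob) {
          allele <- mutate_seq(base, sc$het_divergence)
          if (sc$indel_prob > 0 && stats::runif(1) < sc$indel_prob) {
            allele <- delete_stretch(allele)
            sp_exact <- FALSE
          }
          add_copy(allele)
        }
        if (stats::runif(1) < sc$dup_prob) {
          dup <- mutate_seq(base, sc$het_divergence)
          if (sc$indel_prob > 0 && stats::runif(1) < sc$indel_prob) {
            dup <- delete_stretch(dup)
            sp_exact <- FALSE
          }
          add_copy(dup)
        }
        if (stats::runif(1) < sc$paralog_prob)
          add_copy(mutate_seq(base, sc$paralog_divergence))
        if (length(copies) > 1L) {
          sp_min <- NA_real_
          if (sp_exact) {
            pairs <- utils::combn(length(copies), 2L)
            sp_min <- min(apply(pairs, 2L, function(p)
              hamming_identity(copies[[p[1]]], copies[[p[2]]])))
            min_id <- min(min_id, sp_min, na.rm = TRUE)
          } else {
            exact_id <- FALSE
          }
          sp_rows[[length(sp_rows) + 1L]] <- data.frame(
            og_id = og_id, species = sp, n_copies = length(copies),
            min_identity = sp_min, stringsAsFactors = FALSE)
        }
        members[[sp]] <- copies
      }
      if (length(members) == 0L) {
        ## total loss; re-inject one species so the orthogroup is observable
        sp <- species[1]
        base <- mutate_seq(root, sc$species_divergence)
        anc[sp] <- base
        members[[sp]] <- stats::setNames(base, sprintf("%s_%s_c1", sp, og_id))
      }
      n_present <- length(members)
      ## absent species are explicit empty entries, matching the table dialect
      members <- stats::setNames(lapply(species, function(sp)
        members[[sp]] %||% stats::setNames(character(0), character(0))), species)
      og <- orthogroup(og_id, members)
      ogs[[i]] <- og
      truth_rows[[i]] <- data.frame(
        og_id = og_id,
        n_missing = sc$n_species - n_present,
        missing_rate = (sc$n_species - n_present) / sc$n_species,
        max_copy = max(lengths(members)),
        min_identity = if (exact_id) min_id else NA_real_,
        stringsAsFactors = FALSE)
      ancestral[[i]] <- anc
    }
    truth_tab <- do.call(rbind, truth_rows)
    per_species <- if (length(sp_rows)) do.call(rbind, sp_rows) else
      data.frame(og_id = character(0), species = character(0),
                 n_copies = integer(0), min_identity = numeric(0))
    names(ancestral) <- truth_tab$og_id
    set <- orthogroup_set(species, ogs)
    truth <- structure(list(table = truth_tab, per_species = per_species,
                            ancestral = ancestral, scenario = sc),
                       class = "synth_truth")
    files <- NULL
    if (!is.null(dir)) {
      files <- write_orthogroups_tsv(set, dir)
      gt_path <- file.path(dir, "ground_truth.tsv")
      utils::write.table(truth_tab, gt_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      sp_path <- file.path(dir, "ground_truth_species.tsv")
      utils::write.table(per_species, sp_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files$ground_truth <- gt_path
      files$ground_truth_species <- sp_path
    }
    list(set = set, truth = truth, files = files)
  })
}

#' Expected filter outcome for each simulated orthogroup
#'
#' Derives the per-orthogroup outcome labels from the realized ground-truth
#' statistics under a given threshold set, with the same precedence as the
#' filter: missing rate, then copy number, then similarity. Labels come from
#' the recorded draws, not from running the pipeline, so they are an
#' independent oracle for [filter_orthogroups()].
#'
#' @param truth A `synth_truth` (from [generate_dataset()]).
#' @param params A [filter_params()].
#' @return Character vector of outcomes (`pass`, `fail_missing`,
#'   `fail_duplication`, `fail_similarity`), named by og_id.
#' @export
ground_truth_labels <- function(truth, params = filter_params()) {
  stopifnot(inherits(truth, "synth_truth"))
  tb <- truth$table
  lab <- rep("pass", nrow(tb))
  if (params$strict) {
    lab[tb$missing_rate >= params$max_missing_rate] <- "fail_missing"
    lab[lab == "pass" & tb$max_copy >= params$max_duplication_num] <- "fail_duplication"
  } else {
    lab[tb$missing_rate > params$max_missing_rate] <- "fail_missing"
    lab[lab == "pass" & tb$max_copy > params$max_duplication_num] <- "fail_duplication"
  }
  lab[lab == "pass" & !is.na(tb$min_identity) &
        tb$min_identity < params$min_similarity] <- "fail_similarity"
  stats::setNames(lab, tb$og_id)
}
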