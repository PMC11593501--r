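test_that("missing rate is the fraction of roster species with zero copies", {
  roster24 <- sprintf("sp%02d", 1:24)
  og_of <- function(present) {
    members <- lapply(setNames(present, present), function(sp)
      setNames("MKVLD", paste0(sp, "_g")))
    orthogroup("OG", members)
  }
  expect_equal(missing_rate(og_of(roster24[1:23]), roster24), 1 / 24)
  expect_equal(missing_rate(og_of(roster24), roster24), 0)
  og22 <- og_of(roster24[1:22])
  expect_equal(missing_rate(og22, roster24), 2 / 24)
  ## 2/24 fails the default 0.05 threshold but passes 0.10
  expect_equal(passes_structural_filters(og22, roster24, filter_params()),
               "fail_missing")
  expect_equal(passes_structural_filters(og22, roster24,
                                         filter_params(max_missing_rate = 0.10)),
               "pass")
  ## genes only outside the roster: rate 1, not an error
  expect_equal(missing_rate(og_of("zz"), roster24), 1)
})

test_that("maximum copy number is the per-species maximum, not the total", {
  og <- orthogroup("OG", list(A = c(g1 = "MK", g2 = "ML"), B = c(g3 = "MK")))
  expect_equal(max_copy_number(og), 2L)
  og1 <- orthogroup("OG", list(A = c(g1 = "MK"), B = c(g2 = "MK")))
  expect_equal(max_copy_number(og1), 1L)
  og7 <- orthogroup("OG", list(A = setNames(rep("MK", 7), paste0("g", 1:7))))
  expect_equal(max_copy_number(og7), 7L)
  expect_equal(passes_structural_filters(og7, "A", filter_params()),
               "fail_duplication")
})

test_that("threshold comparisons are inclusive by default and strict on request", {
  roster20 <- sprintf("sp%02d", 1:20)
  og <- orthogroup("OG", lapply(setNames(roster20[1:19], roster20[1:19]),
                                function(sp) setNames("MKVLD", paste0(sp, "_g"))))
  expect_equal(missing_rate(og, roster20), 0.05)
  expect_equal(passes_structural_filters(og, roster20, filter_params()), "pass")
  expect_equal(passes_structural_filters(og, roster20, filter_params(strict = TRUE)),
               "fail_missing")
  og6 <- orthogroup("OG", list(A = setNames(rep("MK", 6), paste0("g", 1:6))))
  expect_equal(passes_structural_filters(og6, "A", filter_params()), "pass")
  expect_equal(passes_structural_filters(og6, "A", filter_params(strict = TRUE)),
               "fail_duplication")
})

test_that("similarity values above 1 are interpreted as percentages", {
  expect_equal(filter_params(min_similarity = 97)$min_similarity, 0.97)
  expect_equal(filter_params(min_similarity = 0.97)$min_similarity, 0.97)
})

test_that("filter outcomes partition the input and the report is deterministic", {
  set <- toy_set()
  res <- filter_orthogroups(set, filter_params())
  expect_equal(nrow(res$report$table), length(set$orthogroups))
  expect_equal(sum(res$report$counts), length(set$orthogroups))
  ## OG2 and OG3 each lack one of three species: missing before similarity
  expect_equal(res$report$table$outcome,
               c("pass", "fail_missing", "fail_missing"))
  expect_equal(names(res$set$orthogroups), "OG1")
  ## with a permissive missing-rate threshold OG3 reaches the similarity gate
  res04 <- filter_orthogroups(set, filter_params(max_missing_rate = 0.4))
  expect_equal(res04$report$table$outcome,
               c("pass", "pass", "fail_similarity"))
  expect_equal(names(res04$set$orthogroups), c("OG1", "OG2"))
  res2 <- filter_orthogroups(set, filter_params())
  expect_identical(res$report$table, res2$report$table)
})

test_that("relaxing any threshold never shrinks the pass set (monotonicity)", {
  sc <- synth_scenario(n_species = 12, n_orthogroups = 80, seq_length = 80,
                       het_prob = 0.3, dup_prob = 0.1, paralog_prob = 0.1,
                       loss_prob = 0.08, seed = 5)
  set <- generate_dataset(sc)$set
  pass_ids <- function(p) {
    r <- filter_orthogroups(set, p)$report$table
    r$og_id[r$outcome == "pass"]
  }
  base <- filter_params(0.05, 6, 0.97)
  expect_true(all(pass_ids(base) %in% pass_ids(filter_params(0.10, 6, 0.97))))
  expect_true(all(pass_ids(base) %in% pass_ids(filter_params(0.05, 10, 0.97))))
  expect_true(all(pass_ids(base) %in% pass_ids(filter_params(0.05, 6, 0.95))))
  ## the strictest setting keeps only complete single-copy orthogroups
  strictest <- filter_orthogroups(set, filter_params(0, 1, 1.0))$report$table
  kept <- strictest$og_id[strictest$outcome == "pass"]
  for (id in kept) {
    og <- set$orthogroups[[id]]
    expect_equal(missing_rate(og, set$roster), 0)
    expect_equal(max_copy_number(og), 1L)
  }
})

test_that("drop_species removes only the divergent species and keeps the orthogroup", {
  set <- toy_set()  # OG3: species B holds two ~0% identity copies
  drop_og <- filter_orthogroups(set, filter_params(max_missing_rate = 1))
  expect_equal(drop_og$report$table$outcome[3], "fail_similarity")
  drop_sp <- filter_orthogroups(set, filter_params(max_missing_rate = 1,
                                                   reject_policy = "drop_species"))
  expect_equal(drop_sp$report$table$outcome[3], "pass")
  og3 <- drop_sp$set$orthogroups[["OG3"]]
  expect_false("B" %in% names(og3$members))
  expect_equal(names(og3$members), "C")
  ## missing rate in the report reflects the original membership
  expect_equal(drop_sp$report$table$missing_rate[3], 1 / 3)
})

test_that("filter report serialises to TSV and JSON", {
  res <- filter_orthogroups(toy_set(), filter_params())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_filter_report(res$report, tsv = tsv, json = json)
  back <- read.delim(tsv)
  expect_equal(back$outcome, res$report$table$outcome)
  js <- jsonlite::read_json(json)
  expect_equal(js$counts$pass, 1L)
  expect_equal(sum(unlist(js$counts)), 3L)
})
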