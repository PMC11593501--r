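mk_merged <- function(og_id, seqs) {
  structure(list(og_id = og_id, sequences = seqs, merge_records = list(),
                 rejected = NULL), class = "merged_orthogroup")
}

test_that("the builtin star aligner handles identity, deletions and insertions", {
  ## identical sequences: no gaps
  la <- align_locus(mk_merged("OG1", c(A = "MKVLD", B = "MKVLD")))
  expect_equal(la$length, 5L)
  expect_equal(unname(la$rows), c("MKVLD", "MKVLD"))

  ## one sequence with a single deletion carries exactly one gap
  la <- align_locus(mk_merged("OG2", c(A = "MKVLDE", B = "MKLDE", C = "MKVLDE")))
  expect_equal(la$length, 6L)
  expect_equal(sum(strsplit(la$rows[["B"]], "")[[1]] == "-"), 1L)
  expect_equal(sum(strsplit(la$rows[["A"]], "")[[1]] == "-"), 0L)

  ## a private insertion opens a gap column in every other row
  la <- align_locus(mk_merged("OG3", c(A = "MKVLD", B = "MKVWWLD", C = "MKVLD")))
  expect_equal(la$length, 7L)
  expect_equal(sum(strsplit(la$rows[["A"]], "")[[1]] == "-"), 2L)

  ## de-gapping any row reproduces the input
  set.seed(9)
  seqs <- c(A = random_aa(40),
            B = paste0(random_aa(5), substr(random_aa(40), 1, 30)),
            C = random_aa(35))
  la <- align_locus(mk_merged("OG4", seqs))
  for (sp in names(seqs))
    expect_equal(gsub("-", "", la$rows[[sp]]), unname(seqs[[sp]]))

  ## fewer than two species: skipped with a warning
  expect_warning(expect_null(align_locus(mk_merged("OG5", c(A = "MKV")))),
                 "fewer than two")
})

test_that("the external MAFFT aligner satisfies the locus-alignment contract", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  seqs <- c(A = "MKVLDEAARNDCQEGH", B = "MKVLDEARNDCQEGH", C = "MKVLDEAARNDCQEGH")
  la <- align_locus(mk_merged("OG1", seqs), aligner = "external_mafft")
  expect_s3_class(la, "locus_alignment")
  expect_equal(length(unique(nchar(la$rows))), 1L)
  for (sp in names(seqs))
    expect_equal(gsub("-", "", toupper(la$rows[[sp]])), unname(seqs[[sp]]))
  expect_error(align_locus(mk_merged("OG1", seqs), aligner = "external_mafft",
                           mafft_path = "/no/such/mafft"), "builtin_star")
})

test_that("concatenation tiles loci with exact partition bookkeeping", {
  roster <- c("A", "B", "C")
  l1 <- locus_alignment_for_test("og1", c(A = strrep("M", 10), B = strrep("K", 10)))
  l2 <- locus_alignment_for_test("og2", c(A = strrep("V", 7), C = strrep("L", 7)))
  sm <- concatenate(list(l1, l2), roster)
  expect_equal(nchar(sm$matrix[["A"]]), 17L)
  expect_equal(sm$partitions,
               data.frame(og_id = c("og1", "og2"), start = c(1L, 11L),
                          end = c(10L, 17L), stringsAsFactors = FALSE))
  ## species absent from a locus are gap-padded there
  expect_equal(sm$matrix[["B"]], paste0(strrep("K", 10), strrep("-", 7)))
  expect_equal(sm$matrix[["C"]], paste0(strrep("-", 10), strrep("L", 7)))
  ## single locus: rows equal the locus rows
  sm1 <- concatenate(list(l1), roster)
  expect_equal(sm1$matrix[["A"]], l1$rows[["A"]])
  ## extraction reproduces each locus
  expect_equal(extract_partition(sm, "og1"), l1$rows)
  expect_equal(extract_partition(sm, "og2"), l2$rows)
  ## species outside the roster is a hard error
  bad <- locus_alignment_for_test("og3", c(Z = "MK"))
  expect_error(concatenate(list(bad), roster), "not in roster")
})

test_that("concatenation conserves residues and is associative", {
  set.seed(31)
  roster <- c("A", "B", "C", "D")
  loci <- lapply(1:6, function(i) {
    sp <- sample(roster, sample(2:4, 1))
    L <- sample(8:25, 1)
    locus_alignment_for_test(sprintf("og%d", i),
                             setNames(vapply(sp, function(s) random_aa(L), ""), sp))
  })
  sm <- concatenate(loci, roster)
  for (s in roster) {
    expected <- sum(vapply(loci, function(l)
      if (s %in% names(l$rows)) nchar(gsub("-", "", l$rows[[s]])) else 0L, numeric(1)))
    expect_equal(nchar(gsub("-", "", sm$matrix[[s]])), expected)
  }
  sm12 <- concatenate(loci[1:2], roster)
  sm12_3 <- concatenate(list(locus_alignment_for_test("og12", sm12$matrix), loci[[3]]), roster)
  sm123 <- concatenate(loci[1:3], roster)
  expect_equal(unname(sm12_3$matrix), unname(sm123$matrix))
})

test_that("relaxed PHYLIP output round-trips byte-identically", {
  roster <- c("Camellia_sinensis", "Camellia_crapnelliana", "Stewartia_sinensis")
  l1 <- locus_alignment_for_test("og1", setNames(c("MKVLDEAARN", "MKVLDEABRN", "MKVLDEAARN"), roster))
  l2 <- locus_alignment_for_test("og2", setNames(c("PQRSTPQ", "PQRSTPQ", "PQRSTPW"), roster))
  sm <- concatenate(list(l1, l2), roster)
  p1 <- withr::local_tempfile(fileext = ".phy")
  p2 <- withr::local_tempfile(fileext = ".phy")
  write_phylip(sm, p1)
  expect_equal(readLines(p1)[1], "3 17")
  back <- read_phylip(p1)
  expect_equal(back$matrix, sm$matrix)
  write_phylip(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  ## whitespace in names breaks the format: hard error
  bad <- sm; names(bad$matrix)[1] <- "Camellia sinensis"
  expect_error(write_phylip(bad, p1), "whitespace")
  ## empty matrix: hard error, no file written
  empty <- structure(list(roster = character(0), matrix = character(0),
                          partitions = NULL), class = "supermatrix")
  out <- file.path(withr::local_tempdir(), "x.phy")
  expect_error(write_phylip(empty, out), "empty")
  expect_false(file.exists(out))
})

test_that("partition files round-trip and reject overlaps", {
  roster <- c("A", "B")
  l1 <- locus_alignment_for_test("og1", c(A = "MKVLDEAARN", B = "MKVLDEAARN"))
  l2 <- locus_alignment_for_test("og2", c(A = "PQRSTPQ", B = "PQRSTPQ"))
  sm <- concatenate(list(l1, l2), roster)
  path <- withr::local_tempfile(fileext = ".txt")
  write_partitions(sm, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2L)
  expect_equal(lines[1], "PROT, og1 = 1-10")
  expect_equal(read_partitions(path), sm$partitions)
  sm$partitions$start[2] <- 5L
  expect_error(write_partitions(sm, path), "overlap")
})

test_that("per-locus FASTAs carry the aligned rows with species labels as IDs", {
  dir <- withr::local_tempdir()
  l1 <- locus_alignment_for_test("og1", c(A = "MKV-D", B = "MKVLD"))
  write_locus_fastas(list(l1, NULL), dir)
  expect_equal(list.files(dir), "og1.fasta")
  back <- read_fasta(file.path(dir, "og1.fasta"), strip_stop = FALSE)
  expect_equal(back, c(A = "MKV-D", B = "MKVLD"))
})

test_that("gene-tree aggregation validates, normalises and preserves topology", {
  dir <- withr::local_tempdir()
  nwk <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  paths <- vapply(1:3, function(i) {
    p <- file.path(dir, sprintf("t%d.nwk", i))
    writeLines(nwk[i], p)
    p
  }, "")
  out <- file.path(dir, "all.trees")
  gts <- aggregate_gene_trees(paths, out_path = out, roster = c("A", "B", "C", "D"))
  expect_equal(length(gts$trees), 3L)
  lines <- readLines(out)
  expect_equal(length(lines), 3L)
  ## re-read trees match the inputs topologically
  for (i in 1:3) {
    expect_equal(ape::dist.topo(ape::unroot(ape::read.tree(text = lines[i])),
                                ape::unroot(ape::read.tree(text = nwk[i])))[1], 0)
  }
  ## trailing newline present (one per tree)
  raw <- readChar(out, file.size(out))
  expect_equal(substr(raw, nchar(raw), nchar(raw)), "\n")

  ## Windows line endings are normalised
  crlf <- file.path(dir, "crlf.nwk")
  writeBin(charToRaw("((A,B),C);\r\n"), crlf)
  gts2 <- aggregate_gene_trees(crlf)
  expect_equal(gts2$trees, "((A,B),C);")

  ## unknown leaves warn; junk is a hard error naming the file
  weird <- file.path(dir, "weird.nwk")
  writeLines("((A,ZZZ),C);", weird)
  expect_warning(aggregate_gene_trees(weird, roster = c("A", "B", "C")), "ZZZ")
  junk <- file.path(dir, "junk.nwk")
  writeLines("this is not newick", junk)
  expect_error(aggregate_gene_trees(junk), "junk.nwk")
})
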