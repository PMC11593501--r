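## Independent oracles used by the tests. These re-derive expected values by
## brute force and share no code with the package implementation.

## All global alignments of a and b, scored with affine gaps (a run of k gap
## columns costs gap_open + k * gap_extend; runs in different sequences are
## separate runs). Returns the optimal score and, optionally, the identity
## values of every optimal alignment (identity = matches / columns between
## the first and last column where both sequences have a residue).
## Exponential: only use for nchar <= 5.
oracle_enumerate <- function(a, b, params, want_identities = FALSE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na_ <- length(ca); nb_ <- length(cb)
  best <- -Inf
  ids <- numeric(0)
  identity_of <- function(ops) {
    ## ops: character vector in {"m","a","b"} ("a" = gap in b, etc.)
    i <- 0L; j <- 0L
    colA <- character(0); colB <- character(0)
    for (op in ops) {
      if (op == "m") { i <- i + 1L; j <- j + 1L; colA <- c(colA, ca[i]); colB <- c(colB, cb[j]) }
      else if (op == "a") { i <- i + 1L; colA <- c(colA, ca[i]); colB <- c(colB, "-") }
      else { j <- j + 1L; colA <- c(colA, "-"); colB <- c(colB, cb[j]) }
    }
    both <- which(colA != "-" & colB != "-")
    if (length(both) == 0L) return(0)
    w <- both[1]:both[length(both)]
    mean(colA[w] == colB[w] & colA[w] != "-")
  }
  rec <- function(i, j, last, sc, ops) {
    if (i > na_ && j > nb_) {
      if (sc > best) { best <<- sc; if (want_identities) ids <<- identity_of(ops) }
      else if (want_identities && sc == best) ids <<- c(ids, identity_of(ops))
      return(invisible(NULL))
    }
    if (i <= na_ && j <= nb_) {
      s <- if (ca[i] == cb[j]) params$match_score else params$mismatch_score
      rec(i + 1L, j + 1L, "m", sc + s, c(ops, "m"))
    }
    if (i <= na_)
      rec(i + 1L, j, "a", sc + params$gap_extend +
            if (last == "a") 0 else params$gap_open, c(ops, "a"))
    if (j <= nb_)
      rec(i, j + 1L, "b", sc + params$gap_extend +
            if (last == "b") 0 else params$gap_open, c(ops, "b"))
  }
  rec(1L, 1L, "m", 0, character(0))
  list(score = best, identities = unique(ids))
}

## Memoised recursion over (position in a, position in b, last operation).
## Polynomial; usable up to nchar ~ 30. Cross-validated against
## oracle_enumerate in the tests before it is trusted for longer pairs.
oracle_affine_score <- function(a, b, params) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na_ <- length(ca); nb_ <- length(cb)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j, last) {
    if (i > na_ && j > nb_) return(0)
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= na_ && j <= nb_) {
      s <- if (ca[i] == cb[j]) params$match_score else params$mismatch_score
      best <- max(best, s + f(i + 1L, j + 1L, "m"))
    }
    if (i <= na_)
      best <- max(best, params$gap_extend + (if (last == "a") 0 else params$gap_open) +
                    f(i + 1L, j, "a"))
    if (j <= nb_)
      best <- max(best, params$gap_extend + (if (last == "b") 0 else params$gap_open) +
                    f(i, j + 1L, "b"))
    memo[[key]] <- best
    best
  }
  f(1L, 1L, "m")
}

## Column-vote consensus oracle for equal-length, indel-free copies: votes
## are read positionwise, no alignment involved.
oracle_column_vote <- function(copies) {
  mat <- do.call(rbind, strsplit(copies, ""))
  out <- character(0)
  kinds <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    tab <- table(v)
    if (length(tab) == 1L) { out <- c(out, names(tab)); kinds[j] <- "unanimous" }
    else if (max(tab) > length(v) / 2) { out <- c(out, names(tab)[which.max(tab)]); kinds[j] <- "majority" }
    else kinds[j] <- "trimmed"
  }
  list(consensus = paste(out, collapse = ""),
       n_unanimous = sum(kinds == "unanimous"),
       n_majority = sum(kinds == "majority"),
       n_trimmed = sum(kinds == "trimmed"))
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

## Build a locus_alignment without going through an aligner.
locus_alignment_for_test <- function(og_id, rows) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(og_id = og_id, rows = rows, length = unique(nchar(rows))),
            class = "locus_alignment")
}

## Small in-memory orthogroup set used by several files.
toy_set <- function() {
  orthogroup_set(c("A", "B", "C"), list(
    orthogroup("OG1", list(A = c(a1 = "MKVLDE", a2 = "MKVLDE"),
                           B = c(b1 = "MKVLDE"), C = c(c1 = "MKVLDD"))),
    orthogroup("OG2", list(A = c(a3 = "MKWW"), B = c(b2 = "MKWW"))),
    orthogroup("OG3", list(B = c(b3 = "PQRST", b4 = "AAAAA"),
                           C = c(c2 = "PQRST")))))
}
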