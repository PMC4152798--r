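test_that("IUPAC FASTA expands ambiguity codes to uniform distributions", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 test record", "MAN", ">s2", "ACGT"), fa)
  seqs <- read_iupac_fasta(fa)
  expect_named(seqs, c("s1", "s2"))
  expect_equal(seqs$s1$positions[[1]], c(A = 0.5, C = 0.5))
  expect_equal(seqs$s1$positions[[2]], c(A = 1))
  expect_equal(seqs$s1$positions[[3]], c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_identical(length(seqs$s2), 4L)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "AC!T"), bad)
  expect_error(read_iupac_fasta(bad), "non-IUPAC character '!' at position 2")
})

test_that("two-base ambiguity codes are black at threshold 1/2", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s", "AMT"), fa)
  ws <- read_iupac_fasta(fa)[[1]]
  cl <- colour_positions(filter_letters(ws, 1 / 2), 1 / 2)
  expect_identical(unclass(cl), c("W", "B", "W"))    # 0.5 is not > 0.5
})

test_that("probability matrix round-trips and feeds the colouring", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_probability_matrix(ws_colour_demo(), tsv)
  ws <- read_probability_matrix(tsv)
  expect_identical(length(ws), 11L)
  cl <- colour_positions(filter_letters(ws, 1 / 2), 1 / 2)
  expect_identical(paste(cl, collapse = " "), "W G W W B W W G W W W")

  one <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# alphabet: ab", "0\t1.0\t0.0"), one)
  ws1 <- read_probability_matrix(one)
  expect_equal(ws1$positions[[1]], c(a = 1))
})

test_that("probability matrix validation errors name the offending row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# alphabet: ab", "0\t0.5\t0.4"), f)
  expect_error(read_probability_matrix(f), "row 0")
  writeLines(c("# alphabet: ab", "0\t0.5\t0.5", "2\t0.5\t0.5"), f)
  expect_error(read_probability_matrix(f), "consecutive")
  writeLines(c("no header", "0\t1"), f)
  expect_error(read_probability_matrix(f), "alphabet")
})

test_that("repetition reports round-trip losslessly", {
  reps <- solve_problem1(ws_abaaba(), 1 / 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_repetitions(reps, f, id = "ex")
  back <- read_repetitions(f)
  expect_identical(back$id, rep("ex", nrow(reps)))
  expect_identical(back[, c("i", "p", "e", "b", "u")],
                   reps[, c("i", "p", "e", "b", "u")])
  expect_equal(back$prob, reps$prob)

  write_repetitions(reps[0, ], f)
  empty <- read_repetitions(f)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("id", "i", "p", "e", "b", "u", "prob"))
})

test_that("synthesis is deterministic under a seed", {
  a <- synthesize(60, c("a", "b"), 0.1, list(c(2, 3)), 1 / 4, seed = 7)
  b <- synthesize(60, c("a", "b"), 0.1, list(c(2, 3)), 1 / 4, seed = 7)
  expect_identical(format(a$ws), format(b$ws))
  expect_identical(a$truth, b$truth)
  c2 <- synthesize(60, c("a", "b"), 0.1, list(c(2, 3)), 1 / 4, seed = 8)
  expect_false(identical(format(a$ws), format(c2$ws)))
})

test_that("planted certain repeats are recovered exactly", {
  syn <- synthesize(80, c("a", "b", "c", "d"), 0, list(c(2, 3), c(3, 2)),
                    1 / 2, seed = 5)
  out <- solve_problem1(syn$ws, 1 / 2)
  for (k in seq_len(nrow(syn$truth))) {
    tr <- syn$truth[k, ]
    expect_true(any(out$i == tr$i & out$p == tr$p & out$e == tr$e &
                      out$u == tr$u))
  }
})

test_that("planted repeats with black positions keep |b| >= 1 and are found", {
  found_black <- FALSE
  for (seed in 1:5) {
    syn <- synthesize(60, c("a", "c", "g", "t"), 0.3, list(c(3, 2)),
                      1 / 4, seed = seed)
    out <- solve_problem1(syn$ws, 1 / 4)
    tr <- syn$truth[1, ]
    expect_true(any(out$i == tr$i & out$p == tr$p & out$e == tr$e &
                      out$b == tr$b))
    if (nzchar(tr$b)) found_black <- TRUE
  }
  expect_true(found_black)   # at this density some plant contains a black
})

test_that("the command-line tool finds, synthesizes and refuses bad input", {
  script <- system.file("exec", "wsrep", package = "wsrep")
  if (!nzchar(script)) script <- file.path(testthat::test_path("..", ".."), "exec", "wsrep")
  expect_true(file.exists(script))
  rscript <- file.path(R.home("bin"), "Rscript")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_probability_matrix(ws_ababab(), tsv)
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- system2(rscript, c(script, "find", "--matrix", tsv,
                            "--threshold", "0.25", "--problem", "all",
                            "--output", out, "--log-level", "quiet"),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status"), NULL)
  tab <- utils::read.table(out, sep = "\t", header = TRUE, na.strings = NULL,
                           colClasses = c("character", "integer", "integer",
                                          "integer", "character", "character",
                                          "numeric"))
  expect_true(any(tab$i == 1 & tab$p == 2 & tab$e == 3))

  # identical reruns are byte-identical
  out2 <- withr::local_tempfile(fileext = ".tsv")
  system2(rscript, c(script, "find", "--matrix", tsv, "--threshold", "0.25",
                     "--output", out2, "--log-level", "quiet"),
          stdout = TRUE, stderr = TRUE)
  expect_identical(readLines(out), readLines(out2))

  bad <- suppressWarnings(
    system2(rscript, c(script, "find", "--matrix", tsv, "--threshold", "1.5"),
            stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 2L)
})
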