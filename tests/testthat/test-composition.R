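test_that("valid squares of the worked examples", {
  # plain string: the three overlapping squares of ababab
  sq <- generate_valid_squares(as_weighted_string("ababab"), 1 / 2)$squares
  expect_identical(sq$i, c(0L, 1L, 2L))
  expect_identical(sq$p, rep(2L, 3))
  expect_identical(sq$letters, c("abab", "baba", "abab"))

  # branching string at 1/4: squares at 1 and 3 with span word abab
  sq <- generate_valid_squares(ws_ababab(), 1 / 4)$squares
  expect_true(any(sq$i == 1 & sq$p == 2 & sq$letters == "abab"))
  expect_true(any(sq$i == 3 & sq$p == 2 & sq$letters == "abab"))

  # at 1/2 the square at 3 dies: its half has probability 0.25 < 0.5
  sq <- generate_valid_squares(ws_ababab(), 1 / 2)$squares
  expect_false(any(sq$i == 3 & sq$p == 2))
})

test_that("square halves are each valid at 1/z", {
  set.seed(41)
  for (r in 1:25) {
    ws <- random_family_ws(sample(3:9, 1))
    t <- sample(c(1 / 2, 1 / 4), 1)
    gv <- generate_valid_squares(ws, t)
    for (k in seq_len(nrow(gv$squares))) {
      seg <- gv$segments[[gv$squares$seg[k]]]
      loc <- gv$squares$i[k] - seg$offset
      p <- gv$squares$p[k]
      lets <- gv$squares$letters[k]
      h1 <- wsrep:::span_probability(seg$ws, loc, substr(lets, 1, p))
      h2 <- wsrep:::span_probability(seg$ws, loc + p, substr(lets, p + 1, 2 * p))
      expect_true(wsrep:::ge_tol(h1, t))
      expect_true(wsrep:::ge_tol(h2, t))
      expect_true(is_primitive(substr(lets, 1, p)))
    }
  }
})

test_that("bucketing partitions squares by start and period", {
  gv <- generate_valid_squares(ws_ababab(), 1 / 4)
  buckets <- bucket_squares(gv$squares)
  expect_identical(sort(unlist(as.list(buckets), use.names = FALSE)),
                   seq_len(nrow(gv$squares)))
  for (key in ls(buckets)) {
    rows <- buckets[[key]]
    ip <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    expect_true(all(gv$squares$i[rows] == ip[1] & gv$squares$p[rows] == ip[2]))
  }
  expect_length(ls(bucket_squares(gv$squares[0, ])), 0L)
})

test_that("compatibility compares black letters on the overlap", {
  gv <- generate_valid_squares(ws_ababab(), 1 / 4)
  seg <- gv$segments[[1]]
  s1 <- list(i = 1L, p = 2L, letters = "abab")
  s2 <- list(i = 3L, p = 2L, letters = "abab")
  expect_true(squares_compatible(s1, s2, seg$colours_k, seg$nb_k, seg$offset))
  s2bad <- list(i = 3L, p = 2L, letters = "bbbb")
  expect_false(squares_compatible(s1, s2bad, seg$colours_k, seg$nb_k, seg$offset))
  expect_error(squares_compatible(s1, list(i = 2L, p = 2L, letters = "baba"),
                                  seg$colours_k, seg$nb_k, seg$offset),
               "overlap-aligned")
  # plain squares (no black positions) are always compatible
  gvp <- generate_valid_squares(as_weighted_string("ababab"), 1 / 2)
  segp <- gvp$segments[[1]]
  expect_true(squares_compatible(list(i = 0L, p = 2L, letters = "abab"),
                                 list(i = 2L, p = 2L, letters = "abab"),
                                 segp$colours_k, segp$nb_k, segp$offset))
})

test_that("composition chains the squares of the plain worked example", {
  gv <- generate_valid_squares(as_weighted_string("ababab"), 1 / 2)
  comp <- compose_squares(gv)
  expect_identical(comp$i, c(0L, 1L))
  expect_identical(comp$e, c(3L, 2L))                 # (0,2,3) and (1,2,2)
  expect_identical(comp$u, c("ab", "ba"))
})

test_that("composition merges the branching example into (1,2,{},3)", {
  gv <- generate_valid_squares(ws_ababab(), 1 / 4)
  comp <- compose_squares(gv)
  hit <- comp[comp$i == 1 & comp$p == 2, ]
  expect_identical(hit$e, 3L)
  expect_identical(hit$b, "")
  expect_identical(hit$letters, "ababab")
  # the consumed square at 3 no longer starts a chain of its own
  expect_false(any(comp$i == 3 & comp$p == 2))
})

test_that("composition conserves squares: sum of (e - 1) equals square count", {
  set.seed(42)
  for (r in 1:25) {
    ws <- random_family_ws(sample(3:10, 1))
    t <- sample(c(1 / 2, 1 / 4), 1)
    gv <- generate_valid_squares(ws, t)
    if (!nrow(gv$squares)) next
    comp <- compose_squares(gv)
    expect_identical(sum(comp$e - 1L), nrow(gv$squares))
  }
})

test_that("report_all emits every suffix occurrence with recomputed b", {
  out <- solve_problem1("ababab", 1 / 2)
  expect_identical(out[, c("i", "p", "e")],
                   data.frame(i = 0:2, p = 2L, e = c(3L, 2L, 2L)))
  out6 <- solve_problem1(ws_ababab(), 1 / 4)
  expect_true(any(out6$i == 1 & out6$p == 2 & out6$e == 3 & out6$b == ""))
  expect_true(any(out6$i == 3 & out6$p == 2 & out6$e == 2 &
                    out6$b == "0:a;1:b"))
  # e = 2 maximal repetitions are reported as themselves only
  lone <- solve_problem1("abab", 1 / 2)
  expect_identical(lone[, c("i", "p", "e")], data.frame(i = 0L, p = 2L, e = 2L))
})

test_that("the period-3 branching repetition is found at 1/2", {
  out <- solve_problem1(ws_abaaba(), 1 / 2)
  at1 <- out[out$i == 1, ]
  expect_identical(nrow(at1), 1L)
  expect_identical(at1$p, 3L)
  expect_identical(at1$b, "2:a")
  expect_identical(at1$u, "aba")
})

test_that("all-repetitions output equals the brute-force oracle", {
  set.seed(43)
  for (r in 1:40) {
    ws <- random_family_ws(sample(2:8, 1))
    t <- sample(c(1 / 2, 1 / 4), 1)
    expect_same_reps(solve_problem1(ws, t), brute_force_problem1(ws, t))
  }
  # general alphabet / probabilities
  for (r in 1:20) {
    ws <- random_ws(sample(2:10, 1), alphabet = c("a", "b", "c"))
    t <- sample(c(1 / 2, 1 / 3), 1)
    expect_same_reps(solve_problem1(ws, t), brute_force_problem1(ws, t))
  }
})

test_that("whole-span valid repetitions appear among per-copy repetitions", {
  # Problem 2's outputs are a sub-family of Problem 1's: same root at the
  # same start, with at least as many copies reported by Problem 1
  set.seed(44)
  for (r in 1:20) {
    ws <- random_family_ws(sample(2:8, 1))
    t <- sample(c(1 / 2, 1 / 4), 1)
    p2 <- brute_force_valid_repetitions(ws, t)
    p1 <- brute_force_problem1(ws, t)
    for (k in seq_len(nrow(p2))) {
      expect_true(any(p1$i == p2$i[k] & p1$p == p2$p[k] &
                        p1$u == p2$u[k] & p1$e >= p2$e[k]))
    }
  }
})

test_that("maximal report mode returns only chain heads", {
  mx <- solve_problem1("ababab", 1 / 2, report = "maximal")
  expect_identical(mx[, c("i", "p", "e")],
                   data.frame(i = 0:1, p = 2L, e = c(3L, 2L)))
})
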