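# Worked example inputs (all weighted strings printed in the package docs)
# and small random generators used by the property tests.

# 11-position string whose colouring at 1/2 is W G W W B W W G W W W
ws_colour_demo <- function() {
  weighted_string(list(
    "A",
    c(A = 0.1, C = 0.8, G = 0.1, T = 0.0),
    "T", "T",
    c(A = 0.5, C = 0.5, G = 0.0, T = 0.0),
    "T", "C",
    c(A = 0.6, C = 0.2, G = 0.0, T = 0.2),
    "T", "T", "T"))
}

# aab[(a,.5)(b,.5)][(a,.5)(b,.5)]bab  (8 positions)
ws_abaaba <- function() {
  weighted_string(list("a", "a", "b", c(a = 0.5, b = 0.5),
                       c(a = 0.5, b = 0.5), "b", "a", "b"))
}

# [(a,.6)(c,.4)]bab[(a,.6)(d,.4)]bab  (8 positions, colouring GWWWGWWW)
ws_grey_demo <- function() {
  weighted_string(list(c(a = 0.6, c = 0.4), "b", "a", "b",
                       c(a = 0.6, d = 0.4), "b", "a", "b"))
}

# aab[(a,.5)(b,.5)][(a,.5)(b,.5)]ab  (7 positions)
ws_ababab <- function() {
  weighted_string(list("a", "a", "b", c(a = 0.5, b = 0.5),
                       c(a = 0.5, b = 0.5), "a", "b"))
}

# --- generators -------------------------------------------------------------

# binary weighted string whose positions are drawn from the family
# {certain, (0.5, 0.5), (0.75, 0.25)} (5 concrete position types)
family_types <- c("ca", "cb", "hh", "qa", "qb")

family_position <- function(type) {
  switch(type,
         ca = "a", cb = "b",
         hh = c(a = 0.5, b = 0.5),
         qa = c(a = 0.75, b = 0.25),
         qb = c(b = 0.75, a = 0.25))
}

family_ws <- function(types) {
  weighted_string(lapply(types, family_position), alphabet = c("a", "b"))
}

random_family_ws <- function(n)
  family_ws(sample(family_types, n, replace = TRUE))

# general random weighted string: mixes certain positions and 2-letter
# distributions over a given alphabet
random_ws <- function(n, alphabet = c("a", "b"), p_uncertain = 0.4) {
  pos <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < p_uncertain) {
      ab <- sample(alphabet, 2L)
      pr <- sample(c(0.5, 0.6, 0.75), 1L)
      c(stats::setNames(pr, ab[1]), stats::setNames(1 - pr, ab[2]))
    } else sample(alphabet, 1L)
  })
  weighted_string(pos, alphabet = alphabet)
}

random_plain <- function(n, sigma) {
  paste(sample(letters[seq_len(sigma)], n, replace = TRUE), collapse = "")
}

all_binary_strings <- function(n) {
  vapply(0:(2^n - 1L), function(code)
    paste(c("a", "b")[1L + bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L)],
          collapse = ""), "")
}

# --- comparison helpers -----------------------------------------------------

rep_keys <- function(df)
  sort(paste(df$i, df$p, df$e, df$b, df$u, sep = "|"))

expect_same_reps <- function(a, b) {
  expect_identical(rep_keys(a), rep_keys(b))
}

# Every row of `orc` must be covered by a row of `em`: same period, span
# contained in the emitted span, letters agreeing on the overlap.
all_covered <- function(orc, em) {
  for (r in seq_len(nrow(orc))) {
    vo <- strrep(orc$u[r], orc$e[r])
    io <- orc$i[r]; po <- orc$p[r]
    hit <- FALSE
    for (s in seq_len(nrow(em))) {
      if (em$p[s] != po) next
      ve <- strrep(em$u[s], em$e[s]); ie <- em$i[s]
      if (ie <= io && io + nchar(vo) <= ie + nchar(ve) &&
          substr(ve, io - ie + 1L, io - ie + nchar(vo)) == vo) {
        hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# Whole-span cumulative probability of the word reconstructed from a
# quadruple, computed directly against the weighted string.
quad_span_prob <- function(ws, i, p, e, b, t) {
  v <- reconstruct_v(i, p, e, b, ws, t)
  prod(vapply(seq_len(nchar(v)), function(k)
    wsrep:::letter_prob(ws, i + k - 1L, substr(v, k, k)), 0))
}

# Brute-force enumeration of all valid factors (start, word) of a weighted
# string at threshold t; oracle for the extended-factor coverage property.
brute_valid_factors <- function(ws, t) {
  t <- cw_threshold(t)
  n <- length(ws)
  out <- character(0)
  for (i0 in seq_len(n) - 1L) {
    words <- data.frame(w = "", pr = 1)
    for (j in i0:(n - 1L)) {
      e <- ws$positions[[j + 1L]]
      grid <- expand.grid(k = seq_len(nrow(words)), a = names(e),
                          stringsAsFactors = FALSE)
      words <- data.frame(w = paste0(words$w[grid$k], grid$a),
                          pr = words$pr[grid$k] * unname(e[grid$a]))
      words <- words[wsrep:::ge_tol(words$pr, t$value), , drop = FALSE]
      if (!nrow(words)) break
      out <- c(out, paste0(i0, "|", words$w))
    }
  }
  unique(out)
}
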