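#' Is a string primitive?
#'
#' A non-empty string is primitive when it cannot be written as `v^e` with
#' `e >= 2`, i.e. no proper divisor d of its length has the string equal to
#' its length-d prefix repeated.
#'
#' @param u a single non-empty character string.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_primitive("aba")   # TRUE
#' is_primitive("abab")  # FALSE
#' @export
is_primitive <- function(u) {
  stopifnot(is.character(u), length(u) == 1L)
  m <- nchar(u)
  if (m == 0L) stop("is_primitive is undefined for the empty string")
  if (m == 1L) return(TRUE)
  for (d in seq_len(m %/% 2)) {
    if (m %% d != 0L) next
    if (strrep(substr(u, 1L, d), m %/% d) == u) return(FALSE)
  }
  TRUE
}

# Empty repetition table.
empty_reps <- function()
  data.frame(i = integer(0), p = integer(0), e = integer(0))

#' All maximal repetitions of a plain string
#'
#' A repetition is a triple (i, p, e): e >= 2 adjacent copies of a
#' primitive word u of length p starting at 0-based position i, not
#' followed by a further copy of u.  It is *maximal* when additionally not
#' preceded by a copy of u.  There are O(n log n) maximal repetitions and
#' this function finds them all in O(n log n)-class time.
#'
#' The method is output-equivalent to Crochemore's partitioning algorithm:
#' for every period p it anchors at positions 0, p, 2p, ... and extends the
#' match between positions j and j+p in both directions (vectorised longest
#' common extensions).  Anchor hits are deduplicated into runs (maximal
#' periodic intervals, keeping the minimal period, which is also the period
#' of every primitively-rooted repetition inside the interval), and each
#' run \[s, t\] with period p is expanded into its left-maximal repetitions
#' (i, p, floor((t - i + 1)/p)) for i in s..s+p-1.
#'
#' @param s a character string.
#' @return data.frame with integer columns `i` (0-based start), `p`
#'   (period), `e` (exponent), sorted by (i, p).
#' @examples
#' maximal_repetitions("ababab")   # (0,2,3) and (1,2,2)
#' @seealso [naive_maximal_repetitions()] for the brute-force oracle.
#' @export
maximal_repetitions <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  n <- nchar(s)
  if (n < 2L) return(empty_reps())
  v <- match(strsplit(s, "")[[1]], letters_of(s))
  runs <- new.env(parent = emptyenv())
  for (p in seq_len(n %/% 2L)) {
    for (a in seq.int(1L, n - p, by = p)) {
      b <- a + p
      # forward LCE of suffixes at a and b
      m <- n - b + 1L
      d <- v[a:(a + m - 1L)] != v[b:n]
      rext <- if (any(d)) which.max(d) - 1L else m
      # backward LCE of prefixes ending at a-1 and b-1
      len <- a - 1L
      if (len > 0L) {
        d <- v[1:len] != v[(b - len):(b - 1L)]
        lext <- if (any(d)) len - max(which(d)) else len
      } else lext <- 0L
      if (lext + rext >= p) {
        start <- a - lext
        end <- b + rext - 1L
        key <- paste0(start, ":", end)
        old <- runs[[key]]
        if (is.null(old) || p < old) runs[[key]] <- p
      }
    }
  }
  out <- list()
  for (key in ls(runs)) {
    se <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    p <- runs[[key]]
    for (i in se[1]:(se[1] + p - 1L)) {
      e <- (se[2] - i + 1L) %/% p
      if (e >= 2L)
        out[[length(out) + 1L]] <- c(i - 1L, p, e)   # to 0-based
    }
  }
  if (!length(out)) return(empty_reps())
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("i", "p", "e")
  df <- df[order(df$i, df$p), , drop = FALSE]
  rownames(df) <- NULL
  df
}

letters_of <- function(s) unique(strsplit(s, "")[[1]])

#' Brute-force maximal repetitions (oracle)
#'
#' Direct enumeration of every (i, p): primitivity check on the root,
#' string comparison of consecutive copies for the exponent, and a left
#' comparison for maximality.  Quadratic-plus; intended for strings up to a
#' few hundred letters as the test arbiter for [maximal_repetitions()].
#'
#' @inheritParams maximal_repetitions
#' @return same contract as [maximal_repetitions()].
#' @export
naive_maximal_repetitions <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  n <- nchar(s)
  out <- list()
  if (n >= 2L) {
    for (i0 in 0:(n - 2L)) {
      for (p in seq_len((n - i0) %/% 2L)) {
        u <- substr(s, i0 + 1L, i0 + p)
        if (!is_primitive(u)) next
        e <- 1L
        while (i0 + (e + 1L) * p <= n &&
               substr(s, i0 + e * p + 1L, i0 + (e + 1L) * p) == u)
          e <- e + 1L
        if (e < 2L) next
        if (i0 - p >= 0L && substr(s, i0 - p + 1L, i0) == u) next  # not left-maximal
        out[[length(out) + 1L]] <- c(i0, p, e)
      }
    }
  }
  if (!length(out)) return(empty_reps())
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("i", "p", "e")
  df <- df[order(df$i, df$p), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Break repetitions into their overlapping squares
#'
#' Every repetition (i, p, e) is a sequence of e - 1 overlapping primitive
#' squares (i + kp, p, 2), k = 0..e-2.  Inputs with e = 2 pass through
#' unchanged.
#'
#' @param reps data.frame with columns `i`, `p`, `e` (as returned by
#'   [maximal_repetitions()]).
#' @return data.frame of squares (all `e` = 2), one row per overlapping
#'   square, in input order then ascending k.
#' @examples
#' split_into_squares(data.frame(i = 0L, p = 2L, e = 3L))
#' @export
split_into_squares <- function(reps) {
  if (nrow(reps) == 0L) return(empty_reps())
  out <- lapply(seq_len(nrow(reps)), function(r) {
    k <- 0:(reps$e[r] - 2L)
    data.frame(i = reps$i[r] + k * reps$p[r], p = reps$p[r], e = 2L)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
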