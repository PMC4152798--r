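#' Filter letters below the threshold
#'
#' Removes from every position all letters whose occurrence probability is
#' below 1/z.  Since the retained letters each have probability >= 1/z and
#' the raw probabilities sum to one, at most z letters survive per position.
#' Probabilities are kept as-is (never renormalised); positions may become
#' empty, in which case no valid factor can cross them and the string is
#' split there (see [split_unsupported()]).
#'
#' Filtering is idempotent: filtering a filtered string at the same
#' threshold is a no-op.
#'
#' @param ws a [weighted_string()].
#' @param t threshold, a [cw_threshold()] or the numeric value 1/z.
#' @return a `weighted_string` with the same length; positions possibly
#'   empty; probability sums may now be below 1.
#' @examples
#' ws <- weighted_string(list(c(A = 0.1, C = 0.8, G = 0.1)))
#' filter_letters(ws, 1 / 2)   # keeps only (C, 0.8)
#' @export
filter_letters <- function(ws, t) {
  t <- cw_threshold(t)
  pos <- lapply(ws$positions, function(e) e[ge_tol(unname(e), t$value)])
  structure(list(positions = pos, alphabet = ws$alphabet, n = ws$n),
            class = "weighted_string")
}

#' Split a filtered string at unsupported positions
#'
#' Positions at which no letter reaches the threshold cannot take part in
#' any valid factor, so the weighted string is cut there and each piece is
#' processed independently.  Offsets map each segment back to the original
#' coordinates, so downstream results are reported in original-x
#' coordinates.
#'
#' @param ws a filtered `weighted_string` (see [filter_letters()]).
#' @param t threshold (unused for the cut itself, kept for symmetry of the
#'   pipeline stages; the cut is wherever a position is empty).
#' @return list of segments, each a list with elements `offset` (0-based
#'   start in the original string) and `ws` (the segment, every position
#'   non-empty).  An all-empty input yields an empty list.
#' @export
split_unsupported <- function(ws, t = NULL) {
  keep <- vapply(ws$positions, function(e) length(e) > 0L, TRUE)
  if (ws$n == 0L) return(list())
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    seg <- structure(list(positions = ws$positions[starts[k]:ends[k]],
                          alphabet = ws$alphabet,
                          n = ends[k] - starts[k] + 1L),
                     class = "weighted_string")
    out[[length(out) + 1L]] <- list(offset = starts[k] - 1L, ws = seg)
  }
  out
}

#' Colour positions black, grey or white
#'
#' Classifies every position of a filtered weighted string:
#' \describe{
#'   \item{white (W)}{one letter is certain (probability 1 within
#'     tolerance);}
#'   \item{grey (G)}{one letter has probability strictly greater than
#'     1 - 1/z but none is certain;}
#'   \item{black (B)}{no letter exceeds 1 - 1/z.}
#' }
#' Black positions are the branching positions: the only positions where a
#' valid factor may choose between letters.  A probability of exactly
#' 1 - 1/z is not "greater than", so such positions are black.  When z < 2
#' the filter leaves a single letter per position with probability above
#' 1 - 1/z, so only grey and white occur.
#'
#' @param ws a filtered, split `weighted_string` (every position
#'   non-empty, raw probabilities retained).
#' @param t threshold, [cw_threshold()] or numeric 1/z.
#' @return a `ws_colouring`: character vector of `"B"`, `"G"`, `"W"`, one
#'   per position.
#' @examples
#' ws <- weighted_string(list("a", "a", "b",
#'                            c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5),
#'                            "b", "a", "b"))
#' colour_positions(ws, 1 / 2)   # W W W B B W W W
#' @export
colour_positions <- function(ws, t) {
  t <- cw_threshold(t)
  bound <- 1 - t$value
  marks <- vapply(ws$positions, function(e) {
    if (length(e) == 0L)
      stop("colour_positions: empty position; filter and split first")
    p <- unname(e)
    if (any(eq_tol(p, 1))) "W"
    else if (any(gt_tol(p, bound))) "G"
    else "B"
  }, "")
  structure(marks, class = "ws_colouring")
}

#' @export
print.ws_colouring <- function(x, ...) {
  cat("colouring: ", paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Next-black array
#'
#' For every position i, `NB[i]` (0-based) is the index of the leftmost
#' black position strictly greater than i, or the sentinel n when there is
#' none.  Computed in one right-to-left pass; used to enumerate the black
#' positions inside a repetition's first copy in time proportional to their
#' number.
#'
#' @param colours a `ws_colouring`.
#' @return integer vector of length n; entry r (1-based) holds NB for
#'   0-based position r-1, with sentinel n.
#' @export
next_black <- function(colours) {
  n <- length(colours)
  nb <- integer(n)
  nxt <- n
  for (r in n:1) {
    nb[r] <- nxt
    if (colours[r] == "B") nxt <- r - 1L   # 0-based index of this black
  }
  nb
}

# 0-based black positions in [from, from + len) using NB; `colours` and `nb`
# are segment-local.
blacks_in_range <- function(colours, nb, from, len) {
  out <- integer(0)
  q <- if (colours[from + 1L] == "B") from else nb[from + 1L]
  while (q < from + len) {
    out <- c(out, q)
    q <- nb[q + 1L]
  }
  out
}
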