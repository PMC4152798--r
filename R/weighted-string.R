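#' @keywords internal
"_PACKAGE"

# Relative tolerance for all probability comparisons.  A value within tol of
# a bound counts as meeting ">=" and as failing a strict ">".
.ws_tol <- 1e-9

ge_tol <- function(a, b) a >= b - .ws_tol * pmax(1, abs(b))
gt_tol <- function(a, b) a > b + .ws_tol * pmax(1, abs(b))
eq_tol <- function(a, b, tol = .ws_tol) abs(a - b) <= tol * pmax(1, abs(b))

#' Construct a weighted string
#'
#' A weighted string is a sequence of positions, each holding a probability
#' distribution over the letters of a finite alphabet.  It models uncertain
#' sequence data such as IUPAC-ambiguous DNA or position probability
#' matrices: at every position each letter has an occurrence probability,
#' and the probabilities at a raw position sum to one.
#'
#' Positions may be given either as a single character (a certain letter,
#' probability 1) or as a named numeric vector of letter probabilities.
#' Zero-probability entries are dropped on construction.
#'
#' @param positions list of positions; each element a single character or a
#'   named numeric vector of probabilities, e.g. `c(a = 0.5, b = 0.5)`.
#' @param alphabet character vector of allowed letters; defaults to the
#'   sorted set of letters seen in `positions`.
#' @param validate_sums if `TRUE` (the default, appropriate for raw input)
#'   each position's probabilities must sum to 1 within `1e-6`.  Filtered
#'   strings (where letters below the threshold have been removed) are
#'   built internally with `validate_sums = FALSE` and are never
#'   renormalised.
#' @return an object of class `weighted_string` with fields `positions`
#'   (list of named numeric vectors), `alphabet`, and `n` (length).
#' @examples
#' weighted_string(list("a", "a", "b", c(a = 0.5, b = 0.5)))
#' @export
weighted_string <- function(positions, alphabet = NULL, validate_sums = TRUE) {
  if (is.character(positions) && length(positions) == 1L && nchar(positions) > 0L)
    positions <- as.list(strsplit(positions, "")[[1]])
  stopifnot(is.list(positions))
  pos <- lapply(seq_along(positions), function(r) {
    e <- positions[[r]]
    if (is.character(e)) {
      stopifnot(length(e) == 1L, nchar(e) == 1L)
      e <- stats::setNames(1, e)
    }
    if (!is.numeric(e) || is.null(names(e)) || any(!nzchar(names(e))))
      stop("position ", r - 1L, ": expected a letter or a named numeric vector")
    if (anyDuplicated(names(e)))
      stop("position ", r - 1L, ": duplicate letters")
    if (any(e < 0) || any(e > 1 + 1e-6))
      stop("position ", r - 1L, ": probabilities must lie in [0, 1]")
    if (validate_sums && abs(sum(e) - 1) > 1e-6)
      stop("position ", r - 1L, ": probabilities sum to ", format(sum(e)),
           ", expected 1 within 1e-6")
    e[e > 0]
  })
  if (is.null(alphabet))
    alphabet <- sort(unique(unlist(lapply(pos, names), use.names = FALSE)))
  bad <- setdiff(unlist(lapply(pos, names), use.names = FALSE), alphabet)
  if (length(bad))
    stop("letters outside the declared alphabet: ", paste(bad, collapse = ", "))
  structure(list(positions = pos, alphabet = alphabet, n = length(pos)),
            class = "weighted_string")
}

#' Coerce to a weighted string
#'
#' Plain character strings become all-certain weighted strings (each letter
#' with probability 1).
#'
#' @param x object to coerce.
#' @param ... passed on to methods.
#' @return a `weighted_string`.
#' @export
as_weighted_string <- function(x, ...) UseMethod("as_weighted_string")

#' @rdname as_weighted_string
#' @export
as_weighted_string.weighted_string <- function(x, ...) x

#' @rdname as_weighted_string
#' @export
as_weighted_string.character <- function(x, ...) {
  stopifnot(length(x) == 1L)
  if (nchar(x) == 0L) return(weighted_string(list()))
  weighted_string(as.list(strsplit(x, "")[[1]]), ...)
}

#' @export
length.weighted_string <- function(x) x$n

#' @export
format.weighted_string <- function(x, ...) {
  if (x$n == 0L) return("<empty weighted string>")
  paste(vapply(x$positions, function(e) {
    if (length(e) == 1L && eq_tol(e[[1]], 1)) names(e) else
      paste0("[", paste0("(", names(e), ",", format(unname(e)), ")", collapse = ""), "]")
  }, ""), collapse = "")
}

#' @export
print.weighted_string <- function(x, ...) {
  cat("weighted string, n = ", x$n, ", alphabet {",
      paste(x$alphabet, collapse = ","), "}\n  ", format(x), "\n", sep = "")
  invisible(x)
}

#' Cumulative weight threshold
#'
#' Wraps the threshold 1/z in (0, 1] governing which factors of a weighted
#' string count as present: a concrete word u is a *valid factor* at
#' position i if the product of its per-position letter probabilities is at
#' least 1/z.  The derived quantity `ell = log(z) / log(z / (z - 1))` bounds
#' (for z >= 2) the number of branching (black) positions any valid factor
#' can span, since each black letter has probability at most 1 - 1/z.
#'
#' @param value the threshold 1/z, a number in (0, 1].
#' @return object of class `cw_threshold` with fields `value` (1/z), `z`,
#'   and `ell`.
#' @examples
#' cw_threshold(1 / 2)   # z = 2, ell = 1
#' @export
cw_threshold <- function(value) {
  if (inherits(value, "cw_threshold")) return(value)
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!(value > 0 && value <= 1))
    stop("threshold 1/z must lie in (0, 1], got ", format(value))
  z <- 1 / value
  ell <- if (z <= 1) 0 else log(z) / log(z / (z - 1))
  structure(list(value = value, z = z, ell = ell), class = "cw_threshold")
}

#' @export
print.cw_threshold <- function(x, ...) {
  cat("cumulative weight threshold 1/z = ", format(x$value),
      " (z = ", format(x$z), ", ell = ", format(x$ell), ")\n", sep = "")
  invisible(x)
}

# Single stored letter of a position (positions that are grey/white after
# filtering hold exactly one letter).
forced_letter <- function(entry) names(entry)[[which.max(entry)]]

# Probability of `letter` at 0-based position `i` of ws (0 if absent).
letter_prob <- function(ws, i, letter) {
  e <- ws$positions[[i + 1L]]
  p <- e[letter]
  if (is.na(p)) 0 else unname(p)
}
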