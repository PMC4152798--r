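#' Generate extended factors around black positions
#'
#' Extended factors are concrete strings chosen so that every valid factor
#' of the weighted string occurs inside at least one of them.  Generation
#' walks each segment left to right: grey and white positions contribute
#' their single stored letter (grey probabilities are treated as 1 during
#' generation), while black positions branch, one continuation per stored
#' letter, with the actual letter probability multiplied into the factor's
#' running black-position product.  A factor stops growing at the black
#' position whose inclusion would drop that product below the working
#' threshold.
#'
#' Seeds are: one factor at the segment start; at every black position, one
#' factor per stored letter there; and at every black position an "empty"
#' seed that starts collecting letters at the following position (so its
#' factors do not include the generating black position).  The result is
#' deduplicated on (start, letters), keeping the earliest seed.
#'
#' The count of black positions inside any factor is bounded by
#' `ell = log(z)/log(z/(z-1))`, each black position seeds at most z + 1
#' factors, no position of x lies in more than `z^ell (2 ell + 1)` factors,
#' and the total length of all factors is at most `z^ell (2 ell + 1) n`.
#'
#' @param ws a filtered, split segment (every position non-empty).
#' @param colours the segment's [colour_positions()] result at the working
#'   threshold.
#' @param thr working threshold as a probability (1/z for the valid-
#'   repetition pipeline; 1/z^2 during the first pass of the all-
#'   repetitions pipeline).
#' @return list of `extended_factor` objects: `start` (0-based position in
#'   the segment), `letters` (character string), `black_prob` (product of
#'   chosen-letter probabilities at black positions), `origin` (0-based
#'   seed position).
#' @examples
#' ws <- weighted_string(list("a", "a", "b",
#'                            c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5),
#'                            "b", "a", "b"))
#' efs <- generate_extended_factors(ws, colour_positions(ws, 1/2), 1/2)
#' vapply(efs, function(f) f$letters, "")
#' @export
generate_extended_factors <- function(ws, colours, thr) {
  n <- ws$n
  if (n == 0L) return(list())
  stopifnot(length(colours) == n, is.numeric(thr), thr > 0, thr <= 1)
  blacks <- which(unclass(colours) == "B")            # 1-based
  forced <- vapply(ws$positions, forced_letter, "")
  seeds <- sort(unique(c(1L, blacks, blacks + 1L)))
  seeds <- seeds[seeds <= n]
  # nxtb[r]: smallest black position >= r (1-based), n + 1 when none
  nxtb <- rep(n + 1L, n + 1L)
  isb <- unclass(colours) == "B"
  for (r in n:1) nxtb[r] <- if (isb[r]) r else nxtb[r + 1L]
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (s0 in seeds) {
    done <- list()
    # active factors share start s0 and the current scan position
    active <- list(list(chars = character(0), prob = 1))
    j <- s0
    while (j <= n && length(active)) {
      if (colours[j] != "B") {
        upto <- min(nxtb[j] - 1L, n)        # run of grey/white positions
        seg <- forced[j:upto]
        active <- lapply(active, function(f) {
          f$chars <- c(f$chars, seg); f
        })
        j <- upto
      } else {
        entry <- ws$positions[[j]]
        nxt <- list()
        for (f in active) {
          pr2 <- f$prob * unname(entry)
          keep <- ge_tol(pr2, thr)
          if (!any(keep)) {
            done[[length(done) + 1L]] <- f        # threshold would break: stop
          } else for (k in which(keep)) {
            nxt[[length(nxt) + 1L]] <-
              list(chars = c(f$chars, names(entry)[k]), prob = pr2[k])
          }
        }
        active <- nxt
      }
      j <- j + 1L
    }
    done <- c(done, active)
    for (f in done) {
      if (!length(f$chars)) next
      lets <- paste(f$chars, collapse = "")
      key <- paste0(s0 - 1L, "|", lets)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <-
        structure(list(start = s0 - 1L, letters = lets,
                       black_prob = f$prob, origin = s0 - 1L),
                  class = "extended_factor")
    }
  }
  out
}

#' @export
print.extended_factor <- function(x, ...) {
  cat("extended factor \"", x$letters, "\" at position ", x$start,
      " (black-position probability ", format(x$black_prob), ")\n", sep = "")
  invisible(x)
}

# Actual per-letter probabilities of an extended factor's letters, looked
# up in the (segment) weighted string.  Unlike generation, these include
# the true probabilities at grey positions.
ef_probs <- function(ef, ws) {
  ch <- strsplit(ef$letters, "")[[1]]
  vapply(seq_along(ch),
         function(r) letter_prob(ws, ef$start + r - 1L, ch[r]),
         0)
}

#' Cumulative occurrence probability of a factor slice
#'
#' Product of the actual letter probabilities of an extended factor over
#' the half-open offset range `[i, i + len)` (0-based, relative to the
#' factor).  The empty product is 1.
#'
#' @param ef an `extended_factor`.
#' @param ws the segment `weighted_string` it was generated from.
#' @param i 0-based offset into the factor.
#' @param len slice length.
#' @return a probability.
#' @export
cumulative_prob <- function(ef, ws, i, len) {
  m <- nchar(ef$letters)
  if (i < 0 || len < 0 || i + len > m)
    stop("slice [", i, ", ", i + len, ") out of range for factor of length ", m)
  if (len == 0L) return(1)
  prod(ef_probs(ef, ws)[(i + 1L):(i + len)])
}

#' Longest-valid-factor array
#'
#' `LF[i]` is the length of the longest prefix of the factor's suffix at
#' offset i whose cumulative occurrence probability (actual probabilities
#' at all positions, including grey ones) is at least `thr`.  Because end
#' positions are non-decreasing (the longest valid factor at i + 1 is at
#' least as long as at i minus one), a two-pointer sweep with a running
#' product computes the whole array in linear time.  To guard against
#' floating-point drift the running product is recomputed from scratch
#' after every 64 division steps.
#'
#' @inheritParams cumulative_prob
#' @param thr validity threshold as a probability.
#' @return integer vector `lf` with `lf[r]` the value for 0-based offset
#'   r - 1; satisfies `0 <= LF[i] <= m - i` and `LF[i+1] >= LF[i] - 1`.
#' @examples
#' ws <- weighted_string(list(c(a = 0.6, c = 0.4), "b", "a", "b",
#'                            c(a = 0.6, d = 0.4), "b", "a", "b"))
#' ef <- generate_extended_factors(ws, colour_positions(ws, 1/2), 1/2)[[1]]
#' compute_lf(ef, ws, 1/2)   # 4 7 6 5 4 3 2 1
#' @export
compute_lf <- function(ef, ws, thr) {
  pr <- ef_probs(ef, ws)
  m <- length(pr)
  lf <- integer(m)
  if (m == 0L) return(lf)
  j <- 1L; acc <- 1; ndiv <- 0L
  for (r in 1:m) {
    if (j < r) { j <- r; acc <- 1; ndiv <- 0L }
    while (j <= m && ge_tol(acc * pr[j], thr)) {
      acc <- acc * pr[j]
      j <- j + 1L
    }
    lf[r] <- j - r
    if (j > r) {
      acc <- acc / pr[r]
      ndiv <- ndiv + 1L
      if (ndiv >= 64L) {           # refresh the window product
        acc <- if (j > r + 1L) prod(pr[(r + 1L):(j - 1L)]) else 1
        ndiv <- 0L
      }
    }
  }
  lf
}
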