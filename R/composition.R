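# Problem 1: all repetitions whose every copy is a valid factor at 1/z.
#
# The pipeline runs the valid-repetition machinery at the lowered threshold
# k = 1/z^2 (so that any square whose two halves are each valid at 1/z is
# whole-span valid at k), breaks the maximal extended repetitions into
# overlapping squares, keeps the squares both of whose halves pass the
# longest-valid-factor array LF' computed at 1/z, buckets them by (start,
# period), chains compatible overlapping squares into maximal repetitions,
# and finally reports every suffix occurrence.

#' Generate all valid squares
#'
#' First pass of the all-repetitions pipeline: filter/split/colour the
#' weighted string at k = 1/z^2, generate extended factors at k, compute
#' each factor's maximal repetitions and, on the same factor, the array
#' LF' of longest-factor lengths valid at 1/z.  Maximal extended
#' repetitions are split into their overlapping squares and a square at
#' local offset j with period p is kept when `LF'[j] >= p` and
#' `LF'[j + p] >= p`, i.e. both halves are valid at 1/z.  Results are
#' deduplicated on (start, period, span letters); since a square's second
#' half repeats its first, the span is determined by (start, period, first
#' half).
#'
#' @param ws a raw [weighted_string()].
#' @param t threshold, [cw_threshold()] or numeric 1/z.
#' @return list with elements `squares` (data.frame: `i` segment-global
#'   0-based start in x, `p`, `letters` = the 2p span letters, `seg` index)
#'   and `segments` (list of per-segment `offset`, `colours` at 1/z in
#'   segment coordinates, `nb`, `colours_k`, `ws`), needed downstream.
#' @export
generate_valid_squares <- function(ws, t) {
  t <- cw_threshold(t)
  ws <- as_weighted_string(ws)
  k <- cw_threshold(t$value^2)
  segs <- split_unsupported(filter_letters(ws, k))
  seg_meta <- list()
  rows <- list()
  for (si in seq_along(segs)) {
    seg <- segs[[si]]
    cl_k <- colour_positions(seg$ws, k)
    # colouring at the user's threshold for reported b-sets; restrict the
    # segment to letters >= 1/z first (kept squares only use such letters)
    seg_z <- filter_letters(seg$ws, t)
    cl_z <- vapply(seq_len(seg$ws$n), function(r) {
      e <- seg_z$positions[[r]]
      if (length(e) == 0L) return("B")   # unused: no kept square crosses it
      p <- unname(e)
      if (any(eq_tol(p, 1))) "W" else if (any(gt_tol(p, 1 - t$value))) "G" else "B"
    }, "")
    cl_z <- structure(cl_z, class = "ws_colouring")
    seg_meta[[si]] <- list(offset = seg$offset, ws = seg$ws, ws_z = seg_z,
                           colours = cl_z, nb = next_black(cl_z),
                           colours_k = cl_k, nb_k = next_black(cl_k))
    efs <- generate_extended_factors(seg$ws, cl_k, k$value)
    for (ef in efs) {
      reps <- maximal_repetitions(ef$letters)
      if (!nrow(reps)) next
      lfp <- compute_lf(ef, seg$ws, t$value)        # LF' at 1/z
      sqs <- split_into_squares(reps)
      for (r in seq_len(nrow(sqs))) {
        j <- sqs$i[r]; p <- sqs$p[r]
        if (lfp[j + 1L] < p || lfp[j + p + 1L] < p) next
        rows[[length(rows) + 1L]] <- data.frame(
          i = seg$offset + ef$start + j, p = p,
          letters = substr(ef$letters, j + 1L, j + 2L * p), seg = si)
      }
    }
  }
  squares <- if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[!duplicated(df[c("i", "p", "letters")]), , drop = FALSE]
    df <- df[order(df$i, df$p, df$letters), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else data.frame(i = integer(0), p = integer(0),
                    letters = character(0), seg = integer(0))
  list(squares = squares, segments = seg_meta)
}

#' Bucket squares by start position and period
#'
#' The composition step looks squares up by (start, period); an
#' associative map (R environment keyed "i:p") plays the role of the
#' per-position linked-list arrays, preserving expected constant-time
#' lookup and deletion.
#'
#' @param squares data.frame from [generate_valid_squares()].
#' @return environment mapping "i:p" to a list of row indices into
#'   `squares`.
#' @export
bucket_squares <- function(squares) {
  buckets <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(squares))) {
    key <- paste0(squares$i[r], ":", squares$p[r])
    buckets[[key]] <- c(buckets[[key]], r)
  }
  buckets
}

#' Are two overlapping squares compatible?
#'
#' For squares (i, p) and (i + p, p), the second half of the first square
#' occupies the same positions as the first half of the second; the chain
#' may be extended when the letters chosen at the black positions of that
#' overlap agree.  Grey and white positions carry a single letter, so
#' checking the (at most ell) black positions suffices — equivalently, the
#' two spans agree on the overlap.
#'
#' @param first,second rows (lists) with fields `i`, `p`, `letters` (2p
#'   span letters); must satisfy `second$i == first$i + first$p` and equal
#'   periods.
#' @param colours,nb segment-local colouring and next-black array (at the
#'   working colouring), with `offset` the segment's 0-based start in x.
#' @param offset segment offset.
#' @return `TRUE` or `FALSE`.
#' @export
squares_compatible <- function(first, second, colours, nb, offset) {
  p <- first$p
  if (second$p != p || second$i != first$i + p)
    stop("squares_compatible: squares are not overlap-aligned")
  qs <- blacks_in_range(colours, nb, second$i - offset, p)
  if (!length(qs)) return(TRUE)
  off1 <- (qs + offset - first$i) + 1L       # 1-based into first's span
  off2 <- (qs + offset - second$i) + 1L
  all(substring(first$letters, off1, off1) ==
        substring(second$letters, off2, off2))
}

#' Compose overlapping squares into maximal repetitions
#'
#' Scans start positions in ascending order (periods ascending within a
#' position).  Each surviving square starts a chain: while a compatible
#' square exists one period further right, the exponent grows and the
#' consumed square is deleted from its bucket.  Every input square is
#' consumed by exactly one chain (possibly the chain of itself alone,
#' giving an e = 2 repetition).
#'
#' @param sq result of [generate_valid_squares()].
#' @return data.frame of maximal repetitions: `i`, `p`, `e`, `b` (at the
#'   1/z colouring), `u`, `prob` (whole-span cumulative probability), plus
#'   a `letters` column with the full composed span.
#' @export
compose_squares <- function(sq) {
  squares <- sq$squares
  if (!nrow(squares)) return(cbind(empty_wreps(), letters = character(0)))
  buckets <- bucket_squares(squares)
  consumed <- rep(FALSE, nrow(squares))
  rows <- list()
  ord <- order(squares$i, squares$p)
  for (r in ord) {
    if (consumed[r]) next
    consumed[r] <- TRUE
    seg <- sq$segments[[squares$seg[r]]]
    cur <- list(i = squares$i[r], p = squares$p[r],
                letters = squares$letters[r])
    p <- cur$p
    span <- cur$letters
    e <- 2L
    repeat {
      key <- paste0(cur$i + p, ":", p)
      cand <- buckets[[key]]
      cand <- cand[!consumed[cand]]
      hit <- NULL
      for (cc in cand) {
        nxt <- list(i = squares$i[cc], p = p, letters = squares$letters[cc])
        if (squares_compatible(cur, nxt, seg$colours_k, seg$nb_k,
                               seg$offset)) { hit <- cc; break }
      }
      if (is.null(hit)) break
      consumed[hit] <- TRUE
      e <- e + 1L
      span <- paste0(span, substr(squares$letters[hit], p + 1L, 2L * p))
      cur <- list(i = squares$i[hit], p = p, letters = squares$letters[hit])
    }
    start <- squares$i[r]
    loc <- start - seg$offset
    u <- substr(span, 1L, p)
    pr <- span_probability(seg$ws, loc, span)
    rows[[length(rows) + 1L]] <- data.frame(
      i = start, p = p, e = e,
      b = attach_b(loc, p, u, seg$colours, seg$nb),
      u = u, prob = pr, letters = span)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$i, df$p, df$e, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Cumulative probability of concrete letters `span` at segment-local
# 0-based position `loc`.
span_probability <- function(ws, loc, span) {
  ch <- strsplit(span, "")[[1]]
  prod(vapply(seq_along(ch),
              function(r) letter_prob(ws, loc + r - 1L, ch[r]), 0))
}

#' Report all suffix occurrences of maximal repetitions
#'
#' A repetition per the problem definition is right-maximal only, so each
#' maximal repetition (i, p, b, e) also contains the repetitions
#' (i + kp, p, b_k, e - k) for k = 1..e-2; b_k is recomputed for the copy
#' starting at i + kp.
#'
#' @param maximal data.frame from [compose_squares()] (with `letters`).
#' @param segments segment metadata from [generate_valid_squares()].
#' @param seg_index integer vector mapping rows of `maximal` to segments.
#' @return deduplicated data.frame of quadruples (standard columns).
#' @export
report_all <- function(maximal, segments, seg_index) {
  rows <- list()
  for (r in seq_len(nrow(maximal))) {
    seg <- segments[[seg_index[r]]]
    p <- maximal$p[r]; e <- maximal$e[r]
    for (k in 0:(e - 2L)) {
      start <- maximal$i[r] + k * p
      loc <- start - seg$offset
      span <- substr(maximal$letters[r], k * p + 1L, e * p)
      u <- substr(span, 1L, p)
      rows[[length(rows) + 1L]] <- data.frame(
        i = start, p = p, e = e - k,
        b = attach_b(loc, p, u, seg$colours, seg$nb),
        u = u, prob = span_probability(seg$ws, loc, span))
    }
  }
  finish_wreps(rows)
}

#' Find all repetitions (every copy valid)
#'
#' Solves the main problem: all repetitions u^e, e >= 2, primitive u, in
#' which *each individual copy* of u is a valid factor at 1/z, with e
#' maximal under appending another valid copy.  See the module header for
#' the pipeline.  O(n log n)-class for constant z.
#'
#' @param ws a raw [weighted_string()] (or plain character string).
#' @param t threshold, [cw_threshold()] or numeric 1/z.
#' @param report `"all"` (default; every suffix occurrence, the problem's
#'   definition) or `"maximal"` (only left-maximal composed repetitions).
#' @return data.frame of quadruples: `i`, `p`, `e`, `b`, `u`, `prob`
#'   (whole-span cumulative probability, which may be below 1/z even
#'   though each copy is valid), sorted by (i, p, e, b).
#' @examples
#' solve_problem1("ababab", 1/2)
#' @export
solve_problem1 <- function(ws, t, report = c("all", "maximal")) {
  report <- match.arg(report)
  sq <- generate_valid_squares(ws, t)
  if (!nrow(sq$squares)) return(empty_wreps())
  maximal <- compose_squares(sq)
  seg_index <- vapply(seq_len(nrow(maximal)), function(r) {
    # recover the segment of each composed repetition from its start
    for (si in seq_along(sq$segments)) {
      s <- sq$segments[[si]]
      if (s$offset <= maximal$i[r] &&
          maximal$i[r] < s$offset + s$ws$n) return(si)
    }
    stop("internal: composed repetition outside all segments")
  }, 0L)
  if (report == "maximal") {
    out <- maximal[, c("i", "p", "e", "b", "u", "prob")]
    out <- out[order(out$i, out$p, out$e, out$b), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  report_all(maximal, sq$segments, seg_index)
}

#' Brute-force all repetitions (oracle)
#'
#' Direct enumeration of every (start, period, concrete primitive root):
#' the exponent is the largest number of consecutive copies each of which
#' is a valid factor at 1/z.  Exponential in n; the arbiter for
#' [solve_problem1()] on small inputs.
#'
#' @inheritParams solve_problem2
#' @return same table contract as [solve_problem1()].
#' @export
brute_force_problem1 <- function(ws, t) {
  brute_force_reps(ws, t, whole_span = FALSE)
}
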