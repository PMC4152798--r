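# Weighted-repetition result tables -----------------------------------------
#
# Repetitions in a weighted string are quadruples (i, p, b, e): e >= 2
# adjacent copies of a primitive word u of length p starting at 0-based
# position i, where b records the letter chosen at each black position
# inside the first copy (offsets relative to i).  They are returned as
# data.frames with columns i, p, e, b (serialised "offset:letter" pairs
# joined by ";"), u (the root with the choices of b applied), and prob
# (cumulative occurrence probability of the whole span).

empty_wreps <- function()
  data.frame(i = integer(0), p = integer(0), e = integer(0),
             b = character(0), u = character(0), prob = numeric(0))

serialise_b <- function(offsets, lets) {
  if (!length(offsets)) return("")
  o <- order(offsets)
  paste(paste0(offsets[o], ":", lets[o]), collapse = ";")
}

parse_b <- function(b) {
  if (is.na(b) || !nzchar(b))
    return(list(offsets = integer(0), letters = character(0)))
  parts <- strsplit(strsplit(b, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  list(offsets = vapply(parts, function(x) as.integer(x[1]), 0L),
       letters = vapply(parts, function(x) x[2], ""))
}

# Dedupe on the full quadruple and order by (i, p, e, b).
finish_wreps <- function(rows) {
  if (!length(rows)) return(empty_wreps())
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("i", "p", "e", "b")]), , drop = FALSE]
  df <- df[order(df$i, df$p, df$e, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Maximal repetitions of every extended factor
#'
#' Runs the plain-string partitioner over each extended factor; the union
#' is the set of all maximal extended repetitions.  Results are reported
#' both in factor-local and in segment coordinates and deduplicated on
#' (segment start, period, exponent, span letters).
#'
#' @param efs list of `extended_factor` objects from one segment.
#' @return data.frame with columns `factor` (index into `efs`), `local_i`
#'   (0-based start within the factor), `i` (0-based start in the
#'   segment), `p`, `e`, `letters` (the span's concrete letters).
#' @export
extended_repetitions <- function(efs) {
  rows <- list()
  for (f in seq_along(efs)) {
    reps <- maximal_repetitions(efs[[f]]$letters)
    if (!nrow(reps)) next
    for (r in seq_len(nrow(reps))) {
      i0 <- reps$i[r]; p <- reps$p[r]; e <- reps$e[r]
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, local_i = i0, i = efs[[f]]$start + i0, p = p, e = e,
        letters = substr(efs[[f]]$letters, i0 + 1L, i0 + e * p))
    }
  }
  if (!length(rows))
    return(data.frame(factor = integer(0), local_i = integer(0),
                      i = integer(0), p = integer(0), e = integer(0),
                      letters = character(0)))
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("i", "p", "e", "letters")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Attach the black-choice set b to a repetition
#'
#' b records, for every black position inside the repetition's first copy,
#' the offset (relative to the repetition start) and the letter the
#' extended factor chose there.  Black positions are located by jumping
#' with the next-black array, so the cost is proportional to their number
#' (at most ell).
#'
#' @param x_start 0-based start of the repetition in segment coordinates.
#' @param p period.
#' @param letters concrete letters of (at least) the first copy.
#' @param colours segment colouring at the output threshold.
#' @param nb [next_black()] array for `colours`.
#' @return serialised b string ("offset:letter;..." or "").
#' @export
attach_b <- function(x_start, p, letters, colours, nb) {
  qs <- blacks_in_range(colours, nb, x_start, p)
  if (!length(qs)) return("")
  offs <- qs - x_start
  serialise_b(offs, substring(letters, offs + 1L, offs + 1L))
}

#' Break a maximal extended repetition at the validity boundary
#'
#' Extended factors may contain factors that are not valid (grey
#' probabilities are ignored during generation), so a maximal extended
#' repetition need not be a valid repetition.  Scanning its occurrence
#' starts j = i, i+p, ..., i+(e-2)p left to right, the longest valid
#' repetition at each start is `e_j = min(floor(LF[j]/p), copies remaining
#' from j)`; it is emitted when `e_j >= 2` and its span is not contained in
#' the immediately preceding emission's span.
#'
#' @param local_i,p,e the maximal extended repetition in factor-local
#'   0-based coordinates.
#' @param lf the factor's [compute_lf()] array at the validity threshold.
#' @return data.frame with columns `local_i`, `p`, `e` of the emitted
#'   valid repetitions (possibly empty).
#' @export
break_into_valid <- function(local_i, p, e, lf) {
  out <- list()
  prev_end <- -1L
  for (k in 0:(e - 2L)) {
    j <- local_i + k * p
    ej <- min(lf[j + 1L] %/% p, e - k)
    if (ej < 2L) next
    end <- j + ej * p
    if (end <= prev_end) next          # contained in previous emission
    out[[length(out) + 1L]] <- c(j, p, ej)
    prev_end <- end
  }
  if (!length(out))
    return(data.frame(local_i = integer(0), p = integer(0), e = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("local_i", "p", "e")
  df
}

#' Find all valid repetitions (whole span above threshold)
#'
#' A *valid repetition* is a repetition u^e whose entire span has
#' cumulative occurrence probability at least 1/z.  The pipeline: filter
#' letters at 1/z, split at unsupported positions, colour, generate
#' extended factors at 1/z, find each factor's maximal repetitions, cut
#' them at the longest-valid-factor boundary, attach b-sets, and
#' deduplicate.  Runs in O(n log n)-class time for constant z.
#'
#' @param ws a raw [weighted_string()].
#' @param t threshold, [cw_threshold()] or numeric 1/z.
#' @return data.frame of quadruples (see package overview): columns `i`,
#'   `p`, `e`, `b`, `u`, `prob`, sorted by (i, p, e, b).  Every row's span
#'   has cumulative probability >= 1/z.
#' @examples
#' ws <- weighted_string(list("a", "a", "b",
#'                            c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5),
#'                            "b", "a", "b"))
#' solve_problem2(ws, 1/4)
#' @export
solve_problem2 <- function(ws, t) {
  t <- cw_threshold(t)
  ws <- as_weighted_string(ws)
  segs <- split_unsupported(filter_letters(ws, t))
  rows <- list()
  for (seg in segs) {
    cl <- colour_positions(seg$ws, t)
    nb <- next_black(cl)
    efs <- generate_extended_factors(seg$ws, cl, t$value)
    for (ef in efs) {
      reps <- maximal_repetitions(ef$letters)
      if (!nrow(reps)) next
      lf <- compute_lf(ef, seg$ws, t$value)
      for (r in seq_len(nrow(reps))) {
        cuts <- break_into_valid(reps$i[r], reps$p[r], reps$e[r], lf)
        for (cc in seq_len(nrow(cuts))) {
          j <- cuts$local_i[cc]; p <- cuts$p[cc]; e <- cuts$e[cc]
          seg_i <- ef$start + j
          u <- substr(ef$letters, j + 1L, j + p)
          rows[[length(rows) + 1L]] <- data.frame(
            i = seg$offset + seg_i, p = p, e = e,
            b = attach_b(seg_i, p, u, cl, nb),
            u = u, prob = cumulative_prob(ef, seg$ws, j, e * p))
        }
      }
    }
  }
  finish_wreps(rows)
}

#' Reconstruct the repeated word from a quadruple
#'
#' Inverse of the quadruple encoding: given (i, p, b, e) and the weighted
#' string, rebuild v = u^e.  Offset j of u takes b's letter when position
#' i + j is black; otherwise the first non-black occurrence of offset j in
#' some copy forces the letter (grey and white positions store a single
#' letter after filtering).
#'
#' @param i,p,e the quadruple's start, period and exponent (0-based i).
#' @param b serialised b-set ("offset:letter;..." or "").
#' @param ws the raw weighted string.
#' @param t threshold used for filtering/colouring.
#' @return the concrete string v of length e * p.
#' @examples
#' ws <- weighted_string(list("a", "a", "b",
#'                            c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5),
#'                            "b", "a", "b"))
#' reconstruct_v(1, 3, 2, "2:a", ws, 1/2)   # "abaaba"
#' @export
reconstruct_v <- function(i, p, e, b, ws, t) {
  t <- cw_threshold(t)
  fw <- filter_letters(as_weighted_string(ws), t)
  segs <- split_unsupported(fw)
  seg <- NULL
  for (s in segs)
    if (s$offset <= i && i + e * p <= s$offset + s$ws$n) seg <- s
  if (is.null(seg))
    stop("span [", i, ", ", i + e * p, ") does not lie in one supported segment")
  cl <- colour_positions(seg$ws, t)
  bb <- parse_b(b)
  u <- character(p)
  for (j in seq_len(p) - 1L) {
    if (j %in% bb$offsets) {
      u[j + 1L] <- bb$letters[match(j, bb$offsets)]
      next
    }
    lj <- NA_character_
    for (k in 0:(e - 1L)) {
      pos <- i - seg$offset + k * p + j           # segment-local 0-based
      if (cl[pos + 1L] != "B") {
        lj <- forced_letter(seg$ws$positions[[pos + 1L]])
        break
      }
    }
    if (is.na(lj))
      stop("inconsistent quadruple: offset ", j,
           " is neither in b nor forced at any copy")
    u[j + 1L] <- lj
  }
  strrep(paste(u, collapse = ""), e)
}

#' Brute-force valid repetitions (oracle)
#'
#' Direct enumeration over all starts, periods and concrete root words
#' (letters drawn from the threshold-filtered positions): a quadruple is
#' reported when the root is primitive, the whole span u^e has cumulative
#' probability >= 1/z, and e is maximal under adding another valid copy.
#' Exponential in n; intended for n up to about a dozen as the arbiter for
#' [solve_problem2()].
#'
#' @inheritParams solve_problem2
#' @return same table contract as [solve_problem2()].
#' @export
brute_force_valid_repetitions <- function(ws, t) {
  brute_force_reps(ws, t, whole_span = TRUE)
}

# Shared enumeration for the two brute-force oracles.  whole_span = TRUE:
# validity of the entire span (Problem 2); FALSE: per-copy validity
# (Problem 1).
brute_force_reps <- function(ws, t, whole_span) {
  t <- cw_threshold(t)
  ws <- as_weighted_string(ws)
  fw <- filter_letters(ws, t)
  segs <- split_unsupported(fw)
  rows <- list()
  for (seg in segs) {
    n <- seg$ws$n
    if (n < 2L) next
    cl <- colour_positions(seg$ws, t)
    nb <- next_black(cl)
    probs <- seg$ws$positions
    for (i0 in 0:(n - 2L)) {
      for (p in seq_len((n - i0) %/% 2L)) {
        roots <- expand_roots(probs[(i0 + 1L):(i0 + p)])
        for (u in roots) {
          if (!is_primitive(paste(u, collapse = ""))) next
          # per-copy cumulative probabilities, as many copies as fit
          emax <- 0L
          span_pr <- 1
          repeat {
            k <- emax
            if (i0 + (k + 1L) * p > n) break
            cp <- 1
            ok <- TRUE
            for (j in seq_len(p)) {
              pr <- probs[[i0 + k * p + j]][u[j]]
              if (is.na(pr)) { ok <- FALSE; break }
              cp <- cp * unname(pr)
            }
            if (!ok) break
            if (whole_span) {
              if (!ge_tol(span_pr * cp, t$value)) break
              span_pr <- span_pr * cp
            } else {
              if (!ge_tol(cp, t$value)) break
              span_pr <- span_pr * cp
            }
            emax <- emax + 1L
          }
          if (emax < 2L) next
          ustr <- paste(u, collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            i = seg$offset + i0, p = p, e = emax,
            b = attach_b(i0, p, ustr, cl, nb),
            u = ustr, prob = span_pr)
        }
      }
    }
  }
  finish_wreps(rows)
}

# All concrete words over a list of filtered positions (named prob vectors).
expand_roots <- function(poslist) {
  opts <- lapply(poslist, names)
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(r) as.character(unlist(grid[r, ])))
}
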