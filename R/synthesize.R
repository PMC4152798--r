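#' Synthesize a weighted string with planted tandem repeats
#'
#' Generates a random weighted string for benchmarking and recall testing.
#' A fraction `black_density` of positions is uncertain (branching): the
#' intended letter gets probability 0.6 and one random other letter 0.4,
#' which makes the position black at any threshold 1/z with z >= 2.5 and
#' keeps the intended word recoverable.  Requested tandem repeats are
#' planted at random non-overlapping starts: a random primitive root of
#' the requested period is written `exponent` times, the flanking letters
#' are set to break the period (so the planted exponent is exact), and the
#' number of uncertain positions inside any single copy is capped so that
#' every copy stays valid at `threshold` (0.6^c >= 1/z).
#'
#' @param n total length.
#' @param alphabet letters to draw from (at least 2).
#' @param black_density fraction of positions made uncertain, in [0, 1).
#' @param planted list of `c(period, exponent)` pairs to plant.
#' @param threshold validity threshold 1/z the planted copies must meet.
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments and the seed.
#' @return list with `ws` (the [weighted_string()]) and `truth`
#'   (data.frame of planted quadruples: `i`, `p`, `e`, `b`, `u`).
#' @examples
#' syn <- synthesize(40, c("a", "b"), 0, list(c(2, 3)), 1/2, seed = 7)
#' syn$truth
#' @export
synthesize <- function(n, alphabet = c("A", "C", "G", "T"),
                       black_density = 0.05, planted = list(),
                       threshold = 1/4, seed = NULL) {
  stopifnot(length(alphabet) >= 2L, n >= 1L,
            black_density >= 0, black_density < 1)
  t <- cw_threshold(threshold)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  # uncertain positions use probabilities (0.6, 0.4); copies stay valid
  # while they contain at most floor(log(1/z)/log(0.6)) such positions
  q <- 0.6
  budget <- if (t$value >= 1) 0L else as.integer(floor(log(t$value) / log(q) + 1e-9))
  base <- sample(alphabet, n, replace = TRUE)
  taken <- rep(FALSE, n)                       # 1-based occupancy
  protect <- rep(FALSE, n)                     # flank breakers stay certain
  truth <- list()
  for (pl in planted) {
    p <- as.integer(pl[1]); e <- as.integer(pl[2])
    span <- p * e
    if (span + 2L > n)
      stop("planted repeat of span ", span, " does not fit in n = ", n)
    # random primitive root
    repeat {
      u <- sample(alphabet, p, replace = TRUE)
      if (is_primitive(paste(u, collapse = ""))) break
    }
    # random start leaving one breakable flank on each side
    free <- which(!taken)
    ok_starts <- integer(0)
    for (s in free) {                          # s = 1-based start
      if (s < 2L || s + span > n) next
      if (all(!taken[(s - 1L):min(n, s + span)])) ok_starts <- c(ok_starts, s)
    }
    if (!length(ok_starts))
      stop("no room left to plant a repeat of span ", span)
    s <- if (length(ok_starts) == 1L) ok_starts else sample(ok_starts, 1L)
    base[s:(s + span - 1L)] <- rep(u, e)
    # break the period on both flanks
    base[s - 1L] <- sample(setdiff(alphabet, u[p]), 1L)
    protect[s - 1L] <- TRUE
    if (s + span <= n) {
      base[s + span] <- sample(setdiff(alphabet, u[1]), 1L)
      protect[s + span] <- TRUE
    }
    taken[(s - 1L):min(n, s + span)] <- TRUE
    truth[[length(truth) + 1L]] <- list(i = s - 1L, p = p, e = e, u = u)
  }
  # choose uncertain positions: cap the count per planted copy
  unc <- rep(FALSE, n)
  cand <- which(stats::runif(n) < black_density)
  for (s in cand) unc[s] <- TRUE
  unc[protect] <- FALSE
  for (tr in truth) {
    for (k in 0:(tr$e - 1L)) {
      idx <- (tr$i + k * tr$p + 1L):(tr$i + (k + 1L) * tr$p)
      inside <- idx[unc[idx]]
      if (length(inside) > budget) {
        drop <- if (budget > 0L) inside[-seq_len(budget)] else inside
        unc[drop] <- FALSE
      }
    }
  }
  pos <- vector("list", n)
  for (r in seq_len(n)) {
    if (unc[r]) {
      other <- sample(setdiff(alphabet, base[r]), 1L)
      pos[[r]] <- stats::setNames(c(q, 1 - q), c(base[r], other))
    } else pos[[r]] <- base[r]
  }
  ws <- weighted_string(pos, alphabet = alphabet)
  # truth quadruples with b at the 1/z colouring (positions left empty by
  # the filter never lie inside a planted span; mark them B, harmlessly)
  fw <- filter_letters(ws, t)
  cl <- structure(vapply(fw$positions, function(e) {
    if (length(e) == 0L) return("B")
    pv <- unname(e)
    if (any(eq_tol(pv, 1))) "W" else if (any(gt_tol(pv, 1 - t$value))) "G" else "B"
  }, ""), class = "ws_colouring")
  nb <- next_black(cl)
  tdf <- if (length(truth)) {
    do.call(rbind, lapply(truth, function(tr) {
      ustr <- paste(tr$u, collapse = "")
      data.frame(i = tr$i, p = tr$p, e = tr$e,
                 b = attach_b(tr$i, tr$p, ustr, cl, nb), u = ustr)
    }))
  } else data.frame(i = integer(0), p = integer(0), e = integer(0),
                    b = character(0), u = character(0))
  list(ws = ws, truth = tdf)
}
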