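# File formats: IUPAC FASTA in, native probability-matrix TSV in/out, and a
# repetition-report TSV out/in.  All coordinates in files are 0-based.

#' Read IUPAC-encoded DNA FASTA as weighted strings
#'
#' Each IUPAC ambiguity code expands to the uniform distribution over its
#' base set (M -> A and C at probability 0.5 each; N -> all four at 0.25);
#' plain bases map to probability 1.  This is the lossy convenience path
#' for uncertain sequence data — arbitrary distributions use the
#' probability-matrix format ([read_probability_matrix()]).
#'
#' @param path FASTA file; letters restricted to IUPAC nucleotide codes.
#' @return named list of [weighted_string()]s (names = record ids), each
#'   on alphabet A, C, G, T.
#' @export
read_iupac_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  code_map <- Biostrings::IUPAC_CODE_MAP
  out <- lapply(seq_along(recs), function(k) {
    chars <- strsplit(toupper(as.character(recs[[k]])), "")[[1]]
    bad <- which(!(chars %in% names(code_map)))
    if (length(bad))
      stop("record '", names(recs)[k], "': non-IUPAC character '",
           chars[bad[1]], "' at position ", bad[1] - 1L)
    pos <- lapply(chars, function(ch) {
      bases <- strsplit(code_map[[ch]], "")[[1]]
      stats::setNames(rep(1 / length(bases), length(bases)), bases)
    })
    weighted_string(pos, alphabet = c("A", "C", "G", "T"))
  })
  names(out) <- sub("\\s.*$", "", names(recs))
  out
}

#' Read a probability-matrix TSV as a weighted string
#'
#' The native format: "#"-prefixed header lines, the first being
#' `# alphabet: <letters>`; then one tab-separated row per position with
#' the 0-based position index followed by one probability per alphabet
#' letter.  Row indices must be consecutive from 0 and each row must sum
#' to 1 within 1e-6.  Zero-probability entries are dropped.
#'
#' @param path TSV file.
#' @return a [weighted_string()] with exactly the declared alphabet.
#' @export
read_probability_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (!length(headers) || !grepl("^#\\s*alphabet:", headers[1]))
    stop("first header line must be '# alphabet: <letters>'")
  alpha <- strsplit(trimws(sub("^#\\s*alphabet:", "", headers[1])), "\\s+")[[1]]
  alpha <- unlist(strsplit(alpha, ""), use.names = FALSE)
  pos <- vector("list", length(body))
  for (r in seq_along(body)) {
    f <- strsplit(body[r], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(alpha) + 1L)
      stop("row ", r - 1L, ": expected ", length(alpha) + 1L,
           " fields, got ", length(f))
    idx <- as.integer(f[1])
    if (is.na(idx) || idx != r - 1L)
      stop("row ", r - 1L, ": position indices must be consecutive from 0")
    p <- as.numeric(f[-1])
    if (anyNA(p) || any(p < 0) || any(p > 1))
      stop("row ", r - 1L, ": probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-6)
      stop("row ", r - 1L, ": probabilities sum to ", format(sum(p)),
           ", expected 1 within 1e-6")
    pos[[r]] <- stats::setNames(p, alpha)
  }
  weighted_string(pos, alphabet = alpha)
}

#' Write a weighted string as a probability-matrix TSV
#'
#' @param ws a raw [weighted_string()] (per-position sums of 1).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probability_matrix <- function(ws, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# alphabet: ", paste(ws$alphabet, collapse = "")), con)
  for (r in seq_len(ws$n)) {
    e <- ws$positions[[r]]
    p <- vapply(ws$alphabet, function(a) {
      v <- e[a]; if (is.na(v)) 0 else unname(v)
    }, 0)
    writeLines(paste(c(r - 1L, format(p, digits = 15, trim = TRUE,
                                      scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read repetition reports
#'
#' Fixed-column TSV (`id`, `i`, `p`, `e`, `b`, `u`, `prob`), 0-based
#' coordinates, deterministic (i, p, e, b) ordering; round-trips
#' losslessly.  An empty result writes a header-only file.
#'
#' @param reps data.frame of quadruples as returned by [solve_problem1()]
#'   or [solve_problem2()].
#' @param path output (input) file.
#' @param id sequence identifier stored in the `id` column.
#' @return `write_repetitions`: `path` invisibly; `read_repetitions`: the
#'   data.frame (with the `id` column).
#' @export
write_repetitions <- function(reps, path, id = "seq") {
  df <- data.frame(id = if (nrow(reps)) id else character(0),
                   reps[, c("i", "p", "e", "b", "u", "prob")])
  if (nrow(df)) {
    df <- df[order(df$i, df$p, df$e, df$b), , drop = FALSE]
    df$prob <- format(df$prob, digits = 15, trim = TRUE, scientific = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_repetitions
#' @export
read_repetitions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "integer",
                                         "integer", "character", "character",
                                         "numeric"),
                          na.strings = NULL)
  df$b[is.na(df$b)] <- ""
  df
}
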