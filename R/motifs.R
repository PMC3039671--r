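# Native position-weight-matrix scanning: per-window log-odds scores against a
# uniform background, both strands, N-containing windows skipped.

#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param matrix A 4 x L numeric matrix of log-odds weights with rows
#'   `A`, `C`, `G`, `T` (log2 of base probability over the uniform 0.25
#'   background).
#' @param score_threshold Absolute log-odds score a window must reach to
#'   count as a hit; defaults to `relative_threshold` times the maximal
#'   achievable score.
#' @param relative_threshold Fraction of the maximal score used when
#'   `score_threshold` is `NULL` (default 0.8).
#' @return A `pwm` object.
#' @export
pwm <- function(name, matrix, score_threshold = NULL, relative_threshold = 0.8) {
  if (!is.matrix(matrix) || nrow(matrix) != 4 || ncol(matrix) < 1) {
    abort("`matrix` must be a 4-row matrix with >= 1 position")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  max_score <- sum(apply(matrix, 2, max))
  thr <- score_threshold %||% (relative_threshold * max_score)
  if (thr > max_score) {
    abort("`score_threshold` exceeds the maximal achievable score")
  }
  structure(list(name = name, matrix = matrix, score_threshold = thr,
                 max_score = max_score),
            class = "pwm")
}

#' Build a PWM from a consensus sequence
#'
#' A convenience constructor for promoter-element style motifs: the
#' consensus base at each position gets probability `p_match`, the other
#' three split the remainder evenly, and the weights are the log2 odds
#' against a uniform background.
#'
#' @param name Motif name.
#' @param consensus A string over `ACGT`.
#' @param p_match Probability mass on the consensus base (default 0.85).
#' @param relative_threshold Passed to [pwm()] (default 0.8).
#' @return A `pwm` object.
#' @examples
#' pwm_from_consensus("CAAT", "CCAAT")
#' @export
pwm_from_consensus <- function(name, consensus, p_match = 0.85,
                               relative_threshold = 0.8) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort("`consensus` must use only A/C/G/T")
  }
  p_other <- (1 - p_match) / 3
  mat <- vapply(bases, function(b) {
    p <- rep(p_other, 4)
    p[match(b, c("A", "C", "G", "T"))] <- p_match
    log2(p / 0.25)
  }, numeric(4))
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  pwm(name, mat, relative_threshold = relative_threshold)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d position(s), threshold %.2f (max score %.2f)\n",
              x$name, ncol(x$matrix), x$score_threshold, x$max_score))
  invisible(x)
}

# Log-odds score of every window of `seq` (a character string) under `mat`.
# Windows containing a non-ACGT character score NA.
scan_scores <- function(seq, mat) {
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  L <- ncol(mat)
  n <- length(code) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    s <- s + mat[code[j:(j + n - 1)] + (j - 1) * 4L]
  }
  s
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Motif density over a set of region sequences
#'
#' Slides each PWM over every sequence and its reverse complement,
#' counting windows whose log-odds score reaches the motif's threshold
#' (windows containing `N` are skipped), and reports hits per 1000 bp
#' of sequence — the per-kilobase normalization used throughout.
#'
#' @param sequences A tibble with interval columns and a `seq` column,
#'   e.g. from [region_sequences()]; each sequence must match its
#'   region's length.
#' @param pwms A list of [pwm()] objects (a single `pwm` is accepted).
#' @return A tibble with one row per motif: `motif`, `n_hits`,
#'   `density` (hits per kb over the total sequence length).
#' @export
motif_density <- function(sequences, pwms) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(is.data.frame(sequences), "seq" %in% names(sequences))
  if (all(c("start", "end") %in% names(sequences))) {
    bad <- nchar(sequences$seq) != sequences$end - sequences$start
    if (any(bad)) {
      abort(sprintf("sequence %d length does not match its region length",
                    which(bad)[1]))
    }
  }
  if (any(grepl("[^ACGTNacgtn]", sequences$seq))) {
    abort("sequences must be over the ACGTN alphabet")
  }
  total_bp <- sum(nchar(sequences$seq))
  dplyr::bind_rows(lapply(pwms, function(p) {
    stopifnot(inherits(p, "pwm"))
    hits <- sum(vapply(sequences$seq, function(sq) {
      fwd <- scan_scores(sq, p$matrix)
      rev <- scan_scores(revcomp(sq), p$matrix)
      sum(fwd >= p$score_threshold, na.rm = TRUE) +
        sum(rev >= p$score_threshold, na.rm = TRUE)
    }, numeric(1), USE.NAMES = FALSE))
    tibble(motif = p$name, n_hits = as.integer(hits),
           density = 1000 * hits / total_bp)
  }))
}
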