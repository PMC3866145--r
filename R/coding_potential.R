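## Fickett TESTCODE coding-potential statistic.
##
## The eight parameters (per-base positional asymmetry and content) are
## mapped through the published probability lookup tables and combined with
## the published weights. Tables are embedded verbatim as versioned
## constants (v1982, as propagated by the EMBOSS `tcode` data file).

## probability of coding for the position parameter, rows indexed by the
## interval thresholds >= 1.9, 1.8, ..., 1.1, and < 1.1 (last entry)
.tc_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.tc_position_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)

## content parameter, thresholds >= 0.33, 0.31, ..., 0.17, and < 0.17
.tc_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.tc_content_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17)

.tc_weights <- c(
  pos_A = 0.26, pos_C = 0.18, pos_G = 0.31, pos_T = 0.33,
  cont_A = 0.11, cont_C = 0.12, cont_G = 0.15, cont_T = 0.14
)

.tc_lookup <- function(value, breaks, probs) {
  i <- which(value >= breaks)
  probs[if (length(i)) i[1L] else length(probs)]
}

#' Fickett TESTCODE coding-potential score
#'
#' Computes the TESTCODE statistic of a nucleotide sequence (the putative
#' sense strand of an ORF). For each base the position parameter is
#' `max(n1, n2, n3) / (min(n1, n2, n3) + 1)` over the three reading phases
#' and the content parameter is the base frequency; the eight values are
#' mapped through the published lookup tables and combined with the
#' published weights. Verdicts use the published thresholds: noncoding
#' below 0.74, no-opinion in (0.74, 0.95), coding above 0.95. The reported
#' probability of coding is a monotone calibration anchored at those
#' thresholds.
#'
#' @param seq Nucleotide string; the annotated ORF including the start
#'   codon. Scores on sequences shorter than 200 nt are flagged
#'   low-confidence.
#' @param include_stop Kept for symmetry with annotation conventions: when
#'   `FALSE` (default) a terminal stop codon present in `seq` is removed
#'   before scoring.
#' @param code Genetic-code id used only to recognise a terminal stop.
#' @return List with `score`, `verdict` (`"coding"`, `"noncoding"`,
#'   `"no-opinion"`), `probability_coding` (percentage) and
#'   `low_confidence`.
#' @export
testcode <- function(seq, include_stop = FALSE, code = "5") {
  if (!nzchar(seq)) stop("empty sequence")
  seq <- toupper(seq)
  if (!include_stop && nchar(seq) %% 3L == 0L && nchar(seq) >= 6L) {
    last <- substr(seq, nchar(seq) - 2L, nchar(seq))
    if (last %in% stop_codons(code)) {
      seq <- substr(seq, 1L, nchar(seq) - 3L)
    }
  }
  ch <- seq_chars(seq)
  n <- length(ch)
  phase <- ((seq_len(n) - 1L) %% 3L) + 1L
  score <- 0
  for (b in DNA_ALPHABET) {
    cnt <- vapply(1:3, function(p) sum(ch == b & phase == p), numeric(1L))
    posval <- max(cnt) / (min(cnt) + 1)
    contval <- sum(cnt) / n
    score <- score +
      .tc_weights[[paste0("pos_", b)]] *
        .tc_lookup(posval, .tc_position_breaks, .tc_position_prob[[b]]) +
      .tc_weights[[paste0("cont_", b)]] *
        .tc_lookup(contval, .tc_content_breaks, .tc_content_prob[[b]])
  }
  verdict <- if (score >= 0.95) "coding"
             else if (score <= 0.74) "noncoding"
             else "no-opinion"
  prob <- max(0, min(100, round(74 + 70 * (score - 0.74))))
  list(score = unname(score), verdict = verdict,
       probability_coding = prob, low_confidence = n < 200L)
}

#' TESTCODE report for annotated features
#'
#' @param genome A `mito_genome`.
#' @param labels Feature labels to score (default: all `ORF` features).
#' @param ... Passed to [testcode()].
#' @return Data frame with `label`, `score`, `verdict`,
#'   `probability_coding`, `low_confidence`.
#' @export
testcode_report <- function(genome, labels = NULL, ...) {
  f <- genome$features
  if (is.null(labels)) labels <- f$label[f$kind == "ORF"]
  if (!length(labels)) stop("no ORF features to score in ", genome$id)
  rows <- lapply(labels, function(l) {
    r <- testcode(feature_sequence(genome, l), ...)
    data.frame(label = l, score = r$score, verdict = r$verdict,
               probability_coding = r$probability_coding,
               low_confidence = r$low_confidence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
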