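## Tandem-repeat detection, stem-loop (hairpin) potential and the
## three-criteria control-region ranking (length, AT richness, tandem
## repeats with stem-loop potential).

#' Detect approximate tandem repeats
#'
#' Substitution-aware detector: candidate periods are taken from the
#' distances between recurring exact k-mers; for each period the lag-match
#' profile is segmented into maximal runs whose identity stays above
#' `min_identity`, and overlapping reports are reduced to the
#' highest-identity (then smallest-period, then leftmost) maximal arrays.
#' Copy comparison is substitution-only (no indels between copies).
#'
#' @param seq Nucleotide string.
#' @param min_period Minimum repeat unit length (bp), default 20.
#' @param min_copies Minimum (possibly fractional) copy number, default 2.
#' @param min_identity Minimum mean identity between successive copies,
#'   default 0.85.
#' @param k Seed k-mer length, default 12.
#' @return Data frame with columns `start` (0-based offset), `period`,
#'   `copies`, `span`, `identity`, `unit` (majority consensus), ordered by
#'   `start`.
#' @export
tandem_repeats <- function(seq, min_period = 20L, min_copies = 2,
                           min_identity = 0.85, k = 12L) {
  empty <- data.frame(start = integer(0), period = integer(0),
                      copies = numeric(0), span = integer(0),
                      identity = numeric(0), unit = character(0),
                      stringsAsFactors = FALSE)
  seq <- toupper(seq)
  n <- nchar(seq)
  max_period <- floor(n / min_copies)
  if (max_period < min_period) return(empty)
  ch <- seq_chars(seq)
  ## candidate periods from recurring k-mer distances; the seed length
  ## adapts to short inputs
  k <- max(3L, min(k, n %/% 2L))
  if (n <= k) return(empty)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  groups <- split(seq_along(kmers), kmers)
  cand <- integer(0)
  for (g in groups) {
    if (length(g) < 2L) next
    d <- diff(g)
    cand <- c(cand, d[d >= min_period & d <= max_period])
  }
  cand <- sort(unique(cand))
  if (!length(cand)) return(empty)
  hits <- list()
  for (p in cand) {
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    ## maximal runs of matches, merged across short mismatch gaps while
    ## overall identity stays above threshold
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    runs <- data.frame(s = starts[r$values], e = ends[r$values])
    if (!nrow(runs)) next
    merged <- runs[1L, , drop = FALSE]
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        last <- nrow(merged)
        cand_s <- merged$s[last]; cand_e <- runs$e[i]
        ident <- sum(m[cand_s:cand_e]) / (cand_e - cand_s + 1L)
        if (ident >= min_identity) {
          merged$e[last] <- cand_e
        } else {
          merged <- rbind(merged, runs[i, ])
        }
      }
    }
    for (i in seq_len(nrow(merged))) {
      ## trim merged ends whose local identity falls below threshold
      s0 <- merged$s[i]; e0 <- merged$e[i]
      w <- min(15L, e0 - s0 + 1L)
      while (e0 - s0 + 1L > w &&
             mean(m[s0:(s0 + w - 1L)]) < min_identity) s0 <- s0 + 1L
      while (e0 - s0 + 1L > w &&
             mean(m[(e0 - w + 1L):e0]) < min_identity) e0 <- e0 - 1L
      L <- e0 - s0 + 1L
      span <- L + p
      copies <- span / p
      ident <- sum(m[s0:e0]) / L
      merged$s[i] <- s0; merged$e[i] <- e0
      if (copies >= min_copies && ident >= min_identity) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = merged$s[i] - 1L, period = p, copies = copies,
          span = span, identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  ## reduce overlapping reports to divisor-minimal periods: a report is
  ## dropped when most of its own span is covered by a preferred
  ## (smaller-period, then higher-identity, then leftmost) report
  h <- h[order(h$period, -h$identity, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(h))) {
      if (j <= i || !keep[j]) next
      ov <- min(h$start[i] + h$span[i], h$start[j] + h$span[j]) -
        max(h$start[i], h$start[j])
      if (ov > 0.5 * h$span[j]) keep[j] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h$unit <- vapply(seq_len(nrow(h)), function(i) {
    consensus_unit(ch, h$start[i], h$period[i], h$span[i])
  }, character(1L))
  h <- h[order(h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

## majority-vote consensus of the aligned full copies
consensus_unit <- function(ch, start, period, span) {
  ncop <- span %/% period
  mat <- matrix(NA_character_, nrow = ncop, ncol = period)
  for (i in seq_len(ncop)) {
    idx <- start + (i - 1L) * period + seq_len(period)
    idx <- idx[idx <= length(ch)]
    mat[i, seq_along(idx)] <- ch[idx]
  }
  paste(apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    names(sort(table(col), decreasing = TRUE))[1L]
  }), collapse = "")
}

.pairable <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) {
    wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  wc
}

#' Maximum base-pair hairpin structure (Nussinov recursion)
#'
#' Finds a maximum-cardinality nested set of Watson-Crick (optionally G-U)
#' base pairs with a minimum loop constraint, by the Nussinov dynamic
#' program with a deterministic traceback that extends helices outermost
#' first (giving long contiguous stems, 5'-most on ties). The reported stem
#' is the longest contiguous helix of the optimal structure.
#'
#' @param seq Nucleotide string (DNA alphabet; pairing rules apply to the
#'   transcribed sense).
#' @param min_loop Minimum unpaired loop length, default 3.
#' @param allow_gu Allow G-U (G-T in DNA) wobble pairs, default `TRUE`.
#' @return List with `pairs` (two-column matrix of 1-based paired indices),
#'   `n_pairs`, `stem_length`, `loop_length` (loop subtended by the
#'   innermost pair of the reported stem; `NA` if no pairs), `dot_bracket`.
#' @export
max_hairpin <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < min_loop + 2L) {
    return(list(pairs = matrix(integer(0), ncol = 2L), n_pairs = 0L,
                stem_length = 0L, loop_length = NA_integer_,
                dot_bracket = strrep(".", n)))
  }
  F <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- F[i + 1L, j]
      if (.pairable(ch[i], ch[j], allow_gu)) {
        inner <- if (j - 1L >= i + 1L) F[i + 1L, j - 1L] else 0L
        best <- max(best, inner + 1L)
      }
      if (j - 1L > i) {
        ks <- (i + 1L):(j - 1L)
        split_best <- max(F[i, ks] + F[cbind(ks + 1L, j)])
        best <- max(best, split_best)
      }
      F[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), ncol = 2L)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i <= min_loop) return(invisible(NULL))
      inner <- if (j - 1L >= i + 1L) F[i + 1L, j - 1L] else 0L
      if (.pairable(ch[i], ch[j], allow_gu) && F[i, j] == inner + 1L) {
        pairs <<- rbind(pairs, c(i, j))
        i <- i + 1L; j <- j - 1L
        next
      }
      if (F[i, j] == F[i + 1L, j]) { i <- i + 1L; next }
      ks <- (i + 1L):(j - 1L)
      k <- ks[which(F[i, ks] + F[cbind(ks + 1L, j)] == F[i, j])[1L]]
      trace(i, k)
      i <- k + 1L
    }
  }
  trace(1L, n)
  n_pairs <- nrow(pairs)
  stem_length <- 0L; loop_length <- NA_integer_
  if (n_pairs > 0L) {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    run_start <- 1L; best_run <- c(1L, 1L); best_len <- 1L; len <- 1L
    if (n_pairs > 1L) {
      for (i in 2:n_pairs) {
        contiguous <- pairs[i, 1L] == pairs[i - 1L, 1L] + 1L &&
          pairs[i, 2L] == pairs[i - 1L, 2L] - 1L
        if (contiguous) len <- len + 1L else { run_start <- i; len <- 1L }
        if (len > best_len) { best_len <- len; best_run <- c(run_start, i) }
      }
    }
    stem_length <- best_len
    inner_pair <- pairs[best_run[2L], ]
    loop_length <- inner_pair[2L] - inner_pair[1L] - 1L
  }
  db <- rep(".", n)
  if (n_pairs > 0L) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  list(pairs = pairs, n_pairs = as.integer(n_pairs),
       stem_length = as.integer(stem_length),
       loop_length = as.integer(loop_length),
       dot_bracket = paste(db, collapse = ""))
}

#' Rank unassigned regions as control-region candidates
#'
#' Scores every unassigned region on the three control-region criteria:
#' (i) length, (ii) AT content relative to the other regions, and (iii) the
#' presence of a tandem repeat whose unit can fold into a hairpin with at
#' least `min_stem` contiguous stem pairs. The composite score is
#' `z(length) + z(AT%) + qualifying_repeat`, with ties broken by length.
#'
#' @param genome A `mito_genome` with features.
#' @param min_period,min_copies,min_identity Passed to [tandem_repeats()].
#' @param min_stem Minimum contiguous stem pairs for a qualifying hairpin,
#'   default 6.
#' @param min_length_bp Length below which a region is flagged as failing
#'   the length criterion, default 500.
#' @return Data frame (one row per unassigned region, ranked): `start`,
#'   `length`, `wraps_origin`, `flank_upstream`, `flank_downstream`,
#'   `at_pct`, `n_repeats`, `best_period`, `best_copies`, `best_identity`,
#'   `stem_length`, `qualifying_repeat`, `length_ok`, `score`, `rank`,
#'   `sequence`.
#' @export
control_region_candidates <- function(genome, min_period = 20L,
                                      min_copies = 2, min_identity = 0.85,
                                      min_stem = 6L, min_length_bp = 500L) {
  regs <- intergenic_regions(genome)
  if (!nrow(regs)) {
    message("no intergenic regions: no control-region candidates")
    return(data.frame())
  }
  rows <- lapply(seq_len(nrow(regs)), function(i) {
    s <- regs$sequence[i]
    at <- base_stats(s)$at_pct
    reps <- tandem_repeats(s, min_period = min_period,
                           min_copies = min_copies,
                           min_identity = min_identity)
    best <- if (nrow(reps)) reps[order(-reps$span), ][1L, ] else NULL
    stem <- 0L
    if (!is.null(best)) {
      stem <- max_hairpin(best$unit)$stem_length
    }
    data.frame(
      start = regs$start[i], length = regs$length[i],
      wraps_origin = regs$wraps_origin[i],
      flank_upstream = regs$flank_upstream[i],
      flank_downstream = regs$flank_downstream[i],
      at_pct = at, n_repeats = nrow(reps),
      best_period = if (is.null(best)) NA_integer_ else best$period,
      best_copies = if (is.null(best)) NA_real_ else best$copies,
      best_identity = if (is.null(best)) NA_real_ else best$identity,
      stem_length = stem,
      qualifying_repeat = !is.null(best) && stem >= min_stem,
      length_ok = regs$length[i] >= min_length_bp,
      sequence = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  z <- function(x) {
    if (length(x) < 2L || sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) / sd(x)
  }
  out$score <- z(out$length) + z(out$at_pct) +
    as.numeric(out$qualifying_repeat)
  out <- out[order(-out$score, -out$length), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
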