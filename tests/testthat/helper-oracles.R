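## Shared fixtures and independent brute-force oracles used across the
## suite. Oracles are written straight from the definitions and stay
## independent of the package's implementations.

.fixture_env <- new.env()

## the study-condition synthetic F/M pair, generated once per session
get_pair <- function() {
  if (is.null(.fixture_env$pair)) {
    .fixture_env$pair <- unionoid_pair(seed = 1)
  }
  .fixture_env$pair
}

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

feat <- function(label, start, end, kind = "other", strand = 1L,
                 wraps = FALSE) {
  data.frame(label = label, kind = kind, start = start, end = end,
             strand = strand, wraps_origin = wraps,
             incomplete_stop = FALSE, stringsAsFactors = FALSE)
}

toy_genome <- function(len, feats, seed = 1, id = "toy") {
  mito_genome(id, rand_dna(len, seed), feats)
}

## reverse-complement a whole genome, flipping feature strands/coordinates
revcomp_genome <- function(g) {
  n <- g$length
  f <- g$features
  sp <- feature_spans(g)
  stopifnot(!any(f$wraps_origin))
  new_start <- n - f$end
  f$start <- new_start
  f$end <- new_start + sp
  f$strand <- -f$strand
  mito_genome(g$id, revcomp(g$sequence), f, sex_type = g$sex_type)
}

## --- NG86 pathway oracle ----------------------------------------------------

## average syn/nonsyn differences between two codons over all substitution
## orderings, skipping orderings that pass through a stop codon
oracle_pair_diff <- function(c1, c2, code = "5") {
  gc <- genetic_code(code)
  p1 <- strsplit(c1, "")[[1L]]
  p2 <- strsplit(c2, "")[[1L]]
  dpos <- which(p1 != p2)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  perms <- if (length(dpos) == 1L) {
    list(dpos)
  } else if (length(dpos) == 2L) {
    list(dpos, rev(dpos))
  } else {
    list(dpos[c(1, 2, 3)], dpos[c(1, 3, 2)], dpos[c(2, 1, 3)],
         dpos[c(2, 3, 1)], dpos[c(3, 1, 2)], dpos[c(3, 2, 1)])
  }
  score_path <- function(ord, allow_stop) {
    cur <- p1; sd <- 0; nd <- 0
    for (pos in ord) {
      prev_aa <- gc[paste(cur, collapse = "")]
      cur[pos] <- p2[pos]
      aa <- gc[paste(cur, collapse = "")]
      if (!allow_stop && aa == "*") return(NULL)
      if (aa == prev_aa && aa != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null),
                  lapply(perms, score_path, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(perms, score_path, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

oracle_alignment_diffs <- function(a, b, code = "5") {
  ca <- duimito:::split_codons(a)
  cb <- duimito:::split_codons(b)
  tot <- c(sd = 0, nd = 0)
  for (i in seq_along(ca)) tot <- tot + oracle_pair_diff(ca[i], cb[i], code)
  tot
}

## --- hairpin oracle ---------------------------------------------------------

## top-down maximum-pairing recursion over (i pairs with k) splits,
## independent of the package's bottom-up DP and traceback
oracle_max_pairs <- function(seq, min_loop = 3L, allow_gu = TRUE) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  can_pair <- function(a, b) {
    ok <- (a == "A" & b == "T") || (a == "T" & b == "A") ||
      (a == "G" & b == "C") || (a == "C" & b == "G")
    if (allow_gu) {
      ok <- ok || (a == "G" & b == "T") || (a == "T" & b == "G")
    }
    ok
  }
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can_pair(ch[i], ch[k])) {
        inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        rest <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(ch))
}

## --- global-alignment oracle ------------------------------------------------

## exhaustive optimal global alignment score for short peptides under
## BLOSUM62 with affine gaps costing opening + length * extension
oracle_align_score <- local({
  B62 <- NULL
  function(a, b, gap_open = 10, gap_ext = 1) {
    if (is.null(B62)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      B62 <<- e$BLOSUM62
    }
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    ## enumerate move sequences (match / insert / delete) recursively,
    ## tracking the previous move for affine gap opening
    rec <- function(i, j, prev) {
      if (i > length(ca) && j > length(cb)) return(0)
      best <- -Inf
      if (i <= length(ca) && j <= length(cb)) {
        best <- max(best, B62[ca[i], cb[j]] + rec(i + 1L, j + 1L, "M"))
      }
      if (i <= length(ca)) {
        cost <- gap_ext + if (prev != "D") gap_open else 0
        best <- max(best, -cost + rec(i + 1L, j, "D"))
      }
      if (j <= length(cb)) {
        cost <- gap_ext + if (prev != "I") gap_open else 0
        best <- max(best, -cost + rec(i, j + 1L, "I"))
      }
      best
    }
    rec(1L, 1L, "M")
  }
})

## --- ORF oracle -------------------------------------------------------------

## every in-frame start is walked to its stop; per (strand, frame, stop)
## the 5'-most qualifying start wins
oracle_orfs <- function(region, min_aa,
                        starts = c("ATG", "ATA", "ATT", "ATC", "TTG",
                                   "GTG"),
                        code = "5") {
  gc <- genetic_code(code)
  stops <- names(gc)[gc == "*"]
  out <- list()
  n <- nchar(region)
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0L) toupper(region) else revcomp(region)
    ch <- strsplit(s, "")[[1L]]
    for (fr in 0:2) {
      pos <- seq(fr + 1L, n - 2L, by = 3L)
      if (fr + 3L > n) next
      codons <- paste0(ch[pos], ch[pos + 1L], ch[pos + 2L])
      claimed_stop <- character(0)
      for (si in seq_along(codons)) {
        if (!codons[si] %in% starts) next
        ei <- si
        while (ei <= length(codons) && !codons[ei] %in% stops) {
          ei <- ei + 1L
        }
        hit_stop <- ei <= length(codons)
        if (!hit_stop) ei <- length(codons)
        key <- paste(fr, ei)
        if (key %in% claimed_stop) next
        ## skip starts preceded in-frame by an earlier start of this ORF
        claimed_stop <- c(claimed_stop, key)
        aa_len <- if (hit_stop) ei - si else ei - si + 1L
        if (aa_len < min_aa) next
        s0 <- pos[si] - 1L
        e0 <- pos[ei] + 2L
        if (strand < 0L) { tmp <- s0; s0 <- n - e0; e0 <- n - tmp }
        out[[length(out) + 1L]] <- c(fr, strand, s0, e0, aa_len)
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 5L))
  m <- do.call(rbind, out)
  m[order(-m[, 5L], m[, 3L], m[, 2L]), , drop = FALSE]
}

## --- adjacency oracle -------------------------------------------------------

## conserved-adjacency count by direct scanning of consecutive signed pairs
## in both reading directions
oracle_breakpoints <- function(la, sa, lb, sb) {
  pairs_of <- function(l, s) {
    n <- length(l)
    res <- character(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      res <- c(res,
               paste(l[i], s[i], l[j], s[j]),
               paste(l[j], -s[j], l[i], -s[i]))
    }
    res
  }
  pa <- pairs_of(la, sa)
  pb <- pairs_of(lb, sb)
  length(la) - sum(vapply(seq_along(la), function(i) {
    pa[2L * i - 1L] %in% pb
  }, logical(1L)))
}

## --- TESTCODE oracle --------------------------------------------------------

## straight-from-the-tables application, independent of the package path
oracle_testcode <- function(seq) {
  posp <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  contp <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  wpos <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  wcont <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ch <- strsplit(toupper(seq), "")[[1L]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- numeric(3)
    for (i in seq_along(ch)) {
      if (ch[i] == b) {
        ph <- ((i - 1L) %% 3L) + 1L
        counts[ph] <- counts[ph] + 1
      }
    }
    pv <- max(counts) / (min(counts) + 1)
    cv <- sum(counts) / length(ch)
    pi <- 11 - findInterval(pv, c(-Inf, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6,
                                  1.7, 1.8, 1.9))
    ci <- 11 - findInterval(cv, c(-Inf, 0.17, 0.19, 0.21, 0.23, 0.25,
                                  0.27, 0.29, 0.31, 0.33))
    total <- total + wpos[[b]] * posp[[b]][pi] + wcont[[b]] * contp[[b]][ci]
  }
  total
}
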