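## Base composition, AT/GC strand skews, per-partition composition and
## codon usage (RSCU).

#' Base composition and strand skews of a sequence
#'
#' Computes AT%/GC% and the strand-asymmetry skews
#' `AT skew = (A - T) / (A + T)` and `GC skew = (G - C) / (G + C)` over the
#' unambiguous bases of `seq`. Ambiguity codes are excluded from both
#' numerators and denominators; `n_effective` counts the A/C/G/T bases used.
#'
#' @param seq Nucleotide string.
#' @return List with `at_pct`, `gc_pct` (percentages), `at_skew`, `gc_skew`
#'   (dimensionless, in `[-1, 1]`; `NA` for an empty A+T or G+C pool) and
#'   `n_effective`.
#' @export
base_stats <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- seq_chars(seq)
  cnt <- c(A = sum(ch == "A"), C = sum(ch == "C"),
           G = sum(ch == "G"), T = sum(ch == "T"))
  n <- sum(cnt)
  if (n == 0L) stop("no unambiguous bases: composition undefined")
  at <- cnt[["A"]] + cnt[["T"]]
  gc <- cnt[["G"]] + cnt[["C"]]
  list(
    at_pct = 100 * at / n,
    gc_pct = 100 * gc / n,
    at_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_,
    n_effective = as.integer(n)
  )
}

## the 13 "typical" mitochondrial PCGs (gender-specific ORFs excluded)
TYPICAL_PCGS <- c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4",
                  "nad4L", "nad5", "nad6", "cob", "atp6", "atp8")

## concatenated sense-strand CDS of the typical PCGs present in the genome
concat_pcg_cds <- function(genome, include_orf = FALSE) {
  f <- genome$features
  keep <- f$label %in% TYPICAL_PCGS
  if (include_orf) keep <- keep | f$kind == "ORF"
  labs <- f$label[keep]
  if (!length(labs)) return(character(0))
  vapply(labs, function(l) feature_sequence(genome, l), character(1L))
}

#' Per-partition composition table
#'
#' Computes [base_stats()] for the standard report partitions: the whole
#' genome (L strand as deposited), each rRNA (sense strand), the
#' concatenated protein-coding genes and their three codon positions (sense
#' strand, reading frame), the concatenated tRNAs (sense strand) and the
#' control region. Gender-specific ORFs are excluded from the PCG partition
#' by default (the 13-gene convention); set `include_orf = TRUE` to include
#' them.
#'
#' @param genome A `mito_genome`.
#' @param cr Optional control region: a single row of
#'   [intergenic_regions()] output (or any list with a `sequence` field).
#'   When `NULL`, a feature of kind `CR` is used if annotated, otherwise the
#'   top-ranked [control_region_candidates()] region, otherwise the
#'   partition is omitted.
#' @param include_orf Include FORF/MORF in the PCG partition (default
#'   `FALSE`).
#' @return Data frame keyed by `partition` with the [base_stats()] columns.
#' @export
partition_stats <- function(genome, cr = NULL, include_orf = FALSE) {
  rows <- list()
  add <- function(name, s) {
    if (is.null(s) || !nzchar(s)) return(invisible(NULL))
    st <- base_stats(s)
    rows[[length(rows) + 1L]] <<- data.frame(
      partition = name, at_pct = st$at_pct, gc_pct = st$gc_pct,
      at_skew = st$at_skew, gc_skew = st$gc_skew,
      n_effective = st$n_effective, stringsAsFactors = FALSE)
  }
  add("whole", genome$sequence)
  f <- genome$features
  for (r in c("rrnS", "rrnL")) {
    if (r %in% f$label) add(r, feature_sequence(genome, r))
  }
  cds <- concat_pcg_cds(genome, include_orf = include_orf)
  if (length(cds)) {
    cat_cds <- paste(cds, collapse = "")
    add("PCGs", cat_cds)
    ## codon positions taken per gene so reading frames are respected
    for (p in 1:3) {
      pos_seq <- paste(vapply(cds, function(s) {
        ch <- seq_chars(s)
        paste(ch[seq(p, 3L * (length(ch) %/% 3L), by = 3L)], collapse = "")
      }, character(1L)), collapse = "")
      add(paste0("codon-pos-", p), pos_seq)
    }
  }
  trn <- f$label[f$kind == "tRNA"]
  if (length(trn)) {
    add("tRNAs", paste(vapply(trn, function(l) feature_sequence(genome, l),
                              character(1L)), collapse = ""))
  }
  if (is.null(cr)) {
    if ("CR" %in% f$label) {
      cr <- list(sequence = feature_sequence(genome, "CR"))
    } else if (nrow(f)) {
      cand <- tryCatch(control_region_candidates(genome),
                       error = function(e) NULL)
      if (!is.null(cand) && nrow(cand)) {
        cr <- list(sequence = cand$sequence[1L])
      } else {
        message("no control region resolvable; CR partition omitted")
      }
    }
  }
  if (!is.null(cr)) add("CR", cr$sequence)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Codon usage table with RSCU
#'
#' Counts every in-frame codon of a collection of coding sequences (stop
#' codons included and flagged) and derives, per amino acid, the relative
#' synonymous codon usage (RSCU = observed count / mean count of the
#' synonymous family).
#'
#' @param cds_collection Character vector of in-frame coding sequences.
#' @param code Genetic-code id, default `"5"`.
#' @return List with `table` (data frame: `codon`, `aa`, `count`, `rscu`,
#'   `is_stop`), `total` (total codon count), `most_frequent` and
#'   `least_frequent` (least-used non-stop codon with count > 0 reported
#'   lexicographically on ties; zero-count codons ignored).
#' @export
codon_usage <- function(cds_collection, code = "5") {
  bad <- nchar(cds_collection) %% 3L != 0L
  if (any(bad)) {
    stop("frame error: sequence ", which(bad)[1L], " not a multiple of 3")
  }
  gc <- genetic_code(code)
  codons <- unlist(lapply(cds_collection, split_codons))
  counts <- table(factor(codons, levels = names(gc)))
  tab <- data.frame(codon = names(gc), aa = unname(gc),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  tab$is_stop <- tab$aa == "*"
  tab$rscu <- NA_real_
  for (a in unique(tab$aa[!tab$is_stop])) {
    i <- which(tab$aa == a)
    m <- mean(tab$count[i])
    tab$rscu[i] <- if (m > 0) tab$count[i] / m else NA_real_
  }
  nonstop <- tab[!tab$is_stop & tab$count > 0L, ]
  ord_most <- nonstop[order(-nonstop$count, nonstop$codon), ]
  ord_least <- nonstop[order(nonstop$count, nonstop$codon), ]
  list(table = tab, total = sum(tab$count),
       most_frequent = if (nrow(nonstop)) ord_most$codon[1L] else NA_character_,
       least_frequent = if (nrow(nonstop)) ord_least$codon[1L] else NA_character_)
}
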