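## Circular mitogenome data model: parsing, architecture statistics.
##
## Internal coordinate convention: 0-based, half-open, on the deposited light
## (L) strand. A feature spanning the origin keeps its numeric start in
## [0, length) and an end <= start together with wraps_origin = TRUE; it is
## never split into two intervals. GenBank 1-based closed coordinates are
## converted at the I/O boundary.

## canonical gene-name synonym table -----------------------------------------

.label_synonyms <- local({
  syn <- c(
    "COI" = "cox1", "CO1" = "cox1", "COXI" = "cox1", "COX1" = "cox1",
    "COII" = "cox2", "CO2" = "cox2", "COXII" = "cox2", "COX2" = "cox2",
    "COIII" = "cox3", "CO3" = "cox3", "COXIII" = "cox3", "COX3" = "cox3",
    "CYTB" = "cob", "CYB" = "cob", "COB" = "cob",
    "ND1" = "nad1", "ND2" = "nad2", "ND3" = "nad3", "ND4" = "nad4",
    "ND4L" = "nad4L", "ND5" = "nad5", "ND6" = "nad6",
    "NAD4L" = "nad4L",
    "ATP6" = "atp6", "ATPASE6" = "atp6", "ATP8" = "atp8", "ATPASE8" = "atp8",
    "12S" = "rrnS", "SRRNA" = "rrnS", "RRN12" = "rrnS", "12SRRNA" = "rrnS",
    "RRNS" = "rrnS",
    "16S" = "rrnL", "LRRNA" = "rrnL", "RRN16" = "rrnL", "16SRRNA" = "rrnL",
    "RRNL" = "rrnL",
    "FORF" = "FORF", "MORF" = "MORF", "F-ORF" = "FORF", "M-ORF" = "MORF",
    "CR" = "CR", "D-LOOP" = "CR", "DLOOP" = "CR", "CONTROL REGION" = "CR"
  )
  for (g in c("cox1", "cox2", "cox3", "cob", "atp6", "atp8",
              paste0("nad", 1:6), "nad4L", "rrnS", "rrnL")) {
    syn[toupper(g)] <- g
  }
  syn
})

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Canonicalize a gene label
#'
#' Maps common synonyms (COI, ND2, 12S, CYTB, tRNA-Ser(UCU), ...) onto the
#' canonical labels used throughout the package: `cox1..3`, `nad1..6`,
#' `nad4L`, `atp6`, `atp8`, `cob`, `rrnS`, `rrnL`, `trnX` (with `S1/S2` and
#' `L1/L2` disambiguation), `FORF`, `MORF`, `CR`.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of canonical labels (unknown labels are passed
#'   through unchanged, trimmed).
#' @export
canonical_label <- function(x) {
  vapply(x, function(lbl) {
    raw <- trimws(lbl)
    up <- toupper(raw)
    if (!is.na(.label_synonyms[up])) return(unname(.label_synonyms[up]))
    if (grepl("16S|LARGE SUBUNIT RIBOSOMAL", up) && grepl("R(IBOSOMAL )?RNA|RRN", up)) {
      return("rrnL")
    }
    if (grepl("12S|SMALL SUBUNIT RIBOSOMAL", up) && grepl("R(IBOSOMAL )?RNA|RRN", up)) {
      return("rrnS")
    }
    if (grepl("^TRN[A-Z][0-9]?$", up)) {
      return(paste0("trn", substr(raw, 4L, nchar(raw))))
    }
    m <- regmatches(up, regexec("^TRNA[-_ ]?([A-Z]{3})", up))[[1L]]
    if (length(m) == 2L && !is.na(.aa3to1[m[2L]])) {
      one <- unname(.aa3to1[m[2L]])
      ## disambiguate the two-copy serine/leucine tRNAs by anticodon
      anti <- regmatches(up, regexec("\\(([ACGTU]{3})\\)", up))[[1L]]
      if (one == "S" && length(anti) == 2L) {
        one <- if (gsub("U", "T", anti[2L]) == "TCT") "S1" else "S2"
      }
      if (one == "L" && length(anti) == 2L) {
        one <- if (gsub("U", "T", anti[2L]) == "TAG") "L1" else "L2"
      }
      return(paste0("trn", one))
    }
    raw
  }, character(1L), USE.NAMES = FALSE)
}

## constructor ----------------------------------------------------------------

empty_features <- function() {
  data.frame(
    label = character(0), kind = character(0), start = integer(0),
    end = integer(0), strand = integer(0), wraps_origin = logical(0),
    incomplete_stop = logical(0), stringsAsFactors = FALSE
  )
}

#' Construct a circular mitogenome object
#'
#' @param id Identifier (accession or label).
#' @param sequence Nucleotide string for the deposited light (L) strand.
#' @param features Data frame with columns `label`, `kind` (one of `PCG`,
#'   `ORF`, `rRNA`, `tRNA`, `CR`, `other`), `start`, `end` (0-based,
#'   half-open, L strand), `strand` (+1 = L, -1 = H) and optionally
#'   `wraps_origin`, `incomplete_stop`.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @param sex_type One of `"F"`, `"M"`, `"H"`, `"unknown"`.
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, features = empty_features(),
                        circular = TRUE,
                        sex_type = c("unknown", "F", "M", "H")) {
  sex_type <- match.arg(sex_type)
  sequence <- toupper(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(features$wraps_origin)) features$wraps_origin <- FALSE
  if (is.null(features$incomplete_stop)) features$incomplete_stop <- FALSE
  features$label <- canonical_label(features$label)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  g <- structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular), features = features,
         sex_type = sex_type),
    class = "mito_genome"
  )
  validate_mito_genome(g)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s, %d features, sex_type=%s\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              nrow(x$features), x$sex_type))
  if (nrow(x$features)) {
    tab <- table(x$features$kind)
    cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

validate_mito_genome <- function(g) {
  if (g$length != nchar(g$sequence)) stop("length/sequence mismatch")
  f <- g$features
  if (nrow(f)) {
    if (any(f$start < 0L | f$start >= g$length)) {
      stop("feature start outside [0, length)")
    }
    if (any(f$end < 0L | f$end > g$length)) stop("feature end outside range")
    sp <- feature_spans(g)
    if (any(sp <= 0L)) stop("feature with non-positive span")
    dup <- duplicated(f$label)
    if (any(dup)) {
      stop("duplicate canonical feature label: ",
           paste(unique(f$label[dup]), collapse = ", "))
    }
    coding <- f$kind %in% c("PCG", "ORF")
    bad <- coding & (sp %% 3L != 0L) & !f$incomplete_stop
    if (any(bad)) {
      stop("coding feature length not a multiple of 3: ",
           paste(f$label[bad], collapse = ", "))
    }
    g$features <- f[order(f$start, f$end), , drop = FALSE]
    rownames(g$features) <- NULL
  }
  g
}

#' Feature spans in bp (wrap-aware)
#'
#' @param genome A `mito_genome`.
#' @return Integer vector of feature lengths, in feature-table order.
#' @export
feature_spans <- function(genome) {
  f <- genome$features
  ifelse(f$wraps_origin | f$end <= f$start,
         genome$length - f$start + f$end,
         f$end - f$start)
}

#' Extract the strand-corrected sequence of a feature
#'
#' @param genome A `mito_genome`.
#' @param label Canonical feature label.
#' @return Sense-strand nucleotide string of the feature.
#' @export
feature_sequence <- function(genome, label) {
  f <- genome$features
  i <- match(label, f$label)
  if (is.na(i)) stop("no feature labelled '", label, "' in ", genome$id)
  s <- extract_arc(genome$sequence, f$start[i], f$end[i],
                   f$wraps_origin[i] || f$end[i] <= f$start[i])
  if (f$strand[i] < 0L) revcomp(s) else s
}

## [start, end) on the circle, optionally wrapping the origin
extract_arc <- function(sequence, start, end, wraps) {
  if (wraps) {
    paste0(substr(sequence, start + 1L, nchar(sequence)),
           substr(sequence, 1L, end))
  } else {
    substr(sequence, start + 1L, end)
  }
}

## I/O ------------------------------------------------------------------------

#' Load an annotated mitogenome
#'
#' Reads either a GenBank flat file (sequence + features) or a FASTA file
#' with an optional companion plain-text feature table (TSV with columns
#' `label`, `kind`, `start`, `end`, `strand`, `wraps_origin`, and optionally
#' `incomplete_stop`; coordinates 0-based half-open on the L strand).
#'
#' @param path Path to the record.
#' @param format `"genbank"` or `"fasta"`.
#' @param feature_table For `format = "fasta"`, optional path to the TSV
#'   feature table; omit for a featureless genome.
#' @param sex_type Passed to [mito_genome()].
#' @return A `mito_genome`.
#' @examples
#' toy <- system.file("extdata", "synthetic_toy_mitogenome.gb",
#'                    package = "duimito")
#' load_genome(toy, format = "genbank")
#' @export
load_genome <- function(path, format = c("genbank", "fasta"),
                        feature_table = NULL,
                        sex_type = c("unknown", "F", "M", "H")) {
  format <- match.arg(format)
  sex_type <- match.arg(sex_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") {
    parse_genbank(readLines(path, warn = FALSE), sex_type = sex_type)
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) < 1L) stop("no sequence in FASTA: ", path)
    feats <- if (!is.null(feature_table)) {
      read_feature_table(feature_table)
    } else {
      empty_features()
    }
    mito_genome(id = sub("\\s.*$", "", names(ss)[1L]),
                sequence = as.character(ss[[1L]]), features = feats,
                sex_type = sex_type)
  }
}

read_feature_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "kind", "start", "end", "strand")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$wraps_origin)) tab$wraps_origin <- FALSE
  if (is.null(tab$incomplete_stop)) tab$incomplete_stop <- FALSE
  tab
}

#' Write a genome's feature table (and optionally its sequence) to disk
#'
#' @param genome A `mito_genome`.
#' @param path Output TSV path for the feature table.
#' @param fasta Optional FASTA path for the sequence.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(genome, path, fasta = NULL) {
  write.table(genome$features, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(path)
}

## minimal GenBank flat-file parser (LOCUS/FEATURES/ORIGIN)
parse_genbank <- function(lines, sex_type = "unknown") {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  id <- toks[2L]
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))

  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("no ORIGIN section")
  seq_lines <- lines[(o[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(o[1L] - 1L)]
    key_idx <- grep("^ {5}\\S", block)
    for (k in seq_along(key_idx)) {
      i0 <- key_idx[k]
      i1 <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      chunk <- block[i0:i1]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1L])
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
      ## location may continue over lines until the first qualifier
      qual_at <- grep("^\\s+/", chunk)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(chunk)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", chunk[1L]),
                            if (loc_end >= 2L) chunk[2:loc_end])),
                   collapse = "")
      quals <- chunk[qual_at]
      getq <- function(name) {
        ln <- grep(paste0("/", name, "="), quals, value = TRUE)
        if (!length(ln)) return(NA_character_)
        gsub("\"", "", sub(paste0(".*/", name, "="), "", ln[1L]))
      }
      lab <- getq("gene")
      if (is.na(lab)) lab <- getq("product")
      if (is.na(lab) && key == "D-loop") lab <- "CR"
      if (is.na(lab)) next
      p <- parse_gb_location(loc, nchar(sequence))
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     `D-loop` = "CR", "other")
      canon <- canonical_label(lab)
      if (canon %in% c("FORF", "MORF")) kind <- "ORF"
      feats <- rbind(feats, data.frame(
        label = canon, kind = kind, start = p$start, end = p$end,
        strand = p$strand, wraps_origin = p$wraps,
        incomplete_stop = p$partial, stringsAsFactors = FALSE
      ))
    }
  }
  dup <- duplicated(feats$label)
  if (any(dup)) {
    stop("annotation error: duplicate canonical label ",
         paste(unique(feats$label[dup]), collapse = ", "))
  }
  mito_genome(id = id, sequence = sequence, features = feats,
              circular = circular, sex_type = sex_type)
}

parse_gb_location <- function(loc, genome_len) {
  strand <- 1L
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- -1L
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  partial <- grepl("[<>]", x)
  x <- gsub("[<>]", "", x)
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "..",
                                                         fixed = TRUE)[[1L]]))
    ## origin-spanning join: first segment ends at genome end,
    ## second starts at 1
    if (length(rng) == 2L && rng[[1L]][2L] == genome_len &&
        rng[[2L]][1L] == 1L) {
      return(list(start = rng[[1L]][1L] - 1L, end = rng[[2L]][2L],
                  strand = strand, wraps = TRUE, partial = partial))
    }
    stop("unsupported join() location: ", loc)
  }
  ab <- as.integer(strsplit(x, "..", fixed = TRUE)[[1L]])
  if (length(ab) != 2L || any(is.na(ab))) stop("unparseable location: ", loc)
  list(start = ab[1L] - 1L, end = ab[2L], strand = strand,
       wraps = FALSE, partial = partial)
}

## architecture statistics ----------------------------------------------------

## logical coverage vector over the circle
coverage_mask <- function(genome) {
  cov <- logical(genome$length)
  f <- genome$features
  sp <- feature_spans(genome)
  for (i in seq_len(nrow(f))) {
    idx <- (f$start[i] + seq_len(sp[i]) - 1L) %% genome$length
    cov[idx + 1L] <- TRUE
  }
  cov
}

#' Maximal unassigned (intergenic) regions of a circular genome
#'
#' Regions are maximal feature-free arcs; a region spanning the origin is
#' reported once with `wraps_origin = TRUE`. Flanking feature labels are the
#' nearest features on each side along the circle.
#'
#' @param genome A `mito_genome` with at least one feature.
#' @return Data frame with columns `start`, `end`, `wraps_origin`, `length`,
#'   `flank_upstream`, `flank_downstream`, `sequence`, ordered by `start`.
#' @export
intergenic_regions <- function(genome) {
  if (nrow(genome$features) == 0L) {
    stop("cannot define intergenic space on a featureless genome")
  }
  n <- genome$length
  cov <- coverage_mask(genome)
  if (all(cov)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      wraps_origin = logical(0), length = integer(0),
                      flank_upstream = character(0),
                      flank_downstream = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  ## rotate so position 0 is covered (guaranteed unless no coverage at all)
  anchor <- which(cov)[1L] - 1L
  rot <- cov[((anchor + seq_len(n) - 1L) %% n) + 1L]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  gaps <- which(!r$values)
  res <- lapply(gaps, function(gi) {
    s <- (starts[gi] - 1L + anchor) %% n
    e <- (ends[gi] + anchor) %% n          # half-open end, may wrap to 0
    len <- r$lengths[gi]
    wraps <- (s + len) > n
    data.frame(start = s, end = if (e == 0L) n else e,
               wraps_origin = wraps, length = len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$start), , drop = FALSE]
  ## flanks: nearest feature boundary on each side
  f <- genome$features
  sp <- feature_spans(genome)
  fends <- (f$start + sp) %% n
  out$flank_upstream <- vapply(seq_len(nrow(out)), function(i) {
    d <- (out$start[i] - fends) %% n
    f$label[which.min(d)]
  }, character(1L))
  out$flank_downstream <- vapply(seq_len(nrow(out)), function(i) {
    gap_end <- (out$start[i] + out$length[i]) %% n
    d <- (f$start - gap_end) %% n
    f$label[which.min(d)]
  }, character(1L))
  out$sequence <- vapply(seq_len(nrow(out)), function(i) {
    extract_arc(genome$sequence, out$start[i],
                (out$start[i] + out$length[i] - 1L) %% n + 1L,
                out$wraps_origin[i])
  }, character(1L))
  rownames(out) <- NULL
  out
}

#' Overlapping gene pairs
#'
#' One record per unordered pair of features sharing at least one base on
#' the circle. Abutting half-open intervals do not overlap.
#'
#' @param genome A `mito_genome`.
#' @return Data frame with columns `gene_a`, `gene_b`, `overlap_length`,
#'   sorted by position of the overlap.
#' @export
gene_overlaps <- function(genome) {
  f <- genome$features
  n <- genome$length
  sp <- feature_spans(genome)
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    overlap_length = integer(0), pos = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(f) < 2L) return(out[, 1:3])
  for (i in seq_len(nrow(f) - 1L)) {
    for (j in (i + 1L):nrow(f)) {
      ## unwrap both to [start, start+span) and compare with +/- n shifts
      a0 <- f$start[i]; a1 <- a0 + sp[i]
      b0 <- f$start[j]; b1 <- b0 + sp[j]
      best <- 0L; pos <- NA_integer_
      for (shift in c(-n, 0L, n)) {
        lo <- max(a0, b0 + shift); hi <- min(a1, b1 + shift)
        if (hi - lo > best) { best <- hi - lo; pos <- lo %% n }
      }
      if (best > 0L) {
        out <- rbind(out, data.frame(
          gene_a = f$label[i], gene_b = f$label[j],
          overlap_length = as.integer(best), pos = as.integer(pos),
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene_a", "gene_b", "overlap_length")]
}

#' Start/stop codon table for protein-coding features
#'
#' Codons are read from the strand-corrected CDS. `start_class` is
#' `conventional` for ATG/ATA/ATT, `alternative` for ATC/TTG/GTG, otherwise
#' `other`.
#'
#' @param genome A `mito_genome`.
#' @param code Genetic-code id (unused for codon identity, kept for report
#'   symmetry).
#' @return Data frame with columns `label`, `length`, `start_codon`,
#'   `stop_codon`, `start_class`.
#' @export
gene_table <- function(genome, code = "5") {
  f <- genome$features
  keep <- f$kind %in% c("PCG", "ORF")
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0L) stop("no protein-coding features in ", genome$id)
  sp <- feature_spans(genome)[keep]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    cds <- feature_sequence(genome, f$label[i])
    if (nchar(cds) %% 3L != 0L && !f$incomplete_stop[i]) {
      stop("frame error: CDS of ", f$label[i], " is not a multiple of 3")
    }
    sc <- substr(cds, 1L, 3L)
    st <- if (f$incomplete_stop[i]) {
      substr(cds, nchar(cds) - (nchar(cds) - 1L) %% 3L, nchar(cds))
    } else {
      substr(cds, nchar(cds) - 2L, nchar(cds))
    }
    cls <- if (sc %in% c("ATG", "ATA", "ATT")) "conventional"
           else if (sc %in% c("ATC", "TTG", "GTG")) "alternative"
           else "other"
    data.frame(label = f$label[i], length = sp[i], start_codon = sc,
               stop_codon = st, start_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a region for open reading frames on both strands
#'
#' An ORF runs from a qualifying start codon to the next in-frame stop codon
#' (included in the span) or the region end; per (strand, frame, stop) only
#' the longest ORF (5'-most start) is reported. Results are sorted by length
#' (descending).
#'
#' @param region Nucleotide string.
#' @param code Genetic-code id, default `"5"`.
#' @param min_aa Minimum peptide length (aa, stop excluded), default 30.
#' @param starts Allowed start codons.
#' @return Data frame with columns `frame` (0-2), `strand`, `start`, `end`
#'   (0-based half-open, forward-strand coordinates of the region),
#'   `aa_length`.
#' @export
find_orfs <- function(region, code = "5", min_aa = 30L,
                      starts = c("ATG", "ATA", "ATT", "ATC", "TTG", "GTG")) {
  if (!nzchar(region)) stop("empty region")
  n <- nchar(region)
  stops <- stop_codons(code)
  scan_strand <- function(s, strand) {
    res <- list()
    ch <- seq_chars(s)
    for (fr in 0:2) {
      idx <- seq(fr + 1L, n - 2L, by = 3L)
      if (fr + 3L > n) next
      codons <- paste0(ch[idx], ch[idx + 1L], ch[idx + 2L])
      is_stop <- codons %in% stops
      is_start <- codons %in% starts
      open_from <- NA_integer_
      for (k in seq_along(codons)) {
        if (is.na(open_from) && is_start[k]) open_from <- k
        if (!is.na(open_from) && (is_stop[k] || k == length(codons))) {
          n_cod <- k - open_from + 1L
          aa_len <- if (is_stop[k]) n_cod - 1L else n_cod
          if (aa_len >= min_aa) {
            s0 <- idx[open_from] - 1L
            e0 <- idx[k] + 2L
            if (strand < 0L) { tmp <- s0; s0 <- n - e0; e0 <- n - tmp }
            res[[length(res) + 1L]] <- data.frame(
              frame = fr, strand = strand, start = s0, end = e0,
              aa_length = aa_len, stringsAsFactors = FALSE)
          }
          open_from <- NA_integer_
        }
      }
    }
    res
  }
  res <- c(scan_strand(toupper(region), 1L),
           scan_strand(revcomp(region), -1L))
  if (!length(res)) {
    return(data.frame(frame = integer(0), strand = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$aa_length, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' cox2 extension of the male relative to the female genome
#'
#' @param f_genome,m_genome `mito_genome` objects annotating `cox2`.
#' @return List with `extension_bp` (length difference in bp) and
#'   `extension_pct` (fraction of the female gene length).
#' @export
cox2_extension <- function(f_genome, m_genome) {
  len_of <- function(g) {
    i <- match("cox2", g$features$label)
    if (is.na(i)) stop("cox2 not annotated in ", g$id)
    feature_spans(g)[i]
  }
  lf <- len_of(f_genome); lm <- len_of(m_genome)
  list(extension_bp = as.integer(lm - lf),
       extension_pct = (lm - lf) / lf)
}

#' Rotate a circular genome's origin
#'
#' Utility (used heavily in invariance tests): shifts the sequence origin by
#' `offset` bases; features are re-coordinated accordingly.
#'
#' @param genome A `mito_genome`.
#' @param offset Number of bases to rotate (new origin = old position
#'   `offset`).
#' @return A `mito_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  n <- genome$length
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, offset + 1L, n),
                 substr(genome$sequence, 1L, offset))
  f <- genome$features
  sp <- feature_spans(genome)
  f$start <- (f$start - offset) %% n
  ends <- (f$start + sp)
  f$wraps_origin <- ends > n
  f$end <- ends %% n
  f$end[f$end == 0L] <- n
  mito_genome(genome$id, seq2, f, circular = genome$circular,
              sex_type = genome$sex_type)
}
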