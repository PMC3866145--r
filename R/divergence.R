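## Pairwise F/M divergence: amino-acid-guided codon alignment, p-distances
## with site-bootstrap SEs, Nei-Gojobori (NG86) Ka/Ks with Jukes-Cantor
## correction, concatenation and codon-position masking.

#' Construct a codon alignment
#'
#' @param a,b Gap-aware nucleotide strings of equal length, a multiple of 3;
#'   gaps only in whole-codon triplets.
#' @param labels Pair of sequence identifiers.
#' @param code Genetic-code id.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(a, b, labels = c("A", "B"), code = "5") {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("rows differ in length")
  if (nchar(a) %% 3L != 0L) stop("alignment length not a multiple of 3")
  for (row in list(a, b)) {
    cod <- split_codons(row)
    partial <- grepl("-", cod) & cod != "---"
    if (any(partial)) stop("gap not aligned to codon boundaries")
  }
  structure(list(labels = labels, a = a, b = b, code = code),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s vs %s: %d columns (%d codons)\n",
              x$labels[1L], x$labels[2L], nchar(x$a), nchar(x$a) %/% 3L))
  invisible(x)
}

#' Global amino-acid alignment (Needleman-Wunsch)
#'
#' Optimal global pairwise alignment under BLOSUM62 with affine gap
#' penalties (opening 10, extension 1), the pairwise stand-in for a
#' multiple-alignment step when only two sequences are compared.
#'
#' @param pep_a,pep_b Amino-acid strings without internal stops.
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @return List with aligned rows `a`, `b` and the alignment `score`.
#' @export
align_aa_global <- function(pep_a, pep_b, substitution = "BLOSUM62",
                            gap_opening = 10, gap_extension = 1) {
  if (!nzchar(pep_a) || !nzchar(pep_b)) stop("empty peptide")
  if (grepl("\\*", pep_a) || grepl("\\*", pep_b)) {
    stop("internal stop in peptide")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep_a), Biostrings::AAString(pep_b),
    substitutionMatrix = substitution, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Impose an amino-acid alignment back onto codons (retro-alignment)
#'
#' Each aligned residue is replaced by its source codon and each residue gap
#' by a 3-base gap, producing a frame-preserving codon alignment.
#'
#' @param aa_alignment List with aligned rows `a` and `b` (as returned by
#'   [align_aa_global()]).
#' @param cds_a,cds_b In-frame nucleotide sequences whose translations
#'   (terminal stop dropped) equal the ungapped alignment rows.
#' @param labels Sequence identifiers.
#' @param code Genetic-code id.
#' @return A [codon_alignment()].
#' @export
retro_align <- function(aa_alignment, cds_a, cds_b, labels = c("A", "B"),
                        code = "5") {
  expand <- function(aa_row, cds, which) {
    codons <- split_codons(cds)
    gc <- genetic_code(code)
    if (gc[codons[length(codons)]] == "*") codons <- codons[-length(codons)]
    aa <- seq_chars(aa_row)
    res <- character(length(aa))
    k <- 0L
    tr <- unname(gc[codons]); tr[1L] <- "M"
    for (i in seq_along(aa)) {
      if (aa[i] == "-") {
        res[i] <- "---"
      } else {
        k <- k + 1L
        if (k > length(codons) || tr[k] != aa[i]) {
          stop("correspondence error in cds_", which,
               " at residue ", i, ": alignment '", aa[i], "' vs CDS '",
               if (k <= length(codons)) tr[k] else "<end>", "'")
        }
        res[i] <- codons[k]
      }
    }
    if (k != length(codons)) {
      stop("correspondence error in cds_", which,
           ": CDS longer than aligned residues")
    }
    paste(res, collapse = "")
  }
  codon_alignment(expand(aa_alignment$a, cds_a, "a"),
                  expand(aa_alignment$b, cds_b, "b"),
                  labels = labels, code = code)
}

## columns usable for distance computations
.valid_cols <- function(cha, chb, level) {
  ok <- if (level == "nt") {
    cha %in% DNA_ALPHABET & chb %in% DNA_ALPHABET
  } else {
    std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    cha %in% std & chb %in% std
  }
  ok
}

#' Pairwise p-distance
#'
#' Proportion of differing sites among comparable sites, after pairwise
#' deletion of columns containing gaps or ambiguity codes.
#'
#' @param a,b Aligned rows of equal length; alternatively `a` may be a
#'   [codon_alignment()] (then `b` is ignored).
#' @param level `"nt"` or `"aa"`.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b = NULL, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (inherits(a, "codon_alignment")) { b <- a$b; a <- a$a }
  cha <- seq_chars(a); chb <- seq_chars(b)
  if (length(cha) != length(chb)) stop("rows differ in length")
  ok <- .valid_cols(cha, chb, level)
  if (!any(ok)) stop("no comparable sites: p-distance undefined")
  mean(cha[ok] != chb[ok])
}

#' Site-resampling bootstrap standard error of an alignment statistic
#'
#' Columns are resampled with replacement; the statistic is recomputed on
#' each replicate and its standard deviation reported.
#'
#' @param a,b Aligned rows (or `a` a [codon_alignment()]).
#' @param level `"nt"` or `"aa"`.
#' @param statistic Function of two aligned rows and `level`
#'   (default [p_distance()]).
#' @param replicates Number of bootstrap replicates (>= 100), default 1000.
#' @param seed RNG seed, default 42.
#' @return Standard error (numeric scalar).
#' @export
bootstrap_se <- function(a, b = NULL, level = c("nt", "aa"),
                         statistic = p_distance, replicates = 1000L,
                         seed = 42L) {
  level <- match.arg(level)
  if (inherits(a, "codon_alignment")) { b <- a$b; a <- a$a }
  if (replicates < 100L) stop("use at least 100 replicates")
  cha <- seq_chars(a); chb <- seq_chars(b)
  if (!any(.valid_cols(cha, chb, level))) {
    stop("degenerate alignment: no comparable sites")
  }
  n <- length(cha)
  vals <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(paste(cha[idx], collapse = ""),
                         paste(chb[idx], collapse = ""), level = level),
               error = function(e) NA_real_)
    }, numeric(1L))
  })
  sd(vals, na.rm = TRUE)
}

## NG86 machinery -------------------------------------------------------------

.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function(code = "5") {
  key <- paste0("tab", code)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  gc <- genetic_code(code)
  codons <- names(gc)
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (gc[cod] == "*") { syn_sites[cod] <- NA_real_; next }
    ch <- strsplit(cod, "")[[1L]]
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(DNA_ALPHABET, ch[pos])) {
        mut <- ch; mut[pos] <- alt
        mutc <- paste(mut, collapse = "")
        ## changes into stop codons count as nonsynonymous
        if (gc[mutc] != "*" && gc[mutc] == gc[cod]) s <- s + 1 / 3
      }
    }
    syn_sites[cod] <- s
  }
  out <- list(gc = gc, syn_sites = syn_sites)
  .ng_cache[[key]] <- out
  out
}

## average synonymous/nonsynonymous differences between two codons over all
## minimal-substitution pathways; pathways through stops excluded (falling
## back to all pathways when every one is blocked)
ng_pair_diff <- function(c1, c2, code = "5") {
  key <- paste0("d", code, c1, c2)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  gc <- ng_tables(code)$gc
  p1 <- strsplit(c1, "")[[1L]]; p2 <- strsplit(c2, "")[[1L]]
  diffpos <- which(p1 != p2)
  nd <- length(diffpos)
  if (nd == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- if (nd == 1L) list(diffpos) else {
      prm <- list()
      gen <- function(rest, acc) {
        if (!length(rest)) { prm[[length(prm) + 1L]] <<- acc; return() }
        for (i in seq_along(rest)) gen(rest[-i], c(acc, rest[i]))
      }
      gen(diffpos, integer(0))
      prm
    }
    walk <- function(ord) {
      cur <- p1; sd <- 0; ndn <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- p2[pos]
        a1 <- gc[paste(cur, collapse = "")]
        a2 <- gc[paste(nxt, collapse = "")]
        if (a2 == "*" || a1 == "*") return(NULL)
        if (a1 == a2) sd <- sd + 1 else ndn <- ndn + 1
        cur <- nxt
      }
      c(sd = sd, nd = ndn)
    }
    paths <- Filter(Negate(is.null), lapply(perms, walk))
    if (!length(paths)) {
      ## every pathway passes a stop: fall back to counting through them
      walk_all <- function(ord) {
        cur <- p1; sd <- 0; ndn <- 0
        for (pos in ord) {
          nxt <- cur; nxt[pos] <- p2[pos]
          a1 <- gc[paste(cur, collapse = "")]
          a2 <- gc[paste(nxt, collapse = "")]
          if (!is.na(a1) && !is.na(a2) && a1 == a2 && a1 != "*") {
            sd <- sd + 1
          } else {
            ndn <- ndn + 1
          }
          cur <- nxt
        }
        c(sd = sd, nd = ndn)
      }
      paths <- lapply(perms, walk_all)
    }
    m <- do.call(rbind, paths)
    res <- c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
  }
  .ng_cache[[key]] <- res
  res
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; errors at saturation (`p >= 3/4`).
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance.
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75)) stop("saturation: Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (NG86) Ka/Ks for a codon alignment
#'
#' Classic equal-pathway-weight NG86: synonymous site fractions per codon
#' averaged over the two sequences; pairwise codon differences averaged over
#' all minimal substitution pathways (pathways through stop codons
#' excluded); `ps = Sd/S`, `pn = Nd/N`; Jukes-Cantor correction applied to
#' each. Codons containing gaps or ambiguity codes are masked whole.
#'
#' @param alignment A [codon_alignment()].
#' @param code Genetic-code id (default taken from the alignment).
#' @return List with `Ka`, `Ks`, `omega` (`NA` when `Ks` is 0), `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `codons_used`.
#' @export
nei_gojobori <- function(alignment, code = NULL) {
  cnt <- ng_counts(alignment, code)
  ps <- if (cnt$S > 0) cnt$Sd / cnt$S else 0
  pn <- if (cnt$N > 0) cnt$Nd / cnt$N else 0
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  list(Ka = Ka, Ks = Ks,
       omega = if (Ks > 0) Ka / Ks else NA_real_,
       S_sites = cnt$S, N_sites = cnt$N, Sd = cnt$Sd, Nd = cnt$Nd,
       codons_used = cnt$codons_used)
}

## NG86 site and difference counting (no distance correction): masked
## codons removed whole, synonymous site fractions averaged over the two
## sequences, differences pathway-averaged
ng_counts <- function(alignment, code = NULL) {
  stopifnot(inherits(alignment, "codon_alignment"))
  code <- code %||% alignment$code
  tabs <- ng_tables(code)
  ca <- split_codons(alignment$a)
  cb <- split_codons(alignment$b)
  clean <- function(x) {
    ok <- grepl("^[ACGT]{3}$", x)
    ok[ok] <- tabs$gc[x[ok]] != "*"
    ok
  }
  ok <- clean(ca) & clean(cb)
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons after masking")
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  sd_tot <- 0; nd_tot <- 0
  for (i in which(ca != cb)) {
    d <- ng_pair_diff(ca[i], cb[i], code)
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  list(S = S, N = N, Sd = sd_tot, Nd = nd_tot, codons_used = length(ca))
}

#' Concatenate codon alignments and mask codon positions
#'
#' Genes are concatenated in the order given; the stated codon positions are
#' then removed from every codon. A partition map records each gene's column
#' range (1-based, inclusive) in the final matrix.
#'
#' @param alignments Named list of [codon_alignment()] objects over the same
#'   label pair.
#' @param drop_positions Subset of `c(1, 2, 3)` to remove (default none).
#' @return List with `a`, `b` (concatenated, masked rows), `labels` and
#'   `partition` (data frame `gene`, `from`, `to`; zero-width ranges occur
#'   only if a gene loses all columns).
#' @export
concat_and_mask <- function(alignments, drop_positions = integer(0)) {
  stopifnot(length(alignments) >= 1L)
  labs <- alignments[[1L]]$labels
  for (al in alignments) {
    if (!identical(al$labels, labs)) {
      stop("label mismatch between alignments: ",
           paste(al$labels, collapse = "/"), " vs ",
           paste(labs, collapse = "/"))
    }
  }
  keep_cols <- function(len) {
    pos <- ((seq_len(len) - 1L) %% 3L) + 1L
    !(pos %in% drop_positions)
  }
  pieces_a <- character(0); pieces_b <- character(0)
  part <- data.frame(gene = character(0), from = integer(0), to = integer(0),
                     stringsAsFactors = FALSE)
  at <- 0L
  nm <- names(alignments) %||% as.character(seq_along(alignments))
  for (i in seq_along(alignments)) {
    al <- alignments[[i]]
    kc <- keep_cols(nchar(al$a))
    a <- paste(seq_chars(al$a)[kc], collapse = "")
    b <- paste(seq_chars(al$b)[kc], collapse = "")
    pieces_a <- c(pieces_a, a); pieces_b <- c(pieces_b, b)
    part <- rbind(part, data.frame(gene = nm[i], from = at + 1L,
                                   to = at + nchar(a),
                                   stringsAsFactors = FALSE))
    at <- at + nchar(a)
  }
  list(a = paste(pieces_a, collapse = ""), b = paste(pieces_b, collapse = ""),
       labels = labs, partition = part)
}

#' Per-gene F/M divergence table
#'
#' For every shared protein-coding gene: strand-corrected CDS extraction,
#' terminal-stop stripping, global amino-acid alignment, retro-alignment to
#' codons, nucleotide and amino-acid p-distances with site-bootstrap SEs,
#' and NG86 Ka/Ks. rRNA genes get a direct nucleotide alignment and
#' nucleotide p-distance only. A final `all_PCGs` row is computed on the
#' concatenation of the shared typical protein-coding genes (gender-specific
#' ORFs excluded).
#'
#' @param f_genome,m_genome `mito_genome` objects.
#' @param genes Genes to compare; default the shared typical PCGs and rRNAs.
#' @param code Genetic-code id.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed (default 42).
#' @return List with `table` (data frame) and `alignments` (named list of
#'   codon alignments for the protein-coding genes).
#' @export
divergence_table <- function(f_genome, m_genome, genes = NULL, code = "5",
                             replicates = 1000L, seed = 42L) {
  shared <- intersect(f_genome$features$label, m_genome$features$label)
  if (is.null(genes)) {
    genes <- c(intersect(c("rrnS", "rrnL"), shared),
               intersect(TYPICAL_PCGS, shared))
  }
  rows <- list(); alns <- list()
  for (g in genes) {
    kind <- f_genome$features$kind[match(g, f_genome$features$label)]
    sf <- feature_sequence(f_genome, g)
    sm <- feature_sequence(m_genome, g)
    if (kind == "rRNA") {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(sf), Biostrings::DNAString(sm),
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 5, gapExtension = 2, type = "global")
      a <- as.character(Biostrings::alignedPattern(al))
      b <- as.character(Biostrings::alignedSubject(al))
      rows[[g]] <- data.frame(
        gene = g, pd_nt = p_distance(a, b, "nt"),
        pd_nt_se = bootstrap_se(a, b, "nt", replicates = replicates,
                                seed = derive_seed(seed, match(g, genes))),
        pd_aa = NA_real_, pd_aa_se = NA_real_, Ka = NA_real_, Ks = NA_real_,
        omega = NA_real_, sites_used = sum(.valid_cols(seq_chars(a),
                                                       seq_chars(b), "nt")),
        stringsAsFactors = FALSE)
    } else {
      pf <- translate_cds(sf, code); pm <- translate_cds(sm, code)
      aa <- align_aa_global(pf, pm)
      ca <- retro_align(aa, sf, sm, labels = c(f_genome$id, m_genome$id),
                        code = code)
      ## saturated genes (Jukes-Cantor undefined) are reported as NA
      ng <- tryCatch(nei_gojobori(ca), error = function(e) {
        list(Ka = NA_real_, Ks = NA_real_, omega = NA_real_,
             codons_used = nchar(ca$a) %/% 3L)
      })
      sub <- derive_seed(seed, match(g, genes))
      rows[[g]] <- data.frame(
        gene = g, pd_nt = p_distance(ca, level = "nt"),
        pd_nt_se = bootstrap_se(ca, level = "nt", replicates = replicates,
                                seed = sub),
        pd_aa = p_distance(aa$a, aa$b, "aa"),
        pd_aa_se = bootstrap_se(aa$a, aa$b, "aa", replicates = replicates,
                                seed = sub + 1L),
        Ka = ng$Ka, Ks = ng$Ks, omega = ng$omega,
        sites_used = 3L * ng$codons_used, stringsAsFactors = FALSE)
      alns[[g]] <- ca
    }
  }
  if (length(alns) >= 2L) {
    cc <- concat_and_mask(alns)
    cal <- codon_alignment(cc$a, cc$b, labels = cc$labels, code = code)
    ng <- tryCatch(nei_gojobori(cal), error = function(e) {
      list(Ka = NA_real_, Ks = NA_real_, omega = NA_real_,
           codons_used = nchar(cal$a) %/% 3L)
    })
    pep <- lapply(names(alns),
                  function(g) align_aa_global(
                    translate_cds(feature_sequence(f_genome, g), code),
                    translate_cds(feature_sequence(m_genome, g), code)))
    aa_a <- paste(vapply(pep, `[[`, character(1L), "a"), collapse = "")
    aa_b <- paste(vapply(pep, `[[`, character(1L), "b"), collapse = "")
    rows[["all_PCGs"]] <- data.frame(
      gene = "all_PCGs", pd_nt = p_distance(cal, level = "nt"),
      pd_nt_se = bootstrap_se(cal, level = "nt", replicates = replicates,
                              seed = derive_seed(seed, 101L)),
      pd_aa = p_distance(aa_a, aa_b, "aa"),
      pd_aa_se = bootstrap_se(aa_a, aa_b, "aa", replicates = replicates,
                              seed = derive_seed(seed, 102L)),
      Ka = ng$Ka, Ks = ng$Ks, omega = ng$omega,
      sites_used = 3L * ng$codons_used, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, alignments = alns)
}
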