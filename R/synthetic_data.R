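## Deterministic synthetic-mitogenome generator: a download-free test
## surface emulating unionoid F/M mitogenome pairs (circular architecture,
## per-partition composition and skews, a control region carrying a
## hairpin-capable tandem repeat, and F/M coding sequences diverged under a
## controllable nonsynonymous/synonymous acceptance ratio).

## strand-specific base probabilities solved from (AT%, AT skew, GC skew)
base_probs <- function(at_pct, at_skew, gc_skew) {
  at <- at_pct / 100
  gc <- 1 - at
  p <- c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
         G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
  if (any(p < 0)) stop("infeasible composition target")
  p[DNA_ALPHABET]
}

## per-partition composition targets; defaults are unionoid-like F/M values
comp_targets <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  if (sex == "F") {
    list(
      background = c(60.9, 0.22, -0.39),
      rrnS = c(60.2, 0.22, -0.14), rrnL = c(61.6, 0.19, -0.18),
      pos1 = c(55.9, -0.10, 0.29), pos2 = c(59.9, -0.46, -0.03),
      pos3 = c(64.0, -0.20, 0.23),
      tRNA = c(62.8, 0.08, -0.03), cr = c(63.7, -0.05, -0.50)
    )
  } else {
    list(
      background = c(61.0, 0.27, -0.38),
      rrnS = c(60.9, 0.26, -0.18), rrnL = c(60.7, 0.27, -0.19),
      pos1 = c(56.9, -0.06, 0.29), pos2 = c(60.5, -0.41, 0.03),
      pos3 = c(64.1, -0.28, 0.27),
      tRNA = c(61.1, 0.13, -0.07), cr = c(66.5, 0.00, -0.43)
    )
  }
}

sample_bases <- function(n, probs) {
  if (n <= 0L) return(character(0))
  sample(DNA_ALPHABET, n, replace = TRUE, prob = probs)
}

## sample n sense codons with per-position base probabilities, stop-free
sample_codons <- function(n, p1, p2, p3, code = "5") {
  if (n <= 0L) return(character(0))
  c1 <- sample_bases(n, p1); c2 <- sample_bases(n, p2)
  c3 <- sample_bases(n, p3)
  cod <- paste0(c1, c2, c3)
  stops <- stop_codons(code)
  bad <- which(cod %in% stops)
  for (i in bad) {
    ## resample the third position among bases that break the stop
    ok <- DNA_ALPHABET[!paste0(c1[i], c2[i], DNA_ALPHABET) %in% stops]
    w <- p3[match(ok, DNA_ALPHABET)]
    c3[i] <- sample(ok, 1L, prob = w)
    cod[i] <- paste0(c1[i], c2[i], c3[i])
  }
  cod
}

## expected Metropolis-Hastings acceptance of the biased replacement chain
## at stationarity (used to keep realized substitution rates on target)
mh_acceptance <- function(probs) {
  acc <- 0
  for (i in 1:4) {
    for (j in setdiff(1:4, i)) {
      acc <- acc + probs[i] * (probs[j] / (1 - probs[i])) *
        min(1, (1 - probs[i]) / (1 - probs[j]))
    }
  }
  acc
}

## per-site substitution; replacements drawn uniformly or from a target
## base distribution (mutation bias) excluding the current base
mutate_seq <- function(s, rate, probs = NULL) {
  ch <- seq_chars(s)
  if (!is.null(probs)) rate <- min(1, rate / mh_acceptance(probs))
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    others <- setdiff(DNA_ALPHABET, ch[i])
    if (is.null(probs)) {
      ch[i] <- sample(others, 1L)
    } else {
      new <- sample(others, 1L, prob = probs[match(others, DNA_ALPHABET)])
      q_cur <- probs[match(ch[i], DNA_ALPHABET)]
      q_new <- probs[match(new, DNA_ALPHABET)]
      ## Hastings factor keeps the target distribution stationary
      if (runif(1L) <= min(1, (1 - q_cur) / (1 - q_new))) ch[i] <- new
    }
  }
  paste(ch, collapse = "")
}

## roster tables --------------------------------------------------------------

.roster_row <- function(label, kind, length, strand, start_codon = NA,
                        stop_codon = NA, gap = NA_real_) {
  data.frame(label = label, kind = kind, length = as.integer(length),
             strand = as.integer(strand), start_codon = start_codon,
             stop_codon = stop_codon, gap_after = gap,
             stringsAsFactors = FALSE)
}

## gap_after: NA = flexible (budget-filled), >= 0 fixed gap, < 0 overlap
## with the next feature; the control region is the gap after `cr_after`.
unionoid_roster <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  r <- .roster_row
  if (sex == "F") {
    rows <- rbind(
      r("cox1",  "PCG", 1545, +1, "TTG", "TAG"),
      r("trnV",  "tRNA",  66, +1),
      r("cox2",  "PCG",  681, +1, "ATG", "TAA"),
      r("trnI",  "tRNA",  66, +1, gap = 0),
      r("nad2",  "PCG",  963, +1, "ATG", "TAA"),
      r("trnM",  "tRNA",  66, +1, gap = 0),
      r("nad3",  "PCG",  357, +1, "ATG", "TAG"),
      r("trnS1", "tRNA",  66, +1),
      r("rrnS",  "rRNA", 857, +1, gap = 0),
      r("trnK",  "tRNA",  66, +1),
      r("trnT",  "tRNA",  66, +1, gap = 0),
      r("trnY",  "tRNA",  66, +1),
      r("rrnL",  "rRNA", 1296, +1),
      r("trnL1", "tRNA",  61, +1, gap = 0),
      r("trnL2", "tRNA",  66, +1),
      r("cob",   "PCG", 1161, -1, "ATC", "TAG", gap = -1),
      r("trnP",  "tRNA",  66, +1),
      r("trnS2", "tRNA",  66, +1),
      r("nad5",  "PCG", 1734, -1, "ATG", "TAA"),   # followed by the CR
      r("trnQ",  "tRNA",  66, +1),
      r("trnC",  "tRNA",  66, +1, gap = 0),
      r("trnA",  "tRNA",  74, +1),
      r("nad1",  "PCG",  897, -1, "ATC", "TAA"),
      r("trnF",  "tRNA",  66, +1, gap = 0),
      r("trnN",  "tRNA",  66, +1),
      r("trnH",  "tRNA",  66, -1),
      r("nad6",  "PCG",  489, -1, "ATC", "TAA"),
      r("nad4",  "PCG", 1350, -1, "ATT", "TAG", gap = -8),
      r("nad4L", "PCG",  297, -1, "ATG", "TAG"),
      r("atp8",  "PCG",  198, +1, "GTG", "TAG", gap = 0),
      r("trnD",  "tRNA",  66, +1),
      r("trnE",  "tRNA",  66, +1),
      r("FORF",  "ORF",  261, +1, "ATA", "TAA"),
      r("trnW",  "tRNA",  66, +1, gap = 0),
      r("trnG",  "tRNA",  61, +1),
      r("trnR",  "tRNA",  66, +1),
      r("atp6",  "PCG",  708, -1, "ATG", "TAG"),
      r("cox3",  "PCG",  780, -1, "ATG", "TAA")
    )
    list(roster = rows, total = 16716L, cr_after = "nad5",
         cr_length = 1049L)
  } else {
    rows <- rbind(
      r("cox1",  "PCG", 1602, +1, "TTG", "TAG"),
      r("trnV",  "tRNA",  66, +1),
      r("cox2",  "PCG", 1224, +1, "ATG", "TAA"),
      r("trnI",  "tRNA",  66, +1, gap = 0),
      r("nad3",  "PCG",  360, +1, "ATG", "TAG"),
      r("trnM",  "tRNA",  66, +1, gap = -2),
      r("nad2",  "PCG",  996, +1, "TTG", "TAA"),
      r("trnS1", "tRNA",  66, +1, gap = 0),
      r("rrnS",  "rRNA", 857, +1),
      r("trnK",  "tRNA",  66, +1, gap = 0),
      r("trnT",  "tRNA",  66, +1),
      r("trnY",  "tRNA",  62, +1, gap = 0),
      r("rrnL",  "rRNA", 1313, +1),
      r("trnL1", "tRNA",  66, +1, gap = 0),
      r("trnL2", "tRNA",  66, +1),
      r("cob",   "PCG", 1149, -1, "ATG", "TAG"),
      r("trnS2", "tRNA",  66, +1),
      r("nad5",  "PCG", 1764, -1, "GTG", "TAG"),
      r("trnH",  "tRNA",  71, -1),                  # followed by the CR
      r("trnQ",  "tRNA",  66, +1, gap = -1),
      r("trnC",  "tRNA",  66, +1),
      r("trnA",  "tRNA",  66, +1, gap = 0),
      r("nad1",  "PCG",  909, -1, "ATA", "TAA"),
      r("trnF",  "tRNA",  66, +1),
      r("trnN",  "tRNA",  66, +1, gap = -1),
      r("trnP",  "tRNA",  66, +1),
      r("nad6",  "PCG",  681, +1, "ATC", "TAG", gap = -168),
      r("nad4",  "PCG", 1374, -1, "TTG", "TAG", gap = -7),
      r("nad4L", "PCG",  300, -1, "ATT", "TAG"),
      r("MORF",  "ORF",  435, -1, "ATA", "TAA"),
      r("trnD",  "tRNA",  66, -1),
      r("atp8",  "PCG",  177, -1, "ATG", "TAG"),
      r("trnE",  "tRNA",  66, +1, gap = 0),
      r("trnW",  "tRNA",  66, +1),
      r("trnG",  "tRNA",  66, +1, gap = 0),
      r("trnR",  "tRNA",  66, +1, gap = 0),
      r("atp6",  "PCG",  684, -1, "ATG", "TAG"),
      r("cox3",  "PCG",  774, -1, "ATT", "TAG", gap = -8)
    )
    list(roster = rows, total = 17102L, cr_after = "trnH",
         cr_length = 848L)
  }
}

#' Build a unionoid-like genome specification
#'
#' Assembles the architecture specification of a synthetic F-type or M-type
#' unionoid mitogenome: the gene roster (labels, kinds, lengths, strands,
#' start/stop codons), the typical unionoid PCG+rRNA order (with the
#' nad2/nad3 relative inversion and cox2--rrnS rearrangement distinguishing
#' the F order), intergenic budget, a control region carrying a
#' hairpin-capable tandem-repeat array, and per-partition composition
#' targets.
#'
#' @param sex `"F"` or `"M"`.
#' @param seed RNG seed of the generated genome.
#' @param fixed Optional named list fixing sense sequences: for PCG/ORF
#'   features a string of body codons (start/stop excluded); for tRNA/rRNA
#'   features the full sense sequence.
#' @return A `genome_spec` list understood by [simulate_genome()].
#' @export
unionoid_genome_spec <- function(sex = c("F", "M"), seed = 1L,
                                 fixed = list()) {
  sex <- match.arg(sex)
  arch <- unionoid_roster(sex)
  roster <- arch$roster
  ## control region occupies the gap after `cr_after`
  icr <- match(arch$cr_after, roster$label)
  roster$gap_after[icr] <- arch$cr_length
  ## distribute the remaining intergenic budget over the flexible gaps
  flex <- which(is.na(roster$gap_after))
  budget <- arch$total - sum(roster$length) -
    sum(roster$gap_after, na.rm = TRUE)
  if (budget < 3L * length(flex)) stop("infeasible intergenic budget")
  base <- budget %/% length(flex)
  extra <- budget - base * length(flex)
  g <- rep(base, length(flex))
  if (extra > 0L) g[seq_len(extra)] <- g[seq_len(extra)] + 1L
  roster$gap_after[flex] <- g
  cr <- if (sex == "F") {
    list(period = 101L, copies = 8L, identity = 0.98, arm = 22L, loop = 7L)
  } else {
    list(period = 102L, copies = 7L, identity = 0.98, arm = 22L, loop = 7L)
  }
  structure(
    list(id = paste0("syn_", sex), sex_type = sex, total = arch$total,
         roster = roster, cr = cr, comp = comp_targets(sex),
         seed = as.integer(seed), fixed = fixed),
    class = "genome_spec")
}

validate_genome_spec <- function(spec) {
  roster <- spec$roster
  if (anyDuplicated(roster$label)) stop("duplicate roster labels")
  if (sum(roster$length) + sum(roster$gap_after) != spec$total) {
    stop("roster lengths + intergenic budget do not equal the genome ",
         "length (", sum(roster$length) + sum(roster$gap_after), " vs ",
         spec$total, ")")
  }
  coding <- roster$kind %in% c("PCG", "ORF")
  if (any(roster$length[coding] %% 3L != 0L)) {
    stop("coding roster length not a multiple of 3")
  }
  invisible(spec)
}

## shuffled sequence with base counts matching the probabilities exactly
## (largest-remainder rounding); keeps a tandem array's composition on
## target even though one unit is replicated many times
exact_comp_sample <- function(n, probs) {
  if (n <= 0L) return("")
  raw <- probs * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0L) {
    up <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[up] <- cnt[up] + 1L
  }
  paste(sample(rep(DNA_ALPHABET, times = cnt)), collapse = "")
}

## build the control-region sequence: AT-rich background around a tandem
## array whose unit carries an inverted repeat (hairpin-capable)
build_cr_seq <- function(len, cr, probs) {
  arm <- exact_comp_sample(cr$arm, probs)
  loop <- exact_comp_sample(cr$loop, probs)
  filler_n <- cr$period - 2L * cr$arm - cr$loop
  if (filler_n < 0L) stop("repeat unit shorter than hairpin arms")
  filler <- exact_comp_sample(filler_n, probs)
  unit <- paste0(arm, loop, revcomp(arm), filler)
  copies <- vapply(seq_len(cr$copies), function(i) {
    if (i == 1L) unit else mutate_seq(unit, 1 - cr$identity)
  }, character(1L))
  array <- paste(copies, collapse = "")
  pad <- len - nchar(array)
  if (pad < 0L) stop("control region shorter than its repeat array")
  pre <- pad %/% 2L
  paste0(exact_comp_sample(pre, probs), array,
         exact_comp_sample(pad - pre, probs))
}

## write a sense-strand string into the genomic character vector
write_arc <- function(chars, start, sense, strand, n) {
  s <- if (strand < 0L) revcomp(sense) else sense
  idx <- (start + seq_len(nchar(s)) - 1L) %% n + 1L
  chars[idx] <- seq_chars(s)
  chars
}

## genomic (0-based) positions of sense codon t (0-based) of a laid-out gene
codon_positions <- function(start, len, strand, t, n) {
  off <- if (strand > 0L) 3L * t + 0:2 else len - 3L * t - (3:1)
  (start + off) %% n
}

read_sense_codon <- function(chars, start, len, strand, t, n) {
  p <- codon_positions(start, len, strand, t, n)
  s <- paste(chars[p + 1L], collapse = "")
  if (strand < 0L) revcomp(s) else s
}

#' Simulate an annotated circular mitogenome from a specification
#'
#' Realizes the roster and gene order exactly: protein-coding genes are
#' planted with their specified start/stop codons and stop-free bodies
#' (codon bodies sampled with per-position composition targets), tRNA/rRNA
#' and intergenic tracts follow their partition targets, and the control
#' region carries the specified tandem-repeat array whose unit folds into a
#' stem-loop. Overlapping genes are reconciled by a repair pass that keeps
#' every coding frame stop-free without touching planted codons. Fully
#' reproducible for a fixed spec seed.
#'
#' @param spec A `genome_spec` from [unionoid_genome_spec()] (or a
#'   compatible list).
#' @return A `mito_genome`.
#' @export
simulate_genome <- function(spec) {
  validate_genome_spec(spec)
  with_seed(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  roster <- spec$roster
  n <- spec$total
  comp <- spec$comp
  pbg <- base_probs(comp$background[1L], comp$background[2L],
                    comp$background[3L])
  p1 <- base_probs(comp$pos1[1L], comp$pos1[2L], comp$pos1[3L])
  p2 <- base_probs(comp$pos2[1L], comp$pos2[2L], comp$pos2[3L])
  p3 <- base_probs(comp$pos3[1L], comp$pos3[2L], comp$pos3[3L])
  ptr <- base_probs(comp$tRNA[1L], comp$tRNA[2L], comp$tRNA[3L])
  pcr <- base_probs(comp$cr[1L], comp$cr[2L], comp$cr[3L])

  ## layout
  starts <- integer(nrow(roster))
  cur <- 0L
  for (i in seq_len(nrow(roster))) {
    starts[i] <- cur %% n
    cur <- cur + roster$length[i] + as.integer(roster$gap_after[i])
  }
  if (cur != n) stop("layout does not close the circle (", cur, " vs ",
                     n, ")")

  ## background fill, then control region (the largest gap), then features
  chars <- sample_bases(n, pbg)
  if (!is.null(spec$cr)) {
    cr_row <- which(roster$gap_after == max(roster$gap_after))[1L]
    cr_len <- as.integer(roster$gap_after[cr_row])
    cr_start <- (starts[cr_row] + roster$length[cr_row]) %% n
    crs <- build_cr_seq(cr_len, spec$cr, pcr)
    chars <- write_arc(chars, cr_start, crs, +1L, n)
  }

  planted <- logical(n)
  for (i in seq_len(nrow(roster))) {
    kind <- roster$kind[i]
    len <- roster$length[i]
    fixed <- spec$fixed[[roster$label[i]]]
    sense <- if (kind %in% c("PCG", "ORF")) {
      n_cod <- len %/% 3L
      body <- if (!is.null(fixed)) fixed
              else paste(sample_codons(n_cod - 2L, p1, p2, p3),
                         collapse = "")
      paste0(roster$start_codon[i], body, roster$stop_codon[i])
    } else if (kind == "rRNA") {
      tgt <- comp[[roster$label[i]]] %||% comp$background
      if (!is.null(fixed)) fixed
      else exact_comp_sample(len, base_probs(tgt[1L], tgt[2L], tgt[3L]))
    } else {
      if (!is.null(fixed)) fixed
      else exact_comp_sample(len, ptr)
    }
    if (nchar(sense) != len) {
      stop("fixed sequence length mismatch for ", roster$label[i])
    }
    chars <- write_arc(chars, starts[i], sense, roster$strand[i], n)
  }

  ## plant start/stop codons (they win over any overlap overwrites) and an
  ## in-frame stop immediately upstream of each gender-specific ORF so that
  ## ORF scans recover the annotated extent
  coding <- which(roster$kind %in% c("PCG", "ORF"))
  for (i in coding) {
    len <- roster$length[i]; st <- roster$strand[i]
    for (what in c("start", "stop")) {
      t <- if (what == "start") 0L else len %/% 3L - 1L
      cod <- if (what == "start") roster$start_codon[i]
             else roster$stop_codon[i]
      p <- codon_positions(starts[i], len, st, t, n)
      chars[p + 1L] <- seq_chars(if (st < 0L) revcomp(cod) else cod)
      planted[p + 1L] <- TRUE
    }
    if (roster$kind[i] == "ORF") {
      up <- if (st > 0L) (starts[i] - 3L + 0:2) %% n
            else (starts[i] + len + 0:2) %% n
      chars[up + 1L] <- seq_chars(if (st < 0L) revcomp("TAG") else "TAG")
      planted[up + 1L] <- TRUE
    }
  }

  chars <- repair_internal_stops(chars, roster, starts, planted, n)

  ends_raw <- starts + roster$length
  feats <- data.frame(
    label = roster$label, kind = roster$kind, start = starts,
    end = ifelse(ends_raw %% n == 0L, n, ends_raw %% n),
    strand = roster$strand, wraps_origin = ends_raw > n,
    incomplete_stop = FALSE, stringsAsFactors = FALSE)
  mito_genome(spec$id, paste(chars, collapse = ""), feats,
              circular = TRUE, sex_type = spec$sex_type)
}

## keep every coding frame stop-free without touching planted codons
repair_internal_stops <- function(chars, roster, starts, planted, n,
                                  max_fixes = 500L) {
  stops <- stop_codons("5")
  coding <- which(roster$kind %in% c("PCG", "ORF"))
  masks <- lapply(coding, function(i) {
    idx <- (starts[i] + seq_len(roster$length[i]) - 1L) %% n
    m <- logical(n); m[idx + 1L] <- TRUE; m
  })
  find_violation <- function() {
    for (k in seq_along(coding)) {
      i <- coding[k]
      ncod <- roster$length[i] %/% 3L
      if (ncod < 3L) next
      for (t in 1:(ncod - 2L)) {
        cod <- read_sense_codon(chars, starts[i], roster$length[i],
                                roster$strand[i], t, n)
        if (cod %in% stops) return(c(k, t))
      }
    }
    NULL
  }
  for (fix in seq_len(max_fixes)) {
    v <- find_violation()
    if (is.null(v)) return(chars)
    k <- v[1L]; t <- v[2L]; i <- coding[k]
    P <- codon_positions(starts[i], roster$length[i], roster$strand[i],
                         t, n)
    cands <- sample(setdiff(names(genetic_code("5")), stops))
    fixed_here <- FALSE
    for (cand in cands) {
      genomic <- seq_chars(if (roster$strand[i] < 0L) revcomp(cand)
                           else cand)
      if (any(planted[P + 1L] & chars[P + 1L] != genomic)) next
      trial <- chars
      trial[P + 1L] <- genomic
      ok <- TRUE
      for (k2 in seq_along(coding)) {
        if (!any(masks[[k2]][P + 1L])) next
        j <- coding[k2]
        ncod2 <- roster$length[j] %/% 3L
        ## codon indices of gene j touched by positions P
        offs <- (P - starts[j]) %% n
        offs <- offs[offs < roster$length[j]]
        sidx <- if (roster$strand[j] > 0L) offs
                else roster$length[j] - 1L - offs
        for (t2 in unique(sidx %/% 3L)) {
          if (t2 <= 0L || t2 >= ncod2 - 1L) next
          cod2 <- read_sense_codon(trial, starts[j], roster$length[j],
                                   roster$strand[j], t2, n)
          if (cod2 %in% stops) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) { chars <- trial; fixed_here <- TRUE; break }
    }
    if (!fixed_here) {
      stop("cannot reconcile overlapping reading frames at ",
           roster$label[i], " codon ", t)
    }
  }
  v <- find_violation()
  if (!is.null(v)) stop("unresolved internal stops after repair pass")
  chars
}

## codon-evolution machinery --------------------------------------------------

## proposal/acceptance codon evolution: uniform nucleotide proposals,
## synonymous changes always accepted, nonsynonymous accepted with
## probability omega, stop-creating proposals rejected
evolve_codons <- function(codons, omega, ks_target, code = "5",
                          prop_probs = NULL) {
  stopifnot(omega >= 0)
  if (ks_target < 0 || ks_target > 2.2) {
    stop("unreachable synonymous divergence target: ", ks_target)
  }
  tabs <- ng_tables(code)
  ncod <- length(codons)
  n_prop <- round(ks_target * 3 * ncod)
  if (!is.null(prop_probs)) {
    ## compensate the proposal budget for Hastings thinning
    e_acc <- mean(vapply(prop_probs, mh_acceptance, numeric(1)))
    n_prop <- round(n_prop / e_acc)
  }
  if (n_prop == 0L) return(codons)
  ci <- sample.int(ncod, n_prop, replace = TRUE)
  pos <- sample.int(3L, n_prop, replace = TRUE)
  u_alt <- runif(n_prop)
  acc <- runif(n_prop)
  u_mh <- runif(n_prop)
  gc <- tabs$gc
  for (m in seq_len(n_prop)) {
    cod <- codons[ci[m]]
    ch <- strsplit(cod, "")[[1L]]
    others <- setdiff(DNA_ALPHABET, ch[pos[m]])
    hast <- 1
    if (is.null(prop_probs)) {
      w <- c(1, 2, 3) / 3
    } else {
      q <- prop_probs[[pos[m]]]
      qo <- q[match(others, DNA_ALPHABET)]
      w <- cumsum(qo / sum(qo))
    }
    alt <- others[findInterval(u_alt[m], w) + 1L]
    if (!is.null(prop_probs)) {
      ## Metropolis-Hastings factor so the base distribution at each codon
      ## position is the stationary law of the proposal chain
      q <- prop_probs[[pos[m]]]
      q_cur <- q[match(ch[pos[m]], DNA_ALPHABET)]
      q_new <- q[match(alt, DNA_ALPHABET)]
      hast <- min(1, (1 - q_cur) / (1 - q_new))
    }
    ch[pos[m]] <- alt
    new <- paste(ch, collapse = "")
    if (gc[new] == "*") next
    if (u_mh[m] > hast) next
    if (gc[new] == gc[cod] || acc[m] <= omega) codons[ci[m]] <- new
  }
  codons
}

#' Evolve a gap-free ancestor/descendant codon-sequence pair
#'
#' The ancestor is sampled uniformly over non-stop codons; substitutions
#' are proposed per site as uniform nucleotide changes at a rate tuned to
#' the synonymous-divergence target, nonsynonymous proposals are accepted
#' with probability `omega`, and stop-creating proposals are rejected.
#'
#' @param n_codons Number of codons.
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param ks_target Target synonymous divergence (substitutions per
#'   synonymous site).
#' @param code Genetic-code id.
#' @param seed RNG seed.
#' @return A [codon_alignment()] (ancestor row `a`, descendant row `b`).
#' @export
evolve_codon_sequences <- function(n_codons, omega, ks_target, code = "5",
                                   seed = 1L) {
  with_seed(seed, {
    pool <- setdiff(names(genetic_code(code)), stop_codons(code))
    anc <- sample(pool, n_codons, replace = TRUE)
    des <- evolve_codons(anc, omega, ks_target, code)
    codon_alignment(paste(anc, collapse = ""), paste(des, collapse = ""),
                    labels = c("ancestor", "descendant"), code = code)
  })
}

## per-gene divergence targets used when deriving the M genes from the F
## genes of a paper-like pair (omega and synonymous divergence per gene);
## near-saturating synonymous targets are capped at 1.8 to stay inside the
## Jukes-Cantor domain of the NG86 estimator
PAIR_DIVERGENCE <- data.frame(
  gene = c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4",
           "nad4L", "nad5", "nad6", "cob", "atp6", "atp8"),
  omega = c(0.2054, 0.3851, 0.2717, 0.1909, 0.4754, 0.5195, 0.3979,
            0.7374, 0.4635, 0.5209, 0.1488, 0.3175, 0.7548),
  ks = c(1.1643, 1.0467, 1.2319, 2.3138, 1.4316, 0.9738, 1.1809,
         0.9322, 1.1510, 1.1898, 2.3282, 1.5631, 1.0234),
  stringsAsFactors = FALSE
)

#' Generate a paper-like F/M mitogenome pair
#'
#' Simulates the F-type genome, then derives the shared genes of the M-type
#' genome from the F copies: protein-coding bodies are evolved under the
#' per-gene nonsynonymous/synonymous targets of `PAIR_DIVERGENCE` (with 3'
#' extension or truncation to the M gene lengths, reproducing the male cox2
#' extension), rRNA/tRNA genes are mutated at fixed per-site rates, and the
#' M-specific architecture (gene order, overlaps, control region) follows
#' the M roster.
#'
#' @param seed Master RNG seed.
#' @param trna_rate Per-site substitution rate applied to tRNA genes
#'   (default 0.2).
#' @return List with elements `F` and `M` (`mito_genome` objects).
#' @export
unionoid_pair <- function(seed = 1L, trna_rate = 0.2) {
  specF <- unionoid_genome_spec("F", seed = derive_seed(seed, 1L))
  gF <- simulate_genome(specF)
  rosterM <- unionoid_roster("M")$roster
  compM <- comp_targets("M")
  ## mutation-biased proposals/replacements keep the derived M genes on the
  ## AT-rich M composition targets
  probsM <- lapply(c("pos1", "pos2", "pos3"), function(k) {
    base_probs(compM[[k]][1L], compM[[k]][2L], compM[[k]][3L])
  })
  bgM <- base_probs(compM$background[1L], compM$background[2L],
                    compM$background[3L])
  fixed <- list()
  k <- 10L
  for (i in seq_len(nrow(rosterM))) {
    lab <- rosterM$label[i]
    kind <- rosterM$kind[i]
    lenM <- rosterM$length[i]
    if (!lab %in% gF$features$label) next
    k <- k + 1L
    if (kind == "PCG") {
      div <- PAIR_DIVERGENCE[PAIR_DIVERGENCE$gene == lab, ]
      if (!nrow(div)) next
      bodyF <- split_codons(feature_sequence(gF, lab))
      bodyF <- bodyF[-c(1L, length(bodyF))]
      n_body <- lenM %/% 3L - 2L
      core <- bodyF[seq_len(min(length(bodyF), n_body))]
      fixed[[lab]] <- with_seed(derive_seed(seed, k), {
        ev <- evolve_codons(core, div$omega, min(div$ks, 1.8),
                            prop_probs = probsM)
        extra <- n_body - length(ev)
        if (extra > 0L) {
          ev <- c(ev, sample_codons(extra, probsM[[1L]], probsM[[2L]],
                                    probsM[[3L]]))
        }
        paste(ev, collapse = "")
      })
    } else if (kind %in% c("rRNA", "tRNA")) {
      rate <- if (lab == "rrnS") 0.291 else if (lab == "rrnL") 0.289
              else trna_rate
      tgt <- compM[[lab]] %||% compM$tRNA
      sF <- feature_sequence(gF, lab)
      fixed[[lab]] <- with_seed(derive_seed(seed, k), {
        s <- mutate_seq(sF, rate, probs = base_probs(tgt[1L], tgt[2L],
                                                     tgt[3L]))
        if (nchar(s) > lenM) {
          substr(s, 1L, lenM)
        } else if (nchar(s) < lenM) {
          paste0(s, exact_comp_sample(lenM - nchar(s), bgM))
        } else s
      })
    }
  }
  specM <- unionoid_genome_spec("M", seed = derive_seed(seed, 2L),
                                fixed = fixed)
  gM <- simulate_genome(specM)
  list(F = gF, M = gM)
}
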