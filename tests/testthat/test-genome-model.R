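test_that("intergenic regions are maximal feature-free arcs of the circle", {
  g <- toy_genome(100L, rbind(feat("cox1", 0, 40), feat("cox2", 50, 90)))
  ig <- intergenic_regions(g)
  expect_equal(nrow(ig), 2L)
  expect_equal(ig$start, c(40L, 90L))
  expect_equal(ig$length, c(10L, 10L))
  expect_equal(ig$flank_upstream, c("cox1", "cox2"))
  expect_equal(ig$flank_downstream, c("cox2", "cox1"))
  expect_equal(nchar(ig$sequence), ig$length)

  ## a gap genuinely spanning the origin is reported once, flagged
  g2 <- toy_genome(100L, rbind(feat("cox1", 10, 40), feat("cox2", 50, 90)))
  ig2 <- intergenic_regions(g2)
  expect_equal(nrow(ig2), 2L)
  wrap <- ig2[ig2$wraps_origin, ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$start, 90L)
  expect_equal(wrap$length, 20L)
  expect_equal(nchar(wrap$sequence), 20L)

  tiled <- toy_genome(90L, rbind(feat("cox1", 0, 30), feat("cox2", 30, 60),
                                 feat("cox3", 60, 90)))
  expect_equal(nrow(intergenic_regions(tiled)), 0L)

  bare <- mito_genome("bare", rand_dna(50, 3))
  expect_error(intergenic_regions(bare), "featureless")
})

test_that("gene overlaps respect half-open abutment and origin wrap", {
  g <- toy_genome(100L, rbind(feat("cox1", 0, 10), feat("cox2", 10, 20)))
  expect_equal(nrow(gene_overlaps(g)), 0L)

  gw <- toy_genome(100L, rbind(feat("cox1", 0, 3),
                               feat("cox2", 95, 5, wraps = TRUE)))
  ov <- gene_overlaps(gw)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_length, 3L)
})

test_that("span/overlap/intergenic bookkeeping conserves the genome length", {
  for (g in get_pair()) {
    sp <- sum(feature_spans(g))
    ov <- sum(gene_overlaps(g)$overlap_length)
    ig <- sum(intergenic_regions(g)$length)
    expect_identical(sp - ov + ig, g$length)
  }
})

test_that("architecture statistics are invariant under origin rotation", {
  g <- get_pair()$F
  for (off in c(1000L, 8358L, g$length - 7L)) {
    r <- rotate_genome(g, off)
    expect_identical(sort(intergenic_regions(r)$length),
                     sort(intergenic_regions(g)$length))
    ov <- gene_overlaps(g); ovr <- gene_overlaps(r)
    expect_identical(sort(ov$overlap_length), sort(ovr$overlap_length))
    gt <- gene_table(g); gtr <- gene_table(r)
    expect_equal(gtr[match(gt$label, gtr$label), ], gt,
                 ignore_attr = TRUE)
  }
})

test_that("gene_table reads strand-corrected codons and classes", {
  ## + strand ATG...TAA and - strand planted via reverse complement
  cds <- paste0("ATG", strrep("GCT", 8L), "TAA")
  seq <- paste0(rand_dna(10, 4), cds, rand_dna(10, 5),
                revcomp(cds), rand_dna(10, 6))
  g <- mito_genome("t", seq, rbind(
    feat("cox1", 10, 10 + nchar(cds), kind = "PCG"),
    feat("cox2", 20 + nchar(cds), 20 + 2 * nchar(cds), kind = "PCG",
         strand = -1L)))
  gt <- gene_table(g)
  expect_equal(gt$start_codon, c("ATG", "ATG"))
  expect_equal(gt$stop_codon, c("TAA", "TAA"))
  expect_equal(gt$start_class, rep("conventional", 2L))
})

test_that("reported codons survive strand flip plus genome reverse-complement", {
  g <- get_pair()$F
  rc <- revcomp_genome(rotate_genome(g, g$features$start[1L]))
  a <- gene_table(g); b <- gene_table(rc)
  b <- b[match(a$label, b$label), ]
  expect_equal(a$start_codon, b$start_codon)
  expect_equal(a$stop_codon, b$stop_codon)
})

test_that("ORF scan matches the brute-force enumerator on short regions", {
  for (s in 1:12) {
    region <- rand_dna(sample(80:300, 1L), 700 + s)
    got <- find_orfs(region, min_aa = 10L)
    exp <- oracle_orfs(region, min_aa = 10L)
    expect_equal(nrow(got), nrow(exp), info = paste("seed", s))
    if (nrow(got)) {
      expect_equal(unname(as.matrix(got[, c("frame", "strand", "start",
                                            "end", "aa_length")])),
                   unname(exp[, 1:5, drop = FALSE]), info = paste("seed", s))
    }
  }
})

test_that("ORF scan recovers planted ORFs and rejects start-free input", {
  expect_equal(nrow(find_orfs(strrep("A", 120), min_aa = 5L)), 0L)
  orf <- paste0("ATG", strrep("GAC", 10L), "TAG")
  region <- paste0(strrep("C", 12), orf, strrep("C", 12))
  got <- find_orfs(region, min_aa = 10L)
  expect_true(any(got$start == 12L & got$end == 12L + nchar(orf) &
                    got$strand == 1L & got$aa_length == 11L))
})

test_that("the gender-specific ORF is recovered from its host region", {
  g <- get_pair()$F
  f <- g$features
  lo <- f$end[f$label == "trnE"]
  hi <- f$start[f$label == "trnW"]
  region <- substr(g$sequence, lo + 1L, hi)
  got <- find_orfs(region, min_aa = 80L)
  forf_start <- f$start[f$label == "FORF"] - lo
  expect_true(any(got$strand == 1L & got$start == forf_start &
                    got$end == forf_start + 261L & got$aa_length == 86L))
})

test_that("cox2 extension arithmetic", {
  mk <- function(lenF, lenM) {
    list(
      F = toy_genome(4000L, feat("cox2", 10, 10 + lenF), seed = 8),
      M = toy_genome(4000L, feat("cox2", 10, 10 + lenM), seed = 9))
  }
  p <- mk(681L, 1224L)
  ext <- cox2_extension(p$F, p$M)
  expect_identical(ext$extension_bp, 543L)
  expect_equal(round(100 * ext$extension_pct, 1), 79.7)
  p2 <- mk(102L, 153L)
  expect_equal(cox2_extension(p2$F, p2$M)$extension_pct, 0.5)
  p3 <- mk(300L, 300L)
  expect_equal(cox2_extension(p3$F, p3$M)$extension_bp, 0L)
  noc <- toy_genome(1000L, feat("cox1", 0, 300), seed = 10)
  expect_error(cox2_extension(noc, p$M), "cox2")
})

test_that("GenBank flat files parse: topology, locations, synonyms, wrap", {
  seqn <- rand_dna(120, 11)
  gb <- c(
    "LOCUS       TEST0001             120 bp    DNA     circular INV",
    "DEFINITION  toy mitogenome.",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..34",
    "                     /gene=\"COI\"",
    "     tRNA            complement(40..75)",
    "                     /product=\"tRNA-Ser(UCU)\"",
    "     rRNA            join(101..120,1..2)",
    "                     /product=\"16S ribosomal RNA\"",
    "ORIGIN",
    paste("        1", paste(substring(tolower(seqn),
                                       seq(1, 120, 10),
                                       seq(10, 120, 10)), collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- load_genome(path, format = "genbank")
  expect_identical(g$id, "TEST0001")
  expect_true(g$circular)
  expect_identical(g$sequence, seqn)
  f <- g$features
  expect_setequal(f$label, c("cox1", "trnS1", "rrnL"))
  expect_equal(f$start[f$label == "cox1"], 4L)
  expect_equal(f$end[f$label == "cox1"], 34L)
  expect_equal(f$strand[f$label == "trnS1"], -1L)
  expect_true(f$wraps_origin[f$label == "rrnL"])
  expect_equal(feature_spans(g)[match("rrnL", f$label)], 22L)
})

test_that("FASTA + feature table round-trips a generated genome", {
  g <- get_pair()$F
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_feature_table(g, tsv, fasta = fa)
  g2 <- load_genome(fa, format = "fasta", feature_table = tsv,
                    sex_type = "F")
  expect_identical(g2$sequence, g$sequence)
  expect_equal(g2$features, g$features)
})

test_that("annotation errors are caught and named", {
  expect_error(
    mito_genome("d", rand_dna(100, 12),
                rbind(feat("cox1", 0, 30), feat("COI", 40, 70))),
    "duplicate.*cox1")
  expect_error(
    mito_genome("f", rand_dna(100, 13), feat("cox1", 0, 31, kind = "PCG")),
    "multiple of 3")
  g <- toy_genome(100L, feat("nad2", 0, 30))
  expect_error(feature_sequence(g, "cox1"), "no feature")
})
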