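test_that("p-distance: hand counts, pairwise deletion, degenerate input", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAAAAAAAA", "AAAAAAAACC"), 0.2)
  ## gapped and ambiguous columns are deleted pairwise
  expect_equal(p_distance("AC-GTN", "ACAGAA"), 0.25)
  expect_error(p_distance("---", "AAA"), "no comparable")
  ## symmetric and invariant under column permutation
  a <- rand_dna(60, 61); b <- rand_dna(60, 62)
  expect_equal(p_distance(a, b), p_distance(b, a))
  set.seed(1)
  perm <- sample(60)
  pa <- paste(strsplit(a, "")[[1]][perm], collapse = "")
  pb <- paste(strsplit(b, "")[[1]][perm], collapse = "")
  expect_equal(p_distance(pa, pb), p_distance(a, b))
})

test_that("bootstrap SE matches the binomial closed form on iid sites", {
  n <- 1000L
  a <- strrep("A", n)
  b <- paste0(strrep("C", 200L), strrep("A", 800L))
  se <- bootstrap_se(a, b, "nt", replicates = 1000L, seed = 42L)
  closed <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(se - closed) / closed, 0.15)
  expect_equal(bootstrap_se(a, a, "nt", replicates = 100L, seed = 7L), 0)
  ## reproducible for a fixed seed
  expect_identical(bootstrap_se(a, b, "nt", replicates = 200L, seed = 5L),
                   bootstrap_se(a, b, "nt", replicates = 200L, seed = 5L))
})

test_that("global amino-acid alignment is optimal (brute-force oracle)", {
  al <- align_aa_global("MKV", "MV")
  expect_equal(al$score, oracle_align_score("MKV", "MV"))
  expect_equal(nchar(al$a), 3L)
  expect_equal(al$b, "M-V")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(77)
  for (i in 1:15) {
    a <- paste(sample(aas, sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:6, 1), replace = TRUE), collapse = "")
    expect_equal(align_aa_global(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  ## identical peptides align gap-free
  p <- "MSTALLINKER"
  al2 <- align_aa_global(p, p)
  expect_identical(al2$a, p)
  expect_identical(al2$b, p)
  expect_error(align_aa_global("", "MV"), "empty")
})

test_that("substitution-only divergence never provokes alignment gaps", {
  ca <- evolve_codon_sequences(50L, 0.5, 0.4, seed = 11L)
  pa <- translate_cds(ca$a); pb <- translate_cds(ca$b)
  al <- align_aa_global(pa, pb)
  expect_false(grepl("-", al$a))
  expect_false(grepl("-", al$b))
})

test_that("retro-alignment expands residues to codons and validates", {
  ## gap-free alignment reproduces the CDS side by side
  ra <- retro_align(list(a = "MK", b = "MK"), "ATGAAA", "ATGAAG")
  expect_identical(ra$a, "ATGAAA")
  expect_identical(ra$b, "ATGAAG")
  ## a residue gap becomes a codon gap
  ra2 <- retro_align(list(a = "M-K", b = "MSK"), "ATGAAA", "ATGAGCAAA")
  expect_identical(ra2$a, "ATG---AAA")
  expect_identical(ra2$b, "ATGAGCAAA")
  ## terminal stop is stripped before matching
  ra3 <- retro_align(list(a = "MK", b = "MK"), "ATGAAATAA", "ATGAAG")
  expect_identical(ra3$a, "ATGAAA")
  ## wrong CDS is a correspondence error
  expect_error(retro_align(list(a = "MK", b = "MK"), "ATGCCC", "ATGAAA"),
               "correspondence")
})

test_that("NG86 site counting and JC correction match the hand example", {
  ca <- codon_alignment(strrep("GGG", 5L),
                        paste0(strrep("GGG", 4L), "GGC"))
  ng <- nei_gojobori(ca)
  expect_equal(ng$S_sites, 5)
  expect_equal(ng$N_sites, 10)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$Ks, -0.75 * log(1 - 4 * 0.2 / 3))
  expect_equal(ng$Ka, 0)
  ## identical input: zero divergence, omega undefined
  same <- nei_gojobori(codon_alignment("ATGAAA", "ATGAAA"))
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$omega))
})

test_that("NG86 invariants: site closure, symmetry, gap masking", {
  for (s in 1:8) {
    ca <- evolve_codon_sequences(60L, 0.5, 0.6, seed = 200 + s)
    ng <- nei_gojobori(ca)
    expect_equal(ng$S_sites + ng$N_sites, 3 * ng$codons_used)
    swapped <- codon_alignment(ca$b, ca$a)
    ng2 <- nei_gojobori(swapped)
    expect_equal(ng2$Ka, ng$Ka)
    expect_equal(ng2$Ks, ng$Ks)
  }
  gapped <- codon_alignment("ATG---GGG", "ATGCCCCGG")
  expect_equal(nei_gojobori(gapped)$codons_used, 2L)
})

test_that("NG86 pathway averaging equals the ordering enumerator", {
  pool <- setdiff(names(genetic_code("5")), c("TAA", "TAG"))
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(1:10, 1)
    a <- paste(sample(pool, n, replace = TRUE), collapse = "")
    b <- paste(sample(pool, n, replace = TRUE), collapse = "")
    cnt <- duimito:::ng_counts(codon_alignment(a, b))
    oo <- oracle_alignment_diffs(a, b)
    expect_equal(cnt$Sd, unname(oo["sd"]), info = paste(a, b))
    expect_equal(cnt$Nd, unname(oo["nd"]), info = paste(a, b))
    expect_equal(cnt$S + cnt$N, 3 * cnt$codons_used)
  }
})

test_that("saturation raises an error rather than a distance", {
  expect_error(jukes_cantor(0.76), "saturation")
})

test_that("concatenation and codon-position masking", {
  a1 <- codon_alignment("ATGAAA", "ATGAAG", labels = c("F", "M"))
  a2 <- codon_alignment("CCCGGGTTT", "CCCGGATTC", labels = c("F", "M"))
  cc <- concat_and_mask(list(g1 = a1, g2 = a2))
  expect_identical(cc$a, "ATGAAACCCGGGTTT")
  expect_equal(cc$partition$from, c(1L, 7L))
  expect_equal(cc$partition$to, c(6L, 15L))

  cc3 <- concat_and_mask(list(g1 = a1, g2 = a2), drop_positions = 3L)
  expect_identical(cc3$a, "ATAACCGGTT")
  expect_equal(cc3$partition$to, c(4L, 10L))

  ## dropping the third position removes exactly a third of the columns
  big <- evolve_codon_sequences(3400L, 0.3, 0.5, seed = 31L)
  kept <- concat_and_mask(list(all = big), drop_positions = 3L)
  expect_identical(nchar(kept$a), 6800L)

  b1 <- codon_alignment("ATGAAA", "ATGAAG", labels = c("X", "Y"))
  expect_error(concat_and_mask(list(a1, b1)), "label mismatch")
})

test_that("omega recovery: NG86 estimates track the simulated ratio", {
  est <- function(omega, ks, seeds) {
    mean(vapply(seeds, function(s) {
      nei_gojobori(evolve_codon_sequences(3000L, omega, ks,
                                          seed = s))$omega
    }, numeric(1)))
  }
  o2 <- est(0.2, 1.0, 1:8)
  expect_lt(abs(o2 - 0.2) / 0.2, 0.2)
  o5 <- est(0.5, 0.6, 11:18)
  expect_lt(abs(o5 - 0.5) / 0.5, 0.2)
  ## neutral limit
  o1 <- est(1.0, 0.5, 21:28)
  expect_gt(o1, 0.9)
  expect_lt(o1, 1.1)
})

test_that("per-gene divergence table runs end to end on the F/M pair", {
  p <- get_pair()
  dv <- divergence_table(p$F, p$M, replicates = 150L, seed = 42L)
  tab <- dv$table
  expect_true(all(c("rrnS", "rrnL", "cox1", "atp8", "all_PCGs") %in%
                    tab$gene))
  expect_true(all(tab$pd_nt >= 0 & tab$pd_nt <= 1))
  expect_true(all(is.na(tab$pd_aa[tab$gene %in% c("rrnS", "rrnL")])))
  ## amino-acid divergence exceeds nucleotide divergence for coding genes
  coding <- !tab$gene %in% c("rrnS", "rrnL")
  expect_true(all(tab$pd_aa[coding] > tab$pd_nt[coding] - 0.05))
  ## the concatenated row sits inside the per-gene range
  all_row <- tab[tab$gene == "all_PCGs", ]
  per <- tab[coding & tab$gene != "all_PCGs", ]
  expect_gt(all_row$pd_nt, min(per$pd_nt) - 1e-9)
  expect_lt(all_row$pd_nt, max(per$pd_nt) + 1e-9)
})
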