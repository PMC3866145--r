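test_that("perfect tandem arrays report minimal period and full copy number", {
  expect_equal(tandem_repeats("ACGACGACGACG", min_period = 3L)$period, 3L)
  expect_equal(tandem_repeats("ACGACGACGACG", min_period = 3L)$copies, 4)
  set.seed(5)
  for (rep in 1:12) {
    ulen <- sample(3:120, 1)
    k <- sample(2:10, 1)
    unit <- rand_dna(ulen, 5000 + rep)
    tr <- tandem_repeats(strrep(unit, k), min_period = 3L, k = 3L)
    expect_gte(nrow(tr), 1L)
    best <- tr[which.max(tr$span), ]
    expect_true(best$period <= ulen && ulen %% best$period == 0L,
                info = paste(ulen, k))
    expect_equal(best$copies * best$period, ulen * k,
                 info = paste(ulen, k))
    expect_equal(best$identity, 1)
  }
})

test_that("a planted degenerate array in random background is recovered", {
  set.seed(9)
  for (rep in 1:5) {
    unit <- rand_dna(80, 6000 + rep)
    copies <- vapply(1:4, function(i) {
      if (i == 1) unit else duimito:::mutate_seq(unit, 0.05)
    }, character(1))
    seqr <- paste0(rand_dna(350, 6100 + rep), paste(copies, collapse = ""),
                   rand_dna(330, 6200 + rep))
    tr <- tandem_repeats(seqr, min_period = 40L, min_identity = 0.85)
    expect_equal(nrow(tr), 1L, info = rep)
    expect_lte(abs(tr$period - 80L), 2L)
    expect_gte(tr$copies, 3.5)
  }
  ## plain background yields nothing
  expect_equal(nrow(tandem_repeats(rand_dna(600, 77), min_period = 40L)),
               0L)
})

test_that("hairpin DP equals exhaustive search on short sequences", {
  expect_equal(max_hairpin("AAAAAA")$n_pairs, 0L)
  hp <- max_hairpin("GGGGAAAACCCC", min_loop = 3L, allow_gu = FALSE)
  expect_equal(hp$n_pairs, 4L)
  expect_equal(hp$stem_length, 4L)
  expect_equal(hp$loop_length, 4L)
  for (s in 1:60) {
    x <- rand_dna(sample(8:18, 1), 800 + s)
    expect_equal(max_hairpin(x)$n_pairs, oracle_max_pairs(x),
                 info = paste(s, x))
  }
  ## reported pairs are nested, legal and respect the loop constraint
  x <- rand_dna(18, 870)
  hp2 <- max_hairpin(x)
  if (hp2$n_pairs > 1) {
    p <- hp2$pairs
    expect_true(all(p[, 2] - p[, 1] > 3))
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        nested <- (p[j, 1] > p[i, 2]) ||
          (p[j, 1] > p[i, 1] && p[j, 2] < p[i, 2])
        expect_true(nested)
      }
    }
  }
})

test_that("the generated control regions satisfy all three criteria and rank first", {
  p <- get_pair()
  cf <- control_region_candidates(p$F)
  top <- cf[1L, ]
  expect_identical(top$flank_upstream, "nad5")
  expect_identical(top$flank_downstream, "trnQ")
  expect_identical(top$length, 1049L)
  expect_identical(top$best_period, 101L)
  expect_equal(round(top$best_copies), 8)
  expect_true(top$qualifying_repeat)
  expect_true(top$length_ok)

  cm <- control_region_candidates(p$M)
  topm <- cm[1L, ]
  expect_identical(topm$flank_upstream, "trnH")
  expect_identical(topm$flank_downstream, "trnQ")
  expect_identical(topm$length, 848L)
  expect_identical(topm$best_period, 102L)
  expect_equal(round(topm$best_copies), 7)
})

test_that("control-region ranking is rotation invariant and score monotone", {
  g <- get_pair()$F
  c0 <- control_region_candidates(g)
  c1 <- control_region_candidates(rotate_genome(g, 4321L))
  expect_identical(c0$flank_upstream[1:3], c1$flank_upstream[1:3])
  expect_identical(sort(c0$length), sort(c1$length))
})

test_that("adding a qualifying repeat never lowers a candidate's score", {
  arm <- "GGGCCTAGGTCC"
  unit <- paste0(arm, "AATTA", revcomp(arm), rand_dna(31, 31))  # 60 bp
  array <- strrep(unit, 5L)                                     # 300 bp
  head_f <- rand_dna(100, 34)
  gene2 <- rand_dna(100, 36)
  pad <- rand_dna(150, 35)
  tail_bg <- rand_dna(400, 37)
  feats <- rbind(feat("cox1", 0, 100), feat("cox2", 550, 650))
  g_with <- mito_genome("with", paste0(
    head_f, array, pad, gene2, tail_bg), feats)
  g_without <- mito_genome("without", paste0(
    head_f, rand_dna(300, 38), pad, gene2, tail_bg), feats)
  c_with <- control_region_candidates(g_with, min_period = 20L)
  c_without <- control_region_candidates(g_without, min_period = 20L)
  big_with <- c_with[c_with$length == 450L, ]
  big_without <- c_without[c_without$length == 450L, ]
  expect_true(big_with$qualifying_repeat)
  expect_false(big_without$qualifying_repeat)
  ## score decomposes as z(length) + z(AT%) + repeat indicator: the
  ## qualifying repeat contributes exactly +1 on top of the other criteria
  z <- function(x) {
    if (length(x) < 2 || sd(x) == 0) rep(0, length(x))
    else (x - mean(x)) / sd(x)
  }
  for (cand in list(c_with, c_without)) {
    expect_equal(cand$score,
                 z(cand$length) + z(cand$at_pct) +
                   as.numeric(cand$qualifying_repeat))
  }
})

test_that("a short gap is reported but flagged as failing the length criterion", {
  g <- toy_genome(400L, rbind(feat("cox1", 0, 150), feat("cox2", 160, 400)))
  cand <- control_region_candidates(g)
  expect_equal(nrow(cand), 1L)
  expect_false(cand$length_ok)
})
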