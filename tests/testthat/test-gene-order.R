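TYPICAL_M_ORDER <- c("cox1", "cox2", "nad3", "nad2", "rrnS", "rrnL", "cob",
                     "nad5", "nad1", "nad6", "nad4", "nad4L", "atp8",
                     "atp6", "cox3")

test_that("extracted orders reproduce the typical unionoid arrangement", {
  p <- get_pair()
  om <- extract_order(p$M, "pcg-rrna")
  expect_identical(om$labels, TYPICAL_M_ORDER)
  of <- extract_order(p$F, "pcg-rrna")
  ## the F order differs by the relative inversion of nad2 and nad3 in the
  ## cox2--rrnS segment
  expect_identical(of$labels,
                   TYPICAL_M_ORDER[c(1, 2, 4, 3, 5:15)])
  ## all-gene scope keeps tRNAs and the gender-specific ORF
  oall <- extract_order(p$F, "all")
  expect_equal(length(oall$labels), 38L)
  expect_true("FORF" %in% oall$labels)
})

test_that("order extraction is invariant under genome rotation", {
  g <- get_pair()$M
  o0 <- extract_order(g, "pcg-rrna")
  for (off in c(1000L, 9000L)) {
    o1 <- extract_order(rotate_genome(g, off), "pcg-rrna")
    expect_identical(o1$labels, o0$labels)
    expect_identical(o1$signs, o0$signs)
  }
})

test_that("breakpoint distance: identity, symmetry, known rearrangements", {
  a <- gene_order(letters[1:5])
  expect_identical(breakpoint_distance(a, a), 0L)
  ## moving one gene to a new position breaks 3 adjacencies
  moved <- apply_rearrangement(a, "transposition", from = 2L, to = 2L,
                               dest = 3L)
  expect_identical(breakpoint_distance(a, moved), 3L)
  expect_identical(breakpoint_distance(moved, a), 3L)
  ## an internal segment inversion breaks exactly 2
  inv <- apply_rearrangement(a, "inversion", from = 2L, to = 3L)
  expect_identical(breakpoint_distance(a, inv), 2L)
  ## inverting a single internal gene also breaks 2 (sign flip)
  inv1 <- apply_rearrangement(a, "inversion", from = 3L, to = 3L)
  expect_identical(breakpoint_distance(a, inv1), 2L)
  ## label-set mismatch is an error naming the difference
  b <- gene_order(letters[2:6])
  expect_error(breakpoint_distance(a, b), "label sets differ")
})

test_that("inversions are involutions and segment inversions cost 2", {
  set.seed(42)
  base <- gene_order(paste0("g", 1:9),
                     sample(c(-1L, 1L), 9L, replace = TRUE))
  for (i in 1:10) {
    from <- sample(2:8, 1)
    to <- if (from == 8L) 8L else sample(from:8, 1)
    once <- apply_rearrangement(base, "inversion", from = from, to = to)
    twice <- apply_rearrangement(once, "inversion", from = from, to = to)
    expect_identical(twice$labels, base$labels)
    expect_identical(twice$signs, base$signs)
    expect_identical(breakpoint_distance(base, once), 2L)
  }
})

test_that("F vs M distance agrees with the direct adjacency oracle", {
  p <- get_pair()
  of <- extract_order(p$F, "pcg-rrna")
  om <- extract_order(p$M, "pcg-rrna")
  expect_identical(breakpoint_distance(of, om),
                   oracle_breakpoints(of$labels, of$signs,
                                      om$labels, om$signs))
  ## all-gene scope against a rearranged copy of the same genome
  oa <- extract_order(p$F, "all")
  ob <- apply_rearrangement(
    apply_rearrangement(oa, "inversion", from = 5L, to = 9L),
    "transposition", from = 20L, to = 22L, dest = 2L)
  expect_identical(breakpoint_distance(oa, ob),
                   oracle_breakpoints(oa$labels, oa$signs,
                                      ob$labels, ob$signs))
})

test_that("synapomorphic adjacencies are exactly the planted ones", {
  base <- gene_order(paste0("g", 1:8), rep(1L, 8))
  derived <- apply_rearrangement(base, "inversion", from = 3L, to = 5L)
  orders <- list(a1 = derived, a2 = derived, a3 = derived,
                 b1 = base, b2 = base, b3 = base)
  syn <- synapomorphic_adjacencies(orders, c("a1", "a2", "a3"))
  expect_identical(sort(syn),
                   sort(setdiff(adjacency_set(derived),
                                adjacency_set(base))))
  ## identical orders everywhere: nothing is diagnostic
  expect_length(synapomorphic_adjacencies(
    list(x = base, y = base, z = base), c("x", "y")), 0L)
  expect_error(synapomorphic_adjacencies(orders, character(0)), "non-empty")
})

test_that("the F cox2--rrnS arrangement is diagnostic for the F group", {
  p <- get_pair()
  of <- extract_order(p$F, "pcg-rrna")
  ## outgroup orders carry the typical arrangement with the same strand
  ## signs, isolating the cox2..rrnS rearrangement as the only difference
  sig <- setNames(of$signs, of$labels)
  typical <- gene_order(TYPICAL_M_ORDER,
                        unname(sig[TYPICAL_M_ORDER]), id = "typical")
  orders <- list(F1 = of, F2 = of, O1 = typical, O2 = typical)
  syn <- synapomorphic_adjacencies(orders, c("F1", "F2"))
  expect_gt(length(syn), 0L)
  ## every diagnostic adjacency involves genes of the rearranged
  ## cox2..rrnS segment
  expect_true(all(grepl("cox2|nad2|nad3|rrnS", syn)))
})

test_that("canonicalization anchors at cox1 and falls back when absent", {
  g <- toy_genome(300L, rbind(feat("nad2", 0, 90), feat("cox1", 100, 190),
                              feat("nad3", 200, 290)))
  o <- extract_order(g, "pcg-rrna")
  expect_identical(o$labels[1L], "cox1")
  g2 <- toy_genome(300L, rbind(feat("nad2", 0, 90),
                               feat("nad3", 200, 290)))
  expect_message(o2 <- extract_order(g2, "pcg-rrna"), "canonicalizing")
  expect_identical(o2$labels[1L], "nad2")
})
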