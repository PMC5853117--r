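test_that("raw distances count differing unambiguous non-gap columns", {
  d <- raw_distances(c(a = "ACGT", b = "ACGA"))
  expect_equal(d$N["a", "b"], 1L)
  expect_equal(d$comparable["a", "b"], 4L)
  d <- raw_distances(c(a = "AC-T", b = "ACGT"))
  expect_equal(d$N["a", "b"], 0L)
  expect_equal(d$comparable["a", "b"], 3L)
  d <- raw_distances(c(a = "ANGT", b = "ACGT"))
  expect_equal(d$N["a", "b"], 0L)
  expect_equal(d$comparable["a", "b"], 3L)
  expect_error(raw_distances(c(a = "----", b = "ACGT")), "unambiguous")
  expect_error(raw_distances(c(a = "ACGT")), "at least 2")
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  D <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  nj <- neighbor_joining(D, outgroup = "D")
  # path distances on the tree reproduce the additive input
  expect_equal(ape::cophenetic.phylo(nj)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)
  # A,B sister (four-point condition)
  expect_true(ape::is.monophyletic(nj, c("A", "B")))
})

test_that("3-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj <- neighbor_joining(D, outgroup = "c")
  cp <- ape::cophenetic.phylo(nj)
  expect_equal(cp[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("NJ on tree-derived distances recovers the topology", {
  set.seed(201)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D, outgroup = tr$tip.label[1])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), ape::unroot(tr))), 0)
    # agrees with the reference implementation
    ref <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), ape::unroot(ref))), 0)
  }
})

test_that("NJ requires an outgroup", {
  D <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  expect_error(neighbor_joining(D), "outgroup")
  expect_error(neighbor_joining(D, outgroup = "z"), "outgroup")
})

delim_setup <- function(mut, L = 100) {
  seqs <- seqs_from_mutations(mut, L)
  d <- raw_distances(seqs)
  guide <- phangorn::midpoint(
    ape::unroot(neighbor_joining(d, outgroup = names(seqs)[1])))
  list(d = d, guide = guide, seqs = seqs)
}

test_that("two clades separated by >= min_diff form two lineages", {
  # clade 1: {s1,s2} identical-ish; clade 2: {s3,s4}; cross pairs differ by 5
  s <- delim_setup(list(s1 = integer(0), s2 = 1, s3 = 11:15, s4 = c(11:15, 2)))
  part <- delimit_lineages(s$guide, s$d, min_diff = 3)
  expect_length(part$members, 2L)
  expect_equal(part$lineage[["s1"]], part$lineage[["s2"]])
  expect_false(part$lineage[["s1"]] == part$lineage[["s3"]])
})

test_that("sequences all within min_diff collapse to one lineage", {
  s <- delim_setup(list(s1 = integer(0), s2 = 1, s3 = 2, s4 = c(1, 2)))
  part <- delimit_lineages(s$guide, s$d, min_diff = 3)
  expect_length(part$members, 1L)
})

test_that("a rare central ancestral haplotype is excluded, a common one merged", {
  # central haplotype s0 within 2 diffs of both groups; groups 6 apart
  mut <- list(s0 = integer(0),
              a1 = 1:2, a2 = c(1:2, 11),
              b1 = 21:22, b2 = c(21:22, 31))
  s <- delim_setup(mut)
  part <- delimit_lineages(s$guide, s$d,
                           specimen_counts = c(s0 = 2, a1 = 1, a2 = 1,
                                               b1 = 1, b2 = 1))
  expect_length(part$members, 2L)
  expect_true(is.na(part$lineage[["s0"]]))
  expect_identical(part$excluded, "s0")
  # with > 3 specimens the ancestor is combined instead
  part2 <- delimit_lineages(s$guide, s$d,
                            specimen_counts = c(s0 = 5, a1 = 1, a2 = 1,
                                                b1 = 1, b2 = 1))
  expect_length(part2$members, 1L)
  expect_length(part2$excluded, 0L)
})

test_that("delimitation is the finest valid monophyletic partition", {
  # brute-force check on a 5-sequence case: enumerate all partitions,
  # keep those whose groups are guide-monophyletic with all cross pairs
  # >= min_diff, and compare the finest with the implementation
  mut <- list(s1 = integer(0), s2 = 1, s3 = c(11:14), s4 = c(11:14, 21),
              s5 = c(31:36))
  s <- delim_setup(mut)
  part <- delimit_lineages(s$guide, s$d, min_diff = 3)
  ids <- names(s$seqs)
  parts_of <- function(assig) split(ids, assig)
  best <- 0L
  for (code in seq_len(5^5) - 1L) {
    assig <- (code %/% 5^(0:4)) %% 5
    gr <- parts_of(assig)
    ok <- TRUE
    for (g1 in seq_along(gr)) {
      if (length(gr[[g1]]) > 1 &&
          !ape::is.monophyletic(s$guide, gr[[g1]])) { ok <- FALSE; break }
      for (g2 in seq_along(gr)) if (g2 > g1)
        if (min(s$d$N[gr[[g1]], gr[[g2]]]) < 3) { ok <- FALSE; break }
      if (!ok) break
    }
    if (ok) best <- max(best, length(gr))
  }
  expect_equal(length(part$members), best)
})

test_that("single-linkage species clustering chains below the threshold", {
  d <- raw_distances(seqs_from_mutations(
    list(a = integer(0), b = 1:3, c = 1:6), L = 100))
  # a-b 0.03, b-c 0.03, a-c 0.06: one species under single linkage
  expect_equal(d$prop["a", "c"], 0.06)
  expect_length(unique(cluster_species(d, 0.04)), 1L)
  d2 <- raw_distances(seqs_from_mutations(list(a = integer(0), b = 1:5),
                                          L = 100))
  expect_length(unique(cluster_species(d2, 0.04)), 2L)  # pair at 0.05
  d3 <- raw_distances(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_length(unique(cluster_species(d3, 0.04)), 1L)
})

test_that("medoid exemplars minimize mean within-lineage distance", {
  mut <- list(hub = integer(0), x1 = 1, x2 = 2, far = 11:16)
  s <- delim_setup(mut)
  part <- delimit_lineages(s$guide, s$d, min_diff = 3)
  ex <- select_exemplars(part, s$d)
  lin_hub <- part$lineage[["hub"]]
  expect_equal(unname(ex[as.character(lin_hub)]), "hub")
  expect_equal(unname(ex[as.character(part$lineage[["far"]])]), "far")
  # exemplars of different lineages differ by >= min_diff
  expect_gte(min(s$d$N[ex, ex][upper.tri(diag(length(ex)))]), 3)
})

test_that("lineage and species counts are monotone in their thresholds", {
  sc <- paper_shaped_fixture(seed = 31, n_lineages = 15,
                             specimens_per_lineage = 5)
  d <- raw_distances(sc$alignment)
  guide <- phangorn::midpoint(
    ape::unroot(neighbor_joining(d, outgroup = names(sc$alignment)[1])))
  n_lin <- vapply(c(1, 3, 6, 10), function(md)
    length(delimit_lineages(guide, d, min_diff = md)$members), 0L)
  expect_true(all(diff(n_lin) <= 0))
  n_sp <- vapply(c(0.01, 0.04, 0.1), function(th)
    length(unique(cluster_species(d, th))), 0L)
  expect_true(all(diff(n_sp) <= 0))
})
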