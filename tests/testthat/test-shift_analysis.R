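# 4-tip comb: ((t1:1,t2:1):2,(t3:1,t4:1):2); root at 3 Ma, two shallow
# nodes at 1 Ma
four_tip <- function() read_timetree("((t1:1,t2:1):2,(t3:1,t4:1):2);")

test_that("splits classify by bin and descendant-state disjointness", {
  tr <- four_tip()
  cm <- make_coded(c(t1 = "A", t2 = "A", t3 = "B", t4 = "B"),
                   character = "host_species")
  rec <- parsimony_reconstruct(tr, cm)
  st <- classify_splits(tr, list(host_species = rec), breakpoint = 2)
  tab <- st$table
  for (res in c("acctran", "deltran")) {
    row <- tab[tab$resolution == res, ]
    expect_equal(row$old_shift, 1); expect_equal(row$old_total, 1)
    expect_equal(row$young_shift, 0); expect_equal(row$young_total, 2)
    expect_equal(row$D, 1)
  }
})

test_that("constant characters yield zero shift proportions", {
  tr <- four_tip()
  cm <- make_coded(stats::setNames(rep("A", 4), tr$tip.label))
  rec <- parsimony_reconstruct(tr, cm)
  st <- classify_splits(tr, list(trait = rec), breakpoint = 2)
  expect_true(all(st$table$p_old == 0 & st$table$p_young == 0))
})

test_that("overlapping polymorphic tip sets are not shifts", {
  tr <- read_timetree("((t1:1,t2:1):1,t3:2);")
  cm <- make_coded(list(t1 = c("A", "B"), t2 = c("B", "C"), t3 = "B"))
  rec <- parsimony_reconstruct(tr, cm)
  st <- classify_splits(tr, list(trait = rec), breakpoint = 1.5)
  expect_true(all(st$table$old_shift == 0 & st$table$young_shift == 0))
})

test_that("the composite host shift is a shift in species OR tissue", {
  tr <- four_tip()
  recs <- list(
    host_species = parsimony_reconstruct(tr, make_coded(
      c(t1 = "A", t2 = "A", t3 = "B", t4 = "B"))),
    host_tissue = parsimony_reconstruct(tr, make_coded(
      c(t1 = "seed", t2 = "stem", t3 = "stem", t4 = "stem"))))
  st <- classify_splits(tr, recs, breakpoint = 2)
  comp <- st$table[st$table$character == "host_shift" &
                   st$table$resolution == "deltran", ]
  expect_equal(comp$old_shift, 1)        # species shift at the root
  expect_equal(comp$young_shift, 1)      # tissue shift at one shallow node
})

test_that("old and young totals partition the included internal nodes", {
  set.seed(601)
  for (i in 1:20) {
    tr <- simulate_yule(sample(8:30, 1))
    tr$edge.length <- tr$edge.length * 13 / max(node_ages(tr))
    x <- sample(c("a", "b", "c"), ape::Ntip(tr), TRUE)
    names(x) <- tr$tip.label
    rec <- parsimony_reconstruct(tr, make_coded(x))
    for (excl in c(0, 1)) {
      st <- classify_splits(tr, list(trait = rec), breakpoint = 3,
                            exclusion_age = excl)
      ages <- node_ages(tr)[-seq_len(ape::Ntip(tr))]
      expect_equal(st$table$old_total[1] + st$table$young_total[1],
                   sum(ages >= excl))
    }
  }
})

test_that("acctran/deltran tallies differ only at MPR-ambiguous nodes", {
  set.seed(602)
  for (i in 1:40) {
    tr <- simulate_yule(sample(6:20, 1))
    x <- sample(c("a", "b"), ape::Ntip(tr), TRUE)
    names(x) <- tr$tip.label
    rec <- parsimony_reconstruct(tr, make_coded(x))
    st <- classify_splits(tr, list(trait = rec),
                          breakpoint = max(node_ages(tr)) / 2)
    nd <- st$nodes
    differ <- nd$acctran.trait != nd$deltran.trait
    if (!any(differ)) next
    tv <- divshift:::tree_traversal(tr)
    for (v in nd$node[differ]) {
      kids <- tv$kids[[v]]
      ambig <- any(lengths(rec$mpr[c(v, kids)]) > 1)
      expect_true(ambig)
    }
  }
})

test_that("simmap tallies read branch end states and cap at one per split", {
  tr <- four_tip()
  ages <- node_ages(tr)
  # hand-built history: branch to t1's parent has A->B->A; everything else A
  tv <- divshift:::tree_traversal(tr)
  seg <- function(e, bounds, states) data.frame(
    edge = e, parent = tr$edge[e, 1], child = tr$edge[e, 2],
    start_age = bounds[-length(bounds)], end_age = bounds[-1],
    state = states)
  root <- tv$root
  inner_edge <- which(tr$edge[, 2] == ape::getMRCA(tr, c("t1", "t2")))
  segs <- do.call(rbind, lapply(seq_len(nrow(tr$edge)), function(e) {
    p_age <- ages[tr$edge[e, 1]]; c_age <- ages[tr$edge[e, 2]]
    if (e == inner_edge)
      seg(e, c(p_age, 2.5, 2, c_age), c("A", "B", "A"))
    else seg(e, c(p_age, c_age), "A")
  }))
  h <- list(tree_index = 1L, sim_index = 1L,
            node_state = rep("A", 7), segments = segs)
  maps <- structure(list(h), class = "simmap_set")
  out <- tally_simmap(list(trait = maps), tr, breakpoint = 2)
  # two transitions along the branch, but end states all match: no shift
  expect_equal(out$old_shift, 0)
  expect_equal(out$young_shift, 0)
})

test_that("zero-transition histories imply zero shifts; shifts <= transitions", {
  set.seed(603)
  tr <- simulate_yule(15)
  tr$edge.length <- tr$edge.length * 10 / max(node_ages(tr))
  x <- stats::setNames(sample(c("a", "b"), 15, TRUE), tr$tip.label)
  maps <- stochastic_map(tr, x, n_sim_per_tree = 40, seed = 5)
  out <- tally_simmap(list(trait = maps), tr, breakpoint = 5)
  for (i in seq_along(maps)) {
    transitions <- nrow(maps[[i]]$segments) - nrow(tr$edge)
    shifts <- out$old_shift[i] + out$young_shift[i]
    expect_lte(shifts, transitions)
    if (transitions == 0) expect_equal(shifts, 0)
  }
})

test_that("permutation test: constant character has D = 0 and raw p = 1", {
  tr <- four_tip()
  cm <- make_coded(stats::setNames(rep("A", 4), tr$tip.label))
  pt <- permutation_test(tr, cm, breakpoint = 2, m = 50, seed = 1)
  expect_equal(pt$D_obs, 0)
  expect_equal(pt$p_raw, 1)
})

test_that("a planted old-era signal gives raw p = 0 at m = 1000", {
  # four monomorphic clades: every deep (old) split shifts, no young split
  clade_nwk <- function(tag) sprintf(
    "((%s1:0.5,%s2:0.5):1,((%s3:0.4,%s4:0.4):0.6,(%s5:0.7,%s6:0.7):0.3):0.5)",
    tag, tag, tag, tag, tag, tag)
  # clade crowns at 1.5 Ma; backbone nodes at 6, 5, 4 Ma (all "old")
  tr <- read_timetree(sprintf("((%s:3.5,%s:3.5):1,(%s:2.5,%s:2.5):2);",
                              clade_nwk("a"), clade_nwk("b"),
                              clade_nwk("c"), clade_nwk("d")))
  states <- stats::setNames(
    rep(c("w", "x", "y", "z"), each = 6),
    paste0(rep(c("a", "b", "c", "d"), each = 6), 1:6))
  pt <- permutation_test(tr, make_coded(states), breakpoint = 3, m = 1000,
                         seed = 2)
  # the root split is MPR-ambiguous (either deep state can sit at the
  # root), so 2 of the 3 old splits count as unambiguous shifts
  expect_equal(pt$D_obs, 2 / 3)
  expect_equal(pt$p_raw, 0)
  expect_equal(pt$p_corrected, 1 / 1001)
})

test_that("degenerate bins report NA p-values", {
  tr <- four_tip()
  cm <- make_coded(c(t1 = "A", t2 = "B", t3 = "A", t4 = "B"))
  # breakpoint above the crown: no old splits at all
  pt <- permutation_test(tr, cm, breakpoint = 10, m = 20, seed = 3)
  expect_true(is.na(pt$D_obs) && is.na(pt$p_raw))
})
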