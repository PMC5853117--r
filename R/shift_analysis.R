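# Cross-classification of lineage-splitting events by age bin and by
# inferred character shifts, for parsimony reconstructions (ACCTRAN /
# DELTRAN resolutions) and for stochastic-map histories, plus the
# row-shuffle permutation test of the old-vs-young shift-proportion
# difference D = P_old - P_young.

# internal: age bin for internal nodes. A node exactly at the breakpoint is
# old (the bin is closed on the old side); nodes younger than the exclusion
# age are dropped (NA).
split_bins <- function(ages, breakpoint, exclusion_age) {
  bin <- ifelse(ages >= breakpoint, "old", "young")
  bin[ages < exclusion_age] <- NA
  bin
}

tally_from_shifts <- function(shift, bin) {
  keep <- !is.na(bin)
  old <- keep & bin == "old"; young <- keep & bin == "young"
  c(old_shift = sum(shift[old]), old_total = sum(old),
    young_shift = sum(shift[young]), young_total = sum(young))
}

prop_and_D <- function(counts) {
  p_old <- if (counts[["old_total"]] > 0)
    counts[["old_shift"]] / counts[["old_total"]] else NA_real_
  p_young <- if (counts[["young_total"]] > 0)
    counts[["young_shift"]] / counts[["young_total"]] else NA_real_
  c(p_old = p_old, p_young = p_young, D = p_old - p_young)
}

# default composite: a "host shift" is a shift in host species OR host
# tissue, when both characters are present
default_composite <- function(characters) {
  if (all(c("host_species", "host_tissue") %in% characters))
    list(host_shift = c("host_species", "host_tissue"))
  else list()
}

#' Classify lineage splits by age bin and parsimony-inferred shifts
#'
#' A shift is inferred at an internal node when its two immediate
#' descendants carry different character states: internal descendants
#' contribute their single resolved state (ACCTRAN and DELTRAN tallied
#' separately), tips contribute their coded state set, and "different"
#' means the two descendant sets are disjoint (non-overlapping sets for
#' polymorphic tips). When both `host_species` and `host_tissue` are among
#' the characters, a composite `host_shift` (shift in either) is also
#' tallied.
#'
#' @param tree rooted binary ultrametric `phylo`.
#' @param recs named list (by character) of `parsimony_reconstruction`s.
#' @param breakpoint age separating old from young splits (Ma, default 3);
#'   a node exactly at the breakpoint counts as old.
#' @param exclusion_age drop splits younger than this age (default 0, i.e.
#'   none; 1.0 reproduces an "only splits older than 1 Ma" tally).
#' @param composite named list mapping composite names to character sets
#'   (default: `host_shift` = host species or tissue, when available).
#' @return object of class `split_tally`: `table` (data.frame: resolution,
#'   character, counts, proportions, D) and `nodes` (per-node annotations).
#' @export
classify_splits <- function(tree, recs, breakpoint = 3, exclusion_age = 0,
                            composite = NULL) {
  if (breakpoint <= exclusion_age) stop("breakpoint must exceed exclusion age")
  if (is.null(composite)) composite <- default_composite(names(recs))
  tv <- tree_traversal(tree)
  ages <- node_ages(tree)
  nodes <- tv$internal_post
  bin <- split_bins(ages[nodes], breakpoint, exclusion_age)
  shift_mat <- list()
  for (res in c("acctran", "deltran")) {
    for (ch_name in names(recs)) {
      rec <- recs[[ch_name]]
      resolved <- rec[[res]]
      dstate <- function(v) {
        if (v <= tv$ntip) rec$mpr[[v]] else resolved[v]
      }
      shift_mat[[paste(res, ch_name)]] <- vapply(nodes, function(v) {
        d <- tv$kids[[v]]
        length(intersect(dstate(d[1L]), dstate(d[2L]))) == 0L
      }, TRUE)
    }
    for (cn in names(composite)) {
      members <- paste(res, composite[[cn]])
      shift_mat[[paste(res, cn)]] <-
        Reduce(`|`, shift_mat[members])
    }
  }
  tab <- do.call(rbind, lapply(names(shift_mat), function(nm) {
    counts <- tally_from_shifts(shift_mat[[nm]], bin)
    parts <- strsplit(nm, " ", fixed = TRUE)[[1L]]
    data.frame(resolution = parts[1L], character = parts[2L],
               t(counts), t(prop_and_D(counts)))
  }))
  node_df <- data.frame(node = nodes, age = ages[nodes], bin = bin)
  for (nm in names(shift_mat)) node_df[[gsub(" ", ".", nm)]] <- shift_mat[[nm]]
  structure(list(table = tab, nodes = node_df, breakpoint = breakpoint,
                 exclusion_age = exclusion_age), class = "split_tally")
}

#' @export
print.split_tally <- function(x, ...) {
  cat("Split tally (breakpoint", x$breakpoint, "Ma)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tally shifts across stochastic-map histories
#'
#' For each history and each internal node, the state of each descendant
#' branch is read at its *end* (immediately before that branch's own split,
#' or the sampled tip state), so multiple transitions along a branch count
#' as at most one shift. Returns the per-history tally distribution
#' (boxplot-ready). When maps for several characters are supplied, a
#' composite is tallied by pairing histories with the same (tree, sim)
#' index.
#'
#' @param maps a `simmap_set`, or a named list of them (one per character).
#' @param trees the tree list the maps were generated from.
#' @param breakpoint,exclusion_age,composite as in [classify_splits()].
#' @return data.frame: tree, sim, character, counts, p_old, p_young, D.
#' @export
tally_simmap <- function(maps, trees, breakpoint = 3, exclusion_age = 0,
                         composite = NULL) {
  if (inherits(maps, "simmap_set")) maps <- list(character = maps)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(composite)) composite <- default_composite(names(maps))
  # per-tree geometry
  geom <- lapply(trees, function(tr) {
    tv <- tree_traversal(tr)
    ages <- node_ages(tr)
    nodes <- tv$internal_post
    list(tv = tv, nodes = nodes,
         bin = split_bins(ages[nodes], breakpoint, exclusion_age))
  })
  # end-state of every branch, per history: last segment of each edge
  end_states <- function(h, tv) {
    segs <- h$segments
    last <- !duplicated(segs$edge, fromLast = TRUE)
    st <- character(tv$nn)
    st[segs$child[last]] <- segs$state[last]
    st
  }
  shift_vec <- function(h, g) {
    es <- end_states(h, g$tv)
    vapply(g$nodes, function(v) {
      d <- g$tv$kids[[v]]
      es[d[1L]] != es[d[2L]]
    }, TRUE)
  }
  per_char <- lapply(maps, function(ms) lapply(ms, function(h)
    c(list(tree = h$tree_index, sim = h$sim_index),
      list(shift = shift_vec(h, geom[[h$tree_index]])))))
  keys <- lapply(per_char[[1L]], function(x) c(x$tree, x$sim))
  rows <- list()
  for (i in seq_along(keys)) {
    tr <- keys[[i]][1L]; si <- keys[[i]][2L]
    g <- geom[[tr]]
    shifts <- lapply(per_char, function(pc) pc[[i]]$shift)
    for (cn in names(composite))
      shifts[[cn]] <- Reduce(`|`, shifts[composite[[cn]]])
    for (nm in names(shifts)) {
      counts <- tally_from_shifts(shifts[[nm]], g$bin)
      rows[[length(rows) + 1L]] <- data.frame(
        tree = tr, sim = si, character = nm, t(counts),
        t(prop_and_D(counts)))
    }
  }
  do.call(rbind, rows)
}

# internal: Fitch MPR shift indicators for a batch of tip-state columns.
# States are bitmasks (one bit per state, <= 30 states). Downpass is the
# classic Fitch intersection/union; the uppass computes the MPR set of each
# internal node (Swofford & Maddison rules); a shift at a node means the
# MPR sets (tip states for tips) of its two children are disjoint. Checked
# against the Sankoff down/up route in the test suite.
# tip_masks: ntip x B integer matrix; returns n_internal x B logical,
# rows in tv$internal_post order.
fitch_shift_matrix <- function(tv, tip_masks) {
  nn <- tv$nn; B <- ncol(tip_masks)
  down <- matrix(0L, nn, B)
  down[seq_len(tv$ntip), ] <- tip_masks
  for (v in tv$internal_post) {
    d <- tv$kids[[v]]
    a <- bitwAnd(down[d[1L], ], down[d[2L], ])
    u <- bitwOr(down[d[1L], ], down[d[2L], ])
    down[v, ] <- ifelse(a != 0L, a, u)
  }
  fin <- matrix(0L, nn, B)
  fin[tv$root, ] <- down[tv$root, ]
  fin[seq_len(tv$ntip), ] <- tip_masks
  for (v in tv$internal_pre) {
    d <- tv$kids[[v]]
    sl <- down[d[1L], ]; sr <- down[d[2L], ]
    for (ch in d) {
      if (ch <= tv$ntip) next
      fp <- fin[v, ]; sv <- down[ch, ]
      cl <- down[tv$kids[[ch]][1L], ]; cr <- down[tv$kids[[ch]][2L], ]
      contains <- bitwAnd(fp, sv) == fp          # S(v) superset of F(p)
      was_intersection <- bitwAnd(cl, cr) != 0L
      fin[ch, ] <- ifelse(contains, fp,
                   ifelse(was_intersection,
                          bitwOr(sv, bitwAnd(fp, bitwOr(cl, cr))),
                          bitwOr(sv, fp)))
    }
  }
  shifts <- matrix(FALSE, length(tv$internal_post), B)
  for (i in seq_along(tv$internal_post)) {
    d <- tv$kids[[tv$internal_post[i]]]
    shifts[i, ] <- bitwAnd(fin[d[1L], ], fin[d[2L], ]) == 0L
  }
  shifts
}

# D = P_old - P_young for each column of a batch of (possibly composite)
# shift indicator matrices
batch_D <- function(shifts, bin) {
  old <- !is.na(bin) & bin == "old"; young <- !is.na(bin) & bin == "young"
  if (!any(old) || !any(young)) return(rep(NA_real_, ncol(shifts)))
  colSums(shifts[old, , drop = FALSE]) / sum(old) -
    colSums(shifts[young, , drop = FALSE]) / sum(young)
}

#' Permutation test of the old-vs-young shift-proportion difference
#'
#' The observed statistic is `D = P_old - P_young`, the difference in the
#' proportion of splits accompanied by a character shift before versus
#' after the breakpoint, computed from an MPR parsimony reconstruction of a
#' simplified (singleton-state) matrix: a split counts as a shift only when
#' the two descendant MPR sets (tip states for tips) are disjoint. Each of
#' the `m` permutations shuffles the tip-to-row assignment uniformly
#' (jointly across characters, preserving their correlation) and recomputes
#' D; the one-tailed upper p-value is reported both raw (`b/m`, matching a
#' reported "p = 0") and corrected (`(b+1)/(m+1)`).
#'
#' When several characters are supplied the statistic uses the composite
#' shift (a shift in any character), matching the host-or-tissue host-shift
#' definition; pass a single character for single-character mode.
#'
#' @param tree rooted binary ultrametric `phylo`.
#' @param coded a simplified `coded_matrix` or named list of them.
#' @param breakpoint,exclusion_age as in [classify_splits()].
#' @param m number of permutations (default 1000).
#' @param seed optional integer.
#' @return object of class `permutation_result`: `D_obs`, `null` (length
#'   m), `p_raw`, `p_corrected`, `m`.
#' @export
permutation_test <- function(tree, coded, breakpoint = 3, exclusion_age = 0,
                             m = 1000, seed = NULL) {
  if (inherits(coded, "coded_matrix")) coded <- list(coded)
  if (!is.null(seed)) set.seed(seed)
  tv <- tree_traversal(tree)
  if (any(lengths(tv$kids[tv$internal_post]) != 2L))
    stop("permutation test requires a strictly binary tree")
  ages <- node_ages(tree)
  bin <- split_bins(ages[tv$internal_post], breakpoint, exclusion_age)
  tip_masks <- lapply(coded, function(cm) {
    st <- cm$states
    if (any(lengths(st) != 1L))
      stop("permutation test needs singleton (simplified) tip states")
    alphabet <- sort(unique(unlist(st)))
    if (length(alphabet) > 30L) stop("more than 30 states")
    vapply(tree$tip.label, function(lb)
      bitwShiftL(1L, match(st[[lb]], alphabet) - 1L), 0L)
  })
  # column 1 = observed; columns 2..m+1 = joint row shuffles
  perms <- cbind(seq_len(tv$ntip),
                 replicate(m, sample.int(tv$ntip)))
  shifts <- NULL
  for (masks in tip_masks) {
    cols <- matrix(masks[perms], tv$ntip, m + 1L)
    sh <- fitch_shift_matrix(tv, cols)
    shifts <- if (is.null(shifts)) sh else shifts | sh
  }
  D <- batch_D(shifts, bin)
  D_obs <- D[1L]; null <- D[-1L]
  if (is.na(D_obs)) {
    return(structure(list(D_obs = NA_real_, null = null,
                          p_raw = NA_real_, p_corrected = NA_real_, m = m),
                     class = "permutation_result"))
  }
  b <- sum(null >= D_obs)
  structure(list(D_obs = D_obs, null = null, p_raw = b / m,
                 p_corrected = (b + 1) / (m + 1), m = m),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: D = %.4f, raw p = %.4g, corrected p = %.4g (m = %d)\n",
    x$D_obs, x$p_raw, x$p_corrected, x$m))
  invisible(x)
}
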