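# Unordered (Fitch) parsimony on a binary tree with set-valued tips:
# most-parsimonious-reconstruction (MPR) state sets via a Sankoff-style
# down/up dynamic program with unit costs, and deterministic ACCTRAN /
# DELTRAN resolutions of ambiguous nodes. Polymorphic tips satisfy any of
# their member states at no cost.

# internal: orderings and children lists shared by the parsimony and Mk code
tree_traversal <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  kids <- vector("list", nn)
  for (i in seq_len(nrow(post$edge)))
    kids[[post$edge[i, 1]]] <- c(kids[[post$edge[i, 1]]], post$edge[i, 2])
  internal_post <- unique(post$edge[, 1])          # children-first order
  edge_of <- integer(nn)                           # edge index into tree$edge
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  list(ntip = ntip, nn = nn, root = ntip + 1L, kids = kids,
       internal_post = internal_post,
       internal_pre = rev(internal_post), edge_of = edge_of)
}

# internal: unit-cost Sankoff down/up passes. tip_idx is a list (one entry
# per tip, in tip-number order) of allowed state indices in 1..k. Returns
# down[v,s] (changes within v's subtree given v = s), up[v,s] (changes in
# the rest of the tree), and the tree length.
sankoff_passes <- function(tv, tip_idx, k) {
  nn <- tv$nn
  INF <- nn + 10
  down <- matrix(INF, nn, k)
  for (i in seq_len(tv$ntip)) down[i, tip_idx[[i]]] <- 0
  for (v in tv$internal_post) {
    acc <- 0
    for (ch in tv$kids[[v]])
      acc <- acc + pmin(down[ch, ], min(down[ch, ]) + 1)
    down[v, ] <- acc
  }
  up <- matrix(0, nn, k)
  for (v in tv$internal_pre) {
    ch <- tv$kids[[v]]
    contrib <- lapply(ch, function(w) pmin(down[w, ], min(down[w, ]) + 1))
    for (j in seq_along(ch)) {
      w <- ch[[j]]
      other <- up[v, ]
      for (l in seq_along(ch)) if (l != j) other <- other + contrib[[l]]
      up[w, ] <- pmin(other, min(other) + 1)   # min over parent state + step
    }
  }
  list(down = down, up = up, length = min(down[tv$root, ]))
}

#' Fitch parsimony reconstruction with ACCTRAN/DELTRAN resolution
#'
#' Computes, for an unordered character on a rooted binary tree: the
#' parsimony tree length (minimum number of state changes), the MPR state
#' set of every internal node (states occurring in at least one
#' most-parsimonious reconstruction), and two deterministic single-state
#' resolutions of ambiguity: ACCTRAN (changes placed as early as possible,
#' toward the root) and DELTRAN (as late as possible, toward the tips).
#' Both resolutions realize exactly the MPR tree length. Set-valued
#' (polymorphic) tips may be explained by any member state at no cost.
#'
#' @param tree rooted binary `phylo`.
#' @param coded a `coded_matrix` (or a named list mapping tip label to a
#'   character vector of states).
#' @return object of class `parsimony_reconstruction`: `length` (steps),
#'   `mpr` (list over nodes 1..Ntip+Nnode; tips keep their coded sets),
#'   `acctran`, `deltran` (character vectors over all nodes), `alphabet`.
#' @export
parsimony_reconstruct <- function(tree, coded) {
  states_by_tip <- if (inherits(coded, "coded_matrix")) coded$states else coded
  miss <- setdiff(tree$tip.label, names(states_by_tip))
  if (length(miss)) stop("tips missing from matrix: ",
                         paste(miss, collapse = ", "))
  tv <- tree_traversal(tree)
  if (any(lengths(tv$kids[tv$internal_post]) != 2L))
    stop("parsimony reconstruction requires a strictly binary tree")
  alphabet <- sort(unique(unlist(states_by_tip[tree$tip.label])))
  k <- length(alphabet)
  nn <- tv$nn
  tip_idx <- lapply(tree$tip.label, function(lb)
    match(states_by_tip[[lb]], alphabet))
  sk <- sankoff_passes(tv, tip_idx, k)
  down <- sk$down; up <- sk$up; tree_length <- sk$length
  total <- down + up
  mpr <- lapply(seq_len(nn), function(v) alphabet[total[v, ] <= tree_length])
  for (i in seq_len(tv$ntip))                       # tips keep coded sets
    mpr[[i]] <- sort(states_by_tip[[tree$tip.label[i]]])
  resolve <- function(prefer_change) {
    res <- character(nn)
    root_set <- which(down[tv$root, ] == tree_length)
    res[tv$root] <- alphabet[root_set[1L]]          # lexicographic (sorted)
    for (v in tv$internal_pre) {
      f <- match(res[v], alphabet)
      for (w in tv$kids[[v]]) {
        sc <- down[w, ] + as.numeric(seq_len(k) != f)
        cand <- which(sc == min(sc))
        pick <- if (prefer_change && any(cand != f)) cand[cand != f][1L]
                else if (!prefer_change && f %in% cand) f
                else cand[1L]
        res[w] <- alphabet[pick]
      }
    }
    res
  }
  structure(list(length = tree_length, mpr = mpr,
                 acctran = resolve(TRUE), deltran = resolve(FALSE),
                 alphabet = alphabet),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat("Parsimony reconstruction:", x$length, "steps over",
      length(x$alphabet), "states\n")
  invisible(x)
}

#' Write a parsimony reconstruction to TSV
#'
#' Columns: node (ape index), mpr ("A|B"), acctran, deltran.
#'
#' @param rec a `parsimony_reconstruction`.
#' @param tree the tree it was computed on.
#' @param path output TSV path.
#' @export
write_reconstruction <- function(rec, tree, path) {
  nn <- length(rec$mpr)
  df <- data.frame(node = seq_len(nn),
                   label = c(tree$tip.label, rep("", tree$Nnode)),
                   mpr = vapply(rec$mpr, paste, "", collapse = "|"),
                   acctran = rec$acctran, deltran = rec$deltran)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
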