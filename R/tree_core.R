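# Time-scaled tree model: an ape "phylo" validated to be rooted and
# ultrametric, with node ages (time before present, Ma) as the primary
# temporal coordinate. Branch lengths are derived: parent age - child age.

#' Node ages of a time tree
#'
#' Ages are measured backwards from the present (tips at 0) in the same
#' units as the branch lengths (Ma throughout this package).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed like ape node
#'   numbers (tips first).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Validate (and normalize) a time tree
#'
#' Checks that the tree is rooted, has branch lengths and tip labels, and is
#' ultrametric within `tol`. Tip ages within `tol` of zero are snapped to
#' zero exactly by adjusting terminal branch lengths. Larger deviations are
#' an error unless `force_ultrametric = TRUE`, in which case every terminal
#' branch is extended so all tips reach the maximum root-to-tip depth
#' (useful for consensus trees with median branch lengths).
#'
#' @param tree a `phylo`.
#' @param tol ultrametricity tolerance in age units (default 1e-6).
#' @param force_ultrametric extend short tips instead of erroring.
#' @return the normalized `phylo`.
#' @export
validate_timetree <- function(tree, tol = 1e-6, force_ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(tree$tip.label) || anyNA(tree$tip.label) ||
      any(!nzchar(tree$tip.label)))
    stop("tree has missing or empty tip labels")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (ape::Ntip(tree) < 2L) stop("need at least 2 tips")
  if (any(tree$edge.length < -tol)) stop("negative branch lengths")
  tree$edge.length[tree$edge.length < 0] <- 0
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  tdepth <- depth[seq_len(ntip)]
  dev <- max(tdepth) - tdepth
  if (any(dev > tol) && !force_ultrametric)
    stop("tree is not ultrametric (max tip-age deviation ",
         format(max(dev)), "); use force_ultrametric = TRUE to extend tips")
  # snap every tip onto the present line by stretching its terminal branch
  term <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + dev
  ages <- node_ages(tree)
  if (any(ages[tree$edge[, 1]] - ages[tree$edge[, 2]] < -tol))
    stop("child older than parent after normalization")
  tree
}

#' Read a time tree
#'
#' @param source a file path, or a character string holding the tree text.
#' @param format `"newick"` or `"nexus"`.
#' @param tol,force_ultrametric passed to [validate_timetree()].
#' @return a validated `phylo`.
#' @export
read_timetree <- function(source, format = c("newick", "nexus"),
                          tol = 1e-6, force_ultrametric = FALSE) {
  trees <- read_timetree_set(source, format, tol, force_ultrametric)
  if (length(trees) != 1L) stop("expected exactly one tree, found ",
                                length(trees))
  trees[[1L]]
}

#' Read a set of time trees (one Newick per line, or a NEXUS TREES block)
#'
#' @inheritParams read_timetree
#' @return a `multiPhylo` list of validated trees.
#' @export
read_timetree_set <- function(source, format = c("newick", "nexus"),
                              tol = 1e-6, force_ultrametric = FALSE) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("[(;]", source) &&
    file.exists(source)
  if (format == "newick") {
    trees <- if (is_path) ape::read.tree(source)
             else ape::read.tree(text = paste(source, collapse = "\n"))
  } else {
    if (!is_path) {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf))
      writeLines(source, tf)
      source <- tf
    }
    trees <- ape::read.nexus(source)
  }
  if (is.null(trees)) stop("no tree could be parsed")
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- lapply(trees, validate_timetree, tol = tol,
                force_ultrametric = force_ultrametric)
  class(out) <- "multiPhylo"
  out
}

#' Write a tree (or tree set) to Newick or NEXUS
#'
#' @param tree a `phylo` or `multiPhylo`.
#' @param path output file; if `NULL`, the serialized text is returned.
#' @param format `"newick"` or `"nexus"`.
#' @export
write_timetree <- function(tree, path = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick") {
    txt <- ape::write.tree(tree)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
  } else {
    if (is.null(path)) {
      path <- tempfile(fileext = ".nex")
      on.exit(unlink(path))
      ape::write.nexus(tree, file = path)
      return(readLines(path))
    }
    ape::write.nexus(tree, file = path)
  }
  invisible(path)
}

#' Branching profile (lineage-through-time summary) of a time tree
#'
#' Collects the ordered branching times `b_1 > b_2 > ... > b_{n-1}` (node
#' ages above `cut_age`, re-expressed relative to the cut line), the
#' internode intervals `g_k` during which exactly `k` lineages exist (the
#' last interval `g_n` runs from the final split down to the cut line), and
#' the cumulative weighted sums `T_i = sum_{k=2..i} k * g_k` used by the
#' gamma statistic and the branching-time likelihoods.
#'
#' Simultaneous branching times are ordered deterministically (ties broken
#' by preorder index), which leaves all derived quantities unchanged.
#'
#' @param tree a validated ultrametric `phylo`.
#' @param cut_age measure the profile down to this age (Ma; default 0, the
#'   present). Only splits strictly older than `cut_age` count.
#' @return an object of class `ltt_profile`: list with `n` (lineages at the
#'   cut line), `btimes` (descending, relative to the cut line), `g`
#'   (named `g2..gn`), `Tcum` (cumulative `T_i`, `i = 2..n`) and `Ttot`.
#' @export
branching_profile <- function(tree, cut_age = 0) {
  tree <- validate_timetree(tree)
  if (tree$Nnode != ape::Ntip(tree) - 1L)
    stop("branching profile requires a strictly binary tree ",
         "(multifurcations are accepted for I/O only)")
  ages <- node_ages(tree)
  node_idx <- ape::Ntip(tree) + seq_len(tree$Nnode)
  b <- ages[node_idx] - cut_age
  pre <- preorder_index(tree)[node_idx]
  b <- b[order(-b, pre)]
  b <- b[b > 1e-12]
  n <- length(b) + 1L
  if (n < 3L) stop("fewer than 2 splits above the cut line")
  g <- c(-diff(b), b[length(b)])          # g_2 ... g_n
  k <- seq.int(2L, n)
  Tcum <- cumsum(k * g)
  structure(list(n = n, btimes = b, g = stats::setNames(g, paste0("g", k)),
                 Tcum = stats::setNames(Tcum, paste0("T", k)),
                 Ttot = Tcum[[length(Tcum)]], cut_age = cut_age),
            class = "ltt_profile")
}

#' @export
print.ltt_profile <- function(x, ...) {
  cat("Branching profile:", x$n, "lineages at cut line (cut_age =",
      x$cut_age, "Ma), crown age", format(x$btimes[1]), "\n")
  invisible(x)
}

#' Lineage-through-time step coordinates
#'
#' @param tree a validated ultrametric `phylo`.
#' @return data.frame with `time` (age before present, descending to 0) and
#'   `lineages`, suitable for a step plot or TSV export.
#' @export
ltt_coords <- function(tree) {
  p <- branching_profile(tree)
  data.frame(time = c(p$btimes, 0), lineages = c(seq.int(2L, p$n), p$n))
}

#' Truncate a time tree at an age line
#'
#' Every branch crossing the `age` line becomes a tip at that line and the
#' tree is re-zeroed so those tips sit at the present (the classic "remove
#' lineages younger than the cutoff, then shorten terminal branches by the
#' cutoff" operation). A node sitting exactly on the line is kept (as a
#' tip). New tip labels are the lexicographically smallest descendant tip
#' label of the truncated branch.
#'
#' @param tree a validated ultrametric `phylo`.
#' @param age cutoff age in Ma (> 0 truncates; 0 returns the tree unchanged).
#' @return a validated ultrametric `phylo` whose tip count equals the number
#'   of lineages crossing the age line.
#' @export
truncate_tree <- function(tree, age = 1.0) {
  tree <- validate_timetree(tree)
  if (age < 0) stop("age must be >= 0")
  if (age == 0) return(tree)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  if (age >= ages[root]) stop("age >= crown age: fewer than 2 lineages cross")
  keep <- which(ages > age)                       # internal nodes kept
  keep <- keep[keep > ntip]
  reps <- representative_labels(tree)
  # crossing branches: parent kept, child not (child age <= age)
  cross <- which(tree$edge[, 1] %in% keep & !(tree$edge[, 2] %in% keep))
  n_new <- length(cross)
  new_id <- integer(ntip + tree$Nnode)
  new_id[keep] <- n_new + seq_along(keep)         # internal nodes after tips
  new_id[tree$edge[cross, 2]] <- seq_len(n_new)   # crossing child -> new tip
  in_edges <- which(tree$edge[, 1] %in% keep)
  edge <- cbind(new_id[tree$edge[in_edges, 1]], new_id[tree$edge[in_edges, 2]])
  parent_age <- ages[tree$edge[in_edges, 1]]
  child_age <- pmax(ages[tree$edge[in_edges, 2]], age)
  out <- list(edge = edge, edge.length = parent_age - child_age,
              tip.label = reps[tree$edge[cross, 2]],
              Nnode = length(keep))
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validate_timetree(out)
}

#' Extract a monophyletic clade as a subtree
#'
#' @param tree a validated ultrametric `phylo`.
#' @param tips character vector of tip labels; must be exactly the tip set
#'   of one clade of the tree.
#' @return the subtree rooted at the MRCA of `tips`, ages preserved.
#' @export
extract_clade <- function(tree, tips) {
  tree <- validate_timetree(tree)
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) < 2L) stop("need at least 2 tips")
  mrca <- ape::getMRCA(tree, tips)
  clade_tips <- tree$tip.label[unlist(prop_part_tips(tree, mrca))]
  if (!setequal(clade_tips, tips))
    stop("tip set is not monophyletic (clade of their MRCA also contains: ",
         paste(setdiff(clade_tips, tips), collapse = ", "), ")")
  validate_timetree(ape::extract.clade(tree, mrca))
}

#' Randomly prune tips from a tree
#'
#' Removes `k` uniformly chosen tips; unifurcations left behind are
#' collapsed with branch lengths summed (ape's standard behaviour), so the
#' result is again ultrametric.
#'
#' @param tree a validated ultrametric `phylo`.
#' @param k number of tips to drop (`0 <= k <= Ntip - 3`).
#' @param seed optional integer; if given, sampling is reproducible.
#' @return the pruned `phylo`.
#' @export
prune_random_tips <- function(tree, k, seed = NULL) {
  tree <- validate_timetree(tree)
  n <- ape::Ntip(tree)
  if (k < 0 || k > n - 3L) stop("k must be in [0, Ntip - 3]")
  if (k == 0) return(tree)
  if (!is.null(seed)) set.seed(seed)
  drop <- sample(tree$tip.label, k)
  validate_timetree(ape::drop.tip(tree, drop))
}

# ---- internal helpers -------------------------------------------------

# preorder rank of every node (root = 1); deterministic tie-break key
preorder_index <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  idx <- integer(ape::Ntip(tree) + tree$Nnode)
  root <- ape::Ntip(tree) + 1L
  ord <- c(root, tree$edge[, 2])
  idx[ord] <- seq_along(ord)
  idx
}

# tips descending from an internal node (list of tip indices)
prop_part_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(list(node))
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  list(unlist(lapply(kids, function(k) prop_part_tips(tree, k)[[1L]])))
}

# lexicographically smallest descendant tip label for every node
representative_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  reps <- character(ntip + tree$Nnode)
  reps[seq_len(ntip)] <- tree$tip.label
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    if (!nzchar(reps[p]) || reps[ch] < reps[p]) reps[p] <- reps[ch]
  }
  reps
}
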