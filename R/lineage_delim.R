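# Haplotype-lineage delimitation from an mtCOI alignment: raw pairwise
# difference counts, a neighbor-joining guide tree, the minimum-difference
# monophyletic partition rule (with the ancestral-haplotype paraphyly
# rules), single-linkage species clustering, and medoid exemplar selection.

#' Read a FASTA alignment into a character matrix
#'
#' @param path FASTA file.
#' @return matrix of single upper-case characters, rows named by sequence id.
#' @export
read_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(seqs)))
  if (is.null(dim(m))) stop("sequences are not aligned (unequal lengths)")
  m
}

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    if (is.null(names(aln))) stop("sequences must be named")
    L <- unique(nchar(aln))
    if (length(L) != 1L) stop("sequences differ in length")
    if (L == 0L) stop("empty alignment")
    m <- toupper(do.call(rbind, strsplit(unlist(aln), "")))
    rownames(m) <- names(aln)
  }
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  m
}

#' Raw pairwise difference counts
#'
#' For each pair, `N` counts alignment columns where both sequences carry an
#' unambiguous non-gap base (A/C/G/T) and the bases differ; `comparable`
#' counts columns where both are unambiguous non-gap. The proportional
#' distance is `N / comparable`.
#'
#' @param aln named character vector of aligned sequences, or a character
#'   matrix (rows = sequences).
#' @return list of class `raw_distances`: integer matrices `N` and
#'   `comparable`, numeric matrix `prop`, and `L` (alignment length).
#' @export
raw_distances <- function(aln) {
  m <- as_aln_matrix(aln)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow(m))
  if (any(rowSums(ok) == 0)) stop("sequence with no unambiguous bases")
  # comparable = columns unambiguous in both; matches counted per base
  comp <- tcrossprod(ok * 1L)
  same <- Reduce(`+`, lapply(c("A", "C", "G", "T"), function(b)
    tcrossprod((m == b & ok) * 1L)))
  N <- comp - same
  diag(N) <- 0L
  storage.mode(N) <- "integer"; storage.mode(comp) <- "integer"
  dimnames(N) <- dimnames(comp) <- list(rownames(m), rownames(m))
  structure(list(N = N, comparable = comp, prop = ifelse(comp > 0, N / comp, 0),
                 L = ncol(m)), class = "raw_distances")
}

#' Neighbor-joining guide tree
#'
#' Standard Saitou-Nei agglomeration on the proportional distance matrix.
#' Ties in the Q matrix are broken by the smallest (row, column) index pair;
#' negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch. The unrooted NJ tree is rooted on the designated
#' outgroup for downstream monophyly assessment.
#'
#' @param d a `raw_distances` object or a symmetric numeric matrix with
#'   dimnames.
#' @param outgroup sequence id used to root the tree (required).
#' @return a rooted `phylo` guide tree (not ultrametric).
#' @export
neighbor_joining <- function(d, outgroup) {
  D <- if (inherits(d, "raw_distances")) d$prop else as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("NJ needs at least 3 sequences")
  if (missing(outgroup) || !outgroup %in% rownames(D))
    stop("an outgroup sequence id present in the matrix is required")
  labels <- rownames(D)
  # active "node" for each cluster: tip indices 1..n, internals allocated up
  nodes <- seq_len(n)
  next_node <- n + 1L
  edge <- matrix(0L, 2L * n, 2L); elen <- numeric(2L * n); ne <- 0L
  add_edge <- function(p, ch, l) {
    ne <<- ne + 1L; edge[ne, ] <<- c(p, ch); elen[ne] <<- l
  }
  act <- seq_len(n)                      # indices into D rows still active
  while (length(act) > 2L) {
    m <- length(act)
    Dm <- D[act, act, drop = FALSE]
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # smallest index pair among minima
    idx <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1L, ]
    i <- idx[1L]; j <- idx[2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- dij - li
    # clamp negatives, moving the deficit to the sibling branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    lj <- max(lj, 0)
    new <- next_node; next_node <- next_node + 1L
    add_edge(new, nodes[act[i]], li)
    add_edge(new, nodes[act[j]], lj)
    # distances from the new cluster to the rest
    rest <- act[-c(i, j)]
    dnew <- (D[act[i], rest] + D[act[j], rest] - dij) / 2
    D[act[i], rest] <- dnew; D[rest, act[i]] <- dnew
    nodes[act[i]] <- new
    act <- c(act[i], rest)
  }
  # join the last two clusters through a final internal node
  root <- next_node
  dfin <- D[act[1L], act[2L]]
  add_edge(root, nodes[act[1L]], dfin / 2)
  add_edge(root, nodes[act[2L]], dfin / 2)
  edge <- edge[seq_len(ne), , drop = FALSE]
  # renumber internals to ape convention: root = Ntip + 1, rest sequential
  internals <- seq.int(n + 1L, root)
  remap <- integer(root)
  remap[seq_len(n)] <- seq_len(n)
  remap[rev(internals)] <- n + seq_along(internals)
  edge[] <- remap[edge]
  out <- list(edge = edge, edge.length = pmax(elen[seq_len(ne)], 0),
              tip.label = labels, Nnode = root - n)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  ape::root(out, outgroup = outgroup, resolve.root = TRUE)
}

# connected components of an undirected adjacency matrix (logical)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Delimit haplotype lineages
#'
#' Produces the finest partition of sequences into guide-tree-monophyletic
#' groups such that every between-group pair of sequences differs by at
#' least `min_diff` raw substitutions. Pairs closer than `min_diff` are
#' first chained into components; each component is then closed to
#' monophyly on the rooted guide tree (overlapping clades merged).
#'
#' Paraphyly rule for ancestral haplotypes: if a component is held together
#' only by one haplotype (a set of identical sequences) whose removal
#' splits it into parts that are all pairwise `>= min_diff` apart — the
#' signature of a surviving ancestral haplotype interior to divergent
#' descendant groups — then the ancestral haplotype is excluded from the
#' partition (lineage `NA`) when it carries at most `max_ancestor_specimens`
#' specimens; otherwise ancestor and descendants are combined into one
#' lineage.
#'
#' @param guide rooted guide tree (tip labels = sequence ids), e.g. from
#'   [neighbor_joining()]; outgroup tips absent from `d` are ignored.
#' @param d a `raw_distances` object.
#' @param specimen_counts named integer vector: specimens represented by
#'   each sequence (defaults to 1 each).
#' @param min_diff minimum between-lineage raw difference count (default 3).
#' @param max_ancestor_specimens exclusion threshold for ancestral
#'   haplotypes (default 3).
#' @return list of class `lineage_partition`: `lineage` (named integer,
#'   `NA` = excluded ancestral haplotype), `members` (list per lineage).
#' @export
delimit_lineages <- function(guide, d, specimen_counts = NULL, min_diff = 3L,
                             max_ancestor_specimens = 3L) {
  if (!inherits(d, "raw_distances")) stop("d must come from raw_distances()")
  if (min_diff < 1L) stop("min_diff must be >= 1")
  if (!ape::is.rooted(guide)) stop("guide tree must be rooted")
  ids <- rownames(d$N)
  if (is.null(specimen_counts)) specimen_counts <- stats::setNames(
    rep(1L, length(ids)), ids)
  close_adj <- d$N < min_diff
  diag(close_adj) <- FALSE
  excluded <- character(0)
  sealed <- character(0)       # components already resolved as "combined"
  repeat {
    act <- setdiff(ids, excluded)
    adj <- close_adj[act, act, drop = FALSE]
    comp <- components_of(adj)
    res <- find_ancestral_cut(act, comp, d$N[act, act, drop = FALSE],
                              min_diff, specimen_counts,
                              max_ancestor_specimens, sealed)
    if (is.null(res)) break
    if (res$exclude) excluded <- c(excluded, res$haplotype)
    else sealed <- c(sealed, res$component_key)
  }
  groups <- split(act, comp)
  groups <- monophyly_closure(groups, guide)
  groups <- groups[order(vapply(groups, min, ""))]
  lin <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(groups)) lin[groups[[i]]] <- i
  structure(list(lineage = lin, members = stats::setNames(
    groups, seq_along(groups)), excluded = excluded,
    min_diff = min_diff), class = "lineage_partition")
}

# inspect each unresolved component for an ancestral-haplotype paraphyly
# signature: a haplotype (identical-sequence group) whose removal splits
# the component into >= 2 parts that are pairwise >= min_diff apart while
# the haplotype itself sits within min_diff of several of them. Among the
# qualifying haplotypes the most central one (minimal total distance to the
# component, then lexicographic) is taken to be the surviving ancestor.
# Returns NULL when every component is resolved, otherwise the decision for
# the first affected component: exclude a rare ancestor, or seal the
# component (ancestor + descendants combined into one lineage).
find_ancestral_cut <- function(act, comp, N, min_diff, specimen_counts,
                               max_ancestor_specimens, sealed) {
  for (cc in sort(unique(comp))) {
    mem <- act[comp == cc]
    if (length(mem) < 3L) next
    key <- paste(sort(mem), collapse = "|")
    if (key %in% sealed) next
    # haplotypes = groups of identical sequences within the component
    hap <- components_of(N[mem, mem, drop = FALSE] == 0L &
                           !diag(length(mem)))
    cands <- list()
    for (h in sort(unique(hap))) {
      hseq <- mem[hap == h]
      rest <- mem[hap != h]
      if (length(rest) < 2L) next
      sub <- N[rest, rest, drop = FALSE] < min_diff
      diag(sub) <- FALSE
      parts <- components_of(sub)
      if (max(parts) < 2L) next
      # cross-part pairs are >= min_diff by construction; the ancestor
      # must connect at least two of the parts
      touch <- unique(parts[colSums(N[hseq, rest, drop = FALSE] < min_diff,
                                    na.rm = TRUE) > 0])
      if (length(touch) < 2L) next
      cands[[length(cands) + 1L]] <- hseq
    }
    if (!length(cands)) next
    centrality <- vapply(cands, function(hseq)
      sum(N[hseq, setdiff(mem, hseq), drop = FALSE]) / length(hseq), 0)
    first_id <- vapply(cands, function(hseq) sort(hseq)[1L], "")
    hub <- cands[[order(centrality, first_id)[1L]]]
    if (sum(specimen_counts[hub]) <= max_ancestor_specimens)
      return(list(exclude = TRUE, haplotype = hub))
    return(list(exclude = FALSE, component_key = key))
  }
  NULL
}

# merge groups until each is monophyletic on the guide tree (restricted to
# the sequences under consideration) and no two clades overlap
monophyly_closure <- function(groups, guide) {
  all_ids <- unlist(groups)
  keep <- intersect(guide$tip.label, all_ids)
  gt <- if (length(keep) < ape::Ntip(guide))
    ape::keep.tip(guide, keep) else guide
  repeat {
    closed <- lapply(groups, function(g) {
      if (length(g) < 2L) return(g)
      mrca <- ape::getMRCA(gt, g)
      gt$tip.label[unlist(prop_part_tips(gt, mrca))]
    })
    merged <- FALSE
    i <- 1L
    while (i < length(closed)) {
      j <- i + 1L
      while (j <= length(closed)) {
        if (length(intersect(closed[[i]], closed[[j]]))) {
          groups[[i]] <- union(groups[[i]], groups[[j]])
          closed[[i]] <- union(closed[[i]], closed[[j]])
          groups[[j]] <- NULL; closed[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    expanded <- any(vapply(seq_along(groups), function(k)
      length(setdiff(closed[[k]], groups[[k]])) > 0, TRUE))
    groups <- closed
    if (!merged && !expanded) break
  }
  groups
}

#' Single-linkage species clusters at a divergence threshold
#'
#' Sequences are chained into one species whenever their proportional
#' distance is strictly below `threshold` (single linkage: transitive
#' closure of the below-threshold relation). Cluster ids are assigned in
#' order of first member appearance in the input.
#'
#' @param d a `raw_distances` object.
#' @param threshold proportional-distance cutoff (default 0.04).
#' @return named integer vector: sequence id -> species id.
#' @export
cluster_species <- function(d, threshold = 0.04) {
  if (!inherits(d, "raw_distances")) stop("d must come from raw_distances()")
  adj <- d$prop < threshold
  diag(adj) <- FALSE
  comp <- components_of(adj)
  stats::setNames(match(comp, unique(comp)), rownames(d$N))
}

#' Select one exemplar sequence per lineage (medoid)
#'
#' The exemplar is the member minimizing the mean raw distance to the other
#' members of its lineage; ties break lexicographically.
#'
#' @param partition a `lineage_partition`.
#' @param d a `raw_distances` object.
#' @return named character vector: lineage id -> exemplar sequence id.
#' @export
select_exemplars <- function(partition, d) {
  vapply(partition$members, function(mem) {
    if (length(mem) == 1L) return(mem)
    mean_d <- colMeans(d$N[mem, mem, drop = FALSE])
    mem <- mem[order(mean_d, mem)]
    mem[1L]
  }, "")
}

#' Write a lineage partition to TSV
#'
#' Columns: sequence_id, lineage_id, species_id, exemplar (0/1).
#'
#' @param partition a `lineage_partition`.
#' @param d a `raw_distances` object.
#' @param path output TSV path.
#' @param species_threshold passed to [cluster_species()].
#' @export
write_partition <- function(partition, d, path, species_threshold = 0.04) {
  sp <- cluster_species(d, species_threshold)
  ex <- select_exemplars(partition, d)
  ids <- names(partition$lineage)
  df <- data.frame(sequence_id = ids,
                   lineage_id = partition$lineage[ids],
                   species_id = sp[ids],
                   exemplar = as.integer(ids %in% ex))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
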