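# Shared fixtures and independent oracles. The oracles deliberately use
# brute-force enumeration or direct loop implementations of the published
# formulas, never the package's own code paths.

# wrap a named state vector / list into a coded_matrix
make_coded <- function(x, character = "trait", scheme = NULL) {
  states <- lapply(if (is.list(x)) x else as.list(x), sort)
  if (is.null(scheme))
    scheme <- if (all(lengths(states) == 1L)) "simplified" else "polymorphic"
  structure(list(character = character, scheme = scheme, states = states,
                 alphabet = sort(unique(unlist(states)))),
            class = "coded_matrix")
}

# random ultrametric tree from an independent simulator (coalescent)
random_ultra_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# brute-force Fitch parsimony: enumerate all internal-node assignments.
# Returns tree length and MPR sets (list indexed by internal node - Ntip).
brute_parsimony <- function(tree, states) {
  alphabet <- sort(unique(unlist(states)))
  k <- length(alphabet)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  tipsets <- lapply(tree$tip.label, function(lb) match(states[[lb]], alphabet))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  cost <- apply(grid, 1L, function(assig) {
    tot <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- assig[tree$edge[e, 1L] - ntip]
      ch <- tree$edge[e, 2L]
      tot <- tot + if (ch <= ntip) min(tipsets[[ch]] != p)
                   else as.integer(assig[ch - ntip] != p)
    }
    tot
  })
  L <- min(cost)
  mpr <- lapply(seq_len(nint), function(i)
    sort(alphabet[unique(grid[cost == L, i])]))
  list(length = L, mpr = mpr)
}

# brute-force Mk likelihood: sum over all internal-node assignments with a
# uniform root prior; tip states integrated against their prior vectors
brute_mk <- function(tree, tp, Q) {
  k <- ncol(tp)
  ntip <- ape::Ntip(tree)
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    w <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      p <- grid[r, tree$edge[e, 1L] - ntip]
      ch <- tree$edge[e, 2L]
      w <- w * if (ch <= ntip) sum(P[[e]][p, ] * tp[tree$tip.label[ch], ])
               else P[[e]][p, grid[r, ch - ntip]]
    }
    tot <- tot + w
  }
  log(tot)
}

# brute-force marginal posterior of each node's state (tips included),
# conditioning tip states on their priors as above
brute_mk_marginals <- function(tree, tp, Q) {
  k <- ncol(tp)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  post <- matrix(0, nn, k)
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    w <- 1 / k
    for (i in seq_len(ntip)) w <- w * tp[tree$tip.label[i], grid[r, i]]
    if (w == 0) next
    for (e in seq_len(nrow(tree$edge)))
      w <- w * P[[e]][grid[r, tree$edge[e, 1L]], grid[r, tree$edge[e, 2L]]]
    tot <- tot + w
    for (v in seq_len(nn)) post[v, grid[r, v]] <- post[v, grid[r, v]] + w
  }
  post / tot
}

# independent gamma implementation: explicit loops over the published
# definition, straight from the vector of branching times
gamma_direct <- function(b) {
  b <- sort(b, decreasing = TRUE)
  n <- length(b) + 1L
  g <- numeric(n)
  for (k in 2:n) g[k] <- (if (k == 2) b[1] else b[k - 1]) -
    (if (k < n) b[k] else 0)
  Ttot <- 0
  for (k in 2:n) Ttot <- Ttot + k * g[k]
  inner <- 0
  for (i in 2:(n - 1)) {
    Ti <- 0
    for (k in 2:i) Ti <- Ti + k * g[k]
    inner <- inner + Ti
  }
  (inner / (n - 2) - Ttot / 2) / (Ttot * sqrt(1 / (12 * (n - 2))))
}

# build an alignment (named character vector) from a list of integer
# mutation positions relative to a reference, for delimitation tests
seqs_from_mutations <- function(mut, L = 100) {
  ref <- strsplit(paste(rep("ACGT", ceiling(L / 4)), collapse = ""), "")[[1]][1:L]
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  out <- vapply(mut, function(pos) {
    s <- ref
    if (length(pos)) s[pos] <- flip[s[pos]]
    paste(s, collapse = "")
  }, "")
  out
}
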