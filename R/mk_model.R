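# Mk (continuous-time Markov) models for discrete characters on a time
# tree: pruning-algorithm likelihood with frequency-valued tip priors,
# maximum-likelihood rate estimation (equal-rates / symmetric /
# all-rates-different structures), and stochastic character mapping
# (backward filtering, forward sampling; endpoint-conditioned branch paths
# by rejection sampling with a uniformization fallback).

# build a generator matrix from a parameter vector, given the structure
mk_build_Q <- function(rates, k, structure) {
  Q <- matrix(0, k, k)
  if (structure == "equal-rates") {
    Q[] <- rates[1L]
  } else if (structure == "symmetric") {
    Q[upper.tri(Q)] <- rates
    Q <- Q + t(Q)
  } else {                                    # all-rates-different
    Q[row(Q) != col(Q)] <- rates              # column-major off-diagonals
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

mk_n_rates <- function(k, structure) {
  switch(structure, "equal-rates" = 1L, "symmetric" = k * (k - 1L) / 2L,
         "all-rates-different" = k * (k - 1L))
}

# transition probability matrices for a set of branch lengths; closed form
# for the equal-rates structure, matrix exponential otherwise
mk_pmats <- function(Q, t, structure) {
  k <- nrow(Q)
  if (k == 1L) return(lapply(t, function(ti) matrix(1, 1, 1)))
  if (structure == "equal-rates") {
    q <- Q[1, 2]
    lapply(t, function(ti) {
      e <- exp(-k * q * ti)
      P <- matrix((1 - e) / k, k, k)
      diag(P) <- (1 + (k - 1) * e) / k
      P
    })
  } else {
    lapply(t, function(ti) as.matrix(Matrix::expm(Q * ti)))
  }
}

# tip prior matrix (Ntip x k) from a state_frequencies object or a coded
# matrix / named state vector (one-hot, or uniform over a tip's state set)
mk_tip_priors <- function(tree, data, character = NULL) {
  tips <- tree$tip.label
  if (inherits(data, "state_frequencies")) {
    if (is.null(character)) stop("character must be named for frequencies")
    pl <- data$freq[[character]]
  } else if (inherits(data, "coded_matrix")) {
    pl <- lapply(data$states, function(s)
      stats::setNames(rep(1 / length(s), length(s)), s))
  } else if (is.list(data)) {
    pl <- lapply(data, function(s) {
      if (is.numeric(s)) s
      else stats::setNames(rep(1 / length(s), length(s)), s)
    })
  } else {                                   # named character vector
    pl <- lapply(stats::setNames(as.list(data), names(data)), function(s)
      stats::setNames(1, s))
  }
  miss <- setdiff(tips, names(pl))
  if (length(miss)) stop("tips without data: ", paste(miss, collapse = ", "))
  alphabet <- sort(unique(unlist(lapply(pl, names))))
  P <- matrix(0, length(tips), length(alphabet),
              dimnames = list(tips, alphabet))
  for (i in seq_along(tips)) P[i, names(pl[[tips[i]]])] <- pl[[tips[i]]]
  P
}

# pruning: per-node partial likelihoods given P matrices per edge, with
# per-node rescaling against underflow; the summed log scale factor is
# returned as an attribute
mk_partials <- function(tree, tv, tip_priors, pmats) {
  k <- ncol(tip_priors)
  L <- matrix(1, tv$nn, k)
  L[seq_len(tv$ntip), ] <- tip_priors[tree$tip.label, , drop = FALSE]
  logscale <- 0
  for (v in tv$internal_post) {
    for (ch in tv$kids[[v]]) {
      P <- pmats[[tv$edge_of[ch]]]
      L[v, ] <- L[v, ] * as.numeric(P %*% L[ch, ])
    }
    s <- max(L[v, ])
    if (s > 0 && s < 1e-12) {
      L[v, ] <- L[v, ] / s
      logscale <- logscale + log(s)
    }
  }
  attr(L, "logscale") <- logscale
  L
}

#' Mk-model log-likelihood of a character on a time tree
#'
#' Felsenstein pruning with tip partial likelihoods initialized to the tip
#' prior frequency vectors (one-hot for fixed states) and a uniform root
#' distribution over the state alphabet.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param tip_priors Ntip x k matrix (rows named by tip label, columns by
#'   state), e.g. from the frequencies of a specimen table.
#' @param Q generator matrix (off-diagonals >= 0, rows summing to zero).
#' @param structure rate structure, used to pick the fast path.
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_priors, Q,
                      structure = c("equal-rates", "symmetric",
                                    "all-rates-different")) {
  structure <- match.arg(structure)
  tv <- tree_traversal(tree)
  pmats <- mk_pmats(Q, tree$edge.length, structure)
  pm_by_edge <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) pm_by_edge[[i]] <- pmats[[i]]
  L <- mk_partials(tree, tv, tip_priors, pm_by_edge)
  log(mean(L[tv$root, ])) + attr(L, "logscale")   # uniform root prior
}

#' Maximum-likelihood fit of an Mk model
#'
#' Bounded optimization of the pruning likelihood over the log rate(s).
#' With a single observed state the rate is degenerate at zero.
#'
#' @inheritParams mk_loglik
#' @param data tip data: a `state_frequencies` (+ `character`), a
#'   `coded_matrix`, a named state vector, or a tip-prior matrix.
#' @param character character name when `data` is a `state_frequencies`.
#' @param structure `"equal-rates"` (default), `"symmetric"`, or
#'   `"all-rates-different"`.
#' @return object of class `mk_fit`: `Q`, `rates`, `lnL`, `alphabet`,
#'   `structure`, `convergence`.
#' @export
mk_fit <- function(tree, data, character = NULL,
                   structure = c("equal-rates", "symmetric",
                                 "all-rates-different")) {
  structure <- match.arg(structure)
  tp <- if (is.matrix(data)) data else mk_tip_priors(tree, data, character)
  alphabet <- colnames(tp)
  k <- length(alphabet)
  if (k < 2L) {
    Q <- matrix(0, 1, 1, dimnames = list(alphabet, alphabet))
    return(structure(list(Q = Q, rates = 0, lnL = 0, alphabet = alphabet,
                          structure = structure, convergence = 0L,
                          degenerate = TRUE), class = "mk_fit"))
  }
  nr <- mk_n_rates(k, structure)
  total_depth <- max(node_ages(tree))
  nll <- function(logr)
    -mk_loglik(tree, tp, mk_build_Q(exp(logr), k, structure), structure)
  if (nr == 1L) {
    o <- stats::optimize(nll, lower = log(1e-9 / total_depth),
                         upper = log(1e3 / total_depth), tol = 1e-10)
    rates <- exp(o$minimum); lnL <- -o$objective; conv <- 0L
  } else {
    start <- rep(log(0.5 / total_depth), nr)
    o <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = log(1e-9 / total_depth),
                      upper = log(1e3 / total_depth),
                      control = list(factr = 1e5))
    if (o$convergence != 0)
      warning("Mk optimization did not converge (code ", o$convergence,
              "): ", o$message)
    rates <- exp(o$par); lnL <- -o$value; conv <- o$convergence
  }
  Q <- mk_build_Q(rates, k, structure)
  dimnames(Q) <- list(alphabet, alphabet)
  structure(list(Q = Q, rates = rates, lnL = lnL, alphabet = alphabet,
                 structure = structure, convergence = conv,
                 degenerate = FALSE), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$structure, "): ", length(x$alphabet), " states, lnL = ",
      format(x$lnL), "\n", sep = "")
  invisible(x)
}

# simulate an unconditioned CTMC path from state a for duration t.
# returns list(states, times) of jump events (possibly empty)
ctmc_path <- function(Q, a, t) {
  st <- integer(0); tm <- numeric(0)
  cur <- a; now <- 0
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) break
    now <- now + stats::rexp(1, rate)
    if (now >= t) break
    p <- Q[cur, ]; p[cur] <- 0
    cur <- sample.int(length(p), 1L, prob = p)
    st <- c(st, cur); tm <- c(tm, now)
  }
  list(states = st, times = tm)
}

# endpoint-conditioned path from a to b over duration t: rejection sampling
# with an attempt cap, then uniformization
conditioned_path <- function(Q, P_t, a, b, t, max_attempts = 10000L) {
  for (i in seq_len(max_attempts)) {
    p <- ctmc_path(Q, a, t)
    end <- if (length(p$states)) p$states[length(p$states)] else a
    if (end == b) return(p)
  }
  uniformization_path(Q, P_t, a, b, t)
}

uniformization_path <- function(Q, P_t, a, b, t) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) return(list(states = integer(0), times = numeric(0)))
  R <- diag(k) + Q / mu
  # R powers up to a cap covering essentially all Poisson mass
  nmax <- max(10L, ceiling(mu * t + 10 * sqrt(mu * t) + 10))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1L]] <- Rpow[[i]] %*% R
  w <- vapply(0:nmax, function(n)
    stats::dpois(n, mu * t) * Rpow[[n + 1L]][a, b], 0)
  if (sum(w) <= 0) stop("endpoint-conditioned path simulation failed")
  N <- sample.int(nmax + 1L, 1L, prob = w) - 1L
  if (N == 0L) return(list(states = integer(0), times = numeric(0)))
  jumps <- sort(stats::runif(N, 0, t))
  states <- integer(N)
  cur <- a
  for (i in seq_len(N)) {
    rem <- N - i
    pr <- R[cur, ] * vapply(seq_len(k), function(s) Rpow[[rem + 1L]][s, b], 0)
    states[i] <- sample.int(k, 1L, prob = pr)
    cur <- states[i]
  }
  real <- c(states[1L] != a, diff(states) != 0)
  list(states = states[real], times = jumps[real])
}

#' Stochastic character mapping
#'
#' For each supplied tree: fits an Mk model (per tree, not pooled), runs
#' backward filtering (pruning partials with tip priors), then forward
#' sampling of node states from their joint conditional distribution, and
#' simulates each branch's endpoint-conditioned CTMC path. Tip states are
#' themselves sampled (priors are beliefs, not fixed states).
#'
#' @param trees a `phylo` or `multiPhylo` sample of trees.
#' @param data tip data as in [mk_fit()].
#' @param character character name when `data` is a `state_frequencies`.
#' @param n_sim_per_tree simulated histories per tree (default 10).
#' @param structure Mk rate structure (default equal-rates).
#' @param seed optional integer; the whole set of maps is reproducible.
#' @param Q optional fixed generator matrix (columns/rows in the alphabet
#'   order of the tip priors); skips the per-tree fit when supplied.
#' @return list of class `simmap_set`; each element is a history: list with
#'   `tree_index`, `sim_index`, `node_state` (character, all nodes),
#'   `segments` (data.frame: edge, parent, child, start_age, end_age,
#'   state; segments tile each branch from old to young).
#' @export
stochastic_map <- function(trees, data, character = NULL, n_sim_per_tree = 10,
                           structure = "equal-rates", seed = NULL, Q = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    fit <- if (is.null(Q)) mk_fit(tree, data, character, structure)
           else list(Q = Q, alphabet = colnames(Q), structure = structure)
    alphabet <- fit$alphabet
    k <- length(alphabet)
    tp <- if (is.matrix(data)) data else mk_tip_priors(tree, data, character)
    tp <- tp[, alphabet, drop = FALSE]
    tv <- tree_traversal(tree)
    ages <- node_ages(tree)
    pmats <- mk_pmats(fit$Q, tree$edge.length, fit$structure)
    L <- mk_partials(tree, tv, tp, pmats)
    for (si in seq_len(n_sim_per_tree)) {
      node_state <- integer(tv$nn)
      pr_root <- L[tv$root, ]
      node_state[tv$root] <- sample.int(k, 1L, prob = pr_root)
      for (v in tv$internal_pre) for (ch in tv$kids[[v]]) {
        P <- pmats[[tv$edge_of[ch]]]
        pr <- P[node_state[v], ] * L[ch, ]
        node_state[ch] <- sample.int(k, 1L, prob = pr)
      }
      segs <- vector("list", nrow(tree$edge))
      for (e in seq_len(nrow(tree$edge))) {
        pnode <- tree$edge[e, 1]; cnode <- tree$edge[e, 2]
        t_e <- tree$edge.length[e]
        a <- node_state[pnode]; b <- node_state[cnode]
        path <- if (t_e <= 0) {
          if (a != b) stop("state change across zero-length branch")
          list(states = integer(0), times = numeric(0))
        } else conditioned_path(fit$Q, pmats[[e]], a, b, t_e)
        bounds <- c(0, path$times, t_e)
        st <- c(a, path$states)
        segs[[e]] <- data.frame(
          edge = e, parent = pnode, child = cnode,
          start_age = ages[pnode] - bounds[-length(bounds)],
          end_age = ages[pnode] - bounds[-1L],
          state = alphabet[st])
      }
      out[[length(out) + 1L]] <- list(
        tree_index = ti, sim_index = si,
        node_state = stats::setNames(alphabet[node_state], NULL),
        segments = do.call(rbind, segs))
    }
  }
  structure(out, class = "simmap_set")
}

#' Write a simmap history set to a per-branch segment TSV
#'
#' @param maps a `simmap_set`.
#' @param path output TSV path.
#' @export
write_simmap <- function(maps, path) {
  rows <- do.call(rbind, lapply(maps, function(h)
    cbind(tree = h$tree_index, sim = h$sim_index, h$segments)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
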