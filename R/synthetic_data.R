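# Synthetic study generator: ultrametric trees under pure-birth,
# birth-death or logistic density-dependent branching; discrete characters
# (host species, host tissue, biogeographic region) evolved along the tree
# as CTMCs with era-dependent rates and a logged shift history; per-lineage
# specimen records with Dirichlet-multinomial within-lineage polymorphism;
# and a barcode alignment evolved under Jukes-Cantor. Ground truth is
# recorded so every pipeline stage can be checked against it.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions this pipeline targets: 115
#' haplotype lineages with a 13 Ma crown radiation, three characters (host
#' species, host tissue with the four usage classes, biogeographic region),
#' an abrupt slowdown of host shifting at the 3 Ma breakpoint with
#' region shifting constant through time, strong within-lineage host
#' fidelity (most specimens on the modal state), ~33 specimens per lineage
#' (~3800 total), and 504-column mtCOI-like barcodes at 1% divergence per
#' Ma per lineage pair.
#'
#' @param n_lineages number of tips (haplotype lineages).
#' @param tree_model `"yule"`, `"birth_death"`, or `"DDL"`.
#' @param tree_params model parameters: `lambda` (yule); `r`, `a`
#'   (birth_death); `r`, `K` (DDL).
#' @param crown_age rescale the simulated tree to this crown age (Ma);
#'   `NULL` keeps the simulated depth.
#' @param breakpoint era changepoint for character rates (Ma).
#' @param host_states,region_states alphabet sizes (>= 2) for host species
#'   and region; tissue uses the four usage classes.
#' @param rates named list per character of `c(old, young)` total
#'   transition (shift) rates per lineage per Ma; the destination state is
#'   uniform over the remaining states (equal-rates chain).
#' @param concentration Dirichlet concentration of specimen states on the
#'   lineage's true terminal state (larger = less polymorphism).
#' @param dirichlet_base baseline Dirichlet mass spread over all states.
#' @param specimens_per_lineage specimen records per lineage.
#' @param seqs_per_lineage barcode sequences per lineage (the first is the
#'   tip sequence; extras carry a little within-lineage variation).
#' @param within_mutations expected extra substitutions on each non-focal
#'   within-lineage sequence (Poisson mean; keep well below `min_diff`).
#' @param seq_length alignment columns.
#' @param subst_rate Jukes-Cantor substitution rate per site per Ma.
#' @param couple_host_to_region multiply host rates by `coupling_factor` on
#'   branches where the region history changed (off by default: characters
#'   evolve independently).
#' @param coupling_factor see above.
#' @param seed master seed; every draw derives from it.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_lineages = 115,
                            tree_model = c("yule", "birth_death", "DDL"),
                            tree_params = list(lambda = 1),
                            crown_age = 13,
                            breakpoint = 3,
                            host_states = 12,
                            region_states = 7,
                            rates = list(host_species = c(old = 0.40,
                                                          young = 0.04),
                                         host_tissue = c(old = 0.12,
                                                         young = 0.015),
                                         region = c(old = 0.25,
                                                    young = 0.25)),
                            concentration = 25,
                            dirichlet_base = 0.2,
                            specimens_per_lineage = 33,
                            seqs_per_lineage = 2,
                            within_mutations = 0.5,
                            seq_length = 504,
                            subst_rate = 0.01,
                            couple_host_to_region = FALSE,
                            coupling_factor = 1,
                            seed = 1) {
  tree_model <- match.arg(tree_model)
  stopifnot(n_lineages >= 3, host_states >= 2, region_states >= 2,
            all(unlist(rates) >= 0), breakpoint > 0)
  structure(as.list(environment()), class = "scenario_config")
}

# era-dependent equal-rates CTMC along one branch; returns the end state
# and a data.frame of transition events (age, from, to)
evolve_branch <- function(state, k, age_start, age_end, rate_old, rate_young,
                          breakpoint, alphabet) {
  events <- list()
  age <- age_start
  while (age > age_end + 1e-12) {
    rate <- if (age > breakpoint) rate_old else rate_young
    era_end <- if (age > breakpoint) max(breakpoint, age_end) else age_end
    if (rate <= 0) { age <- era_end; next }
    # `rate` is the total leaving (shift) rate per lineage per Ma; the new
    # state is uniform over the other states (equal-rates chain)
    wait <- stats::rexp(1, rate)
    if (age - wait <= era_end) { age <- era_end; next }
    age <- age - wait
    new <- sample(setdiff(seq_len(k), state), 1L)
    events[[length(events) + 1L]] <- data.frame(
      age = age, from = alphabet[state], to = alphabet[new])
    state <- new
  }
  list(state = state,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

# evolve one character over the whole tree; returns tip states, node
# states, and the shift log (edge, age, from, to)
evolve_character <- function(tree, tv, ages, k, rate_old, rate_young,
                             breakpoint, alphabet, rate_boost = NULL) {
  node_state <- integer(tv$nn)
  node_state[tv$root] <- sample.int(k, 1L)
  log_rows <- list()
  for (v in tv$internal_pre) for (ch in tv$kids[[v]]) {
    e <- tv$edge_of[ch]
    boost <- if (is.null(rate_boost)) 1 else rate_boost[e]
    res <- evolve_branch(node_state[v], k, ages[v], ages[ch],
                         rate_old * boost, rate_young * boost,
                         breakpoint, alphabet)
    node_state[ch] <- res$state
    if (!is.null(res$events))
      log_rows[[length(log_rows) + 1L]] <- cbind(edge = e, res$events)
  }
  list(node_state = alphabet[node_state],
       tip_state = stats::setNames(alphabet[node_state[seq_len(tv$ntip)]],
                                   tree$tip.label),
       shifts = if (length(log_rows)) do.call(rbind, log_rows)
                else data.frame(edge = integer(0), age = numeric(0),
                                from = character(0), to = character(0)))
}

# logistic density-dependent tree: like simulate_yule but the per-lineage
# rate while k lineages exist is r (1 - k / K)
simulate_ddl_tree <- function(n_tips, r, K, seed = NULL) {
  if (K <= n_tips) stop("K must exceed n_tips")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  k <- seq.int(2L, n)
  g <- stats::rexp(n - 1L, rate = k * r * (1 - k / K))
  build_tree_from_intervals(g, n)
}

# shared topology builder: given internode intervals g_2..g_n, grow a tree
# with uniform random splits (used by simulate_yule and the DDL simulator)
build_tree_from_intervals <- function(g, n) {
  split_t <- cumsum(c(0, g[-(n - 1L)]))
  total <- sum(g)
  par_id <- integer(n); par_t <- numeric(n)
  par_id[1:2] <- n + 1L; par_t[1:2] <- 0
  n_act <- 2L
  edge <- matrix(0L, 2L * n - 2L, 2L); elen <- numeric(2L * n - 2L); ne <- 0L
  for (j in seq_len(n - 2L)) {
    i <- sample.int(n_act, 1L)
    node <- n + 1L + j
    ne <- ne + 1L
    edge[ne, ] <- c(par_id[i], node); elen[ne] <- split_t[j + 1L] - par_t[i]
    par_id[i] <- node; par_t[i] <- split_t[j + 1L]
    n_act <- n_act + 1L
    par_id[n_act] <- node; par_t[n_act] <- split_t[j + 1L]
  }
  for (i in seq_len(n)) {
    ne <- ne + 1L
    edge[ne, ] <- c(par_id[i], i); elen[ne] <- total - par_t[i]
  }
  out <- list(edge = edge, edge.length = elen,
              tip.label = sprintf("L%03d", seq_len(n)), Nnode = n - 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Generate a complete synthetic scenario
#'
#' Simulates the tree, evolves the three characters with era-dependent
#' rates (logging every true shift), draws per-lineage specimen records
#' from a Dirichlet-multinomial centered on each lineage's true terminal
#' state, and evolves a Jukes-Cantor barcode alignment along the tree
#' (plus low-divergence within-lineage sequences). Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return list with `alignment` (named character vector), `tree` (`phylo`),
#'   `specimens` (data.frame), and `truth` (tree, per-character tip/node
#'   states and shift logs, diversification parameters, config).
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lineages
  tree <- switch(cfg$tree_model,
    yule = simulate_yule(n, lambda = cfg$tree_params$lambda %||% 1),
    birth_death = {
      lam <- cfg$tree_params$r / (1 - cfg$tree_params$a)
      ape::rphylo(n, birth = lam, death = lam * cfg$tree_params$a)
    },
    DDL = simulate_ddl_tree(n, cfg$tree_params$r, cfg$tree_params$K))
  tree$tip.label <- sprintf("L%03d", seq_len(n))
  if (!is.null(cfg$crown_age)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * cfg$crown_age / depth
  }
  tree <- validate_timetree(tree)
  tv <- tree_traversal(tree)
  ages <- node_ages(tree)
  alphabets <- list(
    host_species = sprintf("host%02d", seq_len(cfg$host_states)),
    host_tissue = c("male_flower", "female_flower", "seed", "stem"),
    region = sprintf("region%02d", seq_len(cfg$region_states)))
  truth_chars <- list()
  for (ch in c("region", "host_tissue", "host_species")) {
    boost <- NULL
    if (ch == "host_species" && cfg$couple_host_to_region) {
      shifted_edges <- unique(truth_chars$region$shifts$edge)
      boost <- rep(1, nrow(tree$edge))
      boost[shifted_edges] <- cfg$coupling_factor
    }
    truth_chars[[ch]] <- evolve_character(
      tree, tv, ages, length(alphabets[[ch]]),
      rate_old = cfg$rates[[ch]][["old"]],
      rate_young = cfg$rates[[ch]][["young"]],
      breakpoint = cfg$breakpoint, alphabet = alphabets[[ch]],
      rate_boost = boost)
  }
  truth_chars <- truth_chars[c("host_species", "host_tissue", "region")]
  # specimen records: Dirichlet-multinomial around the true terminal state
  spec_rows <- list()
  for (i in seq_len(n)) {
    lin <- tree$tip.label[i]
    ns <- cfg$specimens_per_lineage
    row <- list(specimen_id = sprintf("%s_sp%03d", lin, seq_len(ns)),
                lineage_id = lin)
    for (ch in names(alphabets)) {
      ab <- alphabets[[ch]]
      alpha <- rep(cfg$dirichlet_base, length(ab))
      alpha[match(truth_chars[[ch]]$tip_state[lin], ab)] <-
        alpha[match(truth_chars[[ch]]$tip_state[lin], ab)] +
        cfg$concentration
      p <- stats::rgamma(length(ab), alpha)
      p <- p / sum(p)
      row[[ch]] <- sample(ab, ns, replace = TRUE, prob = p)
    }
    spec_rows[[i]] <- as.data.frame(row)
  }
  specimens <- do.call(rbind, spec_rows)
  # barcode alignment: JC along the tree, plus within-lineage variants
  aln <- simulate_jc_alignment(tree, tv, ages, cfg$seq_length, cfg$subst_rate)
  seqs <- list()
  bases <- c("a", "c", "g", "t")
  for (i in seq_len(n)) {
    lin <- tree$tip.label[i]
    seqs[[paste0(lin, "_h1")]] <- aln[[lin]]
    if (cfg$seqs_per_lineage > 1L) for (j in seq.int(2L, cfg$seqs_per_lineage)) {
      s <- aln[[lin]]
      nm <- stats::rpois(1, cfg$within_mutations)
      if (nm > 0) {
        pos <- sample.int(cfg$seq_length, min(nm, cfg$seq_length))
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(bases, b), 1L), "")
      }
      seqs[[sprintf("%s_h%d", lin, j)]] <- s
    }
  }
  alignment <- vapply(seqs, paste, "", collapse = "")
  truth <- list(tree = tree, characters = truth_chars,
                alphabets = alphabets,
                tree_model = cfg$tree_model, tree_params = cfg$tree_params,
                config = cfg)
  list(alignment = toupper(alignment), tree = tree, specimens = specimens,
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jukes-Cantor sequence evolution along the tree; returns a list of
# character vectors (one per tip) of bases
simulate_jc_alignment <- function(tree, tv, ages, L, rate) {
  bases <- c("a", "c", "g", "t")
  seqs <- vector("list", tv$nn)
  seqs[[tv$root]] <- sample(bases, L, replace = TRUE)
  for (v in tv$internal_pre) for (ch in tv$kids[[v]]) {
    t_e <- ages[v] - ages[ch]
    # JC: probability a site differs from its ancestor
    p_change <- 3 / 4 * (1 - exp(-4 / 3 * rate * t_e))
    s <- seqs[[v]]
    hit <- stats::runif(L) < p_change
    if (any(hit)) s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(bases, b), 1L), "")
    seqs[[ch]] <- s
  }
  stats::setNames(seqs[seq_len(tv$ntip)], tree$tip.label)
}

#' Study-shaped convenience scenario
#'
#' A scenario sized like the target study (115 lineages, 13 Ma crown, 3 Ma
#' breakpoint) for integration tests and documentation. Makes no claim of
#' reproducing any empirical value.
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return the generated scenario (see [generate_scenario()]).
#' @export
paper_shaped_fixture <- function(seed = 1, ...) {
  generate_scenario(scenario_config(seed = seed, ...))
}

#' Write a scenario to disk in the formats the pipeline reads
#'
#' FASTA alignment, Newick tree, specimen TSV, and a ground-truth JSON
#' (shift logs and true tip states; the tree is in the Newick file).
#'
#' @param scenario from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alignment.fasta")
  writeLines(paste0(">", names(scenario$alignment), "\n",
                    scenario$alignment), fa)
  write_timetree(scenario$tree, file.path(dir, "tree.nwk"))
  utils::write.table(scenario$specimens, file.path(dir, "specimens.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- scenario$truth
  jsonlite::write_json(list(
    tree_model = truth$tree_model, tree_params = truth$tree_params,
    tip_states = lapply(truth$characters, function(x) as.list(x$tip_state)),
    shifts = lapply(truth$characters, `[[`, "shifts")),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
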