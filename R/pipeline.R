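# Pipeline orchestration: one configuration object holding every threshold
# and seed, and a run_pipeline() driver that executes delimitation, coding,
# reconstruction (parsimony + stochastic mapping), split tallies, the
# permutation test, and the diversification analyses on the full tree, the
# truncated tree, and designated clades, writing a machine-readable bundle.

#' Pipeline configuration
#'
#' Defaults are the study values this pipeline reproduces: lineages split
#' at >= 3 raw mutations, 4% species clusters, 5% polymorphic-coding floor,
#' 0.2 predominant window, 3 Ma breakpoint, 1 Ma truncation, 250 trees x 10
#' stochastic maps, 1000 permutations.
#'
#' @param min_diff minimum between-lineage raw difference count.
#' @param species_threshold proportional distance for species clusters.
#' @param min_freq,window coding-scheme parameters (see [code_matrix()]).
#' @param breakpoint old/young split age (Ma).
#' @param truncation truncation age (Ma) for the truncated-tree analyses.
#' @param n_trees_simmap trees drawn from the tree sample for mapping.
#' @param maps_per_tree stochastic maps per tree.
#' @param n_perm permutations for the shift-proportion test.
#' @param characters character columns tallied from the specimen table.
#' @param clades optional named list of tip-label sets analyzed separately.
#' @param outgroup optional outgroup sequence id for the NJ guide tree;
#'   without one the guide tree is midpoint-rooted.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for the results bundle (NULL = return
#'   the bundle without writing).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_diff = 3L, species_threshold = 0.04,
                            min_freq = 0.05, window = 0.2,
                            breakpoint = 3, truncation = 1,
                            n_trees_simmap = 250L, maps_per_tree = 10L,
                            n_perm = 1000L,
                            characters = c("host_species", "host_tissue",
                                           "region"),
                            clades = NULL, outgroup = NULL,
                            seed = 1L, out_dir = NULL) {
  stopifnot(min_diff >= 1, species_threshold > 0, min_freq > 0, window > 0,
            breakpoint > truncation, truncation >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) lineage delimitation from the alignment (skipped without an
#' alignment); (2) character coding from the specimen table; (3) parsimony
#' reconstruction (polymorphic + predominant codings) and stochastic
#' mapping; (4) split tallies at the breakpoint, with and without the
#' young-split exclusion; (5) permutation test on the simplified matrix;
#' (6) trait-model comparison (equal-rates / early-burst / delta) on the
#' simplified host character; (7) gamma statistics (both tails) and the
#' four-model diversification comparison on the full tree, truncated tree,
#' and each designated clade. Stages 2-6 are skipped without a specimen
#' table. Every numeric block carries the seed and config hash.
#'
#' @param cfg a [pipeline_config()].
#' @param tree the time-calibrated ultrametric tree (`phylo`).
#' @param alignment optional named character vector (or matrix) of aligned
#'   sequences for the delimitation stage.
#' @param specimens optional specimen data.frame (see
#'   [read_specimen_table()]).
#' @param tree_sample optional `multiPhylo` posterior sample for stochastic
#'   mapping (defaults to the single input tree).
#' @return the results bundle (list); written as JSON + TSVs when
#'   `cfg$out_dir` is set.
#' @export
run_pipeline <- function(cfg, tree, alignment = NULL, specimens = NULL,
                         tree_sample = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  tree <- validate_timetree(tree)
  set.seed(cfg$seed)
  bundle <- list(meta = list(schema_version = "1.0", seed = cfg$seed,
                             config = cfg[setdiff(names(cfg), "out_dir")]))

  if (!is.null(alignment)) {
    d <- raw_distances(alignment)
    guide <- if (!is.null(cfg$outgroup)) {
      neighbor_joining(d, outgroup = cfg$outgroup)
    } else {
      phangorn::midpoint(neighbor_joining_unrooted(d))
    }
    part <- delimit_lineages(guide, d, min_diff = cfg$min_diff)
    sp <- cluster_species(d, cfg$species_threshold)
    ex <- select_exemplars(part, d)
    bundle$delimitation <- list(
      n_lineages = length(part$members),
      n_species = length(unique(sp)),
      n_excluded = length(part$excluded),
      lineage = as.list(part$lineage), species = as.list(sp),
      exemplars = as.list(ex))
  }

  if (!is.null(specimens)) {
    freqs <- summarize_frequencies(specimens, cfg$characters)
    codings <- list()
    for (scheme in c("polymorphic", "predominant", "simplified"))
      for (ch in cfg$characters)
        codings[[scheme]][[ch]] <- code_matrix(freqs, ch, scheme,
                                               cfg$min_freq, cfg$window)
    tallies <- list()
    for (scheme in c("polymorphic", "predominant")) {
      recs <- lapply(codings[[scheme]], function(cm)
        parsimony_reconstruct(tree, cm))
      for (excl in unique(c(0, cfg$truncation))) {
        st <- classify_splits(tree, recs, breakpoint = cfg$breakpoint,
                              exclusion_age = excl)
        st$table$coding <- scheme
        st$table$exclusion_age <- excl
        tallies[[length(tallies) + 1L]] <- st$table
      }
    }
    bundle$parsimony_tally <- do.call(rbind, tallies)
    bundle$parsimony_steps <- sapply(cfg$characters, function(ch)
      parsimony_reconstruct(tree, codings$polymorphic[[ch]])$length)

    trees_for_maps <- if (is.null(tree_sample)) list(tree) else tree_sample
    n_draw <- min(cfg$n_trees_simmap, length(trees_for_maps))
    drawn <- sample(seq_along(trees_for_maps), n_draw,
                    replace = length(trees_for_maps) < n_draw)
    map_trees <- trees_for_maps[drawn]
    maps <- lapply(stats::setNames(cfg$characters, cfg$characters),
                   function(ch) stochastic_map(
                     map_trees, freqs, ch,
                     n_sim_per_tree = cfg$maps_per_tree))
    bundle$simmap_tally <- tally_simmap(maps, map_trees,
                                        breakpoint = cfg$breakpoint)

    perm <- permutation_test(
      tree, codings$simplified[intersect(c("host_species", "host_tissue"),
                                         cfg$characters)],
      breakpoint = cfg$breakpoint, m = cfg$n_perm)
    bundle$permutation <- perm[c("D_obs", "p_raw", "p_corrected", "m")]
    bundle$permutation_null <- perm$null

    host_char <- intersect(c("host_species", cfg$characters),
                           cfg$characters)[1L]
    bundle$trait_models <- fit_trait_models(tree,
                                            codings$simplified[[host_char]])
  }

  div_rows <- list()
  targets <- c(list(all = tree),
               lapply(cfg$clades %||% list(), extract_clade, tree = tree))
  for (nm in names(targets)) {
    for (span in c("all", "truncated")) {
      tr <- targets[[nm]]
      if (span == "truncated") {
        if (cfg$truncation <= 0) next
        tr <- tryCatch(truncate_tree(tr, cfg$truncation),
                       error = function(e) NULL)
        if (is.null(tr) || ape::Ntip(tr) < 4L) next
      }
      prof <- branching_profile(tr)
      g <- gamma_stat(prof)
      cm <- compare_models(prof)
      div_rows[[length(div_rows) + 1L]] <- data.frame(
        clade = nm, lineages = span, n_tips = prof$n, gamma = g,
        p_two_tailed = gamma_pvalue(g, "two"),
        p_one_tailed_lower = gamma_pvalue(g, "one_lower"),
        best_model = cm$best_model, dAIC = cm$dAIC)
    }
  }
  bundle$diversification <- do.call(rbind, div_rows)
  bundle$ltt <- ltt_coords(tree)

  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

# unrooted NJ used when no outgroup is available (midpoint-rooted upstream)
neighbor_joining_unrooted <- function(d) {
  D <- if (inherits(d, "raw_distances")) d$prop else as.matrix(d)
  tmp <- neighbor_joining(d, outgroup = rownames(D)[1L])
  ape::unroot(tmp)
}

#' Write a results bundle to disk
#'
#' `results.json` plus TSVs for the tabular blocks; `bundle.md5` holds the
#' hash of the JSON for determinism checks.
#'
#' @param bundle from [run_pipeline()].
#' @param dir output directory.
#' @return the bundle hash (md5 of results.json), invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("parsimony_tally", "simmap_tally", "diversification", "ltt"))
    if (!is.null(bundle[[nm]]))
      utils::write.table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- file.path(dir, "results.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  hash <- unname(tools::md5sum(json_path))
  writeLines(hash, file.path(dir, "bundle.md5"))
  invisible(hash)
}
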