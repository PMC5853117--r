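# From specimen records to per-lineage character state sets: relative state
# frequencies per lineage, and the three coding schemes used to express
# within-lineage variation (polymorphic / predominant / simplified).

#' Read a specimen table (TSV)
#'
#' Expected columns: `specimen_id`, `lineage_id`, and one column per
#' character (typically `host_species`, `host_tissue`, `region`). Missing
#' observations must be coded `"unknown"` (or left empty / NA; both are
#' normalized to `"unknown"`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "lineage_id")
  if (!all(need %in% names(df)))
    stop("specimen table must have columns: ", paste(need, collapse = ", "))
  for (col in setdiff(names(df), "specimen_id")) {
    v <- as.character(df[[col]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    df[[col]] <- v
  }
  df
}

#' Per-lineage state frequencies for each character
#'
#' `"unknown"` records are dropped before computing relative frequencies,
#' which therefore sum to one over the observed states of each lineage.
#'
#' @param specimens data.frame as from [read_specimen_table()].
#' @param characters character columns to summarize (default: all columns
#'   other than `specimen_id` and `lineage_id`).
#' @return object of class `state_frequencies`: `freq[[character]]` is a
#'   list mapping lineage id to a named frequency vector; `counts` is a
#'   lineage x character matrix of usable specimen numbers.
#' @export
summarize_frequencies <- function(specimens, characters = NULL) {
  if (is.null(characters))
    characters <- setdiff(names(specimens), c("specimen_id", "lineage_id"))
  lineages <- sort(unique(as.character(specimens$lineage_id)))
  freq <- list()
  counts <- matrix(0L, length(lineages), length(characters),
                   dimnames = list(lineages, characters))
  for (ch in characters) {
    per <- list()
    for (lin in lineages) {
      v <- specimens[[ch]][specimens$lineage_id == lin]
      v <- v[v != "unknown"]
      if (!length(v))
        stop("lineage ", lin, " has no usable records for character ", ch)
      tab <- table(v)
      per[[lin]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
      counts[lin, ch] <- length(v)
    }
    freq[[ch]] <- per
  }
  structure(list(freq = freq, counts = counts, lineages = lineages,
                 characters = characters), class = "state_frequencies")
}

#' Code per-lineage state sets from state frequencies
#'
#' Three schemes expressing within-lineage polymorphism:
#' * `polymorphic`: all states observed at relative frequency
#'   `>= min_freq` (default 5% of specimens);
#' * `predominant`: the most frequent state plus any state whose frequency
#'   is within `window` (default 0.2) of it;
#' * `simplified`: the single most frequent state (ties broken
#'   lexicographically).
#'
#' @param f a `state_frequencies` object.
#' @param character which character to code.
#' @param scheme `"polymorphic"`, `"predominant"`, or `"simplified"`.
#' @param min_freq floor for the polymorphic scheme.
#' @param window frequency window for the predominant scheme.
#' @return object of class `coded_matrix`: `states` is a list mapping
#'   lineage id to a character vector of states (singleton for simplified).
#' @export
code_matrix <- function(f, character, scheme = c("polymorphic", "predominant",
                                                 "simplified"),
                        min_freq = 0.05, window = 0.2) {
  scheme <- match.arg(scheme)
  if (!character %in% f$characters) stop("unknown character: ", character)
  states <- lapply(f$freq[[character]], function(p) {
    p <- sort(p, decreasing = TRUE)
    top <- max(p)
    out <- switch(scheme,
      polymorphic = names(p)[p >= min_freq],
      predominant = names(p)[p >= top - window],
      simplified  = min(names(p)[p == top]))
    if (!length(out)) out <- min(names(p)[p == top])  # safeguard: keep modal
    sort(out)
  })
  structure(list(character = character, scheme = scheme, states = states,
                 alphabet = sort(unique(unlist(states)))),
            class = "coded_matrix")
}

#' Write coded matrices to TSV (states joined with "|")
#'
#' @param coded a `coded_matrix` or list of them.
#' @param path output TSV path.
#' @export
write_coded_matrix <- function(coded, path) {
  if (inherits(coded, "coded_matrix")) coded <- list(coded)
  rows <- do.call(rbind, lapply(coded, function(cm)
    data.frame(lineage = names(cm$states), character = cm$character,
               scheme = cm$scheme,
               states = vapply(cm$states, paste, "", collapse = "|"))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
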