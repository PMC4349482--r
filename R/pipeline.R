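# End-to-end orchestration: branch/relation restriction -> annotation ->
# test -> BH correction -> pruning -> packaged results.

#' Analysis configuration
#'
#' @param mode `"plain"` (binomial, unweighted ids), `"weighted"`
#'   (saddlepoint on weights) or `"fragment"` (weighted analysis restricted
#'   to the structural branch, leaves and roots protected from pruning).
#' @param branch ontology branch to analyse; fragment mode forces
#'   `"structural"`.
#' @param alpha significance threshold used by the high-p branch pruner.
#' @param population_mode denominator of the per-class success
#'   probability, see [class_success_probability()].
#' @param strategy a `pruning_strategy` or NULL for the mode's preset.
#' @param propagate_has_part include `has_part` in membership propagation.
#' @param seed optional integer for stochastic fixtures only.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("plain", "weighted", "fragment"),
                            branch = c("all", "structural", "role"),
                            alpha = 0.05,
                            population_mode = c("entities", "classes"),
                            strategy = NULL,
                            propagate_has_part = TRUE,
                            seed = NULL) {
  mode <- match.arg(mode)
  branch <- match.arg(branch)
  population_mode <- match.arg(population_mode)
  stopifnot(alpha > 0, alpha < 1)
  if (mode == "fragment") branch <- "structural"
  if (!is.null(strategy)) stopifnot(inherits(strategy, "pruning_strategy"))
  structure(list(mode = mode, branch = branch, alpha = alpha,
                 population_mode = population_mode, strategy = strategy,
                 propagate_has_part = isTRUE(propagate_has_part), seed = seed),
            class = "analysis_config")
}

#' Parse and validate a sample input
#'
#' Accepts one identifier per line, optionally followed by a tab and a
#' weight in \[0, 1\]. Bare numeric ids are normalised to the `CHEBI:`
#' CURIE form; blank lines and `#` comments are skipped; duplicates are
#' merged keeping the maximum weight. Mixing weighted and unweighted rows
#' is an error.
#'
#' @param lines character vector of input lines.
#' @return data.frame with columns `id`, `weight` (`NA` throughout for an
#'   unweighted sample); attributes `weighted` and `n_duplicates`.
#' @export
validate_input <- function(lines) {
  lines <- sub("\r$", "", as.character(lines))
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) stop("empty sample: no identifier lines found")
  parts <- strsplit(trimws(lines[keep]), "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf > 2L)) {
    stop("too many fields at line ", keep[which(nf > 2L)[1]])
  }
  has_w <- nf == 2L
  if (any(has_w) && !all(has_w)) {
    stop("mixed weighted and unweighted rows (first unweighted at line ",
         keep[which(!has_w)[1]], ")")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  ids <- trimws(ids)
  bare <- grepl("^[0-9]+$", ids)
  ids[bare] <- paste0("CHEBI:", ids[bare])
  weights <- rep(NA_real_, length(ids))
  if (all(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bad <- is.na(w) | w < 0 | w > 1
    if (any(bad)) {
      stop("weight not a number in [0, 1] at line ", keep[which(bad)[1]])
    }
    weights <- w
  }
  n_dup <- sum(duplicated(ids))
  if (n_dup) {
    agg <- tapply(weights, ids, function(x) if (all(is.na(x))) NA_real_ else max(x))
    first <- !duplicated(ids)
    ids_u <- ids[first]
    weights <- as.numeric(agg[ids_u])
    ids <- ids_u
  }
  out <- data.frame(id = ids, weight = weights, stringsAsFactors = FALSE)
  attr(out, "weighted") <- all(has_w)
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Run a complete enrichment analysis
#'
#' Restricts the ontology to the configured branch, builds the annotation
#' index (the branch-restricted ontology is the background population),
#' tests every class hit by the sample, corrects with BH, and prunes the
#' display graph with the mode's strategy preset.
#'
#' @param ontology an `ontology_graph`.
#' @param sample data.frame with `id`/`weight` columns (from
#'   [validate_input()]) or a bare character vector of ids for plain mode.
#' @param config an `analysis_config`.
#' @return list with `rows` (sorted enrichment table), `graph` (pruned
#'   `result_graph`), `report` (population sizes, recognised/unrecognised
#'   counts, pruner log, warnings).
#' @export
run_analysis <- function(ontology, sample, config = analysis_config()) {
  stopifnot(inherits(ontology, "ontology_graph"),
            inherits(config, "analysis_config"))
  if (is.character(sample)) {
    sample <- data.frame(id = sample, weight = NA_real_, stringsAsFactors = FALSE)
    attr(sample, "weighted") <- FALSE
  }
  weighted_input <- isTRUE(attr(sample, "weighted")) || any(!is.na(sample$weight))
  if (config$mode == "plain" && weighted_input) {
    stop("plain mode rejects weighted input rows; use mode 'weighted' or 'fragment'")
  }
  if (config$mode %in% c("weighted", "fragment") && !weighted_input) {
    stop(config$mode, " mode requires weights (id<TAB>weight input)")
  }

  g <- restrict_branch(ontology, config$branch)
  index <- build_annotation_index(
    g, propagate_has_part = config$propagate_has_part)

  rows <- if (config$mode == "plain") {
    plain_enrichment(index, sample$id, mode = config$population_mode)
  } else {
    withCallingHandlers(
      weighted_enrichment(index, sample, mode = config$population_mode),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  # attach display names
  rows$name <- g$terms$name[match(rows$class_id, g$terms$id)]

  strategy <- config$strategy %||% strategy_preset(
    switch(config$mode, plain = "plain_default", weighted = "weighted_default",
           fragment = "fragment_default"),
    alpha = config$alpha)
  rg <- result_graph(g, rows)
  rg <- apply_strategy(rg, strategy)

  unrecognised <- attr(rows, "unrecognised") %||% character()
  report <- list(
    mode = config$mode,
    branch = config$branch,
    n_submitted = nrow(sample),
    n_recognised = attr(rows, "n_recognised"),
    unrecognised = unrecognised,
    degenerate_weights = isTRUE(attr(rows, "degenerate")),
    population_entities = index$n_entities,
    population_classes = index$n_classes,
    prune_log = attr(rg, "prune_log"),
    note = if (length(unrecognised)) {
      "unrecognised ids dropped: the recognised molecules act as a sample of the complete submitted set"
    } else NULL
  )
  list(rows = rows, graph = rg, report = report)
}
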