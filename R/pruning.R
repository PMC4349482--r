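# Result-graph pruning. A result graph is the ontology restricted to the
# hierarchical display relations (is_a, has_part) with the enrichment rows
# attached to tested nodes. Five pruners compact it; a strategy composes
# them into pre-loop, loop-to-fixpoint and final phases.

#' Construct a result graph
#'
#' Restricts the graph to `is_a`/`has_part` edges (the display relations)
#' and attaches enrichment rows to their nodes. `collapsed_paths` records,
#' per surviving edge, the ordered ids removed by the linear branch
#' collapser.
#'
#' @param g an `ontology_graph`.
#' @param rows enrichment rows (data.frame with `class_id`, `p_raw`,
#'   `p_adj`, ...) or NULL.
#' @return object of class `result_graph` with fields `graph`, `stats`,
#'   `collapsed_paths`.
#' @export
result_graph <- function(g, rows = NULL) {
  g <- filter_relations(g, HIERARCHICAL_RELATIONS)
  g <- induced_subgraph(g, active_terms(g))
  stats <- NULL
  if (!is.null(rows) && nrow(rows)) {
    stats <- rows[rows$class_id %in% g$terms$id, , drop = FALSE]
    rownames(stats) <- stats$class_id
  }
  structure(list(graph = g, stats = stats, collapsed_paths = list()),
            class = "result_graph")
}

#' @export
print.result_graph <- function(x, ...) {
  cat(sprintf("<result_graph> %d nodes, %d edges, %d tested, %d collapsed edges\n",
              nrow(x$graph$terms), nrow(x$graph$edges),
              if (is.null(x$stats)) 0L else nrow(x$stats),
              length(x$collapsed_paths)))
  invisible(x)
}

rg_node_ids <- function(rg) rg$graph$terms$id

edge_key <- function(child, parent) paste(child, parent, sep = "\r")

# drop nodes (with incident edges) and clean stale collapse records
rg_drop_nodes <- function(rg, drop) {
  if (!length(drop)) return(rg)
  g <- rg$graph
  g$terms <- g$terms[!(g$terms$id %in% drop), , drop = FALSE]
  g$edges <- g$edges[!(g$edges$child %in% drop) & !(g$edges$parent %in% drop), ,
                     drop = FALSE]
  rg$graph <- g
  keep_keys <- edge_key(g$edges$child, g$edges$parent)
  rg$collapsed_paths <- rg$collapsed_paths[
    names(rg$collapsed_paths) %in% keep_keys]
  rg
}

node_pvalues <- function(rg, use_adjusted = TRUE) {
  p <- rep(NA_real_, nrow(rg$graph$terms))
  names(p) <- rg$graph$terms$id
  if (!is.null(rg$stats)) {
    col <- if (use_adjusted) "p_adj" else "p_raw"
    p[rg$stats$class_id] <- rg$stats[[col]]
  }
  p
}

#' Zero degree vertex pruner
#'
#' Removes nodes with neither incoming nor outgoing edges. These typically
#' appear after other pruners have run.
#'
#' @param rg a `result_graph`; @param protect ids never removed.
#' @return pruned `result_graph`.
#' @export
prune_zero_degree <- function(rg, protect = character()) {
  touched <- unique(c(rg$graph$edges$child, rg$graph$edges$parent))
  isolated <- setdiff(rg_node_ids(rg), c(touched, protect))
  rg_drop_nodes(rg, isolated)
}

#' Root children pruner
#'
#' Removes the top `levels` levels of the ontology (very general classes):
#' every node whose minimum distance from some root, measured along
#' reversed (parent -> child) edges, is below `levels`. Roots are nodes
#' with no outgoing child -> parent edge.
#'
#' @param rg a `result_graph`; @param levels depth to remove (>= 1);
#' @param protect ids never removed.
#' @return pruned `result_graph`.
#' @export
prune_root_children <- function(rg, levels = 3L, protect = character()) {
  stopifnot(levels >= 1L)
  ids <- rg_node_ids(rg)
  roots <- setdiff(ids, unique(rg$graph$edges$child))
  if (!length(roots)) return(rg)
  kids_of <- split(rg$graph$edges$child, rg$graph$edges$parent)
  depth <- stats::setNames(rep(Inf, length(ids)), ids)
  depth[roots] <- 0
  frontier <- roots
  d <- 0
  while (length(frontier) && d < levels - 1L) {
    nxt <- unique(unlist(kids_of[frontier], use.names = FALSE))
    nxt <- nxt[depth[nxt] == Inf]
    depth[nxt] <- d + 1
    frontier <- nxt
    d <- d + 1
  }
  drop <- setdiff(names(depth)[depth < levels], protect)
  rg_drop_nodes(rg, drop)
}

#' Molecule leaves pruner
#'
#' Removes nodes that have no incoming edge and represent a distinct small
#' molecule, i.e. carry an InChI line notation. Classes without incoming
#' edges are retained.
#'
#' @param rg a `result_graph`; @param protect ids never removed.
#' @return pruned `result_graph`.
#' @export
prune_molecule_leaves <- function(rg, protect = character()) {
  t <- rg$graph$terms
  has_incoming <- t$id %in% rg$graph$edges$parent
  drop <- setdiff(t$id[!has_incoming & !is.na(t$inchi)], protect)
  rg_drop_nodes(rg, drop)
}

#' High p-value branch pruner
#'
#' Removes every node whose entire down-set (itself plus all descendants
#' toward the leaves) carries p-values above `alpha`; equivalently a node
#' is retained iff it, or some descendant, is significant. Nodes without
#' statistics count as high-p. Operates on the BH-corrected p by default.
#'
#' @param rg a `result_graph`; @param alpha significance threshold;
#' @param use_adjusted use `p_adj` (default) or `p_raw`;
#' @param protect ids never removed.
#' @return pruned `result_graph`.
#' @export
prune_high_p <- function(rg, alpha = 0.05, use_adjusted = TRUE,
                         protect = character()) {
  stopifnot(alpha > 0, alpha < 1)
  p <- node_pvalues(rg, use_adjusted)
  keep <- !is.na(p) & p <= alpha
  e <- rg$graph$edges
  # propagate "significant in down-set" upward along child -> parent edges
  repeat {
    lifted <- keep
    hit <- keep[e$child]
    if (any(hit)) {
      lifted[unique(e$parent[hit])] <- TRUE
    }
    if (identical(lifted, keep)) break
    keep <- lifted
  }
  drop <- setdiff(names(keep)[!keep], protect)
  rg_drop_nodes(rg, drop)
}

#' Linear branch collapser pruner
#'
#' Finds maximal linear stretches (interior nodes with exactly one incoming
#' and one outgoing edge), removes them, and connects the surrounding
#' predecessor and successor with a single edge. The surrounding nodes
#' must be non-branching at the junction (one outgoing edge below, one
#' incoming above), so a diamond's sides are left alone and reachability
#' between retained nodes is preserved exactly. Removed ids are recorded
#' in `collapsed_paths` under the replacement edge; no parallel duplicate
#' edges are created.
#'
#' @param rg a `result_graph`; @param protect ids never collapsed.
#' @return pruned `result_graph`.
#' @export
prune_linear_collapse <- function(rg, protect = character()) {
  e <- rg$graph$edges
  if (!nrow(e)) return(rg)
  indeg <- table(factor(e$parent, levels = rg_node_ids(rg)))
  outdeg <- table(factor(e$child, levels = rg_node_ids(rg)))
  interior <- rg_node_ids(rg)[indeg == 1L & outdeg == 1L]
  interior <- setdiff(interior, protect)
  if (!length(interior)) return(rg)
  in_edge <- match(rg_node_ids(rg), e$parent)   # edge whose parent is node
  names(in_edge) <- rg_node_ids(rg)
  out_edge <- match(rg_node_ids(rg), e$child)   # edge whose child is node
  names(out_edge) <- rg_node_ids(rg)

  is_interior <- stats::setNames(rg_node_ids(rg) %in% interior, rg_node_ids(rg))
  visited <- stats::setNames(rep(FALSE, length(interior)), interior)
  removed <- character()
  new_edges <- list()
  for (v in interior) {
    if (visited[[v]]) next
    chain <- v
    # extend toward the child side (the node below v in the hierarchy)
    below <- e$child[in_edge[[v]]]
    while (isTRUE(is_interior[[below]])) { chain <- c(below, chain); below <- e$child[in_edge[[below]]] }
    above <- e$parent[out_edge[[v]]]
    while (isTRUE(is_interior[[above]])) { chain <- c(chain, above); above <- e$parent[out_edge[[above]]] }
    visited[chain] <- TRUE
    pred <- e$child[in_edge[[chain[1]]]]     # the node entering the stretch
    succ <- e$parent[out_edge[[chain[length(chain)]]]]
    # the surrounding nodes must themselves be linear here: trim the stretch
    # until its predecessor has one outgoing and its successor one incoming
    # edge (a diamond's sides are not linear stretches)
    while (length(chain) && outdeg[[pred]] != 1L) {
      pred <- chain[1]; chain <- chain[-1]
    }
    while (length(chain) && indeg[[succ]] != 1L) {
      succ <- chain[length(chain)]; chain <- chain[-length(chain)]
    }
    if (!length(chain)) next
    relation <- e$relation[in_edge[[chain[1]]]]
    # records on edges consumed by the stretch carry over
    consumed_keys <- c(edge_key(pred, chain[1]),
                       edge_key(chain[-length(chain)], chain[-1]),
                       edge_key(chain[length(chain)], succ))
    carried <- unlist(rg$collapsed_paths[
      names(rg$collapsed_paths) %in% consumed_keys], use.names = FALSE)
    removed <- c(removed, chain)
    new_edges[[length(new_edges) + 1L]] <-
      list(child = pred, parent = succ, relation = relation,
           ids = unique(c(carried, chain)))
  }

  rg <- rg_drop_nodes(rg, removed)
  e2 <- rg$graph$edges
  for (ne in new_edges) {
    key <- edge_key(ne$child, ne$parent)
    exists <- any(e2$child == ne$child & e2$parent == ne$parent)
    if (!exists) {
      e2 <- rbind(e2, data.frame(child = ne$child, parent = ne$parent,
                                 relation = ne$relation,
                                 stringsAsFactors = FALSE))
    }
    prev <- rg$collapsed_paths[[key]]
    rg$collapsed_paths[[key]] <- unique(c(prev, ne$ids))
  }
  rg$graph$edges <- e2
  rg
}

PRUNER_TABLE <- list(
  zero_degree = function(rg, spec, protect)
    prune_zero_degree(rg, protect),
  root_children = function(rg, spec, protect)
    prune_root_children(rg, levels = spec$levels %||% 3L, protect = protect),
  molecule_leaves = function(rg, spec, protect)
    prune_molecule_leaves(rg, protect),
  high_p = function(rg, spec, protect)
    prune_high_p(rg, alpha = spec$alpha %||% 0.05,
                 use_adjusted = spec$use_adjusted %||% TRUE, protect = protect),
  linear_collapse = function(rg, spec, protect)
    prune_linear_collapse(rg, protect)
)

`%||%` <- function(a, b) if (is.null(a)) b else a

pruner_spec <- function(name, ...) c(list(name = name), list(...))

#' Pruning strategy constructor
#'
#' A strategy is three ordered pruner lists -- `pre_loop` (applied once),
#' `loop` (applied repeatedly until a full pass changes nothing) and
#' `final` (applied once) -- plus a set of protected node categories
#' (`"molecule_leaves"`, `"roots"`) that no pruner may remove.
#'
#' @param pre_loop,loop,final lists of pruner specs,
#'   each `list(name = ..., <params>)` with name one of `zero_degree`,
#'   `root_children`, `molecule_leaves`, `high_p`, `linear_collapse`.
#' @param protect character subset of `c("molecule_leaves", "roots")`.
#' @return object of class `pruning_strategy`.
#' @export
pruning_strategy <- function(pre_loop = list(), loop = list(), final = list(),
                             protect = character()) {
  check <- function(phase) {
    for (s in phase) {
      if (is.null(s$name) || !s$name %in% names(PRUNER_TABLE)) {
        stop("unknown pruner: ", s$name %||% "<missing name>")
      }
    }
  }
  check(pre_loop); check(loop); check(final)
  stopifnot(all(protect %in% c("molecule_leaves", "roots")))
  structure(list(pre_loop = pre_loop, loop = loop, final = final,
                 protect = protect),
            class = "pruning_strategy")
}

#' Built-in pruning strategy presets
#'
#' `plain_default` mirrors the plain-analysis strategy: pre-loop high-p
#' branch pruner (at `alpha`), linear branch collapser and root children
#' pruner (3 levels); loop of molecule-leaves, high-p, linear-collapse and
#' zero-degree pruners to fixpoint; no final pruner. `weighted_default`
#' adds a final zero-degree pass. `fragment_default` protects terminal
#' molecule leaves and root vertices and drops the molecule-leaves /
#' root-children pruners entirely.
#'
#' @param name preset name.
#' @param alpha threshold for the high-p pruner.
#' @return a `pruning_strategy`.
#' @export
strategy_preset <- function(name = c("plain_default", "weighted_default",
                                     "fragment_default"),
                            alpha = 0.05) {
  name <- match.arg(name)
  hp <- pruner_spec("high_p", alpha = alpha)
  switch(name,
    plain_default = pruning_strategy(
      pre_loop = list(hp, pruner_spec("linear_collapse"),
                      pruner_spec("root_children", levels = 3L)),
      loop = list(pruner_spec("molecule_leaves"), hp,
                  pruner_spec("linear_collapse"), pruner_spec("zero_degree"))
    ),
    weighted_default = pruning_strategy(
      pre_loop = list(hp, pruner_spec("linear_collapse"),
                      pruner_spec("root_children", levels = 3L)),
      loop = list(pruner_spec("molecule_leaves"), hp,
                  pruner_spec("linear_collapse"), pruner_spec("zero_degree")),
      final = list(pruner_spec("zero_degree"))
    ),
    fragment_default = pruning_strategy(
      pre_loop = list(hp, pruner_spec("linear_collapse")),
      loop = list(hp, pruner_spec("linear_collapse"),
                  pruner_spec("zero_degree")),
      protect = c("molecule_leaves", "roots")
    )
  )
}

#' Apply a pruning strategy
#'
#' Pre-loop pruners run once in order; loop pruners run in order repeatedly
#' until a full pass changes neither node nor edge set; final pruners run
#' once. Protected categories are resolved against the graph as it stands
#' when pruning begins. Returns the pruned graph with a log of removals as
#' attribute `"prune_log"`.
#'
#' @param rg a `result_graph`.
#' @param strategy a `pruning_strategy`.
#' @return pruned `result_graph`.
#' @export
apply_strategy <- function(rg, strategy) {
  stopifnot(inherits(strategy, "pruning_strategy"))
  protect <- character()
  if ("molecule_leaves" %in% strategy$protect) {
    t <- rg$graph$terms
    protect <- c(protect, t$id[!is.na(t$inchi)])
  }
  if ("roots" %in% strategy$protect) {
    protect <- c(protect, setdiff(rg_node_ids(rg), unique(rg$graph$edges$child)))
  }
  log <- list()
  run_one <- function(rg, spec, phase) {
    before_n <- nrow(rg$graph$terms); before_e <- nrow(rg$graph$edges)
    rg <- PRUNER_TABLE[[spec$name]](rg, spec, protect)
    log[[length(log) + 1L]] <<- data.frame(
      phase = phase, pruner = spec$name,
      removed_nodes = before_n - nrow(rg$graph$terms),
      removed_edges = before_e - nrow(rg$graph$edges),
      stringsAsFactors = FALSE)
    rg
  }
  for (s in strategy$pre_loop) rg <- run_one(rg, s, "pre_loop")
  max_passes <- max(10L * nrow(rg$graph$terms), 10L)
  pass <- 0L
  repeat {
    before <- list(rg_node_ids(rg), rg$graph$edges)
    for (s in strategy$loop) rg <- run_one(rg, s, "loop")
    after <- list(rg_node_ids(rg), rg$graph$edges)
    if (identical(before, after)) break
    pass <- pass + 1L
    if (pass > max_passes) stop("pruning loop failed to reach a fixpoint")
    if (length(strategy$loop) == 0L) break
  }
  for (s in strategy$final) rg <- run_one(rg, s, "final")
  attr(rg, "prune_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(phase = character(), pruner = character(),
               removed_nodes = integer(), removed_edges = integer())
  rg
}
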