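# Hand-built fixtures and independent oracles shared across the suite.
# Oracles deliberately avoid the package's own code paths: igraph for
# reachability/closure, literal definitions for BH and the binomial tail,
# resampling for the saddlepoint.

# --- tiny hand-built graphs -------------------------------------------------

# m1 (molecule) -is_a-> C1 -is_a-> C0
tiny_chain_graph <- function() {
  ontology_graph(
    data.frame(id = c("CHEBI:1", "CHEBI:2", "CHEBI:3"),
               name = c("m1", "C1", "C0"),
               inchi = c("InChI=1S/m1", NA, NA),
               is_obsolete = FALSE, branch = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(child = c("CHEBI:1", "CHEBI:2"),
               parent = c("CHEBI:2", "CHEBI:3"),
               relation = "is_a", stringsAsFactors = FALSE)
  )
}

# molecule M1 under structural S1 (is_a S0), with role R1 (is_a role root R0)
mixed_branch_graph <- function() {
  ontology_graph(
    data.frame(
      id = c("CHEBI:10", "CHEBI:11", "CHEBI:20", "CHEBI:21", "CHEBI:30"),
      name = c("chemical entity", "S1", "role", "R1", "M1"),
      inchi = c(NA, NA, NA, NA, "InChI=1S/M1"),
      is_obsolete = FALSE, branch = NA_character_, stringsAsFactors = FALSE),
    data.frame(
      child = c("CHEBI:11", "CHEBI:21", "CHEBI:30", "CHEBI:30"),
      parent = c("CHEBI:10", "CHEBI:20", "CHEBI:11", "CHEBI:21"),
      relation = c("is_a", "is_a", "is_a", "has_role"),
      stringsAsFactors = FALSE)
  )
}

# a class-only DAG turned into a result_graph with chosen p_adj values;
# p NA means untested
dag_result_graph <- function(edges, p = NULL, inchi = NULL) {
  ids <- unique(c(edges$child, edges$parent, names(p), names(inchi)))
  terms <- data.frame(
    id = ids, name = ids,
    inchi = if (is.null(inchi)) NA_character_ else
      ifelse(ids %in% names(inchi), inchi[ids], NA_character_),
    is_obsolete = FALSE, branch = NA_character_, stringsAsFactors = FALSE)
  edges$relation <- edges$relation %||% "is_a"
  g <- ontology_graph(terms, edges)
  rows <- NULL
  if (!is.null(p)) {
    tested <- names(p)[!is.na(p)]
    rows <- data.frame(class_id = tested, p_raw = unname(p[tested]),
                       p_adj = unname(p[tested]), stringsAsFactors = FALSE)
  }
  result_graph(g, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DAG result_graph: edges always point from a later to an earlier
# node index, so acyclicity holds by construction
random_dag_rg <- function(n, p_edge, seed, p_sig = 0.15, frac_untested = 0.3) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    take <- stats::runif(nrow(pairs)) < p_edge
    edges <- data.frame(child = ids[pairs[take, 2]],
                        parent = ids[pairs[take, 1]],
                        relation = rep_len("is_a", sum(take)),
                        stringsAsFactors = FALSE)
    p <- ifelse(stats::runif(n) < p_sig, stats::runif(n, 0, 0.05),
                stats::runif(n, 0.2, 1))
    p[stats::runif(n) < frac_untested] <- NA
    names(p) <- ids
    rg <- dag_result_graph(edges, p = p)
    attr(rg, "node_p") <- p
    rg
  })
}

rg_nodes_of <- function(rg) rg$graph$terms$id
node_p_of <- function(rg) attr(rg, "node_p")

# --- independent oracles ----------------------------------------------------

ig_from_edges <- function(edges, ids) {
  igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                vertices = data.frame(name = ids),
                                directed = TRUE)
}

# transitive ancestor closure via igraph (child -> parent direction)
oracle_ancestors <- function(g, id, relations = c("is_a", "has_part", "has_role")) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  ig <- ig_from_edges(e, g$terms$id)
  out <- names(igraph::subcomponent(ig, id, mode = "out"))
  setdiff(out, id)
}

# boolean reachability matrix over retained nodes
oracle_reach <- function(rg) {
  ids <- rg$graph$terms$id
  ig <- ig_from_edges(rg$graph$edges, ids)
  d <- igraph::distances(ig, mode = "out")
  is.finite(d)[ids, ids, drop = FALSE]
}

# literal BH step-up: p_adj[i] = min(1, min_{j: rank_j >= rank_i} p_(j)*m/j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  sorted <- p[ord]
  vapply(seq_len(m), function(i) {
    js <- ranks[i]:m
    min(1, min(sorted[js] * m / js))
  }, numeric(1))
}

# exhaustive 2^n outcome enumeration of P[X >= k]
oracle_binom_tail <- function(k, n, p) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  s <- rowSums(outcomes)
  prob <- p^s * (1 - p)^(n - s)
  sum(prob[s >= k])
}

# seeded Monte-Carlo resampling oracle for P[sum of m draws >= S]
oracle_mc_tail <- function(background, m, S, reps = 1e5, seed = 1,
                           chunk = 1e5) {
  withr::with_seed(seed, {
    hits <- 0
    done <- 0
    while (done < reps) {
      b <- min(chunk, reps - done)
      draws <- sample(background, m * b, replace = TRUE)
      hits <- hits + sum(colSums(matrix(draws, nrow = m)) >= S)
      done <- done + b
    }
    hits / reps
  })
}

# default acceptance-scale fixture world (criterion 5 conditions)
acceptance_spec <- function(seed) {
  fixture_spec(n_classes = 2000L, n_molecules = 500L, planted_class_size = 20L,
               planted_effect = 10, sample_size = 40L, role_fraction = 0.1,
               seed = seed)
}

# TRUE iff the planted class, or an ancestor with the identical molecule
# set, attains the minimal p_adj (competition ranking: ties share rank 1)
planted_first <- function(rows, index, planted_class) {
  pset <- sort(index$class_to_molecules[[planted_class]])
  top <- rows$class_id[rows$p_adj == min(rows$p_adj)]
  planted_class %in% top ||
    any(vapply(top, function(cid) {
      identical(sort(index$class_to_molecules[[cid]]), pset)
    }, logical(1)))
}
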