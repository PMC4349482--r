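# The five graph pruners and the phase/fixpoint strategy engine.

edges_df <- function(child, parent, relation = "is_a") {
  data.frame(child = child, parent = parent,
             relation = rep_len(relation, length(child)),
             stringsAsFactors = FALSE)
}

test_that("zero degree vertex pruner removes exactly the isolated nodes", {
  rg1 <- dag_result_graph(edges_df(character(), character()),
                          p = c(lonely = NA))
  expect_equal(nrow(prune_zero_degree(rg1)$graph$terms), 0L)

  chain <- dag_result_graph(edges_df(c("a", "b"), c("b", "c")))
  expect_equal(sort(rg_nodes_of(prune_zero_degree(chain))), c("a", "b", "c"))

  mixed <- dag_result_graph(edges_df(c("a", "b", "c"), c("b", "c", "d")),
                            p = c(i1 = NA, i2 = NA))
  expect_setequal(rg_nodes_of(prune_zero_degree(mixed)), c("a", "b", "c", "d"))
})

test_that("root children pruner removes the top levels", {
  # chain m -> B -> A -> R (edges child->parent)
  rg <- dag_result_graph(edges_df(c("m", "B", "A"), c("B", "A", "R")))
  expect_setequal(rg_nodes_of(prune_root_children(rg, levels = 1L)),
                  c("m", "B", "A"))
  out3 <- prune_root_children(rg, levels = 3L)
  expect_equal(rg_nodes_of(out3), "m")
  expect_equal(nrow(out3$graph$edges), 0L)
  expect_equal(nrow(prune_root_children(rg, levels = 10L)$graph$terms), 0L)
})

test_that("molecule leaves pruner removes only InChI-bearing in-degree-0 nodes", {
  # molecules m1..m3 under classes c1, c2; molecule 'whole' has an incoming
  # has_part edge so it is retained
  e <- rbind(edges_df(c("m1", "m2", "m3"), c("c1", "c1", "c2")),
             edges_df("part", "whole", "has_part"))
  rg <- dag_result_graph(
    e, inchi = c(m1 = "InChI=1S/1", m2 = "InChI=1S/2", m3 = "InChI=1S/3",
                 whole = "InChI=1S/w"))
  out <- prune_molecule_leaves(rg)
  expect_setequal(rg_nodes_of(out), c("c1", "c2", "whole", "part"))
})

test_that("high p-value branch pruner keeps significant nodes and their ancestors", {
  # spine s2 -> s1 -> root, significant leaf under s2, noise subtree under root
  e <- edges_df(c("leaf", "s2", "s1", "n1", "n2", "n3", "n4"),
                c("s2", "s1", "root", "root", "n1", "n1", "n3"))
  p <- c(leaf = 0.01, s2 = 0.9, s1 = 0.9, root = 0.9,
         n1 = 0.5, n2 = 0.5, n3 = 0.5, n4 = 0.5)
  out <- prune_high_p(dag_result_graph(e, p = p), alpha = 0.05)
  expect_setequal(rg_nodes_of(out), c("leaf", "s2", "s1", "root"))

  all_high <- dag_result_graph(e, p = rep_len(1.0, 8) |> stats::setNames(names(p)))
  expect_equal(nrow(prune_high_p(all_high, 0.05)$graph$terms), 0L)
})

test_that("nodes without stats count as high-p but protected nodes survive", {
  e <- edges_df("a", "b")
  rg <- dag_result_graph(e, p = c(a = NA, b = NA))
  expect_equal(nrow(prune_high_p(rg, 0.05)$graph$terms), 0L)
  kept <- prune_high_p(rg, 0.05, protect = c("a", "b"))
  expect_setequal(rg_nodes_of(kept), c("a", "b"))
})

test_that("linear branch collapser rewires stretches and records removals", {
  # a -> x -> b: x is interior (one in, one out)
  rg <- dag_result_graph(edges_df(c("a", "x"), c("x", "b")))
  out <- prune_linear_collapse(rg)
  expect_setequal(rg_nodes_of(out), c("a", "b"))
  expect_equal(nrow(out$graph$edges), 1L)
  expect_equal(out$collapsed_paths[[1]], "x")

  # diamond has no degree-1/1 interior
  dia <- dag_result_graph(edges_df(c("m", "m", "A", "B"),
                                   c("A", "B", "T", "T")))
  expect_equal(prune_linear_collapse(dia)$graph$edges, dia$graph$edges)

  # five interior nodes collapse to a single recorded edge
  ids <- c("a", paste0("x", 1:5), "b")
  long <- dag_result_graph(edges_df(ids[-7], ids[-1]))
  out5 <- prune_linear_collapse(long)
  expect_setequal(rg_nodes_of(out5), c("a", "b"))
  expect_length(out5$collapsed_paths[[1]], 5L)
})

test_that("collapser preserves reachability among retained nodes", {
  skip_if_not_installed("igraph")
  for (seed in 1:30) {
    rg <- random_dag_rg(n = sample(10:60, 1), p_edge = 0.08, seed = seed)
    before <- oracle_reach(rg)
    out <- prune_linear_collapse(rg)
    kept <- rg_nodes_of(out)
    after <- oracle_reach(out)
    expect_identical(after[kept, kept], before[kept, kept])
  }
})

test_that("high-p pruner never removes a significant node or its ancestors", {
  for (seed in 1:30) {
    rg <- random_dag_rg(n = sample(10:50, 1), p_edge = 0.1, seed = seed)
    p <- node_p_of(rg)
    out <- prune_high_p(rg, alpha = 0.05)
    sig <- names(p)[!is.na(p) & p <= 0.05]
    must_keep <- unique(c(sig, unlist(
      lapply(sig, function(s) ancestors(rg$graph, s)), use.names = FALSE)))
    expect_true(all(must_keep %in% rg_nodes_of(out)))
  }
})

test_that("apply_strategy phases run in order and reach a loop fixpoint", {
  rg <- random_dag_rg(25, 0.1, seed = 99)
  ident <- apply_strategy(rg, pruning_strategy())
  expect_identical(rg_nodes_of(ident), rg_nodes_of(rg))

  strat <- strategy_preset("plain_default")
  out <- apply_strategy(rg, strat)
  log <- attr(out, "prune_log")
  expect_true(all(log$phase %in% c("pre_loop", "loop", "final")))
  # re-running the loop phase must change nothing
  again <- apply_strategy(out, pruning_strategy(loop = strat$loop))
  expect_identical(rg_nodes_of(again), rg_nodes_of(out))
  expect_identical(again$graph$edges, out$graph$edges)
})

test_that("plain default strategy empties an all-insignificant graph", {
  rg <- dag_result_graph(
    edges_df(c("a", "b", "c"), c("b", "c", "d")),
    p = c(a = 0.8, b = 0.9, c = 0.7, d = 0.95))
  out <- apply_strategy(rg, strategy_preset("plain_default"))
  expect_equal(nrow(out$graph$terms), 0L)
})

test_that("default plain strategy removes most of a large sparse-signal ontology", {
  spec <- acceptance_spec(seed = 404)
  fix <- make_ontology(spec)
  smp <- make_sample(fix$graph, spec, "plain")
  res <- run_analysis(fix$graph, smp, analysis_config("plain"))
  n_before <- nrow(fix$graph$terms)
  n_after <- nrow(res$graph$graph$terms)
  expect_gte((n_before - n_after) / n_before, 0.5)
})

test_that("unknown pruner names and invalid protect categories are rejected", {
  expect_error(pruning_strategy(loop = list(list(name = "nope"))), "unknown pruner")
  expect_error(pruning_strategy(protect = "everything"), "protect")
})
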