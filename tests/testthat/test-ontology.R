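# OBO parsing, branch/relation restriction, ancestor closure, annotation
# index.

test_that("parse_obo builds one node per term and typed edges", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: CHEBI:10", "name: m1",
    "property_value: http://purl.obolibrary.org/obo/chebi/inchi \"InChI=1S/xyz\" xsd:string",
    "is_a: CHEBI:20 ! C1", "",
    "[Term]", "id: CHEBI:20", "name: C1", "is_a: CHEBI:30", "",
    "[Term]", "id: CHEBI:30", "name: C0")
  g <- parse_obo(obo)
  expect_equal(nrow(g$terms), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$edges$relation == "is_a"))
  expect_equal(molecule_ids(g), "CHEBI:10")
  expect_equal(g$terms$inchi[g$terms$id == "CHEBI:10"], "InChI=1S/xyz")
  expect_equal(graph_roots(g), "CHEBI:30")
})

test_that("relationship lines yield typed edges; has_role like the antibiotic example", {
  obo <- c(
    "[Term]", "id: CHEBI:3504", "name: cefpodoxime",
    "property_value: http://x/inchi \"InChI=1S/cef\" xsd:string",
    "is_a: CHEBI:33575",
    "relationship: has_role CHEBI:22582", "",
    "[Term]", "id: CHEBI:33575", "name: carboxylic acid", "",
    "[Term]", "id: CHEBI:22582", "name: antibiotic")
  g <- parse_obo(obo)
  hr <- g$edges[g$edges$relation == "has_role", ]
  expect_equal(nrow(hr), 1L)
  expect_equal(hr$child, "CHEBI:3504")
  expect_equal(hr$parent, "CHEBI:22582")
})

test_that("dangling edge targets are dropped and counted", {
  obo <- c(
    "[Term]", "id: A", "name: a", "is_a: UNDECLARED", "is_a: B", "",
    "[Term]", "id: B", "name: b")
  # independent line scan: edges referencing ids never declared
  declared <- sub("^id: ", "", grep("^id: ", obo, value = TRUE))
  targets <- sub("^is_a: ", "", grep("^is_a: ", obo, value = TRUE))
  expected_dropped <- sum(!targets %in% declared)
  expect_warning(g <- parse_obo(obo), "UNDECLARED")
  expect_equal(g$report$dropped_edges, expected_dropped)
  expect_equal(nrow(g$edges), 1L)
})

test_that("malformed stanza without id reports the line", {
  obo <- c("[Term]", "id: A", "name: a", "", "[Term]", "name: no id here")
  expect_error(parse_obo(obo), "line 5")
})

test_that("obsolete terms are parsed, flagged, and excluded from edges and molecules", {
  obo <- c(
    "[Term]", "id: A", "name: a",
    "property_value: http://x/inchi \"InChI=1S/a\" xsd:string",
    "is_a: C", "is_obsolete: true", "",
    "[Term]", "id: C", "name: c")
  g <- parse_obo(obo)
  expect_true(g$terms$is_obsolete[g$terms$id == "A"])
  expect_equal(nrow(g$edges), 0L)
  expect_length(molecule_ids(g), 0L)
  expect_equal(g$report$n_obsolete, 1L)
})

test_that("unknown relations parse as 'other' and filter_relations removes them", {
  obo <- c(
    "[Term]", "id: A", "name: acyclovir",
    "relationship: has_functional_parent B", "is_a: B", "",
    "[Term]", "id: B", "name: guanine")
  g <- parse_obo(obo)
  expect_setequal(g$edges$relation, c("other", "is_a"))
  f <- filter_relations(g, c("is_a", "has_part"))
  expect_equal(nrow(f$edges), 1L)
  expect_equal(nrow(f$terms), nrow(g$terms))  # node set unchanged
  expect_error(filter_relations(g, character()), "non-empty")
})

test_that("filter_relations keeps exactly the allowed relations", {
  g <- mixed_branch_graph()
  expect_identical(filter_relations(g, c("is_a", "has_part", "has_role"))$edges,
                   g$edges)
  only_isa <- filter_relations(g, "is_a")
  expect_equal(nrow(only_isa$edges), 3L)
})

test_that("restrict_branch selects structural/role subgraphs", {
  g <- mixed_branch_graph()
  expect_identical(restrict_branch(g, "all")$terms$id, g$terms$id)

  s <- restrict_branch(g, "structural")
  expect_setequal(s$terms$id, c("CHEBI:10", "CHEBI:11", "CHEBI:30"))
  expect_false("CHEBI:21" %in% s$terms$id)

  r <- restrict_branch(g, "role")
  expect_setequal(r$terms$id, c("CHEBI:20", "CHEBI:21", "CHEBI:30"))
  expect_true("CHEBI:30" %in% molecule_ids(r))

  g_noroles <- tiny_chain_graph()
  expect_error(restrict_branch(g_noroles, "role"), "role root")
})

test_that("ancestors follows child->parent closure", {
  g <- tiny_chain_graph()
  expect_length(ancestors(g, "CHEBI:3"), 0L)  # root
  expect_setequal(ancestors(g, "CHEBI:1"), c("CHEBI:2", "CHEBI:3"))
  expect_error(ancestors(g, "CHEBI:99"), "unknown term")

  # diamond: m -> A, m -> B, A -> T, B -> T; T counted once
  dg <- ontology_graph(
    data.frame(id = c("m", "A", "B", "T"), name = c("m", "A", "B", "T"),
               inchi = c("InChI=1S/m", NA, NA, NA), is_obsolete = FALSE,
               branch = NA, stringsAsFactors = FALSE),
    data.frame(child = c("m", "m", "A", "B"), parent = c("A", "B", "T", "T"),
               relation = "is_a", stringsAsFactors = FALSE))
  expect_setequal(ancestors(dg, "m"), c("A", "B", "T"))
})

test_that("ancestors matches the igraph closure oracle on random fixtures", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    fix <- make_ontology(fixture_spec(n_classes = 20, n_molecules = 15,
                                      planted_class_size = 3,
                                      sample_size = 5, seed = seed))
    g <- fix$graph
    for (id in sample(g$terms$id, 12)) {
      expect_setequal(ancestors(g, id), oracle_ancestors(g, id))
    }
  }
})

test_that("annotation index: basic membership and population sizes", {
  g <- tiny_chain_graph()
  idx <- build_annotation_index(g)
  expect_equal(idx$class_to_molecules[["CHEBI:2"]], "CHEBI:1")
  expect_equal(idx$class_to_molecules[["CHEBI:3"]], "CHEBI:1")
  expect_equal(idx$n_entities, 1L)
  expect_equal(idx$n_classes, 2L)
})

test_that("has_role membership propagates into the role hierarchy", {
  g <- mixed_branch_graph()  # M1 has_role R1, R1 is_a role-root R0
  idx <- build_annotation_index(g)
  expect_true("CHEBI:30" %in% idx$class_to_molecules[["CHEBI:21"]])
  expect_true("CHEBI:30" %in% idx$class_to_molecules[["CHEBI:20"]])
})

test_that("has_role is never chained class-to-class", {
  g <- ontology_graph(
    data.frame(id = c("m", "R1", "R2"), name = c("m", "R1", "R2"),
               inchi = c("InChI=1S/m", NA, NA), is_obsolete = FALSE,
               branch = NA, stringsAsFactors = FALSE),
    data.frame(child = c("m", "R1"), parent = c("R1", "R2"),
               relation = "has_role", stringsAsFactors = FALSE))
  idx <- build_annotation_index(g)
  expect_true("m" %in% idx$class_to_molecules[["R1"]])
  expect_false("R2" %in% names(idx$class_to_molecules))
})

test_that("propagate_has_part flag controls has_part membership", {
  g <- ontology_graph(
    data.frame(id = c("m", "F"), name = c("m", "F"),
               inchi = c("InChI=1S/m", NA), is_obsolete = FALSE,
               branch = NA, stringsAsFactors = FALSE),
    data.frame(child = "m", parent = "F", relation = "has_part",
               stringsAsFactors = FALSE))
  expect_true("m" %in% build_annotation_index(g)$class_to_molecules[["F"]])
  expect_false("F" %in% names(
    build_annotation_index(g, propagate_has_part = FALSE)$class_to_molecules))
})

test_that("annotation index errors on a moleculeless ontology", {
  g <- ontology_graph(
    data.frame(id = "C", name = "C", inchi = NA_character_,
               is_obsolete = FALSE, branch = NA, stringsAsFactors = FALSE),
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE))
  expect_error(build_annotation_index(g), "no molecule")
})

test_that("membership sets are upward-closed under is_a", {
  for (seed in 1:3) {
    fix <- make_ontology(fixture_spec(n_classes = 25, n_molecules = 20,
                                      planted_class_size = 4,
                                      sample_size = 5, seed = seed))
    g <- fix$graph
    idx <- build_annotation_index(g)
    isa <- g$edges[g$edges$relation == "is_a" &
                     !(g$edges$child %in% molecule_ids(g)), ]
    for (i in seq_len(nrow(isa))) {
      child_set <- idx$class_to_molecules[[isa$child[i]]] %||% character()
      parent_set <- idx$class_to_molecules[[isa$parent[i]]] %||% character()
      expect_true(all(child_set %in% parent_set))
    }
  }
})

test_that("write_obo/parse_obo round-trips ids, names, InChIs and typed edges", {
  fix <- make_ontology(fixture_spec(n_classes = 15, n_molecules = 12,
                                    planted_class_size = 3, sample_size = 4,
                                    seed = 42))
  g1 <- fix$graph
  g2 <- parse_obo(fix$obo)
  ord <- function(t) t[order(t$id), c("id", "name", "inchi", "is_obsolete")]
  expect_equal(ord(g2$terms), ord(g1$terms), ignore_attr = TRUE)
  sorted_edges <- function(g) {
    e <- g$edges[order(g$edges$child, g$edges$parent, g$edges$relation), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(sorted_edges(g2), sorted_edges(g1))
  expect_equal(g2$report$dropped_edges, 0L)
})
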