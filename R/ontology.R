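# Typed directed ontology graph: nodes are terms, edges run child -> parent
# (specific -> general) and carry a relation type. Molecules are the terms
# that carry an InChI line notation; everything else is a class.

HIERARCHICAL_RELATIONS <- c("is_a", "has_part")
KNOWN_RELATIONS <- c("is_a", "has_part", "has_role")

#' Construct an ontology graph
#'
#' Low-level constructor used by [parse_obo()] and the fixture generator.
#' `terms` must have columns `id`, `name`, `inchi` (`NA` for classes),
#' `is_obsolete`, `branch`; `edges` must have columns `child`, `parent`,
#' `relation`. Edges are directed child -> parent (specific -> general).
#'
#' @param terms data.frame of terms.
#' @param edges data.frame of typed edges.
#' @param report named list of parse/build diagnostics.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges, report = list()) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_t <- c("id", "name", "inchi", "is_obsolete", "branch")
  missing_t <- setdiff(need_t, names(terms))
  for (col in missing_t) {
    terms[[col]] <- switch(col,
      inchi = NA_character_,
      is_obsolete = FALSE,
      branch = NA_character_,
      NA_character_
    )
  }
  need_e <- c("child", "parent", "relation")
  if (nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(need_e %in% names(edges)))
  if (anyDuplicated(terms$id)) {
    stop("duplicate term ids: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  if (any(!nzchar(terms$id))) stop("empty term id")
  bad_inchi <- !is.na(terms$inchi) & !startsWith(terms$inchi, "InChI=")
  if (any(bad_inchi)) {
    stop("inchi not starting with 'InChI=' on term(s): ",
         paste(terms$id[bad_inchi], collapse = ", "))
  }
  unknown <- c(setdiff(edges$child, terms$id), setdiff(edges$parent, terms$id))
  if (length(unknown)) {
    stop("edge endpoint(s) not in term set: ",
         paste(unique(unknown), collapse = ", "))
  }
  g <- structure(
    list(terms = terms[, need_t], edges = edges[, need_e], report = report),
    class = "ontology_graph"
  )
  g <- assign_branches(g)
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  act <- active_terms(x)
  cat(sprintf(
    "<ontology_graph> %d terms (%d molecules, %d obsolete), %d edges\n",
    nrow(x$terms), length(molecule_ids(x)), sum(x$terms$is_obsolete),
    nrow(x$edges)
  ))
  tab <- table(x$edges$relation)
  if (length(tab)) {
    cat("  edges by relation:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  cat("  roots:", paste(utils::head(graph_roots(x), 5L), collapse = ", "),
      if (length(graph_roots(x)) > 5L) "..." else "", "\n")
  invisible(x)
}

# non-obsolete term ids
active_terms <- function(g) g$terms$id[!g$terms$is_obsolete]

#' Molecule identifiers of a graph
#'
#' Molecules are the non-obsolete terms carrying an InChI; all other terms
#' are classes. The InChI string is an opaque marker, no chemistry is done.
#'
#' @param g an `ontology_graph`.
#' @return character vector of term ids.
#' @export
molecule_ids <- function(g) {
  g$terms$id[!g$terms$is_obsolete & !is.na(g$terms$inchi)]
}

#' Class identifiers of a graph (non-obsolete terms without an InChI)
#' @param g an `ontology_graph`.
#' @return character vector of term ids.
#' @export
class_ids <- function(g) {
  g$terms$id[!g$terms$is_obsolete & is.na(g$terms$inchi)]
}

#' Roots of a graph
#'
#' A root has no outgoing hierarchical (child -> parent) edge, i.e. it never
#' appears on the child side of an edge.
#'
#' @param g an `ontology_graph`.
#' @return character vector of term ids.
#' @export
graph_roots <- function(g) {
  setdiff(active_terms(g), unique(g$edges$child))
}

# Tag each term with its ontology branch. A term is role-branch iff it is a
# named role root or an is_a descendant of one; molecules always count as
# structural (they reach roles only through has_role).
assign_branches <- function(g, role_roots = "role") {
  ids <- g$terms$id
  role_seed <- ids[tolower(g$terms$name) %in% tolower(role_roots) &
                     !g$terms$is_obsolete]
  role_set <- character()
  if (length(role_seed)) {
    isa <- g$edges[g$edges$relation == "is_a", , drop = FALSE]
    kids_of <- split(isa$child, isa$parent)
    frontier <- role_seed
    seen <- new.env(parent = emptyenv())
    for (r in role_seed) assign(r, TRUE, envir = seen)
    while (length(frontier)) {
      nxt <- unique(unlist(kids_of[frontier], use.names = FALSE))
      nxt <- nxt[!vapply(nxt, exists, logical(1), envir = seen)]
      for (v in nxt) assign(v, TRUE, envir = seen)
      frontier <- nxt
    }
    role_set <- ls(seen)
  }
  branch <- rep("structural", length(ids))
  branch[ids %in% role_set] <- "role"
  branch[!is.na(g$terms$inchi)] <- "structural"
  g$terms$branch <- branch
  g
}

#' Parse an OBO flat file into an ontology graph
#'
#' Understands the OBO 1.2/1.4 constructs this engine needs: `[Term]`
#' stanzas with `id`, `name`, `is_a`, `relationship: <rel> <id>`,
#' `is_obsolete`, and an InChI carried either on a `property_value:` line
#' whose key ends in `inchi` (case-insensitive) or on an `xref:` line whose
#' value contains `InChI=`. Unknown relationship types are kept as relation
#' `"other"`. Obsolete terms are parsed and flagged but excluded from edges.
#' Edges pointing at undeclared ids are dropped and counted in the parse
#' report (`g$report$dropped_edges`).
#'
#' @param src path to an OBO file, a character vector of lines, or a single
#'   string containing newlines.
#' @return An `ontology_graph`; `$report` holds `n_terms`, `n_obsolete`,
#'   `dropped_edges` and `dropped_edge_targets`.
#' @export
parse_obo <- function(src) {
  lines <- if (length(src) == 1L && !grepl("\n", src) && file.exists(src)) {
    readLines(src, warn = FALSE)
  } else if (length(src) == 1L && grepl("\n", src)) {
    strsplit(src, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(src)
  }
  lines <- sub("\r$", "", lines)

  # stanza boundaries
  stanza_at <- grep("^\\[", lines)
  term_at <- grep("^\\[Term\\]$", lines)
  ends <- c(stanza_at[-1] - 1L, length(lines))
  names(ends) <- as.character(stanza_at)

  terms <- list()
  raw_edges <- list()
  for (s in term_at) {
    end <- ends[[as.character(s)]]
    body <- lines[seq.int(s + 1L, length.out = max(0L, end - s))]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    fields <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(fields, function(f) if (length(f)) f[2] else "", "")
    vals <- vapply(fields, function(f) if (length(f)) f[3] else "", "")
    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id", s))
    }
    nm <- vals[keys == "name"][1]
    obsolete <- any(keys == "is_obsolete" & grepl("^true", vals))

    inchi <- NA_character_
    pv <- vals[keys == "property_value"]
    for (v in pv) {
      m <- regexec("^(\\S+)\\s+\"([^\"]*)\"", v)[[1]]
      if (m[1] != -1) {
        key <- regmatches(v, regexec("^(\\S+)\\s+\"([^\"]*)\"", v))[[1]]
        if (grepl("inchi$", key[2], ignore.case = TRUE)) inchi <- key[3]
      }
    }
    if (is.na(inchi)) {
      xr <- vals[keys == "xref"]
      hit <- regmatches(xr, regexpr("InChI=[^\"\\s]+", xr))
      hit <- hit[nzchar(hit)]
      if (length(hit)) inchi <- hit[1]
    }

    isa_targets <- sub("\\s*!.*$", "", vals[keys == "is_a"])
    rel_lines <- vals[keys == "relationship"]
    rel_m <- regmatches(rel_lines,
                        regexec("^(\\S+)\\s+(\\S+)", sub("\\s*!.*$", "", rel_lines)))
    terms[[length(terms) + 1L]] <- list(
      id = id,
      name = if (is.na(nm)) id else nm,
      inchi = inchi,
      is_obsolete = obsolete
    )
    if (!obsolete) {
      if (length(isa_targets)) {
        raw_edges[[length(raw_edges) + 1L]] <- data.frame(
          child = id, parent = trimws(isa_targets), relation = "is_a",
          stringsAsFactors = FALSE)
      }
      if (length(rel_m)) {
        rels <- vapply(rel_m, function(f) if (length(f) == 3L) f[2] else NA_character_, "")
        tgts <- vapply(rel_m, function(f) if (length(f) == 3L) f[3] else NA_character_, "")
        ok <- !is.na(rels)
        if (any(ok)) {
          raw_edges[[length(raw_edges) + 1L]] <- data.frame(
            child = id, parent = tgts[ok],
            relation = ifelse(rels[ok] %in% KNOWN_RELATIONS, rels[ok], "other"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  tdf <- do.call(rbind, lapply(terms, function(t) {
    data.frame(id = t$id, name = t$name, inchi = t$inchi,
               is_obsolete = t$is_obsolete, branch = NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tdf)) stop("no [Term] stanzas found")
  edf <- if (length(raw_edges)) do.call(rbind, raw_edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)

  declared <- tdf$id[!tdf$is_obsolete]
  dangling <- !(edf$parent %in% declared)
  dropped <- edf$parent[dangling]
  if (any(dangling)) {
    warning(sprintf("dropped %d edge(s) with undeclared target(s): %s",
                    sum(dangling), paste(unique(dropped), collapse = ", ")))
    edf <- edf[!dangling, , drop = FALSE]
  }
  ontology_graph(
    tdf, edf,
    report = list(
      n_terms = nrow(tdf),
      n_obsolete = sum(tdf$is_obsolete),
      dropped_edges = length(dropped),
      dropped_edge_targets = unique(dropped)
    )
  )
}

#' Serialise an ontology graph as OBO text
#'
#' Emits the dialect [parse_obo()] reads: one `[Term]` stanza per term with
#' `is_a`/`relationship:` lines and InChIs on `property_value:` lines. Used
#' by the fixture generator and for round-trip testing.
#'
#' @param g an `ontology_graph`.
#' @return character scalar of OBO text.
#' @export
write_obo <- function(g) {
  by_child <- split(seq_len(nrow(g$edges)), g$edges$child)
  stanzas <- vapply(seq_len(nrow(g$terms)), function(i) {
    t <- g$terms[i, ]
    out <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.na(t$inchi)) {
      out <- c(out, sprintf(
        "property_value: http://purl.obolibrary.org/obo/chebi/inchi \"%s\" xsd:string",
        t$inchi))
    }
    idx <- by_child[[t$id]]
    if (length(idx)) {
      e <- g$edges[idx, , drop = FALSE]
      isa <- e$relation == "is_a"
      out <- c(out,
               paste0("is_a: ", e$parent[isa]),
               sprintf("relationship: %s %s", e$relation[!isa], e$parent[!isa]))
    }
    if (t$is_obsolete) out <- c(out, "is_obsolete: true")
    paste(out, collapse = "\n")
  }, "")
  paste0("format-version: 1.2\n\n", paste(stanzas, collapse = "\n\n"), "\n")
}

# induced subgraph on a set of term ids (obsolete terms dropped)
induced_subgraph <- function(g, keep) {
  terms <- g$terms[g$terms$id %in% keep & !g$terms$is_obsolete, , drop = FALSE]
  edges <- g$edges[g$edges$child %in% terms$id & g$edges$parent %in% terms$id, ,
                   drop = FALSE]
  ontology_graph(terms, edges, report = g$report)
}

#' Restrict an ontology graph to the structural or role branch
#'
#' `branch = "structural"` keeps structural classes and molecules;
#' `branch = "role"` keeps the role branch plus all molecule leaves attached
#' to it via `has_role` (molecules remain the annotation sources);
#' `branch = "all"` is the identity.
#'
#' @param g an `ontology_graph`.
#' @param branch `"structural"`, `"role"` or `"all"`.
#' @param role_roots term names recognised as role roots.
#' @return An `ontology_graph`.
#' @export
restrict_branch <- function(g, branch = c("all", "structural", "role"),
                            role_roots = "role") {
  branch <- match.arg(branch)
  if (branch == "all") return(g)
  g <- assign_branches(g, role_roots = role_roots)
  if (branch == "structural") {
    return(induced_subgraph(g, g$terms$id[g$terms$branch != "role"]))
  }
  role_terms <- g$terms$id[g$terms$branch == "role" & !g$terms$is_obsolete]
  if (!length(role_terms)) {
    stop("no role root found (looked for term name(s): ",
         paste(role_roots, collapse = ", "), ")")
  }
  mol <- molecule_ids(g)
  attached <- unique(g$edges$child[g$edges$relation == "has_role" &
                                     g$edges$child %in% mol &
                                     g$edges$parent %in% role_terms])
  induced_subgraph(g, c(role_terms, attached))
}

#' Keep only edges of the allowed relation types
#'
#' The node set is unchanged; only edges whose relation is not in `allowed`
#' are removed. Non-hierarchical ChEBI relations (e.g.
#' `has_functional_parent`, stored as `"other"`) are dropped this way before
#' display.
#'
#' @param g an `ontology_graph`.
#' @param allowed non-empty character vector of relation types.
#' @return An `ontology_graph`.
#' @export
filter_relations <- function(g, allowed = HIERARCHICAL_RELATIONS) {
  if (!length(allowed)) stop("allowed relation set must be non-empty")
  g$edges <- g$edges[g$edges$relation %in% allowed, , drop = FALSE]
  g
}

# adjacency: for each child id, data.frame rows of its outgoing edges
edges_by_child <- function(g, relations) {
  e <- g$edges[g$edges$relation %in% relations, , drop = FALSE]
  split(e$parent, e$child)
}

#' Transitive ancestors of a term
#'
#' Closure along child -> parent edges of the given relation types,
#' excluding the term itself.
#'
#' @param g an `ontology_graph`.
#' @param term_id a term id present in `g`.
#' @param relations relation types to traverse.
#' @return character vector of ancestor ids.
#' @export
ancestors <- function(g, term_id, relations = KNOWN_RELATIONS) {
  if (!term_id %in% g$terms$id) stop("unknown term id: ", term_id)
  up <- edges_by_child(g, relations)
  seen <- character()
  frontier <- term_id
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(up[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setdiff(seen, term_id)
}

# Annotation closure for a single molecule: has_role may only be taken as
# the first hop (molecule -> role); from there only is_a/has_part chain
# upward. This matches the semantics "molecule has_role R, R is_a R0".
molecule_annotation <- function(up_all, up_no_role, m, use_role) {
  first <- if (use_role) up_all[[m]] else up_no_role[[m]]
  seen <- unique(first)
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(up_no_role[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setdiff(seen, m)
}

#' Build the class -> molecules annotation index
#'
#' For every class `c`, collects the set of molecule leaves whose ancestor
#' closure (via the given relations) contains `c`. `has_role` edges are
#' traversed only as the first hop from a molecule, never chained between
#' classes. The index also records the background population sizes: `N_e`
#' (number of distinct molecule leaves) and `N_c` (number of classes).
#'
#' @param g an `ontology_graph`.
#' @param relations relations that propagate membership.
#' @param propagate_has_part include `has_part` in membership propagation.
#' @return An object of class `annotation_index` with fields
#'   `class_to_molecules`, `molecule_to_classes`, `molecules`,
#'   `n_entities`, `n_classes`.
#' @export
build_annotation_index <- function(g, relations = KNOWN_RELATIONS,
                                   propagate_has_part = TRUE) {
  if (!propagate_has_part) relations <- setdiff(relations, "has_part")
  mols <- molecule_ids(g)
  if (!length(mols)) stop("ontology has no molecule leaves (no InChI-bearing terms)")
  up_all <- edges_by_child(g, relations)
  up_no_role <- edges_by_child(g, setdiff(relations, "has_role"))
  use_role <- "has_role" %in% relations
  mol_to_cls <- lapply(stats::setNames(mols, mols), function(m) {
    molecule_annotation(up_all, up_no_role, m, use_role)
  })
  pairs_cls <- unlist(mol_to_cls, use.names = FALSE)
  pairs_mol <- rep(names(mol_to_cls), lengths(mol_to_cls))
  cls_to_mol <- split(pairs_mol, pairs_cls)
  structure(
    list(
      class_to_molecules = cls_to_mol,
      molecule_to_classes = mol_to_cls,
      molecules = mols,
      n_entities = length(mols),
      n_classes = length(class_ids(g))
    ),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("<annotation_index> %d molecules, %d classes, %d annotated classes\n",
              x$n_entities, x$n_classes, length(x$class_to_molecules)))
  invisible(x)
}
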