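# Synthetic ChEBI-like ontologies and samples with a known planted signal,
# so every stage of the engine is testable without downloading a real
# ontology release. InChI strings are syntactic placeholders: the engine
# treats their presence as a boolean molecule marker and does no chemistry.

#' Specification for a synthetic ontology fixture
#'
#' `n_classes` random structural classes are grown into a DAG (each new
#' class picks 1..`max_parents` earlier parents); on top of those the
#' generator always adds the motifs each pruner needs a target for -- a
#' 3-node linear chain, a diamond, an isolated class -- plus a role branch
#' of `max(1, round(role_fraction * n_classes))` classes under a root named
#' "role", and a dedicated planted class holding `planted_class_size`
#' molecules attached to it exclusively. The remaining molecules attach to
#' random structural classes; each gets a `has_role` edge with probability
#' `role_fraction`.
#'
#' @param n_classes number of random structural classes (>= 1).
#' @param n_molecules number of molecule leaves (>= 1).
#' @param max_parents maximum is_a parents per random class/molecule.
#' @param role_fraction fraction sizing the role branch and the chance a
#'   molecule carries a role.
#' @param planted_class_size molecules attached to the planted class.
#' @param planted_effect enrichment odds (plain sampling) or weight-shift
#'   factor (weighted sampling); 1 = null.
#' @param sample_size ids drawn by [make_sample()] in plain mode.
#' @param seed integer seed; same seed gives byte-identical output.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes = 50L, n_molecules = 30L, max_parents = 2L,
                         role_fraction = 0.2, planted_class_size = 5L,
                         planted_effect = 8, sample_size = 15L, seed = 1L) {
  stopifnot(n_classes >= 1L, n_molecules >= 1L, max_parents >= 1L,
            role_fraction >= 0, role_fraction <= 1,
            planted_class_size >= 1L, planted_class_size <= n_molecules,
            planted_effect >= 1, sample_size >= 1L,
            sample_size <= n_molecules, is.numeric(seed))
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic ontology
#'
#' @param spec a `fixture_spec`.
#' @return list with `graph` (an `ontology_graph` carrying
#'   `planted_class` / `planted_molecules` fields), `obo` (the equivalent
#'   OBO text), `planted_class`, `planted_molecules`.
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    ec <- list(); ep <- list(); er <- list()   # edge child/parent/relation
    add_edges <- function(child, parent, relation = "is_a") {
      n <- max(length(child), length(parent))
      i <- length(ec) + 1L
      ec[[i]] <<- rep_len(child, n); ep[[i]] <<- rep_len(parent, n)
      er[[i]] <<- rep_len(relation, n)
    }
    id_of <- function(i) sprintf("CHEBI:%d", 1000L + i)

    nc <- spec$n_classes
    s_classes <- id_of(seq_len(nc))
    s_root <- s_classes[1]
    if (nc > 1L) {
      # each class picks 1..max_parents parents among earlier classes (DAG)
      n_par <- pmin(1L + stats::rbinom(nc - 1L, spec$max_parents - 1L, 0.3),
                    seq_len(nc - 1L))
      for (i in seq_len(nc - 1L)) {
        add_edges(s_classes[i + 1L], sample(s_classes[seq_len(i)], n_par[i]))
      }
    }
    # guaranteed pruner targets: linear chain, diamond, isolated node
    motif <- id_of(nc + 1:8)
    names(motif) <- c("x3", "x2", "x1", "dt", "da", "db", "db2", "iso")
    add_edges(motif[c("x3", "x2", "x1")], c(s_root, motif[c("x3", "x2")]))
    add_edges(motif[c("dt", "da", "db", "db2", "db2")],
              c(s_root, motif[c("dt", "dt", "da", "db")]))

    # occasional has_part edges between random structural classes
    if (nc >= 4L) {
      n_hp <- max(1L, nc %/% 10L)
      lo <- sample(nc - 1L, n_hp, replace = TRUE)
      hi <- lo + vapply(nc - lo, sample.int, 1L, size = 1L)
      add_edges(s_classes[hi], s_classes[lo], "has_part")
    }

    n_role <- max(1L, round(spec$role_fraction * nc))
    r_classes <- id_of(nc + 8L + seq_len(n_role + 1L))
    r_root <- r_classes[1]
    add_edges(r_classes[-1],
              r_classes[vapply(seq_len(n_role), sample.int, 1L, size = 1L)])

    # The planted class is a distinct top-level family directly under the
    # structural root, with its molecules attached to it exclusively: its
    # only proper ancestor is the root (near-background K), so the planted
    # signal is identified with exactly one class.
    planted <- id_of(nc + 8L + n_role + 2L)
    add_edges(planted, s_root)

    nm <- spec$n_molecules
    mols <- id_of(nc + 8L + n_role + 2L + seq_len(nm))
    n_planted <- spec$planted_class_size
    add_edges(mols[seq_len(n_planted)], planted)
    if (nm > n_planted) {
      free <- mols[(n_planted + 1L):nm]
      n_par <- pmin(1L + stats::rbinom(length(free), spec$max_parents - 1L, 0.3),
                    length(s_classes))
      for (i in seq_along(free)) {
        add_edges(free[i], sample(s_classes, n_par[i]))
      }
    }
    role_hit <- stats::runif(nm) < spec$role_fraction
    if (any(role_hit) && n_role >= 1L) {
      add_edges(mols[role_hit],
                r_classes[-1][sample.int(n_role, sum(role_hit), replace = TRUE)],
                "has_role")
    }

    terms <- data.frame(
      id = c(s_classes, motif, r_classes, planted, mols),
      name = c("chemical entity",
               sprintf("structural class %d", seq_len(max(nc - 1L, 0L))),
               "chain top", "chain mid", "chain bottom", "diamond top",
               "diamond left", "diamond right", "diamond bottom",
               "isolated class", "role",
               sprintf("role class %d", seq_len(n_role)),
               "planted class", sprintf("molecule %d", seq_len(nm))),
      inchi = c(rep(NA_character_, nc + 8L + n_role + 2L),
                sprintf("InChI=1S/C%dH%d/synthetic",
                        seq_len(nm) %% 30 + 1L, seq_len(nm))),
      is_obsolete = FALSE, branch = NA_character_,
      stringsAsFactors = FALSE, row.names = NULL)
    edges <- data.frame(
      child = unlist(ec), parent = unlist(ep), relation = unlist(er),
      stringsAsFactors = FALSE, row.names = NULL)

    g <- ontology_graph(terms, edges)
    g$planted_class <- planted
    g$planted_molecules <- mols[seq_len(spec$planted_class_size)]
    list(graph = g, obo = write_obo(g), planted_class = planted,
         planted_molecules = g$planted_molecules)
  })
}

#' Draw a synthetic sample with a planted signal
#'
#' Plain mode draws `sample_size` molecule ids without replacement, with
#' planted-class molecules weighted by `planted_effect`-fold odds
#' (`planted_effect = 1` is the exchangeable null). Weighted mode submits
#' every molecule: background weights are truncated normal centred at 0.1
#' (sd 0.1); planted members are centred at
#' `0.1 + 0.8 * (1 - 1/planted_effect)` (0.9 for a strong effect, 0.1 at
#' the null).
#'
#' @param graph an `ontology_graph` from [make_ontology()].
#' @param spec the `fixture_spec` used to build it.
#' @param mode `"plain"` or `"weighted"`.
#' @param seed seed for the draw (defaults to `spec$seed`).
#' @return data.frame with `id`, `weight` columns (attribute `weighted`).
#' @export
make_sample <- function(graph, spec, mode = c("plain", "weighted"),
                        seed = spec$seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "fixture_spec"))
  planted <- graph$planted_molecules
  if (length(planted) < spec$planted_class_size) {
    stop("planted class smaller than planted_class_size")
  }
  mols <- molecule_ids(graph)
  withr::with_seed(seed, {
    if (mode == "plain") {
      odds <- ifelse(mols %in% planted, spec$planted_effect, 1)
      ids <- sample(mols, spec$sample_size, prob = odds)
      out <- data.frame(id = ids, weight = NA_real_, stringsAsFactors = FALSE)
      attr(out, "weighted") <- FALSE
    } else {
      mu_hi <- 0.1 + 0.8 * (1 - 1 / spec$planted_effect)
      mu <- ifelse(mols %in% planted, mu_hi, 0.1)
      w <- pmin(pmax(stats::rnorm(length(mols), mu, 0.1), 0), 1)
      out <- data.frame(id = mols, weight = w, stringsAsFactors = FALSE)
      attr(out, "weighted") <- TRUE
    }
    out
  })
}
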