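# Plain (unweighted) over-representation statistics. Each ontology class is
# a binomial test: n trials (one per recognised sample molecule), a success
# when the molecule belongs to the class, success probability from the
# background population.

#' Upper binomial tail P[X >= k]
#'
#' One-sided over-representation tail for X ~ Binomial(n, p), computed via
#' the survival function for numerical stability.
#'
#' @param k number of successes (vectorised).
#' @param n number of trials.
#' @param p success probability (vectorised).
#' @return P\[X >= k\] in \[0, 1\].
#' @export
binomial_tail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Per-class success probability
#'
#' `mode = "entities"` divides the class annotation count K by the number of
#' molecule leaves in the background population (the statistically coherent
#' binomial population, the default). `mode = "classes"` divides by the
#' number of ontology classes instead.
#'
#' @param K class annotation count (number of molecules in the class).
#' @param index an `annotation_index`.
#' @param mode `"entities"` or `"classes"`.
#' @return probability in \[0, 1\].
#' @export
class_success_probability <- function(K, index, mode = c("entities", "classes")) {
  mode <- match.arg(mode)
  if (any(K < 0)) stop("K must be >= 0")
  denom <- if (mode == "entities") index$n_entities else index$n_classes
  if (!isTRUE(denom > 0)) stop("background population size is zero for mode ", mode)
  K / denom
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Order-preserving adjusted p-values:
#' `p_adj[i] = min(1, min_{j: rank(j) >= rank(i)} p_(j) * m / rank(j))`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fold of enrichment
#'
#' Ratio of the class proportion in the sample to its proportion in the
#' background population: `(k/n) / (K/N)`. Undefined (NA) when `K = 0`.
#'
#' @param k sample successes; @param n sample size;
#' @param K population annotation count; @param N population size.
#' @return nonnegative fold, `NA` where `K = 0`.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(N <= 0)) stop("n and N must be positive")
  out <- (k / n) / (K / N)
  out[K == 0] <- NA_real_
  out
}

# shared row assembly for plain and weighted analyses
enrichment_rows <- function(index, k_by_class, n, p_raw, mode) {
  class_ids <- names(k_by_class)
  K <- lengths(index$class_to_molecules[class_ids])
  N <- if (mode == "entities") index$n_entities else index$n_classes
  k <- as.integer(k_by_class)
  rows <- data.frame(
    class_id = class_ids,
    k = k,
    n = n,
    K = as.integer(K),
    N = as.integer(N),
    p_success = class_success_probability(K, index, mode),
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    sample_pct = 100 * k / n,
    fold = fold_enrichment(k, n, K, N),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  rows[order(rows$p_adj, rows$p_raw, rows$class_id), , drop = FALSE]
}

#' Plain binomial enrichment analysis
#'
#' Tests every ontology class hit by at least one recognised sample
#' molecule. A trial checks whether a queried molecule belongs to the
#' class; the per-class success probability comes from
#' [class_success_probability()]. Raw p-values are the upper binomial tail;
#' the BH correction runs over the family of tested classes.
#'
#' @param index an `annotation_index`.
#' @param sample character vector of molecule ids (duplicates collapsed).
#' @param mode background population mode, see [class_success_probability()].
#' @return data.frame of per-class rows sorted by `p_adj`, `p_raw`,
#'   `class_id`; attributes `n_recognised`, `unrecognised`, `n_duplicates`.
#' @export
plain_enrichment <- function(index, sample, mode = c("entities", "classes")) {
  mode <- match.arg(mode)
  sample <- as.character(sample)
  n_dup <- length(sample) - length(unique(sample))
  sample <- unique(sample)
  recognised <- intersect(sample, index$molecules)
  unrecognised <- setdiff(sample, recognised)
  if (!length(recognised)) {
    stop("no sample id matches a known molecule; unrecognised ids: ",
         paste(unrecognised, collapse = ", "))
  }
  n <- length(recognised)
  hits <- unlist(index$molecule_to_classes[recognised], use.names = FALSE)
  k_by_class <- table(hits)
  k_by_class <- k_by_class[order(names(k_by_class))]
  K <- lengths(index$class_to_molecules[names(k_by_class)])
  p_succ <- class_success_probability(K, index, mode)
  p_raw <- binomial_tail(as.integer(k_by_class), n, pmin(p_succ, 1))
  rows <- enrichment_rows(index, k_by_class, n, p_raw, mode)
  attr(rows, "n_recognised") <- n
  attr(rows, "unrecognised") <- unrecognised
  attr(rows, "n_duplicates") <- n_dup
  rows
}
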