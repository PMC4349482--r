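# Weighted enrichment: significance of the accumulated weight S of the m
# sample molecules inside a class, against the null that the m weights are
# drawn iid from the empirical distribution of the complete submitted
# weight list. The upper tail P[sum >= S] is approximated with the
# Lugannani-Rice saddlepoint formula on the empirical cumulant generating
# function (CGF).

#' Empirical cumulant generating function and derivatives
#'
#' `K(t) = log mean(exp(t * w_i))` computed with max-shift stabilisation;
#' the first and second derivatives are the exponentially tilted mean and
#' variance of the weights.
#'
#' @param weights non-empty numeric vector.
#' @param t evaluation point.
#' @return list with `value`, `d1`, `d2`.
#' @export
empirical_cgf <- function(weights, t) {
  if (!length(weights)) stop("weights must be non-empty")
  x <- t * weights
  M <- max(x)
  z <- exp(x - M)
  sz <- sum(z)
  if (!is.finite(sz) || sz <= 0) stop("numeric overflow in empirical CGF")
  d1 <- sum(weights * z) / sz
  d2 <- max(sum(weights^2 * z) / sz - d1^2, 0)
  list(value = M + log(sz) - log(length(weights)), d1 = d1, d2 = d2)
}

#' Solve the saddlepoint equation m * K'(t) = S
#'
#' Newton iteration with a bisection safeguard on a bracketing interval.
#' Requires S strictly inside the support: `m*min(w) < S < m*max(w)` and a
#' non-degenerate weight list.
#'
#' @param weights background weights.
#' @param m number of summands.
#' @param S observed weight sum.
#' @param tol residual tolerance, relative to `max(1, |S|)`.
#' @return the saddlepoint `t_hat`.
#' @export
solve_saddlepoint <- function(weights, m, S, tol = 1e-10) {
  target <- S / m
  if (target <= min(weights) || target >= max(weights)) {
    stop("S must lie strictly inside the support (m*min(w), m*max(w))")
  }
  resid <- function(t) empirical_cgf(weights, t)$d1 - target
  r0 <- resid(0)
  if (abs(m * r0) <= tol * max(1, abs(S))) return(0)
  # bracket the root: K' is increasing in t
  if (r0 < 0) {
    lo <- 0; hi <- 1
    while (resid(hi) < 0) { lo <- hi; hi <- hi * 2; if (hi > 1e8) break }
  } else {
    hi <- 0; lo <- -1
    while (resid(lo) > 0) { hi <- lo; lo <- lo * 2; if (lo < -1e8) break }
  }
  t <- (lo + hi) / 2
  for (iter in seq_len(200L)) {
    cg <- empirical_cgf(weights, t)
    r <- cg$d1 - target
    if (abs(m * r) <= tol * max(1, abs(S))) return(t)
    if (r > 0) hi <- t else lo <- t
    step <- if (cg$d2 > 0) -r / cg$d2 else NA_real_
    t_new <- t + step
    if (!is.finite(t_new) || t_new <= lo || t_new >= hi) t_new <- (lo + hi) / 2
    if (t_new == t) t_new <- (lo + hi) / 2
    t <- t_new
  }
  cg <- empirical_cgf(weights, t)
  if (abs(m * (cg$d1 - target)) <= 1e-6 * max(1, abs(S))) return(t)
  stop("saddlepoint iteration failed to converge")
}

#' Saddlepoint tail probability of an accumulated weight
#'
#' Approximates `P[sum_{j=1..m} W_j >= S]` for W_j iid from the empirical
#' distribution of `background`, via Lugannani-Rice:
#' `w = sign(t)*sqrt(2*(t*S - m*K(t)))`, `u = t*sqrt(m*K''(t))`,
#' `p = 1 - Phi(w) + phi(w)*(1/u - 1/w)`. For `m = 1` the exact empirical
#' tail proportion is returned instead (the saddlepoint is unreliable for a
#' single lattice-like draw). Near `t = 0` a normal approximation is used.
#' Boundary cases: `S <= m*min(w)` gives 1; `S > m*max(w)` gives 0; at the
#' upper support point the exact point-mass power is returned. The result
#' is clamped to \[0, 1\].
#'
#' @param background numeric vector of all submitted weights.
#' @param m number of sample molecules in the class (>= 1).
#' @param S observed weight sum for the class.
#' @return tail probability.
#' @export
saddlesum_pvalue <- function(background, m, S) {
  if (!length(background)) stop("background weights must be non-empty")
  if (m < 1) stop("m must be >= 1")
  eps <- 1e-12
  if (m == 1) return(mean(background >= S - eps))
  mn <- min(background); mx <- max(background)
  if (S <= m * mn + eps) return(1)
  if (S > m * mx + eps) return(0)
  if (S >= m * mx - eps) return(mean(background >= mx - eps)^m)
  if (mx - mn < eps) return(1)  # degenerate and S <= m*mn handled above

  t_hat <- solve_saddlepoint(background, m, S)
  cg <- empirical_cgf(background, t_hat)
  if (abs(t_hat) < 1e-8) {
    mu <- mean(background)
    v <- mean(background^2) - mu^2
    return(stats::pnorm((S - m * mu) / sqrt(m * v), lower.tail = FALSE))
  }
  arg <- t_hat * S - m * cg$value
  w_hat <- sign(t_hat) * sqrt(2 * max(arg, 0))
  u_hat <- t_hat * sqrt(m * cg$d2)
  p <- stats::pnorm(w_hat, lower.tail = FALSE) +
    stats::dnorm(w_hat) * (1 / u_hat - 1 / w_hat)
  min(max(p, 0), 1)
}

#' Weighted (SaddleSum-style) enrichment analysis
#'
#' For each class with at least one sample member: `m` = member count,
#' `S` = sum of member weights, raw p from [saddlesum_pvalue()] with the
#' complete submitted weight list as background. BH correction, fold and
#' sample percentage are computed as in the plain analysis with `k = m`.
#' With fewer than two distinct weights the background is degenerate and
#' the analysis falls back (with a warning) to plain semantics on the id
#' set.
#'
#' @param index an `annotation_index`.
#' @param sample data.frame with columns `id` and `weight` (weights in
#'   \[0, 1\], ids unique).
#' @param mode background population mode for fold/p_success bookkeeping.
#' @return data.frame of per-class rows sorted by `p_adj`, `p_raw`,
#'   `class_id`; attribute `degenerate` reports a fallback.
#' @export
weighted_enrichment <- function(index, sample, mode = c("entities", "classes")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(sample), all(c("id", "weight") %in% names(sample)))
  bad <- which(is.na(sample$weight) | sample$weight < 0 | sample$weight > 1)
  if (length(bad)) {
    stop("weight outside [0, 1] for id(s): ",
         paste(sample$id[bad], collapse = ", "))
  }
  if (anyDuplicated(sample$id)) stop("duplicate ids in weighted sample")

  if (length(unique(sample$weight)) < 2L) {
    warning("degenerate background (all weights equal); falling back to plain analysis")
    rows <- plain_enrichment(index, sample$id, mode = mode)
    attr(rows, "degenerate") <- TRUE
    return(rows)
  }

  background <- sample$weight
  recognised <- sample[sample$id %in% index$molecules, , drop = FALSE]
  unrecognised <- setdiff(sample$id, recognised$id)
  if (!nrow(recognised)) {
    stop("no sample id matches a known molecule; unrecognised ids: ",
         paste(unrecognised, collapse = ", "))
  }
  n <- nrow(recognised)
  w_of <- stats::setNames(recognised$weight, recognised$id)
  hits <- index$molecule_to_classes[recognised$id]
  cls <- unlist(hits, use.names = FALSE)
  mol <- rep(names(hits), lengths(hits))
  m_by_class <- table(cls)
  S_by_class <- tapply(w_of[mol], cls, sum)
  ord <- order(names(m_by_class))
  m_by_class <- m_by_class[ord]
  S_by_class <- S_by_class[names(m_by_class)]
  p_raw <- vapply(seq_along(m_by_class), function(i) {
    saddlesum_pvalue(background, as.integer(m_by_class[[i]]), S_by_class[[i]])
  }, numeric(1))
  rows <- enrichment_rows(index, m_by_class, n, p_raw, mode)
  attr(rows, "n_recognised") <- n
  attr(rows, "unrecognised") <- unrecognised
  attr(rows, "degenerate") <- FALSE
  rows
}
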