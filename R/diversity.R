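#' Chao1 richness estimator
#'
#' Classic Chao1 from a vector of taxon counts:
#' \deqn{S_{chao1} = S_{obs} + F_1^2 / (2 F_2)}
#' where \eqn{F_1} and \eqn{F_2} are the numbers of singletons and
#' doubletons. When \eqn{F_2 = 0} the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} is used so the estimator
#' is always finite.
#'
#' @param counts integer vector of per-taxon counts; at least one positive.
#' @return list with `S_obs`, `F1`, `F2`, `chao1`.
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  S_obs <- sum(counts > 0)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  est <- if (F2 > 0) S_obs + F1^2 / (2 * F2)
         else S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))
  list(S_obs = S_obs, F1 = F1, F2 = F2, chao1 = est)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log p_i} over taxa with positive counts; natural
#' log by default. Zero counts contribute nothing.
#'
#' @param counts non-negative count (or abundance) vector, at least one
#'   positive entry.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon index, a non-negative real.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (!is.numeric(counts) || any(counts < 0))
    stop("counts must be non-negative numbers")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0))
    stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers; use raw counts, not proportions")
  counts <- round(counts)
  if (sum(counts) <= 0) stop("all-zero count vector")
  counts
}

#' Rarefaction curve for one sample
#'
#' Subsamples the count vector without replacement (multivariate
#' hypergeometric) at `n_points` evenly spaced depths from
#' `total/n_points` up to the full depth, averaging observed richness
#' over `n_rep` random subsamples per depth. Deterministic given `seed`.
#'
#' @param counts integer count vector.
#' @param n_points number of sub-sampling depths (default 10).
#' @param n_rep random subsamples averaged per depth (default 10).
#' @param seed integer seed.
#' @return data.frame with columns `depth`, `mean_observed`.
#' @export
rarefaction_curve <- function(counts, n_points = 10, n_rep = 10, seed = 1) {
  counts <- check_counts(counts)
  total <- sum(counts)
  if (total < n_points)
    stop("total count (", total, ") smaller than n_points (", n_points, ")")
  depths <- unique(round(seq_len(n_points) * total / n_points))
  obs <- withr::with_seed(as.integer(seed), {
    vapply(depths, function(d) {
      mean(vapply(seq_len(n_rep), function(i) {
        sub <- suppressWarnings(vegan::rrarefy(counts, d))
        sum(sub > 0)
      }, numeric(1)))
    }, numeric(1))
  })
  data.frame(depth = depths, mean_observed = obs)
}

#' Per-sample alpha diversity for an abundance table of counts
#'
#' Computes observed richness, singleton/doubleton counts, Chao1 and
#' Shannon for every sample, optionally after rarefying each sample to a
#' common `depth` (without replacement).
#'
#' @param table an `abundance_table` with `type = "counts"`.
#' @param depth optional common subsampling depth; samples with fewer
#'   reads are kept at full depth.
#' @param seed seed for the optional subsampling.
#' @return data.frame: `sample_id`, `S_obs`, `F1`, `F2`, `chao1`,
#'   `shannon`, `depth`.
#' @export
alpha_diversity <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$type != "counts")
    stop("alpha diversity needs raw counts, not relative abundances")
  vals <- round(table$values)
  rows <- lapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    if (!is.null(depth) && sum(x) > depth)
      x <- withr::with_seed(as.integer(seed) + i,
                            as.numeric(suppressWarnings(vegan::rrarefy(x, depth))))
    c1 <- chao1(x)
    data.frame(sample_id = rownames(vals)[i], S_obs = c1$S_obs,
               F1 = c1$F1, F2 = c1$F2, chao1 = c1$chao1,
               shannon = shannon(x), depth = sum(x))
  })
  do.call(rbind, rows)
}
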