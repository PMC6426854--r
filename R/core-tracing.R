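#' Configuration for prevalence-based core tracing
#'
#' @param prevalence_threshold prevalence a taxon must strictly exceed
#'   within a (site, matrix) group to be called present (default 0.70; with
#'   10 samples a taxon therefore needs at least 8).
#' @param min_matrices_for_core matrices a taxon must be present in at a
#'   site to qualify for the core table (default 3 of the 4).
#' @param matrices ordered matrix labels (default CF, LIT, MIL, PC).
#' @return a `tracing_config` list.
#' @export
tracing_config <- function(prevalence_threshold = 0.70,
                           min_matrices_for_core = 3L,
                           matrices = CHAIN_MATRICES) {
  stopifnot(prevalence_threshold > 0, prevalence_threshold < 1,
            min_matrices_for_core >= 1,
            min_matrices_for_core <= length(matrices))
  structure(list(prevalence_threshold = prevalence_threshold,
                 min_matrices_for_core = as.integer(min_matrices_for_core),
                 matrices = matrices),
            class = "tracing_config")
}

#' Prevalence-filter an abundance table into a presence map
#'
#' For every taxon and every (site, matrix) group of samples, computes the
#' prevalence (fraction of samples with abundance > 0) and calls the taxon
#' present when prevalence strictly exceeds the threshold
#' (`mode = "prevalence"`), or when detected in any sample
#' (`mode = "detection"`).
#'
#' @param table an `abundance_table`.
#' @param config a [tracing_config()].
#' @param mode `"prevalence"` (default) or `"detection"`.
#' @return a `presence_map`: data.frame with columns `taxon`, `site`,
#'   `matrix`, `n_samples`, `prevalence`, `present`; attributes record the
#'   threshold and mode.
#' @export
prevalence_filter <- function(table, config = tracing_config(),
                              mode = c("prevalence", "detection")) {
  stopifnot(inherits(table, "abundance_table"))
  mode <- match.arg(mode)
  if (nrow(table$values) == 0)
    stop("table has no samples; nothing to prevalence-filter")
  grp <- split(seq_len(nrow(table$values)),
               list(site = table$meta$site, matrix = table$meta$matrix),
               drop = TRUE)
  if (any(lengths(grp) == 0))
    stop("empty sample group(s): ",
         paste(names(grp)[lengths(grp) == 0], collapse = ", "))
  keys <- strsplit(names(grp), ".", fixed = TRUE)
  rows <- lapply(seq_along(grp), function(g) {
    prev <- colMeans(table$values[grp[[g]], , drop = FALSE] > 0)
    present <- if (mode == "prevalence") prev > config$prevalence_threshold
               else prev > 0
    data.frame(taxon = colnames(table$values),
               site = keys[[g]][1], matrix = keys[[g]][2],
               n_samples = length(grp[[g]]),
               prevalence = as.numeric(prev), present = present,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  pm <- do.call(rbind, rows)
  pm <- pm[order(pm$site, pm$matrix, pm$taxon), , drop = FALSE]
  rownames(pm) <- NULL
  new_presence_map(pm, threshold = config$prevalence_threshold, mode = mode,
                   matrices = config$matrices)
}

new_presence_map <- function(df, threshold, mode, matrices) {
  stopifnot(all(c("taxon", "site", "matrix", "present") %in% names(df)))
  structure(df, class = c("presence_map", "data.frame"),
            threshold = threshold, mode = mode, matrices = matrices)
}

#' Build a presence map directly from a logical taxon x group pattern
#'
#' Used for presence patterns that are given rather than derived from
#' per-sample tables (e.g. a published core-taxon table whose cells mark
#' which (site, matrix) groups passed the prevalence rule).
#'
#' @param present logical matrix, rows = taxa, columns = `site|matrix`
#'   group keys (separator `"|"`).
#' @param threshold the prevalence threshold the pattern encodes.
#' @param matrices matrix labels in effect.
#' @return a `presence_map`.
#' @export
presence_map_from_matrix <- function(present, threshold = 0.70,
                                     matrices = CHAIN_MATRICES) {
  stopifnot(is.logical(present), !is.null(rownames(present)),
            !is.null(colnames(present)))
  keys <- strsplit(colnames(present), "|", fixed = TRUE)
  df <- do.call(rbind, lapply(seq_along(keys), function(j) {
    data.frame(taxon = rownames(present), site = keys[[j]][1],
               matrix = keys[[j]][2], n_samples = NA_integer_,
               prevalence = NA_real_, present = present[, j],
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$site, df$matrix, df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  new_presence_map(df, threshold = threshold, mode = "prevalence",
                   matrices = matrices)
}

present_set <- function(presence, site, matrix) {
  sel <- presence$site == site & presence$matrix == matrix & presence$present
  sort(unique(presence$taxon[sel]))
}

#' Taxa shared across a set of matrices at one site
#'
#' Set intersection of the per-matrix present taxa at `site`.
#'
#' @param presence a `presence_map`.
#' @param site site label.
#' @param matrices non-empty subset of the configured matrices.
#' @return sorted character vector of shared taxa.
#' @export
shared_across_matrices <- function(presence, site, matrices) {
  stopifnot(inherits(presence, "presence_map"), length(matrices) >= 1)
  known_m <- attr(presence, "matrices")
  if (!all(matrices %in% known_m))
    stop("unknown matrix: ", paste(setdiff(matrices, known_m), collapse = ", "))
  if (!site %in% presence$site) stop("unknown site: ", site)
  sets <- lapply(matrices, function(m) present_set(presence, site, m))
  sort(Reduce(intersect, sets))
}

#' Shared-taxon counts for every matrix combination
#'
#' For every combination of two or more matrices, counts the taxa shared
#' (present in all matrices of the combination) at each site, and the
#' average of those counts across sites.
#'
#' @param presence a `presence_map`.
#' @param sites sites to tabulate (default: all sites in the map).
#' @return data.frame with columns `site`, `combination` (matrix labels
#'   joined by "+"), `n_matrices`, `count`; per-site rows followed by rows
#'   with `site == "average"` carrying the cross-site mean.
#' @export
pairwise_sharing_counts <- function(presence, sites = NULL) {
  stopifnot(inherits(presence, "presence_map"))
  if (is.null(sites)) sites <- sort(unique(presence$site))
  mats <- intersect(attr(presence, "matrices"), unique(presence$matrix))
  combos <- unlist(lapply(2:length(mats), function(k)
    combn(mats, k, simplify = FALSE)), recursive = FALSE)
  per_site <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site = s,
               combination = vapply(combos, paste, character(1), collapse = "+"),
               n_matrices = lengths(combos),
               count = vapply(combos, function(cm)
                 length(shared_across_matrices(presence, s, cm)), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  avg <- stats::aggregate(count ~ combination + n_matrices, per_site, mean)
  avg <- data.frame(site = "average", combination = avg$combination,
                    n_matrices = avg$n_matrices, count = avg$count,
                    stringsAsFactors = FALSE)
  out <- rbind(per_site, avg)
  rownames(out) <- NULL
  out
}

#' Number of sites at which each taxon qualifies
#'
#' A taxon qualifies at a site when it is present (per the presence map)
#' in at least `min_matrices` of the matrices sampled there. This is the
#' rule behind the published core table: taxa with a prevalence > 70% in
#' at least three matrices of a cheese-making site.
#'
#' @param presence a `presence_map`.
#' @param min_matrices minimum matrices per site (default 3).
#' @return data.frame `taxon`, `n_sites` (sites where the taxon
#'   qualifies), sorted by taxon; attribute `histogram` tabulates
#'   n_sites over taxa with at least one qualifying site.
#' @export
site_sharing <- function(presence, min_matrices = 3L) {
  stopifnot(inherits(presence, "presence_map"), min_matrices >= 1)
  sub <- presence[presence$present, c("taxon", "site", "matrix")]
  qual <- stats::aggregate(matrix ~ taxon + site, sub, length)
  qual <- qual[qual$matrix >= min_matrices, ]
  n_sites <- table(qual$taxon)
  taxa <- sort(unique(presence$taxon))
  out <- data.frame(taxon = taxa,
                    n_sites = as.integer(n_sites[taxa]),
                    stringsAsFactors = FALSE)
  out$n_sites[is.na(out$n_sites)] <- 0L
  attr(out, "histogram") <- table(out$n_sites[out$n_sites > 0])
  out
}

#' Core table of mean relative abundances
#'
#' For every taxon qualifying under the site-sharing rule (present in at
#' least `config$min_matrices_for_core` matrices at one or more sites),
#' the mean relative abundance per (site, matrix) group where the taxon
#' is present; `NA` where it is not.
#'
#' @param table the `abundance_table` the presence map was computed from.
#' @param presence a `presence_map`.
#' @param config a [tracing_config()].
#' @return numeric matrix, rows = `site|matrix` groups, columns =
#'   qualifying taxa, `NA` marking absence.
#' @export
core_table <- function(table, presence, config = tracing_config()) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(presence, "presence_map"))
  ss <- site_sharing(presence, config$min_matrices_for_core)
  taxa <- ss$taxon[ss$n_sites >= 1]
  if (!all(taxa %in% colnames(table$values)))
    stop("presence map names taxa absent from the table")
  grp <- split(seq_len(nrow(table$values)),
               paste(table$meta$site, table$meta$matrix, sep = "|"))
  mm <- vapply(grp, function(idx)
    colMeans(table$values[idx, taxa, drop = FALSE]),
    numeric(length(taxa)))
  means <- matrix(mm, nrow = length(grp), ncol = length(taxa),
                  byrow = length(taxa) > 1,
                  dimnames = list(names(grp), taxa))
  # blank out cells where the taxon is not called present
  for (g in rownames(means)) {
    key <- strsplit(g, "|", fixed = TRUE)[[1]]
    ps <- present_set(presence, key[1], key[2])
    means[g, !(taxa %in% ps)] <- NA_real_
  }
  means[order(rownames(means)), , drop = FALSE]
}

#' Write a presence map, sharing counts or core table as TSV
#'
#' @param x the object (`presence_map`, sharing-count data.frame, or core
#'   table matrix).
#' @param path output file.
#' @export
write_tracing_tsv <- function(x, path) {
  if (is.matrix(x))
    x <- cbind(data.frame(group = rownames(x)),
               as.data.frame(x, check.names = FALSE))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
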