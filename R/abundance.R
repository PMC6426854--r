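CHAIN_MATRICES <- c("CF", "LIT", "MIL", "PC")

#' Construct an abundance table
#'
#' Samples x taxa matrix of counts or relative abundances with per-sample
#' metadata giving the production site and the sampled matrix (material
#' type): CF = cow feces, LIT = litter, MIL = raw milk, PC = fresh cheese.
#'
#' @param values numeric matrix, rows = samples, columns = taxa. Row names
#'   are taken as sample ids when `meta` lacks them.
#' @param meta data.frame with columns `sample_id`, `site`, `matrix` and
#'   optionally `replicate`, one row per sample, in row order of `values`.
#' @param type `"relative"` (row sums must be <= 1 + 1e-9) or `"counts"`.
#' @param matrices allowed matrix labels (default CF, LIT, MIL, PC).
#' @return an object of class `abundance_table`: list with elements
#'   `values`, `meta`, `type`.
#' @export
abundance_table <- function(values, meta,
                            type = c("relative", "counts"),
                            matrices = CHAIN_MATRICES) {
  type <- match.arg(type)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "site", "matrix") %in% names(meta)))
    stop("meta must have columns sample_id, site, matrix")
  if (nrow(meta) != nrow(values))
    stop("meta has ", nrow(meta), " rows but values has ", nrow(values))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad_mat <- setdiff(unique(meta$matrix), matrices)
  if (length(bad_mat))
    stop("unknown matrix label(s): ", paste(bad_mat, collapse = ", "),
         " (allowed: ", paste(matrices, collapse = ", "), ")")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at sample '", meta$sample_id[neg[1, 1]],
         "', taxon '", colnames(values)[neg[1, 2]], "'")
  if (type == "relative" && nrow(values)) {
    rs <- rowSums(values, na.rm = TRUE)
    if (any(rs > 1 + 1e-9))
      stop("relative-abundance row sums exceed 1 (sample '",
           meta$sample_id[which.max(rs)], "': ", max(rs), ")")
  }
  if (is.null(colnames(values)))
    stop("values must have taxon column names")
  rownames(values) <- meta$sample_id
  if (is.null(meta$replicate)) meta$replicate <- seq_len(nrow(meta))
  structure(list(values = values, meta = meta, type = type,
                 matrices = matrices),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values), x$type))
  tab <- table(x$meta$site, x$meta$matrix)
  print(tab)
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

META_COLS <- c("sample_id", "site", "matrix", "replicate")

#' Read / write abundance tables as TSV
#'
#' The on-disk layout is one row per sample: the metadata columns
#' `sample_id`, `site`, `matrix`, `replicate` followed by one numeric
#' column per taxon. `write_table()` then `read_table()` is lossless.
#'
#' @param path TSV file path.
#' @param type passed to [abundance_table()].
#' @return `read_table()`: an `abundance_table`; `write_table()`: the path,
#'   invisibly.
#' @export
read_table <- function(path, type = c("relative", "counts")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "site", "matrix"), names(df))
  if (length(miss))
    stop("abundance TSV '", path, "' lacks metadata column(s): ",
         paste(miss, collapse = ", "))
  taxa <- setdiff(names(df), META_COLS)
  vals <- as.matrix(df[, taxa, drop = FALSE])
  meta <- df[, intersect(META_COLS, names(df)), drop = FALSE]
  abundance_table(vals, meta, type = match.arg(type))
}

#' @param table an `abundance_table`.
#' @rdname read_table
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- cbind(table$meta[, META_COLS, drop = FALSE],
              as.data.frame(table$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

group_index <- function(table) {
  interaction(table$meta$site, table$meta$matrix, drop = TRUE, sep = "\r")
}

#' Prevalence of a taxon in a group of samples
#'
#' Fraction of the group's samples in which the taxon is detected
#' (abundance strictly greater than zero).
#'
#' @param table an `abundance_table`.
#' @param samples character vector of sample ids forming the group.
#' @param taxon taxon (column) name.
#' @return fraction in \[0, 1\].
#' @export
prevalence <- function(table, samples, taxon) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(samples) == 0) stop("empty sample group")
  miss <- setdiff(samples, rownames(table$values))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  if (!taxon %in% colnames(table$values)) stop("unknown taxon: ", taxon)
  mean(table$values[samples, taxon] > 0)
}
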