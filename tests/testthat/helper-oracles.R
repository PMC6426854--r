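# Independent oracles written in plain base R (no Biostrings), used to
# cross-check the package's matchers on randomized instances.

rc_plain <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# all exact full-length occurrences of each read (both strands) in a set
# of contigs, by brute-force substring comparison
naive_hits <- function(reads, contigs) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    w <- nchar(reads$sequence[i])
    for (cn in names(contigs)) {
      L <- nchar(contigs[[cn]])
      if (L < w) next
      starts <- seq_len(L - w + 1)
      wins <- substring(contigs[[cn]], starts, starts + w - 1)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") reads$sequence[i]
               else rc_plain(reads$sequence[i])
        hit <- which(wins == pat & !grepl("[^ACGT]", pat))
        if (length(hit))
          out[[length(out) + 1]] <- data.frame(
            read_id = reads$read_id[i], contig = cn, start = hit - 1L,
            end = hit - 1L + w, strand = strand,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  do.call(rbind, out)
}

hit_key <- function(h) sort(paste(h$read_id, h$contig, h$start, h$strand))

# per-read accumulation pileup oracle
naive_pileup <- function(hits, reads, contigs) {
  seqs <- setNames(reads$sequence, reads$read_id)
  lapply(setNames(nm = names(contigs)), function(cn) {
    L <- nchar(contigs[[cn]])
    counts <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    h <- hits[hits$contig == cn, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      s <- seqs[[h$read_id[i]]]
      if (h$strand[i] == "-") s <- rc_plain(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (j in seq_along(ch)) {
        b <- ch[j]
        if (b %in% rownames(counts))
          counts[b, h$start[i] + j] <- counts[b, h$start[i] + j] + 1L
      }
    }
    counts
  })
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# presence map from an explicit taxon x group truth list
toy_presence <- function(truth, sites, matrices) {
  taxa <- names(truth)
  keys <- as.vector(outer(sites, matrices, paste, sep = "|"))
  m <- matrix(FALSE, length(taxa), length(keys),
              dimnames = list(taxa, keys))
  for (tx in taxa)
    for (g in truth[[tx]]) m[tx, g] <- TRUE
  presence_map_from_matrix(m)
}
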