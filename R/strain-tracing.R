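#' Construct a contig set
#'
#' Species-assigned assembled contigs, the raw material for strain-marker
#' selection.
#'
#' @param id character vector of unique contig ids.
#' @param sequence character vector of contig sequences.
#' @param species species label per contig.
#' @param sample sample of origin per contig (optional).
#' @return a `contig_set` data.frame: `id`, `sequence`, `species`,
#'   `sample`, `length`.
#' @export
contig_set <- function(id, sequence, species = NA_character_,
                       sample = NA_character_) {
  sequence <- toupper(sequence)
  if (anyDuplicated(id)) stop("contig ids must be unique")
  df <- data.frame(id = as.character(id), sequence = sequence,
                   species = species, sample = sample,
                   length = nchar(sequence), stringsAsFactors = FALSE)
  structure(df, class = c("contig_set", "data.frame"))
}

#' Retain contigs longer than a minimum length
#'
#' Keeps contigs with length strictly greater than `min_len` (default
#' 3000 bp, the accuracy filter applied before taxonomic assignment of
#' assembled sequences); order preserved.
#'
#' @param contigs a [contig_set()].
#' @param min_len minimum length, exclusive.
#' @return the filtered `contig_set`.
#' @export
filter_contigs <- function(contigs, min_len = 3000) {
  stopifnot(inherits(contigs, "contig_set"))
  out <- contigs[contigs$length > min_len, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contig_set", "data.frame"))
}

#' Select the marker contig for a species
#'
#' The largest contig assigned to the species — taken to represent a
#' chromosomal region of one specific strain — is used for primer design;
#' length ties are broken by lexicographically smallest id.
#'
#' @param contigs a [contig_set()].
#' @param species species to select for; default uses all rows.
#' @return a one-row `contig_set`.
#' @export
select_marker_contig <- function(contigs, species = NULL) {
  stopifnot(inherits(contigs, "contig_set"))
  sub <- if (is.null(species)) contigs
         else contigs[!is.na(contigs$species) & contigs$species == species, ,
                      drop = FALSE]
  if (nrow(sub) == 0)
    stop("no contigs", if (!is.null(species)) paste0(" for species '", species, "'"))
  sub <- sub[order(-sub$length, sub$id), , drop = FALSE]
  out <- sub[1, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contig_set", "data.frame"))
}

#' Primer design constraints
#'
#' @param primer_len inclusive primer length bounds (default 18-25 nt).
#' @param product_len inclusive amplicon length bounds (default 100-600 bp).
#' @param gc inclusive GC-fraction bounds (default 0.40-0.60).
#' @param tm inclusive Wallace-rule melting-temperature window in degrees
#'   C (default 50-65).
#' @return a `primer_constraints` list.
#' @export
primer_constraints <- function(primer_len = c(18L, 25L),
                               product_len = c(100L, 600L),
                               gc = c(0.40, 0.60),
                               tm = c(50, 65)) {
  stopifnot(length(primer_len) == 2, primer_len[1] <= primer_len[2],
            length(product_len) == 2, product_len[1] <= product_len[2],
            gc[1] <= gc[2], tm[1] <= tm[2])
  structure(list(primer_len = as.integer(primer_len),
                 product_len = as.integer(product_len),
                 gc = gc, tm = tm),
            class = "primer_constraints")
}

# all constraint-satisfying primer windows of a sequence, ordered by
# (start, length); returns data.frame(start0, len, seq)
candidate_windows <- function(seq, cons) {
  L <- nchar(seq)
  subj <- Biostrings::DNAString(seq)
  out <- list()
  for (len in cons$primer_len[1]:cons$primer_len[2]) {
    if (len > L) next
    v <- Biostrings::Views(subj, start = seq_len(L - len + 1), width = len)
    gc <- as.vector(Biostrings::letterFrequency(v, "GC"))
    gcf <- gc / len
    tm <- 2 * (len - gc) + 4 * gc
    ok <- gcf >= cons$gc[1] & gcf <= cons$gc[2] &
          tm >= cons$tm[1] & tm <= cons$tm[2]
    if (any(ok))
      out[[length(out) + 1]] <- data.frame(
        start0 = which(ok) - 1L, len = len,
        seq = as.character(v[ok]), tm = tm[ok],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start0 = integer(0), len = integer(0),
                      seq = character(0), tm = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$start0, df$len), , drop = FALSE]
}

count_hits <- function(pattern, subjects) {
  sum(vapply(subjects, function(s)
    Biostrings::countPattern(pattern, s, fixed = TRUE), numeric(1)))
}

# specific = absent (both strands) from every background sequence
is_specific <- function(primer, background_dna) {
  if (length(background_dna) == 0) return(TRUE)
  count_hits(Biostrings::DNAString(primer), background_dna) == 0 &&
    count_hits(Biostrings::DNAString(revcomp(primer)), background_dna) == 0
}

occurs_once_in_marker <- function(primer, marker_dna) {
  (count_hits(Biostrings::DNAString(primer), list(marker_dna)) +
     count_hits(Biostrings::DNAString(revcomp(primer)), list(marker_dna))) == 1
}

#' Design a strain-specific primer pair on a marker contig
#'
#' Deterministic left-to-right scan over the marker: forward-primer
#' windows are visited in order of (start, length), amplicon lengths in
#' increasing order, reverse-primer lengths in increasing order. The
#' first pair is returned in which each primer satisfies the length / GC
#' / melting-temperature constraints, occurs exactly once in the marker
#' (either strand), and neither the primer nor its reverse complement
#' occurs as an exact substring of any background sequence. The exact
#' background screen is a conservative, fully deterministic specificity
#' criterion: one exact hit anywhere disqualifies the primer.
#'
#' @param marker a one-row [contig_set()] (or list with `id`, `sequence`,
#'   `species`).
#' @param background character vector of background sequences the pair
#'   must not match (may be empty).
#' @param constraints a [primer_constraints()].
#' @return a `strain_marker`: list with `species`, `contig_id`,
#'   `marker_length`, `fwd` (`seq`, `start`, `tm`), `rev` (`seq`,
#'   `start` of its binding site on the + strand, `tm`),
#'   `product_length`, `specificity` (`n_background`, `exact_hits`).
#' @export
design_primers <- function(marker, background = character(0),
                           constraints = primer_constraints()) {
  seqx <- toupper(if (is.data.frame(marker)) marker$sequence[1]
                  else marker$sequence)
  cid <- if (is.data.frame(marker)) marker$id[1] else marker$id
  spp <- if (is.data.frame(marker)) marker$species[1] else marker$species
  cons <- constraints
  L <- nchar(seqx)
  if (L < cons$product_len[1])
    stop("marker shorter than the minimum product length")
  marker_dna <- Biostrings::DNAString(seqx)
  bg <- lapply(toupper(background), Biostrings::DNAString)

  wins <- candidate_windows(seqx, cons)
  if (nrow(wins) == 0)
    stop("no specific primer pair exists under the given constraints")
  # index candidate reverse windows by their (exclusive) end coordinate
  wins$end0 <- wins$start0 + wins$len
  by_end <- split(seq_len(nrow(wins)), wins$end0)

  fwd_ok <- logical(nrow(wins)); fwd_checked <- logical(nrow(wins))
  check_fwd <- function(i) {
    if (!fwd_checked[i]) {
      fwd_checked[i] <<- TRUE
      fwd_ok[i] <<- occurs_once_in_marker(wins$seq[i], marker_dna) &&
        is_specific(wins$seq[i], bg)
    }
    fwd_ok[i]
  }

  for (i in seq_len(nrow(wins))) {
    if (!check_fwd(i)) next
    f_start <- wins$start0[i]
    for (plen in cons$product_len[1]:cons$product_len[2]) {
      pend <- f_start + plen                     # exclusive, 0-based
      if (pend > L) break
      js <- by_end[[as.character(pend)]]
      if (is.null(js)) next
      js <- js[wins$start0[js] > f_start + wins$len[i]]  # no overlap with fwd
      for (j in js[order(wins$len[js])]) {
        rev_primer <- revcomp(wins$seq[j])
        if (!occurs_once_in_marker(rev_primer, marker_dna)) next
        if (!is_specific(rev_primer, bg)) next
        return(structure(list(
          species = spp, contig_id = cid, marker_length = L,
          marker_sequence = seqx,
          fwd = list(seq = wins$seq[i], start = f_start, tm = wins$tm[i]),
          rev = list(seq = rev_primer, start = wins$start0[j],
                     tm = wins$tm[j]),
          product_length = plen,
          specificity = list(n_background = length(bg), exact_hits = 0L)),
          class = "strain_marker"))
      }
    }
  }
  stop("no specific primer pair exists under the given constraints",
       " (marker '", cid, "' is not strain-discriminative against this",
       " background)")
}

#' @export
print.strain_marker <- function(x, ...) {
  cat(sprintf(paste0("strain_marker for %s (contig %s, %d bp)\n",
                     "  fwd %s @%d (Tm %.0f)\n  rev %s @%d (Tm %.0f)\n",
                     "  product %d bp; screened against %d background",
                     " sequences, 0 exact hits\n"),
              x$species, x$contig_id, x$marker_length,
              x$fwd$seq, x$fwd$start, x$fwd$tm,
              x$rev$seq, x$rev$start, x$rev$tm,
              x$product_length, x$specificity$n_background))
  invisible(x)
}

#' Run an in-silico PCR with a strain-specific primer pair
#'
#' Reports an amplicon wherever the forward primer matches exactly on one
#' strand and the reverse primer's reverse complement matches exactly
#' downstream within `max_product`. Both orientations are searched; a
#' single mismatch in either primer site suppresses the amplicon (exact-
#' match semantics). Presence call = at least one amplicon.
#'
#' @param marker a `strain_marker` from [design_primers()].
#' @param targets named character vector of target sequences.
#' @param max_product maximum amplicon length searched (default 2000 bp).
#' @return data.frame `target`, `start` (0-based on the given sequence),
#'   `end` (exclusive), `length`, `orientation` ("+" = forward primer on
#'   the given strand); zero rows = negative call.
#' @export
in_silico_pcr <- function(marker, targets, max_product = 2000) {
  stopifnot(inherits(marker, "strain_marker"))
  if (is.null(names(targets)))
    names(targets) <- paste0("target", seq_along(targets))
  res <- list()
  for (nm in names(targets)) {
    tseq <- toupper(targets[[nm]])
    L <- nchar(tseq)
    for (orient in c("+", "-")) {
      s <- if (orient == "+") tseq else revcomp(tseq)
      subj <- Biostrings::DNAString(s)
      fs <- Biostrings::start(Biostrings::matchPattern(marker$fwd$seq, subj,
                                                       fixed = TRUE)) - 1L
      rr <- Biostrings::matchPattern(revcomp(marker$rev$seq), subj,
                                     fixed = TRUE)
      re <- Biostrings::end(rr)                  # 1-based inclusive = 0-based excl
      if (!length(fs) || !length(re)) next
      for (f in fs) {
        hits <- re[re > f & (re - f) <= max_product]
        for (h in hits) {
          st <- f; en <- h
          if (orient == "-") { st <- L - h; en <- L - f }
          res[[length(res) + 1]] <- data.frame(
            target = nm, start = as.integer(st), end = as.integer(en),
            length = as.integer(en - st), orientation = orient,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(target = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, res)[, c("target", "start", "end", "length",
                                        "orientation")])
  rownames(out) <- NULL
  out
}

#' Read-mapping configuration
#'
#' The defaults encode the strict presence rule: a read counts only if it
#' maps with 100% identity over 100% of its length.
#'
#' @param identity_cutoff minimum alignment identity in (0, 1\];
#'   values below 1 route mapping through the mismatch-tolerant engine.
#' @param coverage_cutoff minimum aligned fraction of the read in (0, 1\];
#'   values below 1 allow alignments truncated by contig ends.
#' @param both_strands search both strands (default TRUE).
#' @param min_reads minimum mapped reads for a presence call (default 1).
#' @param min_breadth minimum reference breadth of coverage for a
#'   presence call (default 0.5).
#' @return a `mapping_config` list.
#' @export
mapping_config <- function(identity_cutoff = 1.0, coverage_cutoff = 1.0,
                           both_strands = TRUE, min_reads = 1L,
                           min_breadth = 0.5) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 1,
            coverage_cutoff > 0, coverage_cutoff <= 1,
            min_reads >= 0, min_breadth >= 0, min_breadth <= 1)
  structure(list(identity_cutoff = identity_cutoff,
                 coverage_cutoff = coverage_cutoff,
                 both_strands = both_strands,
                 min_reads = as.integer(min_reads),
                 min_breadth = min_breadth),
            class = "mapping_config")
}

as_reference <- function(reference) {
  if (inherits(reference, "contig_set"))
    setNames(reference$sequence, reference$id)
  else {
    r <- toupper(unlist(reference))
    if (is.null(names(r))) names(r) <- paste0("contig", seq_along(r))
    r
  }
}

empty_hits <- function() {
  data.frame(read_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

#' Strict exact-match read mapping
#'
#' A read hits wherever it (or, with `both_strands`, its reverse
#' complement) is an exact, full-length substring of a reference contig;
#' all occurrences are reported. Reads containing ambiguous bases never
#' match. Internally the constant-width read sets are matched with a
#' preprocessed dictionary (seed-and-verify), which is equivalent to
#' naive substring search.
#'
#' @param reads a `read_set`, data.frame with `read_id` and `sequence`,
#'   or named character vector.
#' @param reference a [contig_set()] or named character vector.
#' @param config a [mapping_config()]; with `identity_cutoff` or
#'   `coverage_cutoff` below 1 the call is delegated to [tolerant_map()].
#' @return hit data.frame: `read_id`, `contig`, `start` (0-based), `end`
#'   (exclusive), `strand`, `mismatches` (all 0 here). Unmapped reads
#'   simply have no rows.
#' @export
strict_map <- function(reads, reference, config = mapping_config()) {
  if (config$identity_cutoff < 1 || config$coverage_cutoff < 1)
    return(tolerant_map(reads, reference,
                        max_mismatch_frac = 1 - config$identity_cutoff,
                        min_cov_frac = config$coverage_cutoff,
                        both_strands = config$both_strands,
                        all_hits = FALSE))
  rd <- normalize_reads(reads)
  if (nrow(rd) == 0) stop("empty read set")
  ref <- as_reference(reference)
  if (length(ref) == 0) stop("empty reference")
  clean <- grepl("^[ACGT]+$", rd$sequence)
  rd_ok <- rd[clean, , drop = FALSE]
  hits <- list()
  for (w in unique(nchar(rd_ok$sequence))) {
    sel <- which(nchar(rd_ok$sequence) == w)
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(rd_ok$sequence[sel]))
    pd_rev <- if (config$both_strands)
      Biostrings::PDict(Biostrings::DNAStringSet(revcomp(rd_ok$sequence[sel])))
    for (cn in names(ref)) {
      subj <- Biostrings::DNAString(ref[[cn]])
      if (nchar(ref[[cn]]) < w) next
      for (strand in c("+", if (config$both_strands) "-")) {
        pd <- if (strand == "+") pd_fwd else pd_rev
        m <- Biostrings::matchPDict(pd, subj)
        st <- Biostrings::startIndex(m)
        nz <- which(lengths(st) > 0)
        if (!length(nz)) next
        hits[[length(hits) + 1]] <- data.frame(
          read_id = rep(rd_ok$read_id[sel][nz], lengths(st)[nz]),
          contig = cn,
          start = unlist(st[nz]) - 1L,
          end = unlist(st[nz]) - 1L + w,
          strand = strand, mismatches = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$contig, out$start, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(data.frame(read_id = ids, sequence = toupper(reads),
                      stringsAsFactors = FALSE))
  }
  df <- as.data.frame(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(df)))
  df$sequence <- toupper(df$sequence)
  df
}

#' Coverage and presence call from mapping hits
#'
#' Breadth = covered reference positions / total reference length; depth
#' = total aligned bases / total reference length. Presence requires at
#' least `min_reads` hits and breadth of at least `min_breadth`.
#'
#' @param hits hit data.frame from [strict_map()] or [tolerant_map()].
#' @param reference the same reference the hits were produced against.
#' @param config a [mapping_config()].
#' @return list: `n_hits`, `breadth`, `depth`, `presence`, and
#'   `per_contig` data.frame (`contig`, `length`, `n_hits`, `breadth`,
#'   `depth`).
#' @export
coverage_and_presence <- function(hits, reference, config = mapping_config()) {
  ref <- as_reference(reference)
  if (nrow(hits) && length(setdiff(unique(hits$contig), names(ref))))
    stop("hits refer to contigs absent from the reference")
  per <- lapply(names(ref), function(cn) {
    L <- nchar(ref[[cn]])
    h <- hits[hits$contig == cn, , drop = FALSE]
    if (nrow(h) == 0)
      return(data.frame(contig = cn, length = L, n_hits = 0L,
                        breadth = 0, depth = 0, stringsAsFactors = FALSE))
    ir <- IRanges::reduce(IRanges::IRanges(start = h$start + 1, end = h$end))
    data.frame(contig = cn, length = L, n_hits = nrow(h),
               breadth = sum(IRanges::width(ir)) / L,
               depth = sum(h$end - h$start) / L, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  tot_len <- sum(per$length)
  breadth <- sum(per$breadth * per$length) / tot_len
  depth <- sum(per$depth * per$length) / tot_len
  list(n_hits = sum(per$n_hits), breadth = breadth, depth = depth,
       presence = sum(per$n_hits) >= config$min_reads &&
         breadth >= config$min_breadth,
       per_contig = per)
}
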