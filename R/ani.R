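#' Fragment-based ANI configuration
#'
#' Defaults follow the fragment convention of BLAST-based ANI: the query
#' is cut into 1020 bp pieces, fragment alignments are retained when they
#' reach at least 30% identity over at least 70% of the fragment length,
#' and the reported value is the mean of both directions.
#'
#' @param fragment_length fragment size in bp (default 1020, >= 100).
#' @param min_identity retention identity threshold in (0, 1\] (default 0.30).
#' @param min_coverage retention fragment-coverage threshold in (0, 1\]
#'   (default 0.70).
#' @param seed_width exact seed width used to locate candidate fragment
#'   placements (default 16).
#' @return an `ani_config` list.
#' @export
ani_config <- function(fragment_length = 1020L, min_identity = 0.30,
                       min_coverage = 0.70, seed_width = 16L) {
  stopifnot(fragment_length >= 100,
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1,
            seed_width >= 8)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_identity = min_identity, min_coverage = min_coverage,
                 seed_width = as.integer(seed_width)),
            class = "ani_config")
}

cut_fragments <- function(genome, flen) {
  L <- nchar(genome)
  starts <- seq.int(1L, L, by = flen)
  frags <- substring(genome, starts, pmin(starts + flen - 1L, L))
  frags[nchar(frags) >= 100L]
}

# best ungapped identity of each query fragment in the subject
ani_one_way <- function(query, subject, config) {
  frags <- cut_fragments(query, config$fragment_length)
  if (!length(frags)) stop("query too short to cut into fragments")
  subj <- list("+" = Biostrings::DNAString(subject),
               "-" = Biostrings::DNAString(revcomp(subject)))
  Ls <- nchar(subject)
  sw <- config$seed_width
  best <- rep(NA_real_, length(frags))
  frag_dna <- lapply(frags, Biostrings::DNAString)

  # one seed dictionary over all (fragment, offset) slices
  seed_tab <- do.call(rbind, lapply(seq_along(frags), function(i) {
    fw <- nchar(frags[i])
    off <- seq.int(0L, fw - sw, by = max(sw * 3L, 1L))
    data.frame(frag = i, off = off,
               seed = substring(frags[i], off + 1, off + sw),
               stringsAsFactors = FALSE)
  }))
  seed_tab <- seed_tab[grepl("^[ACGT]+$", seed_tab$seed), , drop = FALSE]
  if (!nrow(seed_tab)) stop("no usable seeds (non-ACGT genome?)")
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_tab$seed))

  for (strand in c("+", "-")) {
    m <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj[[strand]]))
    hit <- which(lengths(m) > 0)
    if (!length(hit)) next
    # candidate fragment placements, deduplicated per fragment
    cand <- data.frame(
      frag = rep(seed_tab$frag[hit], lengths(m)[hit]),
      start0 = unlist(m[hit]) - 1L - rep(seed_tab$off[hit], lengths(m)[hit]))
    cand <- unique(cand)
    for (i in unique(cand$frag)) {
      fw <- nchar(frags[i])
      fd <- frag_dna[[i]]
      for (s0 in cand$start0[cand$frag == i]) {
        rs <- max(0L, s0); re <- min(Ls, s0 + fw)
        ov <- re - rs
        if (ov < config$min_coverage * fw) next
        pat <- if (ov == fw) fd
               else Biostrings::subseq(fd, start = max(0L, -s0) + 1, width = ov)
        mm <- Biostrings::neditStartingAt(pat, subj[[strand]],
                                          starting.at = rs + 1,
                                          with.indels = FALSE, fixed = TRUE)
        ident <- (ov - mm) / ov
        if (is.na(best[i]) || ident > best[i]) best[i] <- ident
      }
    }
  }
  retained <- best[!is.na(best) & best >= config$min_identity]
  list(ani = if (length(retained)) mean(retained) * 100 else NA_real_,
       n_fragments = length(frags), n_retained = length(retained))
}

#' Average nucleotide identity between two genomes
#'
#' The query is cut into consecutive fragments; each fragment is placed
#' at its best ungapped location in the subject (exact-seed candidates,
#' then full mismatch-count verification, both strands) and retained if
#' it aligns with at least `min_identity` identity over at least
#' `min_coverage` of its length. One direction's ANI is the mean identity
#' of retained fragments (x 100); the reported value averages both
#' directions. An ANI near 100% indicates the same strain.
#'
#' @param query,subject genome sequences (character strings, or named
#'   character vectors of contigs which are concatenated with a
#'   non-matching `N` spacer).
#' @param config an [ani_config()].
#' @return list: `ani` (percent), `forward`, `reverse` (per-direction
#'   results with fragment counts for audit).
#' @export
ani <- function(query, subject, config = ani_config()) {
  q <- paste(toupper(unlist(query)), collapse = strrep("N", 20))
  s <- paste(toupper(unlist(subject)), collapse = strrep("N", 20))
  if (nchar(q) == 0 || nchar(s) == 0) stop("empty genome")
  fwd <- ani_one_way(q, s, config)
  rev <- ani_one_way(s, q, config)
  if (is.na(fwd$ani) && is.na(rev$ani))
    stop("no ANI support: no fragment aligned above the retention thresholds")
  structure(list(ani = mean(c(fwd$ani, rev$ani), na.rm = TRUE),
                 forward = fwd, reverse = rev, config = config),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf(paste0("ANI %.4f%% (query->subject %.4f%% on %d/%d fragments;",
                     " subject->query %.4f%% on %d/%d)\n"),
              x$ani, x$forward$ani, x$forward$n_retained,
              x$forward$n_fragments, x$reverse$ani, x$reverse$n_retained,
              x$reverse$n_fragments))
  invisible(x)
}
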