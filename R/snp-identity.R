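## Mismatch-tolerant ungapped mapping and SNP allele-frequency profiles.
## Alignments are ungapped throughout: reads either fit entirely inside a
## contig or (with min_cov_frac < 1) hang off an end with the overhang
## clipped. Candidate locations come from exact seed matches (pigeonhole:
## with <= k mismatches, at least one of k+1 non-overlapping seeds is
## exact), then every candidate is verified by direct mismatch counting.

mismatch_count <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Mismatch-tolerant ungapped read mapping
#'
#' Aligns each read (both strands) to every reference contig without
#' gaps, allowing at most `floor(max_mismatch_frac * aligned length)`
#' substitutions. Each read is assigned its single best (fewest-mismatch)
#' location; if two or more locations tie for best the read is treated as
#' ambiguous and left unmapped. Ambiguous bases count as mismatches.
#'
#' @param reads a `read_set`, data.frame with `read_id`/`sequence`, or
#'   named character vector.
#' @param reference a [contig_set()] or named character vector.
#' @param max_mismatch_frac maximum mismatch fraction (default 0.05).
#' @param min_cov_frac minimum aligned fraction of the read; below 1
#'   alignments may be clipped by contig ends (default 1).
#' @param both_strands search both strands (default TRUE).
#' @param all_hits return every acceptable location instead of the unique
#'   best one (used by the strict mapper's delegation; default FALSE).
#' @return hit data.frame: `read_id`, `contig`, `start` (0-based), `end`
#'   (exclusive), `strand`, `mismatches`, `qstart` (0-based offset of the
#'   aligned part within the strand-oriented read).
#' @export
tolerant_map <- function(reads, reference, max_mismatch_frac = 0.05,
                         min_cov_frac = 1, both_strands = TRUE,
                         all_hits = FALSE) {
  rd <- normalize_reads(reads)
  if (nrow(rd) == 0) stop("empty read set")
  ref <- as_reference(reference)
  if (length(ref) == 0) stop("empty reference")
  subj_dna <- lapply(ref, Biostrings::DNAString)
  acc <- list()

  for (w in unique(nchar(rd$sequence))) {
    idx <- which(nchar(rd$sequence) == w)
    k <- floor(max_mismatch_frac * w)
    sw <- max(4L, w %/% (k + 1L))
    offsets <- (seq_len(k + 1L) - 1L) * sw
    offsets <- offsets[offsets + sw <= w]
    for (strand in c("+", if (both_strands) "-")) {
      seqs <- if (strand == "+") rd$sequence[idx]
              else revcomp(rd$sequence[idx])
      for (cn in names(ref)) {
        L <- nchar(ref[[cn]])
        cands <- list()
        for (o in offsets) {
          seed <- substring(seqs, o + 1, o + sw)
          ok <- which(grepl("^[ACGT]+$", seed))
          if (!length(ok)) next
          pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed[ok]))
          m <- Biostrings::startIndex(Biostrings::matchPDict(pd,
                                                             subj_dna[[cn]]))
          nz <- which(lengths(m) > 0)
          if (!length(nz)) next
          cands[[length(cands) + 1]] <- data.frame(
            r = ok[rep(nz, lengths(m)[nz])],
            start0 = unlist(m[nz]) - 1L - o)
        }
        if (!length(cands)) next
        ct <- unique(do.call(rbind, cands))
        contained <- ct$start0 >= 0L & ct$start0 + w <= L
        res <- list()
        if (any(contained)) {
          cc <- ct[contained, , drop = FALSE]
          win <- substring(ref[[cn]], cc$start0 + 1, cc$start0 + w)
          mm <- mismatch_count(seqs[cc$r], win)
          keep <- mm <= floor(max_mismatch_frac * w)
          if (any(keep))
            res[[1]] <- data.frame(
              r = cc$r[keep], start = cc$start0[keep],
              end = cc$start0[keep] + w, qstart = 0L,
              mismatches = as.integer(mm[keep]), overlap = w)
        }
        if (min_cov_frac < 1 && any(!contained)) {
          cc <- ct[!contained, , drop = FALSE]
          qs <- pmax(0L, -cc$start0)
          rs <- pmax(0L, cc$start0)
          re <- pmin(L, cc$start0 + w)
          ov <- re - rs
          keep0 <- ov >= ceiling(min_cov_frac * w) & ov > 0L
          if (any(keep0)) {
            cc <- cc[keep0, , drop = FALSE]
            qs <- qs[keep0]; rs <- rs[keep0]; re <- re[keep0]; ov <- ov[keep0]
            pat <- substring(seqs[cc$r], qs + 1, qs + ov)
            win <- substring(ref[[cn]], rs + 1, re)
            mm <- mismatch_count(pat, win)
            keep <- mm <= floor(max_mismatch_frac * ov)
            if (any(keep))
              res[[length(res) + 1]] <- data.frame(
                r = cc$r[keep], start = rs[keep], end = re[keep],
                qstart = qs[keep], mismatches = as.integer(mm[keep]),
                overlap = ov[keep])
          }
        }
        if (length(res)) {
          tab <- do.call(rbind, res)
          tab$read <- idx[tab$r]
          tab$contig <- cn
          tab$strand <- strand
          acc[[length(acc) + 1]] <- tab
        }
      }
    }
  }

  if (!length(acc)) return(cbind(empty_hits(), qstart = integer(0)))
  all_c <- do.call(rbind, acc)
  if (!all_hits) {
    frac <- all_c$mismatches / all_c$overlap
    o <- order(all_c$read, frac, -all_c$overlap)
    all_c <- all_c[o, , drop = FALSE]
    frac <- frac[o]
    n <- nrow(all_c)
    first <- which(!duplicated(all_c$read))
    nxt <- pmin(first + 1L, n)
    tie <- first < n & all_c$read[nxt] == all_c$read[first] &
      abs(frac[nxt] - frac[first]) < 1e-12 &
      all_c$overlap[nxt] == all_c$overlap[first]
    all_c <- all_c[first[!tie], , drop = FALSE]   # ambiguous reads unmapped
  }
  out <- data.frame(read_id = rd$read_id[all_c$read], contig = all_c$contig,
                    start = all_c$start, end = all_c$end,
                    strand = all_c$strand, mismatches = all_c$mismatches,
                    qstart = all_c$qstart, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pileup of mapped reads over a reference
#'
#' Tallies, at every reference position, the A/C/G/T bases contributed by
#' the (strand-oriented) aligned reads. Total tallied bases equal total
#' aligned ACGT bases (conservation).
#'
#' @param hits hit data.frame from [tolerant_map()] or [strict_map()].
#' @param reads the read set the hits came from.
#' @param reference the reference the hits were produced against.
#' @return a `pileup_set`: per contig a list with `counts` (4 x length
#'   integer matrix, rows A/C/G/T), `ref` (reference base vector) and
#'   `coverage`; attribute `reference_id` identifies the contig set.
#' @export
pileup <- function(hits, reads, reference) {
  rd <- normalize_reads(reads)
  ref <- as_reference(reference)
  if (nrow(hits) && length(setdiff(unique(hits$contig), names(ref))))
    stop("hits refer to contigs absent from the reference")
  seq_of <- setNames(rd$sequence, rd$read_id)
  if (nrow(hits) && !all(hits$read_id %in% names(seq_of)))
    stop("hits refer to reads absent from the read set")
  qstart <- if ("qstart" %in% names(hits)) hits$qstart else rep(0L, nrow(hits))
  out <- list()
  for (cn in names(ref)) {
    L <- nchar(ref[[cn]])
    counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(BASES, NULL))
    h <- which(hits$contig == cn)
    if (length(h)) {
      alen <- hits$end[h] - hits$start[h]
      seqs <- seq_of[hits$read_id[h]]
      flip <- hits$strand[h] == "-"
      seqs[flip] <- revcomp(seqs[flip])
      aligned <- substring(seqs, qstart[h] + 1, qstart[h] + alen)
      pos <- unlist(lapply(seq_along(h),
                           function(i) hits$start[h[i]] + seq_len(alen[i])))
      base <- unlist(strsplit(aligned, "", fixed = TRUE))
      bi <- match(base, BASES)
      keep <- !is.na(bi)
      tal <- tabulate((pos[keep] - 1L) * 4L + bi[keep], nbins = 4L * L)
      counts[] <- tal
    }
    out[[cn]] <- list(counts = counts,
                      ref = strsplit(ref[[cn]], "", fixed = TRUE)[[1]],
                      coverage = colSums(counts))
  }
  structure(out, class = "pileup_set",
            reference_id = paste(names(ref), nchar(ref), sep = ":",
                                 collapse = ";"))
}

#' SNP allele-frequency profile from a pileup
#'
#' At every position with coverage of at least `min_cov`, the variant
#' allele frequency is 1 minus the frequency of the reference base; the
#' major-allele frequency is also recorded (used for profile
#' homogeneity).
#'
#' @param pile a `pileup_set` from [pileup()].
#' @param min_cov minimum coverage for a position to enter the profile
#'   (default 5).
#' @return a `snp_profile` data.frame: `contig`, `pos` (0-based),
#'   `coverage`, `ref_base`, `var_freq`, `maj_freq`; attributes carry
#'   `min_cov` and the `reference_id`.
#' @export
snp_profile <- function(pile, min_cov = 5) {
  stopifnot(inherits(pile, "pileup_set"))
  rows <- lapply(names(pile), function(cn) {
    p <- pile[[cn]]
    keep <- which(p$coverage >= min_cov)
    if (!length(keep))
      return(data.frame(contig = character(0), pos = integer(0),
                        coverage = integer(0), ref_base = character(0),
                        var_freq = numeric(0), maj_freq = numeric(0)))
    cov <- p$coverage[keep]
    ref_b <- p$ref[keep]
    ref_i <- match(ref_b, BASES)
    cnt <- p$counts[, keep, drop = FALSE]
    ref_cnt <- cnt[cbind(ref_i, seq_along(keep))]
    ref_cnt[is.na(ref_cnt)] <- 0              # non-ACGT reference base
    data.frame(contig = cn, pos = keep - 1L, coverage = as.integer(cov),
               ref_base = ref_b, var_freq = 1 - ref_cnt / cov,
               maj_freq = apply(cnt, 2, max) / cov,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("snp_profile", "data.frame"),
            min_cov = min_cov, reference_id = attr(pile, "reference_id"))
}

#' Full profile workflow: map, pile up, profile
#'
#' Convenience wrapper running [tolerant_map()], [pileup()] and
#' [snp_profile()] with one call.
#'
#' @inheritParams tolerant_map
#' @inheritParams snp_profile
#' @return a `snp_profile`.
#' @export
profile_sample <- function(reads, reference, max_mismatch_frac = 0.05,
                           min_cov = 5) {
  hits <- tolerant_map(reads, reference, max_mismatch_frac)
  snp_profile(pileup(hits, reads, reference), min_cov = min_cov)
}

join_profiles <- function(a, b) {
  if (!identical(attr(a, "reference_id"), attr(b, "reference_id")))
    stop("profiles were computed against different references")
  merge(as.data.frame(a)[, c("contig", "pos", "var_freq")],
        as.data.frame(b)[, c("contig", "pos", "var_freq")],
        by = c("contig", "pos"), suffixes = c("_a", "_b"))
}

#' Distance between two SNP profiles
#'
#' Mean absolute difference of variant allele frequencies over the
#' jointly covered positions that show variation (variant frequency of at
#' least `var_threshold` in either sample). Restricting the mean to
#' variant positions keeps the distance on the scale of allele-frequency
#' disagreement regardless of reference length: two samples of the same
#' strain score near 0, samples of strains differing by planted SNPs
#' score near 1 at those sites. Sufficiency (`min_joint`) is judged on
#' all jointly covered positions, so two variant-free samples of one
#' strain compare as identical rather than as lacking overlap. On
#' profiles sharing a reference and a variant-position support this is a
#' pseudometric.
#'
#' @param a,b `snp_profile`s over the same reference.
#' @param min_joint minimum jointly covered positions for the distance to
#'   be considered informative (default 50).
#' @param var_threshold variant frequency from which a position counts as
#'   a SNP site (default 0.1).
#' @return list: `distance`, `n_joint` (jointly covered positions),
#'   `n_variant` (positions entering the mean), `sufficient`
#'   (n_joint >= min_joint).
#' @export
profile_distance <- function(a, b, min_joint = 50, var_threshold = 0.1) {
  j <- join_profiles(a, b)
  n <- nrow(j)
  v <- j[pmax(j$var_freq_a, j$var_freq_b) >= var_threshold, , drop = FALSE]
  d <- if (n == 0) NA_real_
       else if (nrow(v) == 0) 0
       else mean(abs(v$var_freq_a - v$var_freq_b))
  list(distance = d, n_joint = n, n_variant = nrow(v),
       sufficient = n >= min_joint)
}

#' Profile homogeneity
#'
#' Fraction of profile positions whose major-allele frequency is at least
#' `maj_threshold`; near 1 for a sample dominated by a single strain.
#'
#' @param profile a `snp_profile`.
#' @param maj_threshold major-allele frequency cut (default 0.9).
#' @return fraction in \[0, 1\] (NA for an empty profile).
#' @export
homogeneity <- function(profile, maj_threshold = 0.9) {
  if (nrow(profile) == 0) return(NA_real_)
  mean(profile$maj_freq >= maj_threshold)
}

#' Same-strain decision from two SNP profiles
#'
#' Verdict `"same-strain"` when the profile distance is at most `delta`
#' and both samples are homogeneous (fraction of positions with
#' major-allele frequency >= 0.9 at least `h`); `"different-strain"`
#' otherwise; `"insufficient-overlap"` overrides both when fewer than
#' `min_joint` positions are jointly covered. The delta / h defaults are
#' calibration parameters validated on synthetic ground truth, not
#' literature values.
#'
#' @param a,b `snp_profile`s over the same reference.
#' @param delta maximum distance for identity (default 0.01).
#' @param h minimum homogeneity of each sample (default 0.95).
#' @param min_joint minimum jointly covered positions (default 50).
#' @param maj_threshold major-allele frequency defining a homogeneous
#'   position (default 0.9).
#' @return an `identity_decision` list: `distance`, `n_joint`,
#'   `homogeneity_a`, `homogeneity_b`, `verdict`.
#' @export
same_strain <- function(a, b, delta = 0.01, h = 0.95, min_joint = 50,
                        maj_threshold = 0.9) {
  pd <- profile_distance(a, b, min_joint = min_joint)
  ha <- homogeneity(a, maj_threshold)
  hb <- homogeneity(b, maj_threshold)
  verdict <- if (!pd$sufficient) "insufficient-overlap"
             else if (pd$distance <= delta &&
                      !is.na(ha) && !is.na(hb) && ha >= h && hb >= h)
               "same-strain"
             else "different-strain"
  structure(list(distance = pd$distance, n_joint = pd$n_joint,
                 homogeneity_a = ha, homogeneity_b = hb, verdict = verdict),
            class = "identity_decision")
}

#' @export
print.identity_decision <- function(x, ...) {
  cat(sprintf(paste0("identity_decision: %s\n  distance %.4g over %d joint",
                     " positions; homogeneity %.3f / %.3f\n"),
              x$verdict, x$distance, x$n_joint,
              x$homogeneity_a, x$homogeneity_b))
  invisible(x)
}
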