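#' @importFrom methods as is
#' @importFrom stats rgamma runif setNames
#' @importFrom utils combn read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper; ambiguity codes are complemented
#' per IUPAC (via [chartr()]), case is preserved upper.
#'
#' @param x character vector of nucleotide sequences (A/C/G/T/N...).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Generate a random genome sequence
#'
#' Uniform i.i.d. bases; deterministic given `seed`.
#'
#' @param length_bp genome length in bp.
#' @param seed integer seed.
#' @param gc target GC content (default 0.5).
#' @return a single character string.
#' @export
random_genome <- function(length_bp, seed, gc = 0.5) {
  stopifnot(length_bp >= 1, gc >= 0, gc <= 1)
  withr::with_seed(as.integer(seed), {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(BASES, length_bp, replace = TRUE, prob = p), collapse = "")
  })
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / n
}

#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) degrees C; the classic approximation for short
#' oligonucleotides. Adequate for screening; not a thermodynamic model.
#'
#' @param x character vector of primer sequences.
#' @return numeric vector of melting temperatures (degrees C).
#' @export
wallace_tm <- function(x) {
  n <- nchar(x)
  gc <- round(gc_fraction(x) * n)
  2 * (n - gc) + 4 * gc
}

as_dna <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "DNAString")) return(x)
  Biostrings::DNAStringSet(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or DNAStringSet) of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  dss <- as_dna(seqs)
  if (is.null(names(dss))) names(dss) <- paste0("seq", seq_along(dss))
  Biostrings::writeXStringSet(dss, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences (upper case).
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(toupper(as.character(dss)), names(dss))
}

#' Write a read set to FASTQ (Sanger Phred+33)
#'
#' Error-free simulated reads get a constant quality; the per-read quality
#' string is constant `qual_char` throughout (the simulator models
#' substitution errors directly, not quality-dependent ones).
#'
#' @param reads a `read_set` (see [simulate_reads()]) or a data.frame with
#'   columns `read_id` and `sequence`.
#' @param path output file.
#' @param qual_char single quality character (default "I" = Q40).
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  df <- as.data.frame(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(df)))
  qual <- vapply(nchar(df$sequence),
                 function(n) strrep(qual_char, n), character(1))
  out <- as.vector(rbind(paste0("@", df$read_id), df$sequence, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(dss), sequence = toupper(as.character(dss)),
             stringsAsFactors = FALSE)
}
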