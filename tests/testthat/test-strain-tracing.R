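test_that("contig length filter is strict at 3000 bp", {
  cs <- contig_set(id = c("c1", "c2", "c3"),
                   sequence = c(rand_seq(3000, 1), rand_seq(3001, 2),
                                rand_seq(5000, 3)),
                   species = "sp")
  kept <- filter_contigs(cs)
  expect_identical(kept$id, c("c2", "c3"))
  expect_equal(nrow(filter_contigs(cs[0, ])), 0)
  # agrees with a brute-force length scan on a random mixed set
  set.seed(4)
  lens <- sample(2500:3500, 30)
  cs2 <- contig_set(sprintf("r%02d", 1:30),
                    vapply(lens, rand_seq, character(1)), "sp")
  expect_identical(filter_contigs(cs2)$id, cs2$id[lens > 3000])
})

test_that("marker selection takes the longest contig, ties by id", {
  cs <- contig_set(c("b", "a", "c"),
                   c(rand_seq(5000, 1), rand_seq(12000, 2), rand_seq(8000, 3)),
                   species = "sp")
  expect_equal(select_marker_contig(cs, "sp")$id, "a")
  tie <- contig_set(c("z", "y"), c(rand_seq(4000, 5), rand_seq(4000, 6)),
                    species = "sp")
  expect_equal(select_marker_contig(tie, "sp")$id, "y")
  expect_error(select_marker_contig(cs, "absent"), "no contigs")
  # sort-based oracle on random sets
  set.seed(9)
  for (i in 1:10) {
    lens <- sample(1000:2000, 8, replace = TRUE)
    ids <- sample(sprintf("ctg%02d", 1:8))
    cs3 <- contig_set(ids, vapply(lens, rand_seq, character(1)), "sp")
    want <- cs3$id[order(-cs3$length, cs3$id)][1]
    expect_equal(select_marker_contig(cs3, "sp")$id, want)
  }
})

test_that("primer design matches an exhaustive scan oracle", {
  set.seed(77)
  marker <- contig_set("m1", rand_seq(600), species = "sp")
  mk <- design_primers(marker, background = character(0))
  # oracle: first (fwd_start, fwd_len, product_len, rev_len) in scan order
  # satisfying length/GC/Tm and single occurrence, by direct enumeration
  seqx <- marker$sequence
  gc_tm_ok <- function(p) {
    n <- nchar(p); gc <- nchar(gsub("[^GC]", "", p))
    gcf <- gc / n; tm <- 2 * (n - gc) + 4 * gc
    gcf >= 0.4 && gcf <= 0.6 && tm >= 50 && tm <= 65
  }
  occ_once <- function(p) {
    cnt <- function(x) {
      res <- gregexpr(x, seqx, fixed = TRUE)[[1]]
      sum(res > 0)
    }
    cnt(p) + cnt(rc_plain(p)) == 1
  }
  found <- NULL
  for (fs in 0:(nchar(seqx) - 1)) {
    for (fl in 18:25) {
      fwd <- substr(seqx, fs + 1, fs + fl)
      if (nchar(fwd) < fl || !gc_tm_ok(fwd) || !occ_once(fwd)) next
      for (pl in 100:600) {
        pe <- fs + pl
        if (pe > nchar(seqx)) break
        for (rl in 18:25) {
          site <- substr(seqx, pe - rl + 1, pe)
          if (pe - rl <= fs + fl) next
          if (!gc_tm_ok(site)) next
          rev <- rc_plain(site)
          if (!occ_once(rev)) next
          found <- list(fs = fs, fwd = fwd, pl = pl, rev = rev)
          break
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  expect_equal(mk$fwd$start, found$fs)
  expect_equal(mk$fwd$seq, found$fwd)
  expect_equal(mk$product_length, found$pl)
  expect_equal(mk$rev$seq, found$rev)
})

test_that("primer specificity screens out background hits", {
  set.seed(13)
  bg_core <- rand_seq(1500)
  unique_seg <- rand_seq(250)
  # marker shares its flanks with the background; only the middle segment
  # is strain-specific
  marker_seq <- paste0(substr(bg_core, 1, 400), unique_seg,
                       substr(bg_core, 401, 800))
  marker <- contig_set("m", marker_seq, species = "sp")
  background <- c(bg_core, rand_seq(1000))
  mk <- design_primers(marker, background)
  # both primers must be absent from the background on either strand
  for (p in c(mk$fwd$seq, mk$rev$seq)) {
    hits <- vapply(background, function(b)
      grepl(p, b, fixed = TRUE) || grepl(rc_plain(p), b, fixed = TRUE),
      logical(1))
    expect_false(any(hits))
  }
  # and the amplicon lies inside the unique segment region
  expect_gte(mk$fwd$start, 400 - 25)
  expect_lte(mk$fwd$start + mk$product_length, 400 + 250 + 25)
  # a marker screened against itself can never be specific
  expect_error(design_primers(marker, marker_seq), "no specific primer")
  # output invariant to background ordering
  mk2 <- design_primers(marker, rev(background))
  expect_identical(mk[c("fwd", "rev", "product_length")],
                   mk2[c("fwd", "rev", "product_length")])
})

test_that("in-silico PCR has exact-match semantics on both strands", {
  set.seed(19)
  marker <- contig_set("m", rand_seq(800), species = "sp")
  mk <- design_primers(marker, character(0))
  target <- paste0(rand_seq(300), marker$sequence, rand_seq(200))
  amp <- in_silico_pcr(mk, c(t1 = target))
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, mk$product_length)
  # reverse-complemented target still amplifies
  amp_rc <- in_silico_pcr(mk, c(t1 = rc_plain(target)))
  expect_equal(nrow(amp_rc), 1)
  expect_equal(amp_rc$length, mk$product_length)
  # one substitution inside the forward primer site kills the amplicon
  mut <- strsplit(target, "")[[1]]
  pos <- 300 + mk$fwd$start + 5   # inside fwd site
  mut[pos + 1] <- setdiff(c("A", "C", "G", "T"), mut[pos + 1])[1]
  amp2 <- in_silico_pcr(mk, c(t1 = paste(mut, collapse = "")))
  expect_equal(nrow(amp2), 0)
  # absent target: clean negative
  expect_equal(nrow(in_silico_pcr(mk, c(t1 = rand_seq(2000)))), 0)
})

test_that("strict mapping equals the naive substring oracle", {
  set.seed(29)
  for (i in 1:20) {
    contigs <- list(c1 = rand_seq(sample(500:1500, 1)),
                    c2 = rand_seq(sample(500:1500, 1)))
    n <- 15
    reads <- data.frame(read_id = sprintf("r%02d", 1:n),
                        sequence = vapply(1:n, function(j) {
                          if (j <= 5) rand_seq(40)      # random: mostly unmapped
                          else {
                            src <- contigs[[sample(1:2, 1)]]
                            s <- sample(nchar(src) - 40, 1)
                            r <- substr(src, s, s + 39)
                            if (runif(1) < 0.5) r <- rc_plain(r)
                            if (runif(1) < 0.3) {       # inject one error
                              ch <- strsplit(r, "")[[1]]
                              p <- sample(40, 1)
                              ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
                              r <- paste(ch, collapse = "")
                            }
                            r
                          }
                        }, character(1)), stringsAsFactors = FALSE)
    got <- strict_map(reads, contigs)
    want <- naive_hits(reads, contigs)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("the 100%/100% rule forces all-or-nothing mapping", {
  g <- random_genome(10000, 55)
  rs <- simulate_reads(list(list(strain = strain_model(g, label = "s"),
                                 proportion = 1)),
                       read_sim_params(100, 500, 0, 56))
  hits <- strict_map(rs, c(ref = g))
  expect_setequal(unique(hits$read_id), rs$read_id)   # error-free: all map
  # every mapped location is the true origin (or an exact duplicate)
  m <- merge(hits, rs, by = "read_id")
  expect_true(all(m$start.x == m$start.y))
  # reads with exactly one injected substitution never map
  rs_err <- simulate_reads(list(list(strain = strain_model(g, label = "s"),
                                     proportion = 1)),
                           read_sim_params(100, 500, 0.01, 57))
  one_err <- rs_err[rs_err$n_errors >= 1, ]
  expect_gt(nrow(one_err), 0)
  expect_equal(nrow(strict_map(one_err, c(ref = g))), 0)
})

test_that("ambiguous-base reads and over-long reads are unmapped", {
  g <- rand_seq(500, 61)
  r <- data.frame(read_id = c("n1", "long1"),
                  sequence = c(paste0("N", substr(g, 2, 50)),
                               paste0(g, g)))
  expect_equal(nrow(strict_map(r, c(ref = g))), 0)
})

test_that("coverage, depth and presence calls behave", {
  g <- rand_seq(1000, 71)
  # perfectly tiling reads
  starts <- seq(1, 901, by = 100)
  reads <- data.frame(read_id = paste0("t", seq_along(starts)),
                      sequence = substring(g, starts, starts + 99))
  hits <- strict_map(reads, c(ref = g))
  cov <- coverage_and_presence(hits, c(ref = g))
  expect_equal(cov$breadth, 1.0)
  expect_equal(cov$depth, 1.0)
  expect_true(cov$presence)
  # zero hits
  cov0 <- coverage_and_presence(hits[0, ], c(ref = g))
  expect_equal(cov0$breadth, 0)
  expect_false(cov0$presence)
  # simulated 10x coverage gives depth 10 +- binomial-scale noise
  rs <- simulate_reads(list(list(strain = strain_model(g, label = "s"),
                                 proportion = 1)),
                       read_sim_params(100, 100, 0, 73))
  c10 <- coverage_and_presence(strict_map(rs, c(ref = g)), c(ref = g))
  expect_equal(c10$depth, 10, tolerance = 0.01)
  expect_error(coverage_and_presence(hits, c(other = rand_seq(100))),
               "absent")
})
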