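test_that("tolerant mapping matches strict mapping on error-free reads", {
  g <- random_genome(8000, 81)
  rs <- simulate_reads(list(list(strain = strain_model(g, label = "s"),
                                 proportion = 1)),
                       read_sim_params(100, 300, 0, 82))
  strict <- strict_map(rs, c(ref = g))
  tol <- tolerant_map(rs, c(ref = g), max_mismatch_frac = 0.05)
  expect_identical(hit_key(strict), hit_key(tol))
  expect_true(all(tol$mismatches == 0))
})

test_that("reads with one substitution map back to their true positions", {
  g <- random_genome(20000, 83)
  rs <- simulate_reads(list(list(strain = strain_model(g, label = "s"),
                                 proportion = 1)),
                       read_sim_params(150, 400, 0, 84))
  # inject exactly one substitution per read
  mut <- vapply(rs$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    p <- sample(150, 1)
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  rd <- data.frame(read_id = rs$read_id, sequence = mut)
  hits <- tolerant_map(rd, c(ref = g), max_mismatch_frac = 0.05)  # <= 7
  expect_equal(nrow(hits), 400)
  m <- merge(hits, rs[, c("read_id", "start", "strand")], by = "read_id")
  expect_true(all(m$start.x == m$start.y))
  expect_true(all(m$mismatches == 1))
})

test_that("a read matching two loci equally well is ambiguous", {
  seg <- rand_seq(200, 85)
  g <- paste0(rand_seq(500), seg, rand_seq(500), seg, rand_seq(300))
  rd <- data.frame(read_id = "amb", sequence = substr(seg, 51, 150))
  expect_equal(nrow(tolerant_map(rd, c(ref = g))), 0)
  # strict_map by contrast reports both occurrences
  expect_equal(nrow(strict_map(rd, c(ref = g))), 2)
})

test_that("pileup equals naive accumulation and conserves bases", {
  set.seed(91)
  for (i in 1:10) {
    contigs <- list(c1 = rand_seq(400), c2 = rand_seq(300))
    reads <- data.frame(
      read_id = sprintf("r%02d", 1:20),
      sequence = vapply(1:20, function(j) {
        src <- contigs[[sample(1:2, 1)]]
        s <- sample(nchar(src) - 50, 1)
        r <- substr(src, s, s + 49)
        if (runif(1) < 0.5) rc_plain(r) else r
      }, character(1)), stringsAsFactors = FALSE)
    hits <- strict_map(reads, contigs)
    pile <- pileup(hits, reads, contigs)
    want <- naive_pileup(hits, reads, contigs)
    for (cn in names(contigs))
      expect_equal(unname(pile[[cn]]$counts), unname(want[[cn]]))
    total <- sum(vapply(pile, function(p) sum(p$counts), numeric(1)))
    expect_equal(total, sum(hits$end - hits$start))
  }
  # no hits: all-zero pileup
  p0 <- pileup(strict_map(data.frame(read_id = "x",
                                     sequence = rand_seq(50)),
                          list(c1 = rand_seq(400)))[0, ],
               data.frame(read_id = "x", sequence = rand_seq(50)),
               list(c1 = rand_seq(400, 1)))
  expect_equal(sum(p0$c1$counts), 0)
})

test_that("ten identical reads over one locus give coverage ten", {
  g <- rand_seq(300, 95)
  reads <- data.frame(read_id = paste0("r", 1:10),
                      sequence = rep(substr(g, 101, 180), 10))
  pile <- pileup(strict_map(reads, c(ref = g)), reads, c(ref = g))
  expect_true(all(pile$ref$coverage[101:180] == 10))
  expect_true(all(pile$ref$coverage[-(101:180)] == 0))
  # every tallied base equals the reference base
  prof <- snp_profile(pile, min_cov = 5)
  expect_true(all(prof$var_freq == 0))
  expect_equal(nrow(prof), 80)
})

test_that("snp profiles respect the coverage threshold", {
  g <- rand_seq(200, 97)
  reads <- data.frame(read_id = paste0("r", 1:4),
                      sequence = rep(substr(g, 51, 120), 4))
  pile <- pileup(strict_map(reads, c(ref = g)), reads, c(ref = g))
  expect_equal(nrow(snp_profile(pile, min_cov = 5)), 0)   # cov 4 < 5
  expect_equal(nrow(snp_profile(pile, min_cov = 4)), 70)
})

test_that("mixture allele frequencies are recovered at planted SNPs", {
  g <- random_genome(10000, 99)
  v <- mutate_genome(g, 50, seed = 100)
  rs <- simulate_reads(
    list(list(strain = strain_model(g, label = "ref"), proportion = 0.7),
         list(strain = v, proportion = 0.3)),
    read_sim_params(100, 3000, 0, 101))          # ~30x
  prof <- profile_sample(rs, c(ref = g))
  at_snp <- prof[prof$pos %in% v$snps$pos, ]
  expect_gt(nrow(at_snp), 40)
  # each frequency within 3 sigma binomial bounds of 0.30
  sig <- sqrt(0.3 * 0.7 / at_snp$coverage)
  inside <- abs(at_snp$var_freq - 0.3) <= 3 * sig
  expect_gte(mean(inside), 0.9)
  expect_lt(abs(mean(at_snp$var_freq) - 0.3), 3 * mean(sig) / sqrt(nrow(at_snp)))
  # away from planted SNPs the variant frequency is 0 (error-free reads)
  away <- prof[!prof$pos %in% v$snps$pos, ]
  expect_true(all(away$var_freq == 0))
})

test_that("profile distance is a pseudometric and detects strain identity", {
  mkprof <- function(vf, ref_id = "ref:1000") {
    structure(data.frame(contig = "ref", pos = seq_along(vf) - 1L,
                         coverage = 50L, ref_base = "A",
                         var_freq = vf, maj_freq = pmax(vf, 1 - vf)),
              class = c("snp_profile", "data.frame"),
              min_cov = 5, reference_id = ref_id)
  }
  set.seed(103)
  for (i in 1:20) {
    # frequencies above the variant threshold so all profiles share support
    a <- mkprof(runif(100, 0.1, 1)); b <- mkprof(runif(100, 0.1, 1))
    c <- mkprof(runif(100, 0.1, 1))
    dab <- profile_distance(a, b)$distance
    dba <- profile_distance(b, a)$distance
    dac <- profile_distance(a, c)$distance
    dcb <- profile_distance(c, b)$distance
    expect_gte(dab, 0)
    expect_equal(dab, dba)
    expect_equal(profile_distance(a, a)$distance, 0)
    expect_lte(dab, dac + dcb + 1e-12)          # triangle inequality
  }
  expect_equal(profile_distance(mkprof(rep(0, 60)),
                                mkprof(rep(1, 60)))$distance, 1.0)
  expect_error(profile_distance(mkprof(runif(10)),
                                mkprof(runif(10), "other:5")),
               "different references")
})

test_that("same-strain decisions recover planted truth", {
  g <- random_genome(10000, 107)
  v <- mutate_genome(g, 50, seed = 108)          # 50 SNPs / 10 kb
  sim <- function(strain, seed)
    simulate_reads(list(list(strain = strain, proportion = 1)),
                   read_sim_params(100, 2000, 0, seed))  # 20x
  ref <- c(ref = g)
  p_same1 <- profile_sample(sim(strain_model(g, label = "a"), 109), ref)
  p_same2 <- profile_sample(sim(strain_model(g, label = "b"), 110), ref)
  p_diff <- profile_sample(sim(v, 111), ref)
  d_within <- same_strain(p_same1, p_same2)
  d_between <- same_strain(p_same1, p_diff)
  expect_equal(d_within$verdict, "same-strain")
  expect_equal(d_between$verdict, "different-strain")
  expect_lt(d_within$distance * 10, d_between$distance)
  # no joint positions: insufficient overlap
  empty <- structure(p_same1[0, ], class = class(p_same1),
                     min_cov = 5, reference_id = attr(p_same1, "reference_id"))
  expect_equal(same_strain(p_same1, empty)$verdict, "insufficient-overlap")
})

test_that("fragment ANI honours identity, strands and substitution load", {
  g <- random_genome(50000, 113)
  expect_equal(ani(g, g)$ani, 100.0)
  expect_equal(ani(g, revcomp(g))$ani, 100.0)
  g1 <- mutate_genome(g, round(0.01 * nchar(g)), seed = 114)$genome
  a1 <- ani(g, g1)$ani
  expect_lt(abs(a1 - 99.0), 0.2)
  # monotone non-increasing in substitution rate
  rates <- c(0, 0.005, 0.01, 0.02)
  anis <- vapply(seq_along(rates), function(i) {
    gm <- if (rates[i] == 0) g
          else mutate_genome(g, round(rates[i] * nchar(g)),
                             seed = 120 + i)$genome
    ani(g, gm)$ani
  }, numeric(1))
  expect_true(all(diff(anis) <= 0))
  # unrelated genomes offer no fragment support
  expect_error(ani(g, random_genome(20000, 130)), "no ANI support")
})
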