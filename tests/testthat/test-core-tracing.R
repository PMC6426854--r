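make_group_table <- function(pattern, n = 10) {
  # pattern: list(site -> list(matrix -> named detection counts per taxon))
  taxa <- sort(unique(unlist(lapply(pattern, function(s) lapply(s, names)))))
  rows <- list(); meta <- list(); k <- 0
  for (s in names(pattern)) for (m in names(pattern[[s]])) {
    det <- pattern[[s]][[m]]
    for (r in seq_len(n)) {
      x <- setNames(numeric(length(taxa)), taxa)
      for (tx in names(det)) if (r <= det[[tx]]) x[tx] <- 0.01
      k <- k + 1
      rows[[k]] <- x
      meta[[k]] <- data.frame(sample_id = sprintf("%s_%s_%d", s, m, r),
                              site = s, matrix = m, replicate = r)
    }
  }
  abundance_table(do.call(rbind, rows), do.call(rbind, meta))
}

test_that("prevalence filtering is strict at the 70% boundary", {
  tab <- make_group_table(list(P1 = list(
    CF = c(TaxIn = 8, TaxEdge = 7, TaxOut = 0))))
  pm <- prevalence_filter(tab, tracing_config(0.70))
  df <- as.data.frame(pm)
  expect_true(df$present[df$taxon == "TaxIn"])     # 0.8  > 0.7
  expect_false(df$present[df$taxon == "TaxEdge"])  # 0.7 !> 0.7
  expect_false(df$present[df$taxon == "TaxOut"])
  # detection mode: any positive sample counts
  dm <- as.data.frame(prevalence_filter(tab, mode = "detection"))
  expect_true(dm$present[dm$taxon == "TaxEdge"])
  expect_false(dm$present[dm$taxon == "TaxOut"])
})

test_that("raising the prevalence threshold never adds a presence", {
  set.seed(11)
  pattern <- list()
  for (s in c("P1", "P2")) {
    pattern[[s]] <- list()
    for (m in c("CF", "LIT", "MIL", "PC"))
      pattern[[s]][[m]] <- setNames(sample(0:10, 6, replace = TRUE),
                                    paste0("t", 1:6))
  }
  tab <- make_group_table(pattern)
  prev_set <- NULL
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    pm <- as.data.frame(prevalence_filter(tab, tracing_config(thr)))
    cur <- with(pm, paste(taxon, site, matrix)[present])
    if (!is.null(prev_set)) expect_true(all(cur %in% prev_set))
    prev_set <- cur
  }
})

test_that("shared sets equal brute-force intersections on random maps", {
  set.seed(23)
  sites <- c("P1", "P2"); mats <- c("CF", "LIT", "MIL", "PC")
  for (rep in 1:25) {
    taxa <- paste0("t", 1:8)
    truth <- lapply(setNames(nm = taxa), function(tx) {
      keys <- as.vector(outer(sites, mats, paste, sep = "|"))
      sample(keys, sample(0:8, 1))
    })
    pm <- toy_presence(truth, sites, mats)
    for (s in sites) {
      sub <- sample(mats, sample(1:4, 1))
      got <- shared_across_matrices(pm, s, sub)
      want <- sort(Filter(function(tx)
        all(paste(s, sub, sep = "|") %in% truth[[tx]]), taxa))
      expect_identical(got, want)
    }
  }
  pm1 <- toy_presence(list(a = "P1|CF"), sites, mats)
  expect_identical(shared_across_matrices(pm1, "P1", "CF"), "a")
  expect_identical(shared_across_matrices(pm1, "P1", c("CF", "PC")),
                   character(0))
  expect_error(shared_across_matrices(pm1, "P1", "XX"), "unknown")
})

test_that("pairwise sharing counts are anti-monotone in combination size", {
  set.seed(31)
  sites <- c("P1", "P2", "P3"); mats <- c("CF", "LIT", "MIL", "PC")
  taxa <- paste0("t", 1:10)
  truth <- lapply(setNames(nm = taxa), function(tx) {
    keys <- as.vector(outer(sites, mats, paste, sep = "|"))
    sample(keys, sample(0:12, 1))
  })
  pm <- toy_presence(truth, sites, mats)
  pc <- pairwise_sharing_counts(pm)
  for (s in sites) {
    sub <- pc[pc$site == s, ]
    for (i in seq_len(nrow(sub))) {
      ms <- strsplit(sub$combination[i], "+", fixed = TRUE)[[1]]
      for (j in seq_len(nrow(sub))) {
        ms2 <- strsplit(sub$combination[j], "+", fixed = TRUE)[[1]]
        if (all(ms %in% ms2)) expect_lte(sub$count[j], sub$count[i])
      }
    }
  }
  # averages across sites are reported
  expect_true("average" %in% pc$site)
  avg <- pc[pc$site == "average" & pc$combination == "CF+LIT", "count"]
  per <- pc[pc$site != "average" & pc$combination == "CF+LIT", "count"]
  expect_equal(avg, mean(per))
})

test_that("a design with k chain-wide taxa yields a quad count of k", {
  sites <- "P1"; mats <- c("CF", "LIT", "MIL", "PC")
  truth <- list(a = paste("P1", mats, sep = "|"),
                b = paste("P1", mats, sep = "|"),
                c = paste("P1", c("CF", "LIT"), sep = "|"))
  pm <- toy_presence(truth, sites, mats)
  pc <- pairwise_sharing_counts(pm, sites = "P1")
  expect_equal(pc$count[pc$site == "P1" &
                          pc$combination == "CF+LIT+MIL+PC"], 2)
  empty <- toy_presence(list(a = character(0)), sites, mats)
  expect_true(all(pairwise_sharing_counts(empty)$count == 0))
})

test_that("site sharing on the packaged fixture reproduces 13/2/3", {
  fx <- table1_fixture()
  ss <- site_sharing(fx$presence, min_matrices = 3)
  expect_equal(sum(ss$n_sites >= 1), 13)
  expect_setequal(ss$taxon[ss$n_sites >= 4],
                  c("Bifidobacterium", "U. m. of Lachnospiraceae family"))
  expect_setequal(ss$taxon[ss$n_sites == 3],
                  c("Bacteroides", "Streptococcus",
                    "U. m. of Actinobacteria class"))
})

test_that("core table cells equal group means where present", {
  set.seed(47)
  tab <- make_group_table(list(
    P1 = list(CF = c(a = 10, b = 9), LIT = c(a = 10, b = 2),
              MIL = c(a = 9), PC = c(a = 8))))
  # add abundance variation
  tab$values <- tab$values * runif(length(tab$values), 0.5, 1.5)
  pm <- prevalence_filter(tab)
  ct <- core_table(tab, pm)
  expect_true("a" %in% colnames(ct))
  expect_false("b" %in% colnames(ct))            # b present in <3 matrices
  for (g in rownames(ct)) {
    key <- strsplit(g, "|", fixed = TRUE)[[1]]
    idx <- tab$meta$site == key[1] & tab$meta$matrix == key[2]
    if (!is.na(ct[g, "a"]))
      expect_equal(ct[g, "a"], mean(tab$values[idx, "a"]), tolerance = 1e-12)
  }
})

test_that("noise-free synthetic chains are recovered exactly", {
  profiles <- list(CF = c(bgA = 0.3, bgB = 0.2), LIT = c(bgA = 0.2),
                   MIL = c(bgB = 0.3), PC = c(bgA = 0.5))
  spec <- community_spec(profiles, n_sites = 2, n_samples_per_matrix = 10,
                         detection_floor = 1e-4)
  planted <- rbind(
    data.frame(taxon = "chainwide", site = "S1",
               matrix = c("CF", "LIT", "MIL", "PC"), abundance = 0.02),
    data.frame(taxon = "partial", site = "S2",
               matrix = c("LIT", "PC"), abundance = 0.02))
  tab <- generate_chain_profiles(spec, transmission_plan(planted, seed = 5))
  pm <- as.data.frame(prevalence_filter(tab))
  for (i in seq_len(nrow(planted)))
    expect_true(pm$present[pm$taxon == planted$taxon[i] &
                             pm$site == planted$site[i] &
                             pm$matrix == planted$matrix[i]])
  expect_false(any(pm$present[pm$taxon == "chainwide" & pm$site == "S2"]))
  expect_false(any(pm$present[pm$taxon == "partial" & pm$site == "S1"]))
  ss <- site_sharing(prevalence_filter(tab), 3)
  expect_equal(ss$n_sites[ss$taxon == "chainwide"], 1L)
  expect_equal(ss$n_sites[ss$taxon == "partial"], 0L)
})
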