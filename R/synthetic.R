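#' Specify a synthetic chain community
#'
#' Defines the background community sampled in each matrix of a synthetic
#' production chain. Per-sample compositions are drawn from a Dirichlet
#' distribution centred on the matrix means with concentration
#' `overdispersion` (larger = tighter around the means); any unassigned
#' mass (1 - sum of means) is given to an unreported remainder component.
#'
#' @param matrix_profiles named list, one element per matrix (CF, LIT,
#'   MIL, PC, or a subset); each a named numeric vector of mean relative
#'   abundances (sum <= 1).
#' @param n_sites number of production sites (labelled S1, S2, ...).
#' @param n_samples_per_matrix samples per (site, matrix) group
#'   (default 10, the sampling depth of the emulated study design).
#' @param overdispersion Dirichlet concentration (default 200).
#' @param detection_floor relative abundance below which a taxon is
#'   recorded as absent (default 1e-4).
#' @return a `community_spec` list.
#' @export
community_spec <- function(matrix_profiles, n_sites = 2,
                           n_samples_per_matrix = 10,
                           overdispersion = 200,
                           detection_floor = 1e-4) {
  stopifnot(is.list(matrix_profiles), length(matrix_profiles) >= 1,
            !is.null(names(matrix_profiles)),
            n_sites >= 1, n_samples_per_matrix >= 1,
            overdispersion > 0,
            detection_floor >= 0, detection_floor < 1)
  for (m in names(matrix_profiles)) {
    p <- matrix_profiles[[m]]
    if (is.null(names(p)) || any(p < 0) || sum(p) > 1 + 1e-9)
      stop("profile for matrix '", m,
           "' must be a named non-negative vector summing to <= 1")
  }
  structure(list(matrix_profiles = matrix_profiles,
                 sites = paste0("S", seq_len(n_sites)),
                 n_samples_per_matrix = as.integer(n_samples_per_matrix),
                 overdispersion = overdispersion,
                 detection_floor = detection_floor),
            class = "community_spec")
}

#' Ground-truth transmission plan for synthetic data
#'
#' Records which taxa (and optionally which strains) are planted in which
#' (site, matrix) groups, with their carry-over abundances; the plan is
#' what downstream tracing must recover.
#'
#' @param planted_taxa data.frame with columns `taxon`, `site`, `matrix`,
#'   `abundance` (carry-over relative abundance in that group), or NULL.
#' @param planted_strains list of plantings, each a list with elements
#'   `species`, `strain` (a [strain_model()]), and `placements`
#'   (data.frame `site`, `matrix`, `proportion` — the strain's proportion
#'   of its species' reads in that group), or NULL.
#' @param seed integer seed governing all randomness downstream.
#' @return a `transmission_plan` list.
#' @export
transmission_plan <- function(planted_taxa = NULL, planted_strains = NULL,
                              seed = 1) {
  if (!is.null(planted_taxa)) {
    planted_taxa <- as.data.frame(planted_taxa, stringsAsFactors = FALSE)
    stopifnot(all(c("taxon", "site", "matrix", "abundance") %in%
                    names(planted_taxa)),
              all(planted_taxa$abundance > 0))
  }
  if (!is.null(planted_strains)) {
    stopifnot(is.list(planted_strains))
    for (ps in planted_strains)
      stopifnot(is.list(ps), !is.null(ps$species),
                inherits(ps$strain, "strain_model"),
                is.data.frame(ps$placements),
                all(c("site", "matrix", "proportion") %in%
                      names(ps$placements)))
  }
  structure(list(planted_taxa = planted_taxa,
                 planted_strains = planted_strains,
                 seed = as.integer(seed)),
            class = "transmission_plan")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  setNames(g / sum(g), names(alpha))
}

#' Generate per-sample abundance profiles along the chain
#'
#' Draws every (site, matrix, replicate) sample from the matrix's
#' Dirichlet profile, injects the planted taxa of the plan at their exact
#' carry-over abundance (rescaling the background so compositions stay
#' <= 1), and zeroes values below the detection floor. Planted taxa thus
#' have prevalence exactly 1 in their planted groups and 0 elsewhere.
#' Byte-identical output for a fixed plan seed.
#'
#' @param spec a [community_spec()].
#' @param plan a [transmission_plan()].
#' @return an `abundance_table` (relative abundances).
#' @export
generate_chain_profiles <- function(spec, plan = transmission_plan()) {
  stopifnot(inherits(spec, "community_spec"),
            inherits(plan, "transmission_plan"))
  pt <- plan$planted_taxa
  if (!is.null(pt)) {
    bad_site <- setdiff(pt$site, spec$sites)
    bad_mat <- setdiff(pt$matrix, names(spec$matrix_profiles))
    if (length(bad_site) || length(bad_mat))
      stop("transmission plan is inconsistent with the community grid: ",
           paste(c(bad_site, bad_mat), collapse = ", "))
    if (any(pt$abundance <= spec$detection_floor))
      stop("planted carry-over abundance must exceed the detection floor")
  }
  bg_taxa <- sort(unique(unlist(lapply(spec$matrix_profiles, names))))
  pl_taxa <- if (is.null(pt)) character(0)
             else sort(setdiff(unique(pt$taxon), bg_taxa))
  taxa <- c(bg_taxa, pl_taxa)
  mats <- names(spec$matrix_profiles)
  n <- spec$n_samples_per_matrix

  withr::with_seed(plan$seed, {
    rows <- list(); meta <- list(); k <- 0
    for (s in spec$sites) for (m in mats) for (r in seq_len(n)) {
      prof <- spec$matrix_profiles[[m]]
      alpha <- spec$overdispersion * c(prof, .rest = max(0, 1 - sum(prof)))
      alpha <- alpha[alpha > 0]
      draw <- rdirichlet1(alpha)
      x <- setNames(numeric(length(taxa)), taxa)
      common <- intersect(names(draw), taxa)
      x[common] <- draw[common]
      if (!is.null(pt)) {
        here <- pt[pt$site == s & pt$matrix == m, , drop = FALSE]
        if (nrow(here)) {
          planted_total <- sum(here$abundance)
          if (planted_total >= 1)
            stop("planted abundances in group (", s, ", ", m, ") sum to >= 1")
          x <- x * (1 - planted_total)
          x[here$taxon] <- here$abundance
        }
      }
      x[x < spec$detection_floor] <- 0
      k <- k + 1
      rows[[k]] <- x
      meta[[k]] <- data.frame(sample_id = sprintf("%s_%s_%02d", s, m, r),
                              site = s, matrix = m, replicate = r,
                              stringsAsFactors = FALSE)
    }
    abundance_table(do.call(rbind, rows), do.call(rbind, meta),
                    type = "relative", matrices = mats)
  })
}

#' Construct a strain model
#'
#' A strain genome together with the set of SNPs that distinguishes it
#' from its parent reference: 0-based positions with the reference and
#' alternative base at each.
#'
#' @param genome character string, the strain's genome sequence (carrying
#'   the alternative alleles).
#' @param snps data.frame `pos` (0-based), `ref`, `alt`; may be empty.
#' @param label strain identifier.
#' @return a `strain_model` list.
#' @export
strain_model <- function(genome, snps = data.frame(pos = integer(0),
                                                   ref = character(0),
                                                   alt = character(0)),
                         label = "strain") {
  genome <- toupper(as.character(genome))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(nchar(genome) >= 1,
            all(c("pos", "ref", "alt") %in% names(snps)))
  if (nrow(snps)) {
    stopifnot(!anyDuplicated(snps$pos),
              all(snps$pos >= 0), all(snps$pos < nchar(genome)),
              all(snps$ref != snps$alt))
    obs <- substring(genome, snps$pos + 1, snps$pos + 1)
    if (!all(obs == snps$alt))
      stop("genome does not carry the alt allele at all SNP positions")
  }
  structure(list(genome = genome, snps = snps, label = label),
            class = "strain_model")
}

#' Derive a strain by planting SNPs in a genome
#'
#' Substitutes `n_snps` distinct, uniformly chosen positions with a
#' uniformly chosen different base, recording the truth set.
#' Deterministic given `seed`.
#'
#' @param genome character string (parent genome).
#' @param n_snps number of substitutions (<= genome length).
#' @param seed integer seed.
#' @param label strain label.
#' @return a [strain_model()] whose `snps` is the planted truth set.
#' @export
mutate_genome <- function(genome, n_snps, seed = 1, label = "variant") {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  if (n_snps > L) stop("n_snps (", n_snps, ") exceeds genome length (", L, ")")
  if (n_snps == 0)
    return(strain_model(genome, label = label))
  withr::with_seed(as.integer(seed), {
    pos <- sort(sample.int(L, n_snps)) - 1L
    ref <- substring(genome, pos + 1, pos + 1)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                  USE.NAMES = FALSE)
    ch <- strsplit(genome, "", fixed = TRUE)[[1]]
    ch[pos + 1] <- alt
    strain_model(paste(ch, collapse = ""),
                 data.frame(pos = pos, ref = ref, alt = alt,
                            stringsAsFactors = FALSE),
                 label = label)
  })
}

#' Read-simulation parameters
#'
#' @param read_length read length in bp.
#' @param n_reads number of reads to draw.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param seed integer seed.
#' @return a `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 100, n_reads = 1000,
                            error_rate = 0, seed = 1) {
  stopifnot(read_length >= 1, n_reads >= 0,
            error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate shotgun reads from a strain mixture
#'
#' Reads are drawn uniformly over start positions and strands of a strain
#' chosen per read with the mixture proportions; substitution errors are
#' applied per base at `error_rate` (no indels). The returned truth
#' columns record source strain, 0-based start on the source genome,
#' strand, and the number of injected errors.
#'
#' @param strains list of `list(strain = strain_model-or-string,
#'   proportion = )`; proportions must sum to 1.
#' @param params a [read_sim_params()].
#' @return a `read_set`: data.frame `read_id`, `sequence`, `strain`,
#'   `start`, `strand`, `n_errors`.
#' @export
simulate_reads <- function(strains, params = read_sim_params()) {
  if (length(strains) == 0) stop("empty strain list")
  genomes <- vapply(strains, function(s) {
    g <- if (inherits(s$strain, "strain_model")) s$strain$genome
         else as.character(s$strain)
    toupper(g)
  }, character(1))
  labels <- vapply(seq_along(strains), function(i) {
    s <- strains[[i]]
    if (inherits(s$strain, "strain_model")) s$strain$label
    else paste0("strain", i)
  }, character(1))
  props <- vapply(strains, function(s) s$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  rl <- params$read_length
  if (any(nchar(genomes) < rl))
    stop("every genome must be at least read_length bp")
  n <- params$n_reads
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      strain = character(0), start = integer(0),
                      strand = character(0), n_errors = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0)
    return(structure(empty, class = c("read_set", "data.frame")))
  withr::with_seed(params$seed, {
    src <- sample.int(length(genomes), n, replace = TRUE, prob = props)
    Ls <- nchar(genomes)[src]
    start <- floor(runif(n) * (Ls - rl + 1))     # 0-based
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genomes[src], start + 1, start + rl)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    n_err <- integer(n)
    if (params$error_rate > 0) {
      n_err <- stats::rbinom(n, rl, params$error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(rl, n_err[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1),
                          character(1), USE.NAMES = FALSE)
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    structure(data.frame(read_id = sprintf("read_%06d", seq_len(n)),
                         sequence = seqs, strain = labels[src],
                         start = as.integer(start), strand = strand,
                         n_errors = n_err, stringsAsFactors = FALSE),
              class = c("read_set", "data.frame"))
  })
}

#' The published core-taxon table as a packaged fixture
#'
#' Returns the transcribed core table of mean relative abundances (in
#' percent) for the 13 genus-level taxa with prevalence > 70% in at least
#' three matrices of a production site, across the 20 (site, matrix)
#' groups of the five-site chain, together with the presence pattern its
#' reported/blank cells encode (a dash is treated as not reported /
#' absent).
#'
#' @return list with `abundance` (an `abundance_table` of the group-mean
#'   relative abundances as fractions, one row per (site, matrix) group,
#'   absent cells as 0), `percent` (the raw numeric matrix in percent,
#'   `NA` = not reported), and `presence` (a `presence_map` with
#'   threshold 0.70).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "core_table_published.tsv",
                      package = "dairytrace", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pct <- as.matrix(df[, setdiff(names(df), c("site", "matrix")), drop = FALSE])
  rownames(pct) <- paste0(df$site, df$matrix)
  vals <- pct / 100
  vals[is.na(vals)] <- 0
  meta <- data.frame(sample_id = rownames(pct), site = df$site,
                     matrix = df$matrix, replicate = "mean",
                     stringsAsFactors = FALSE)
  tab <- abundance_table(vals, meta, type = "relative")
  present <- t(!is.na(pct))                       # taxa x groups
  colnames(present) <- paste(df$site, df$matrix, sep = "|")
  list(abundance = tab, percent = pct,
       presence = presence_map_from_matrix(present, threshold = 0.70))
}
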