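## End-to-end orchestration over a file-based input bundle. The bundle
## layout is the one make_demo() emits; every stage reads files, writes
## TSV reports into out_dir and registers them in a JSON manifest with
## md5 checksums, so a rerun under the same config is byte-identical.

#' Read a pipeline configuration file
#'
#' YAML key-value configuration; all analysis thresholds appear as named
#' keys with the chain-tracing defaults (prevalence 0.70 strict,
#' min 3 matrices, contigs > 3000 bp, 100%/100% mapping, 3-fold screen).
#'
#' @param path YAML file.
#' @return a config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- normalizePath(dirname(path))
  validate_pipeline_config(cfg)
}

default_pipeline_config <- function() {
  list(prevalence_threshold = 0.70, min_matrices = 3L,
       min_contig_len = 3000L, identity_cutoff = 1.0,
       coverage_cutoff = 1.0, min_reads = 10L, min_breadth = 0.5,
       max_mismatch_frac = 0.05, min_cov = 5L, min_joint = 50L,
       snp_delta = 0.01, snp_homogeneity = 0.95, fold = 3,
       expr_total_condition = 1e6, expr_total_control = 1e6,
       stages = list(diversity = TRUE, core = TRUE, strain = TRUE,
                     snp = TRUE, ani = TRUE, expression = TRUE))
}

validate_pipeline_config <- function(cfg) {
  def <- default_pipeline_config()
  for (k in names(def)) if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
  if (is.null(cfg$seed))
    stop("pipeline config must carry an explicit seed")
  if (is.null(cfg$input_dir)) stop("pipeline config must name input_dir")
  if (is.null(cfg$out_dir)) stop("pipeline config must name out_dir")
  structure(cfg, class = "pipeline_config")
}

stage_path <- function(cfg, ...) file.path(cfg$input_dir, ...)

read_demo_contigs <- function(cfg) {
  meta <- read.delim(stage_path(cfg, "contigs_meta.tsv"),
                     stringsAsFactors = FALSE)
  seqs <- read_fasta(stage_path(cfg, "contigs.fasta"))
  contig_set(meta$id, unname(seqs[meta$id]), species = meta$species,
             sample = meta$sample)
}

#' Run the tracing pipeline on an input bundle
#'
#' Executes the enabled stages in workflow order — alpha diversity,
#' prevalence-based core tracing, strain-marker PCR and strict-mapping
#' presence calls, SNP-profile identity decisions, ANI confirmation,
#' expression screen — writing one TSV per report plus `manifest.json`
#' (inputs, parameters, seed, per-output md5 checksums). A rerun with
#' the same config reproduces every checksum.
#'
#' @param config a `pipeline_config` (list or [read_pipeline_config()]
#'   result) with at least `input_dir`, `out_dir`, `seed`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_tracing_tsv(x, p)
    outputs <<- c(outputs, p)
    p
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[dairytrace] stage %-10s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  rel <- read_table(stage_path(cfg, "profiles_relative.tsv"), "relative")
  tc <- tracing_config(cfg$prevalence_threshold, cfg$min_matrices,
                       matrices = intersect(CHAIN_MATRICES,
                                            unique(rel$meta$matrix)))

  if (isTRUE(cfg$stages$diversity)) run_stage("diversity", function() {
    cts <- read_table(stage_path(cfg, "profiles_counts.tsv"), "counts")
    emit(alpha_diversity(cts, seed = cfg$seed), "diversity.tsv")
  })

  presence <- NULL
  if (isTRUE(cfg$stages$core)) run_stage("core", function() {
    presence <<- prevalence_filter(rel, tc)
    emit(as.data.frame(presence), "presence_map.tsv")
    emit(pairwise_sharing_counts(presence), "sharing_counts.tsv")
    emit(site_sharing(presence, tc$min_matrices_for_core), "site_sharing.tsv")
    emit(core_table(rel, presence, tc), "core_table.tsv")
  })

  groups <- unique(rel$meta[, c("site", "matrix")])
  markers <- list()
  if (isTRUE(cfg$stages$strain)) run_stage("strain", function() {
    contigs <- filter_contigs(read_demo_contigs(cfg), cfg$min_contig_len)
    species <- sort(unique(contigs$species))
    gdir <- stage_path(cfg, "genomes")
    genome_files <- list.files(gdir, pattern = "\\.fasta$", full.names = TRUE)
    all_genomes <- lapply(genome_files, read_fasta)
    names(all_genomes) <- sub("\\.fasta$", "", basename(genome_files))
    rows <- list()
    mc <- mapping_config(cfg$identity_cutoff, cfg$coverage_cutoff,
                         min_reads = cfg$min_reads,
                         min_breadth = cfg$min_breadth)
    for (sp in species) {
      marker <- select_marker_contig(contigs, sp)
      bg <- c(unname(unlist(all_genomes[names(all_genomes) != sp])),
              contigs$sequence[contigs$species != sp])
      markers[[sp]] <<- design_primers(marker, bg)
      for (g in seq_len(nrow(groups))) {
        key <- paste0(groups$site[g], "_", groups$matrix[g])
        asm <- read_fasta(stage_path(cfg, "assemblies",
                                     paste0(key, ".fasta")))
        amp <- in_silico_pcr(markers[[sp]], asm)
        reads <- read_fastq(stage_path(cfg, "reads", paste0(key, ".fastq")))
        hits <- strict_map(reads, setNames(marker$sequence, marker$id), mc)
        cov <- coverage_and_presence(hits,
                                     setNames(marker$sequence, marker$id), mc)
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, site = groups$site[g], matrix = groups$matrix[g],
          pcr_present = nrow(amp) > 0, n_amplicons = nrow(amp),
          mapped_reads = cov$n_hits, breadth = cov$breadth,
          depth = cov$depth, map_present = cov$presence,
          stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, rows), "strain_presence.tsv")
    prim <- do.call(rbind, lapply(names(markers), function(sp) {
      mk <- markers[[sp]]
      data.frame(species = sp, contig = mk$contig_id,
                 fwd = mk$fwd$seq, fwd_start = mk$fwd$start,
                 fwd_tm = mk$fwd$tm, rev = mk$rev$seq,
                 rev_start = mk$rev$start, rev_tm = mk$rev$tm,
                 product_length = mk$product_length,
                 stringsAsFactors = FALSE)
    }))
    emit(prim, "primers.tsv")
  })

  if (isTRUE(cfg$stages$snp) && length(markers)) run_stage("snp", function() {
    contigs <- read_demo_contigs(cfg)
    rows <- list()
    for (sp in names(markers)) {
      marker <- select_marker_contig(contigs, sp)
      refseq <- setNames(marker$sequence, marker$id)
      pres <- read.delim(file.path(cfg$out_dir, "strain_presence.tsv"),
                         stringsAsFactors = FALSE)
      pos <- pres[pres$species == sp & pres$map_present, , drop = FALSE]
      if (nrow(pos) < 2) next
      keys <- paste0(pos$site, "_", pos$matrix)
      profs <- lapply(keys[1:2], function(key)
        profile_sample(read_fastq(stage_path(cfg, "reads",
                                             paste0(key, ".fastq"))),
                       refseq, cfg$max_mismatch_frac, cfg$min_cov))
      dec <- same_strain(profs[[1]], profs[[2]], cfg$snp_delta,
                         cfg$snp_homogeneity, cfg$min_joint)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, sample_a = keys[1], sample_b = keys[2],
        distance = dec$distance, n_joint = dec$n_joint,
        homogeneity_a = dec$homogeneity_a,
        homogeneity_b = dec$homogeneity_b, verdict = dec$verdict,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) emit(do.call(rbind, rows), "snp_decisions.tsv")
  })

  if (isTRUE(cfg$stages$ani)) run_stage("ani", function() {
    gdir <- stage_path(cfg, "genomes")
    species_files <- list.files(gdir, pattern = "^species_.*\\.fasta$",
                                full.names = TRUE)
    rows <- list()
    for (f in species_files) {
      sp <- sub("\\.fasta$", "", basename(f))
      g <- read_fasta(f)
      for (i in seq_along(g)) for (j in seq_along(g)) {
        if (i > j) next
        a <- ani(g[[i]], g[[j]])
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, query = names(g)[i], subject = names(g)[j],
          ani = a$ani, stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, rows), "ani_matrix.tsv")
  })

  if (isTRUE(cfg$stages$expression) &&
      file.exists(stage_path(cfg, "expression_counts.tsv")))
    run_stage("expression", function() {
      cts <- read.delim(stage_path(cfg, "expression_counts.tsv"),
                        stringsAsFactors = FALSE)
      emit(expression_screen(cts, cfg$expr_total_condition,
                             cfg$expr_total_control, fold = cfg$fold),
           "expression_screen.tsv")
    })

  manifest <- list(
    package = "dairytrace",
    version = as.character(utils::packageVersion("dairytrace")),
    input_dir = cfg$input_dir, seed = cfg$seed,
    parameters = cfg[setdiff(names(default_pipeline_config()), "stages")],
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Build a miniature synthetic chain as an input bundle
#'
#' Emits a two-site chain (CF/LIT/MIL/PC, 10 samples per matrix) with two
#' planted shared taxa and two planted strains — one transmitted
#' chain-wide across all four matrices of site S1, one partial (LIT and
#' PC of S2) — plus per-group read sets, per-group assemblies for the
#' in-silico PCR, marker contigs, strain genomes (with an isogenic and a
#' diverged "other site" variant per species for the ANI stage), an
#' expression count table with a known number of >3-fold genes, truth
#' files, and a ready-to-run `config.yaml`. Everything is deterministic
#' in `seed`.
#'
#' @param seed integer seed.
#' @param dir output directory (created).
#' @param n_reads reads per (site, matrix) group (default 4000).
#' @param genome_bp strain genome size (default 20000).
#' @return the demo `transmission_plan`, invisibly; side effect = files.
#' @export
make_demo <- function(seed = 1, dir = tempfile("dairytrace_demo_"),
                      n_reads = 4000, genome_bp = 20000) {
  seed <- as.integer(seed)
  for (d in c("", "genomes", "reads", "assemblies", "truth"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)

  profiles <- list(
    CF = c(`U. m. of Ruminococcaceae family` = 0.25,
           `U. m. of Lachnospiraceae family` = 0.20,
           Bacteroides = 0.12, Prevotella = 0.10, Alistipes = 0.06,
           Bifidobacterium = 0.02, Streptococcus = 0.01,
           Lactobacillus = 0.005),
    LIT = c(`U. m. of Lachnospiraceae family` = 0.12,
            `U. m. of Ruminococcaceae family` = 0.12,
            Corynebacterium = 0.10, Acinetobacter = 0.08,
            Bacteroides = 0.05, Lactobacillus = 0.05,
            Streptococcus = 0.04, Bifidobacterium = 0.03),
    MIL = c(Streptococcus = 0.25, Lactococcus = 0.15,
            Staphylococcus = 0.08, Corynebacterium = 0.05,
            Lactobacillus = 0.05,
            `U. m. of Lachnospiraceae family` = 0.02,
            Bifidobacterium = 0.01, Bacteroides = 0.01),
    PC = c(Lactobacillus = 0.903, Streptococcus = 0.087))
  spec <- community_spec(profiles, n_sites = 2, n_samples_per_matrix = 10,
                         overdispersion = 200, detection_floor = 1e-4)

  planted_taxa <- rbind(
    data.frame(taxon = "Planted_chainwide", site = "S1",
               matrix = CHAIN_MATRICES,
               abundance = c(0.02, 0.03, 0.02, 0.005)),
    data.frame(taxon = "Planted_partial", site = "S2",
               matrix = c("LIT", "PC"), abundance = c(0.03, 0.02)))

  parentA <- random_genome(genome_bp, seed)
  parentB <- random_genome(genome_bp, seed + 1L)
  decoy <- random_genome(genome_bp, seed + 2L)
  strainA <- strain_model(parentA, label = "species_A_strain")
  strainB <- strain_model(parentB, label = "species_B_strain")
  othersiteA <- mutate_genome(parentA, 50, seed + 3L, "species_A_othersite")
  othersiteB <- mutate_genome(parentB, 50, seed + 4L, "species_B_othersite")

  placements <- list(
    species_A = data.frame(site = "S1", matrix = CHAIN_MATRICES,
                           proportion = 0.5),
    species_B = data.frame(site = "S2", matrix = c("LIT", "PC"),
                           proportion = 0.5))
  plan <- transmission_plan(
    planted_taxa,
    list(list(species = "species_A", strain = strainA,
              placements = placements$species_A),
         list(species = "species_B", strain = strainB,
              placements = placements$species_B)),
    seed = seed)

  tab <- generate_chain_profiles(spec, plan)
  write_table(tab, file.path(dir, "profiles_relative.tsv"))
  cts <- tab
  cts$values <- round(tab$values * 50000)
  cts$type <- "counts"
  write_table(cts, file.path(dir, "profiles_counts.tsv"))

  write_fasta(c(species_A_isolate = parentA,
                species_A_othersite = othersiteA$genome),
              file.path(dir, "genomes", "species_A.fasta"))
  write_fasta(c(species_B_isolate = parentB,
                species_B_othersite = othersiteB$genome),
              file.path(dir, "genomes", "species_B.fasta"))
  write_fasta(c(decoy = decoy), file.path(dir, "genomes", "background.fasta"))

  # "assembled" marker contigs: a 5 kb slice of each strain genome, plus
  # a short contig that the >3000 bp filter must discard
  contigs <- data.frame(
    id = c("ctg_A1", "ctg_A2", "ctg_B1", "ctg_short"),
    sequence = c(substr(parentA, 1001, 6000), substr(parentA, 8001, 12000),
                 substr(parentB, 1001, 6000), substr(parentB, 100, 2599)),
    species = c("species_A", "species_A", "species_B", "species_B"),
    sample = c("S1_PC", "S1_PC", "S2_PC", "S2_PC"),
    stringsAsFactors = FALSE)
  write_fasta(setNames(contigs$sequence, contigs$id),
              file.path(dir, "contigs.fasta"))
  write.table(contigs[, c("id", "species", "sample")],
              file.path(dir, "contigs_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  strains_truth <- list()
  k <- 0
  gi <- 0
  sites <- spec$sites
  for (s in sites) for (m in names(profiles)) {
    gi <- gi + 1
    key <- paste0(s, "_", m)
    mix <- list()
    asm <- c(decoy = decoy)
    for (sp in names(placements)) {
      pl <- placements[[sp]]
      strain <- if (sp == "species_A") strainA else strainB
      if (any(pl$site == s & pl$matrix == m)) {
        prop <- pl$proportion[pl$site == s & pl$matrix == m][1]
        mix[[length(mix) + 1]] <- list(strain = strain, proportion = prop)
        asm[strain$label] <- strain$genome
        k <- k + 1
        strains_truth[[k]] <- data.frame(species = sp, site = s, matrix = m,
                                         proportion = prop,
                                         stringsAsFactors = FALSE)
      }
    }
    rest <- 1 - sum(vapply(mix, function(x) x$proportion, numeric(1)))
    mix[[length(mix) + 1]] <- list(strain = strain_model(decoy,
                                                         label = "decoy"),
                                   proportion = rest)
    rs <- simulate_reads(mix, read_sim_params(
      read_length = 100, n_reads = n_reads, error_rate = 0,
      seed = seed + 100L + gi))
    write_fastq(rs, file.path(dir, "reads", paste0(key, ".fastq")))
    write_fasta(asm, file.path(dir, "assemblies", paste0(key, ".fasta")))
  }

  write.table(planted_taxa, file.path(dir, "truth", "planted_taxa.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, strains_truth),
              file.path(dir, "truth", "planted_strains.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (v in list(othersiteA, othersiteB))
    write.table(v$snps, file.path(dir, "truth", paste0(v$label, "_snps.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  expr <- withr::with_seed(seed + 9L, {
    n_genes <- 30; n_pass <- 7
    len <- sample(300:3000, n_genes)
    base <- rpois_safe(n_genes, 200)
    data.frame(gene_id = sprintf("gene_%02d", seq_len(n_genes)),
               length_bp = len,
               reads_condition = c(base[seq_len(n_pass)] * 8L,
                                   base[-seq_len(n_pass)]),
               reads_control = base, stringsAsFactors = FALSE)
  })
  write.table(expr, file.path(dir, "expression_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- c(default_pipeline_config(),
           list(seed = seed, input_dir = dir,
                out_dir = file.path(dir, "report")))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(plan)
}

rpois_safe <- function(n, lambda) pmax(1L, stats::rpois(n, lambda))
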