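# End-to-end orchestration: synthetic community -> binning -> composition
# PCA -> gene calling -> pathway scoring -> marker screen, from a single
# declarative config, with a provenance manifest. One master seed fans out
# into per-stage seeds (derive_seed), so any stage can be re-run alone.

#' Default run configuration
#'
#' Community scale defaults are desk-scale stand-ins for a five-site study
#' averaging ~14,000 reads per site; `reads_per_sample` scales them.
#'
#' @param seed Master seed (mandatory for a run).
#' @param out_dir Output directory.
#' @param reads_per_sample Mate pairs per sample.
#' @return A named list config.
#' @export
default_run_config <- function(seed = 1L, out_dir = "metaprof_run",
                               reads_per_sample = 150L) {
  list(
    seed = seed,
    out_dir = out_dir,
    samples = list(
      list(name = "siteA", gc = 0.35, genome_length = 60000L,
           n_pairs = reads_per_sample, divergence = 0.05),
      list(name = "siteB", gc = 0.50, genome_length = 60000L,
           n_pairs = reads_per_sample, divergence = 0.05),
      list(name = "siteC", gc = 0.65, genome_length = 60000L,
           n_pairs = reads_per_sample, divergence = 0.05)
    ),
    read_len_mean = 800, read_len_sd = 40, error_rate = 0.005,
    e_threshold = 1e-10, band_edges = DEFAULT_BAND_EDGES,
    min_contig_length = 1500L, contigs_per_sample = 30L, word_length = 5L,
    min_aa = 30L, cluster_identity = 0.97,
    bit_floor = 50, bit_window = 0.20,
    pathway_samples = 5L, marker_plants = 2L
  )
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [default_run_config()].
#' @return Config list merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  base[names(cfg)] <- cfg
  base
}

.validate_config <- function(config) {
  .assert(!is.null(config$seed), "config must set a seed")
  for (s in config$samples) {
    .assert(s$n_pairs > 0, "sample '%s' has zero reads", s$name)
    .assert(s$divergence >= 0 && s$divergence <= 0.5,
            "sample '%s': divergence out of range", s$name)
  }
  .assert(config$e_threshold > 0, "e_threshold must be positive")
  .assert(config$bit_window >= 0 && config$bit_window < 1,
          "bit_window must be in [0,1)")
  invisible(config)
}

#' Run the full profiling pipeline on a synthetic community
#'
#' Deterministic given the config seed. Emits, under `out_dir`:
#' `bins.tsv`, `bin_summary.tsv`, `recruitment.tsv`, `pca_coords.tsv`,
#' `completeness.tsv`, `activity.tsv`, `pathway_dendrogram.nwk`,
#' `sample_dendrogram.nwk`, `markers.tsv`, `marker_counts.tsv` and
#' `manifest.json`.
#'
#' @param config A config list as from [default_run_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_profile <- function(config = default_run_config()) {
  .validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(failed_stage = name, error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$seed
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # -- community ---------------------------------------------------------
  res <- stage("community", {
    genomes <- list(); refs <- list(); reads <- list(); truth <- list()
    contigs <- list(); contig_truth <- list()
    for (s in config$samples) {
      g <- simulate_genome(
        genome_model(s$name, s$genome_length, gc = s$gc),
        derive_seed(seed, paste0("genome/", s$name)))
      genomes[[s$name]] <- g
      refs[[s$name]] <- mutate_genome(
        g, s$divergence, derive_seed(seed, paste0("ref/", s$name)),
        id = paste0(s$name, "_ref"))
      sh <- shed_reads(g, s$n_pairs, config$read_len_mean,
                       config$read_len_sd, error_rate = config$error_rate,
                       seed = derive_seed(seed, paste0("reads/", s$name)))
      reads[[s$name]] <- sh$reads; truth[[s$name]] <- sh$truth
      ct <- simulate_contigs(g, config$contigs_per_sample,
                             seed = derive_seed(seed,
                                                paste0("contigs/", s$name)))
      contigs[[s$name]] <- ct$contigs; contig_truth[[s$name]] <- ct$truth
    }
    note("community: %d samples, %d reads, %d contigs",
         length(genomes), sum(vapply(reads, nrow, 1L)),
         sum(vapply(contigs, nrow, 1L)))
    list(genomes = genomes, refs = refs,
         reads = do.call(rbind, unname(reads)),
         truth = do.call(rbind, unname(truth)),
         contigs = do.call(rbind, unname(contigs)),
         contig_truth = do.call(rbind, unname(contig_truth)))
  })

  # -- binning -----------------------------------------------------------
  bins <- stage("binning", {
    refs_df <- do.call(rbind, unname(res$refs))
    hits <- align_reads(res$reads, res$truth, refs_df)
    b <- best_hit_bin(hits, config$e_threshold, config$band_edges)
    tsv(b, "bins.tsv")
    tsv(bin_summary(b, total_reads = nrow(res$reads)), "bin_summary.tsv")
    rec <- lapply(seq_len(nrow(refs_df)), function(i) {
      pr <- recruit(hits, refs_df$id[i], nchar(refs_df$seq[i]))
      if (nrow(pr$points) == 0) return(NULL)
      cbind(subject_id = pr$subject_id, pr$points,
            coverage_x = pr$coverage_x)
    })
    tsv(do.call(rbind, rec[!vapply(rec, is.null, TRUE)]), "recruitment.tsv")
    note("binning: %d/%d reads assigned",
         sum(b$subject_id != "Unassigned"), nrow(res$reads))
    b
  })

  # -- composition PCA ---------------------------------------------------
  pca <- stage("composition", {
    kept <- filter_contigs(res$contigs, config$min_contig_length)
    prof <- profile_contigs(kept, L = config$word_length)
    p <- pca_profiles(prof, n_components = 3L)
    coords <- data.frame(contig_id = rownames(p$coords), p$coords,
                         stringsAsFactors = FALSE)
    coords$source <- res$contig_truth$source_genome[
      match(coords$contig_id, res$contig_truth$contig_id)]
    tsv(coords, "pca_coords.tsv")
    note("composition: %d contigs > %d bp, PC1 %.1f%% variance",
         nrow(kept), config$min_contig_length, 100 * p$explained[1])
    p
  })

  # -- gene calling ------------------------------------------------------
  orfs <- stage("gene_calling", {
    sub <- head(res$reads, 40L)  # dereplication demo on a read subset
    o <- call_orfs(sub, min_aa = config$min_aa)
    prot <- sequence_records(o$orf_id, o$protein, mode = "protein")
    cl <- greedy_cluster(prot, config$cluster_identity, type = "protein")
    note("gene_calling: %d candidate ORFs, %d clusters at %.2f identity",
         nrow(o), length(unique(cl$representative)),
         config$cluster_identity)
    list(orfs = o, clusters = cl)
  })

  # -- pathway scoring ---------------------------------------------------
  scores <- stage("pathway_scoring", {
    study <- simulate_pathway_study(
      n_samples = config$pathway_samples,
      seed = derive_seed(seed, "pathway_study"), paired_genomes = TRUE)
    counts <- reaction_hit_counts(study$hits, study$db,
                                  config$bit_floor, config$bit_window)
    comp <- score_matrix(counts, study$db, "completeness")
    act <- score_matrix(counts, study$db, "activity")
    tsv(data.frame(pathway = rownames(comp), comp, check.names = FALSE),
        "completeness.tsv")
    tsv(data.frame(pathway = rownames(act), act, check.names = FALSE),
        "activity.tsv")
    key <- select_key_pathways(comp, study$db)
    trees <- cluster_score_matrix(comp[key, , drop = FALSE],
                                  "completeness")
    write_dendrogram(trees$pathways,
                     file.path(config$out_dir, "pathway_dendrogram.nwk"))
    write_dendrogram(trees$samples,
                     file.path(config$out_dir, "sample_dendrogram.nwk"))
    note("pathway_scoring: %d pathways scored, %d key pathways",
         nrow(comp), length(key))
    list(study = study, counts = counts, completeness = comp,
         activity = act, key = key, trees = trees)
  })

  # -- marker screen -----------------------------------------------------
  markers <- stage("markers", {
    reg <- default_marker_registry()
    study <- simulate_marker_study(
      reg, samples = vapply(config$samples, `[[`, "", "name"),
      plants_per_sample = config$marker_plants, decoys = TRUE,
      seed = derive_seed(seed, "marker_study"))
    cand <- screen_markers(study$hits, reg, config$e_threshold)
    calls <- validate_markers(cand, study$reverse, reg,
                              blacklist = study$blacklist,
                              label_families = study$label_families)
    tab <- marker_count_table(calls, reg)
    tsv(calls, "markers.tsv")
    tsv(data.frame(process = rownames(tab), tab, check.names = FALSE),
        "marker_counts.tsv")
    note("markers: %d candidates, %d confirmed", nrow(cand),
         sum(calls$status == "confirmed"))
    list(calls = calls, table = tab, truth = study$truth)
  })

  manifest <- list(
    config = config[setdiff(names(config), "samples")],
    samples = lapply(config$samples, function(s) s[c("name", "gc",
                                                     "genome_length",
                                                     "n_pairs",
                                                     "divergence")]),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("metaprof")),
    stages = log_lines
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(community = res, bins = bins, pca = pca, orfs = orfs,
                 scores = scores, markers = markers))
}
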