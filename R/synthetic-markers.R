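# Synthetic marker-gene study: plants marker genes into per-sample
# assemblies and emits the two tables the screen consumes — a forward hit
# table (marker queries vs environmental sequences) and a reverse-annotation
# table (best functional label per environmental sequence) — plus the truth.
# Optional decoys exercise each false-positive rule.

#' A small default marker registry
#'
#' Seven process-diagnostic genes spanning CO2 fixation, sulfur and arsenic
#' metabolism, grouped into protein families for the family-mismatch rule.
#' @return A [marker_registry()] data.frame.
#' @export
default_marker_registry <- function() {
  marker_registry(data.frame(
    gene_symbol = c("aclB", "sqr", "doxB", "sreA", "dsrA", "arsB", "merA"),
    query_id = paste0("Q_", c("aclB", "sqr", "doxB", "sreA", "dsrA",
                              "arsB", "merA")),
    query_len = c(390, 430, 580, 710, 350, 430, 560),
    process = c("CO2 fixation (rTCA)", "sulfide oxidation",
                "oxygen reduction", "sulfur reduction",
                "sulfite reduction", "arsenite efflux",
                "mercury detoxification"),
    family = c("citrate lyase", "FAD sulfide oxidoreductase",
               "heme Cu oxidase", "Mo-pterin oxidoreductase",
               "siroheme reductase", "ArsB permease",
               "mercuric reductase"),
    stringsAsFactors = FALSE
  ))
}

#' Simulate a marker-gene study with known truth
#'
#' Plants `plants_per_sample` copies of each of `plant_symbols` in every
#' sample as confident full-length matches. Decoys, when enabled, add one
#' case per rule per sample: a same-family/different-gene relative (rule i),
#' a homologous fragment annotated to a different process (rule ii), a
#' blacklisted mis-annotation (rule iii), and a short fragment below the
#' coverage floor.
#'
#' @param registry A [marker_registry()].
#' @param samples Character vector of sample names.
#' @param plant_symbols Gene symbols to plant.
#' @param plants_per_sample True copies of each symbol per sample.
#' @param decoys Add one decoy per false-positive rule per sample.
#' @param seed Integer seed.
#' @return List: `hits`, `reverse`, `blacklist`, `label_families` (named
#'   vector for [validate_markers()]), `truth` (process x sample matrix of
#'   planted counts).
#' @export
simulate_marker_study <- function(registry = default_marker_registry(),
                                  samples = sprintf("S%02d", 1:5),
                                  plant_symbols = c("sqr", "dsrA"),
                                  plants_per_sample = 2L,
                                  decoys = FALSE, seed = 1L) {
  set.seed(derive_seed(seed, "markers"))
  hit_rows <- list(); rev_rows <- list()
  truth <- matrix(0L, nrow = length(unique(registry$process)),
                  ncol = length(samples),
                  dimnames = list(unique(registry$process), samples))
  blacklist <- "misannotated-homolog"
  add_hit <- function(sample, qsym, env, evalue, cov_frac, label, process) {
    i <- match(qsym, registry$gene_symbol)
    qlen <- registry$query_len[i]
    span <- max(10L, round(cov_frac * qlen))
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      query_id = registry$query_id[i], subject_id = env,
      pct_identity = round(runif(1, 60, 95), 1), aln_len = span,
      mismatches = round(span * 0.2), gap_opens = 0L,
      q_start = 1L, q_end = span, s_start = 1L, s_end = span * 3L,
      evalue = evalue, bitscore = round(span * 1.9),
      sample = sample, stringsAsFactors = FALSE)
    rev_rows[[length(rev_rows) + 1L]] <<- data.frame(
      env_id = env, label = label, process = process,
      stringsAsFactors = FALSE)
  }
  for (s in samples) {
    for (sym in plant_symbols) {
      proc <- registry$process[match(sym, registry$gene_symbol)]
      for (k in seq_len(plants_per_sample)) {
        env <- sprintf("%s_env_%s_%d", s, sym, k)
        add_hit(s, sym, env, evalue = 10^-runif(1, 30, 120),
                cov_frac = runif(1, 0.6, 1), label = sym, process = proc)
        truth[proc, s] <- truth[proc, s] + 1L
      }
    }
    if (decoys) {
      # rule i: right family, wrong gene (a heme Cu oxidase that is coxA,
      # not doxB); label_families maps coxA into doxB's family
      add_hit(s, "doxB", paste0(s, "_decoy_family"), 1e-30, 0.8,
              label = "coxA", process = "oxygen reduction")
      # rule ii: homologous region, different function
      add_hit(s, "sreA", paste0(s, "_decoy_function"), 1e-40, 0.7,
              label = "Mo-pterin oxidoreductase (other)",
              process = "formate oxidation")
      # rule iii: blacklisted mis-annotation
      add_hit(s, "arsB", paste0(s, "_decoy_blacklist"), 1e-35, 0.8,
              label = "misannotated-homolog",
              process = "arsenite efflux")
      # coverage: true gene fragment too short for assignment
      sym <- plant_symbols[1]
      add_hit(s, sym, paste0(s, "_decoy_short"), 1e-20, 0.1,
              label = sym,
              process = registry$process[match(sym, registry$gene_symbol)])
    }
  }
  hits <- do.call(rbind, hit_rows); rownames(hits) <- NULL
  reverse <- do.call(rbind, rev_rows)
  reverse <- reverse[!duplicated(reverse$env_id), , drop = FALSE]
  rownames(reverse) <- NULL
  list(hits = hits, reverse = reverse, blacklist = blacklist,
       label_families = c(coxA = "heme Cu oxidase"), truth = truth)
}
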