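# Marker-gene screen: candidate matches of process-diagnostic query genes
# (e.g. aclB for rTCA CO2 fixation, dsrA for dissimilatory sulfite
# reduction, sqr/doxB/sreA for electron transfer, arsB/merA for
# detoxification) against assembled environmental sequence, followed by
# rule-based false-positive elimination. The expert-judgment rules are
# operationalized as label-matching rules over a supplied reverse-annotation
# table, and every rejection is recorded with the rule that fired so calls
# are auditable.

#' Construct a marker-query registry
#'
#' @param df Data.frame with columns `gene_symbol`, `query_id`,
#'   `query_len` (aa), `process` (free-text process label), `family`
#'   (protein family grouping related symbols).
#' @return The validated registry data.frame.
#' @export
marker_registry <- function(df) {
  need <- c("gene_symbol", "query_id", "query_len", "process", "family")
  .assert(all(need %in% names(df)), "registry needs columns: %s",
          paste(need, collapse = ", "))
  .assert(anyDuplicated(df[, c("gene_symbol", "query_id")]) == 0,
          "duplicate (gene_symbol, query_id) pair")
  df
}

#' Screen a hit table for marker-gene candidates
#'
#' One candidate per (environmental sequence, gene symbol) passing the
#' E-value threshold, keeping the best-evalue hit. Query coverage is the
#' aligned query span divided by the registered query length.
#'
#' @param hits Alignment-hit data.frame: `query_id` = marker query,
#'   `subject_id` = environmental sequence. An optional `sample` column is
#'   carried through.
#' @param registry A [marker_registry()].
#' @param e_threshold E-value cutoff (default `1e-10`, strict).
#' @return Candidate data.frame: `env_id`, `gene_symbol`, `sample`,
#'   `evalue`, `bitscore`, `coverage`.
#' @export
screen_markers <- function(hits, registry, e_threshold = 1e-10) {
  unknown <- setdiff(unique(hits$query_id), registry$query_id)
  .assert(length(unknown) == 0, "query absent from marker registry: %s",
          unknown[1])
  h <- hits[hits$evalue < e_threshold, , drop = FALSE]
  if (!"sample" %in% names(h)) h$sample <- "sample1"
  if (nrow(h) == 0L) {
    return(data.frame(env_id = character(), gene_symbol = character(),
                      sample = character(), evalue = numeric(),
                      bitscore = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(h$query_id, registry$query_id)
  cand <- data.frame(
    env_id = h$subject_id,
    gene_symbol = registry$gene_symbol[idx],
    sample = h$sample,
    evalue = h$evalue,
    bitscore = h$bitscore,
    coverage = (abs(h$q_end - h$q_start) + 1) / registry$query_len[idx],
    stringsAsFactors = FALSE
  )
  ord <- order(cand$env_id, cand$gene_symbol, cand$evalue, -cand$bitscore)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand[, c("env_id", "gene_symbol")]), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Validate marker candidates against reverse annotations
#'
#' Applies the false-positive elimination rules in order:
#' \itemize{
#'   \item rule `i` — the sequence's best reverse-annotation label is a
#'     *different member of the same protein family* as the query gene
#'     (right family, wrong gene);
#'   \item rule `ii` — the reverse label belongs to a different functional
#'     process than the query's process label (homologous region, different
#'     function);
#'   \item rule `iii` — the reverse label is on the configured
#'     mis-annotation blacklist;
#'   \item rule `coverage` — aligned query coverage below `min_coverage`
#'     (insufficient length for a definitive assignment).
#' }
#' A candidate whose environmental sequence is missing from the reverse
#' table gets status `undetermined` (and a message).
#'
#' @param candidates Output of [screen_markers()].
#' @param reverse Data.frame `env_id`, `label` (best reverse-annotation
#'   gene label), `process` (functional label of that annotation).
#' @param registry A [marker_registry()] (provides family and process per
#'   symbol).
#' @param min_coverage Minimum query coverage (default 0.3).
#' @param blacklist Character vector of labels known to be mis-annotated.
#' @param label_families Optional named vector mapping reverse-annotation
#'   labels that are not query symbols to protein families, extending the
#'   registry's family map for rule `i`.
#' @return The candidates with `status`
#'   (`confirmed`/`rejected`/`undetermined`), `reject_rule`
#'   (`i`,`ii`,`iii`,`coverage`,`none`) and `reverse_label` columns.
#' @export
validate_markers <- function(candidates, reverse, registry,
                             min_coverage = 0.3, blacklist = character(),
                             label_families = character()) {
  n <- nrow(candidates)
  status <- character(n); rule <- character(n); rlabel <- character(n)
  fam <- c(setNames(registry$family, registry$gene_symbol), label_families)
  fam <- fam[!duplicated(names(fam))]
  proc <- setNames(registry$process, registry$gene_symbol)
  for (i in seq_len(n)) {
    sym <- candidates$gene_symbol[i]
    j <- match(candidates$env_id[i], reverse$env_id)
    if (is.na(j)) {
      status[i] <- "undetermined"; rule[i] <- "none"; rlabel[i] <- NA
      message("no reverse annotation for ", candidates$env_id[i],
              "; call undetermined")
      next
    }
    lab <- reverse$label[j]
    rlabel[i] <- lab
    if (!is.na(fam[lab]) && fam[lab] == fam[sym] && lab != sym) {
      status[i] <- "rejected"; rule[i] <- "i"
    } else if (lab != sym && !identical(reverse$process[j], proc[[sym]])) {
      status[i] <- "rejected"; rule[i] <- "ii"
    } else if (lab %in% blacklist) {
      status[i] <- "rejected"; rule[i] <- "iii"
    } else if (candidates$coverage[i] < min_coverage) {
      status[i] <- "rejected"; rule[i] <- "coverage"
    } else {
      status[i] <- "confirmed"; rule[i] <- "none"
    }
  }
  out <- candidates
  out$status <- status
  out$reject_rule <- rule
  out$reverse_label <- rlabel
  out
}

#' Marker count table (process x sample)
#'
#' @param calls Validated marker calls.
#' @param registry A [marker_registry()].
#' @param samples Optional sample universe (columns); defaults to samples
#'   present in `calls`.
#' @param processes Optional process universe (rows); defaults to registry
#'   processes.
#' @return Integer matrix process x sample counting distinct confirmed
#'   environmental sequences; absent combinations are 0.
#' @export
marker_count_table <- function(calls, registry, samples = NULL,
                               processes = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  if (is.null(processes)) processes <- unique(registry$process)
  m <- matrix(0L, nrow = length(processes), ncol = length(samples),
              dimnames = list(processes, samples))
  conf <- calls[calls$status == "confirmed", , drop = FALSE]
  if (nrow(conf)) {
    proc <- setNames(registry$process, registry$gene_symbol)
    conf$process <- proc[conf$gene_symbol]
    conf <- conf[!duplicated(conf[, c("env_id", "process", "sample")]), ,
                 drop = FALSE]
    tab <- table(factor(conf$process, levels = processes),
                 factor(conf$sample, levels = samples))
    m[] <- m + as.integer(tab)
  }
  m
}
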