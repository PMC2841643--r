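# Synthetic pathway-study generator: builds a reaction database with
# controlled overlap structure (shared reactions, near-duplicate pathway
# variants), plants per-sample pathway content, and emits per-sample protein
# hit tables with signal hits (bit scores safely above the 50-bit floor) on
# truly encoded reactions plus spurious noise hits on random others. The
# planted indicator matrix is returned so downstream scores can be checked
# against ground truth.

#' Describe a synthetic pathway database
#'
#' @param n_pathways Number of base pathways.
#' @param size_range Inclusive range of reactions per pathway.
#' @param frac_shared Fraction of each pathway's reactions drawn from a
#'   common shared pool (promiscuous reactions) rather than minted fresh.
#' @param n_variant_pairs Number of pathways duplicated as near-identical
#'   variants (one reaction swapped), exercising the no-penalty property.
#' @param proteins_per_reaction Reference proteins per reaction.
#' @param partial_ec_frac Fraction of reactions flagged with partial EC
#'   numbers.
#' @return A spec list consumed by [simulate_pathway_study()].
#' @export
pathway_db_spec <- function(n_pathways = 50L, size_range = c(5L, 10L),
                            frac_shared = 0.15, n_variant_pairs = 3L,
                            proteins_per_reaction = 2L,
                            partial_ec_frac = 0.1) {
  .assert(size_range[1] >= 2, "pathways need at least 2 reactions")
  list(n_pathways = n_pathways, size_range = size_range,
       frac_shared = frac_shared, n_variant_pairs = n_variant_pairs,
       proteins_per_reaction = proteins_per_reaction,
       partial_ec_frac = partial_ec_frac)
}

#' Build a random pathway database from a spec
#'
#' @param spec A [pathway_db_spec()].
#' @param seed Integer seed.
#' @return A [pathway_db()].
#' @export
simulate_pathway_db <- function(spec, seed) {
  set.seed(seed)
  shared_pool <- sprintf("RXN-S%03d", seq_len(max(
    4L, ceiling(spec$frac_shared * mean(spec$size_range) * 4))))
  pathways <- list()
  counter <- 0L
  for (p in seq_len(spec$n_pathways)) {
    sz <- sample(spec$size_range[1]:spec$size_range[2], 1)
    n_shared <- min(rbinom(1, sz, spec$frac_shared), length(shared_pool),
                    sz - 1L)
    own <- sprintf("RXN-%04d", counter + seq_len(sz - n_shared))
    counter <- counter + sz - n_shared
    rxns <- c(own, sample(shared_pool, n_shared))
    pathways[[sprintf("PWY-%03d", p)]] <- sample(rxns)
  }
  # near-duplicate variants: copy a pathway and swap one reaction
  if (spec$n_variant_pairs > 0) {
    base <- sample(names(pathways), spec$n_variant_pairs)
    for (b in base) {
      rxns <- pathways[[b]]
      new_rxn <- sprintf("RXN-%04d", counter + 1L); counter <- counter + 1L
      rxns[sample(length(rxns), 1)] <- new_rxn
      pathways[[paste0(b, "-VAR")]] <- rxns
    }
  }
  all_rxns <- unique(unlist(pathways, use.names = FALSE))
  partial <- runif(length(all_rxns)) < spec$partial_ec_frac
  ec <- ifelse(partial,
               sprintf("%d.%d.-.-", sample(1:6, length(all_rxns), TRUE),
                       sample(1:9, length(all_rxns), TRUE)),
               sprintf("%d.%d.%d.%d", sample(1:6, length(all_rxns), TRUE),
                       sample(1:9, length(all_rxns), TRUE),
                       sample(1:9, length(all_rxns), TRUE),
                       sample(1:99, length(all_rxns), TRUE)))
  reaction_ec <- data.frame(reaction_id = all_rxns, ec = ec,
                            partial = partial, stringsAsFactors = FALSE)
  proteins <- setNames(lapply(seq_along(all_rxns), function(i)
    sprintf("%s_P%d", all_rxns[i], seq_len(spec$proteins_per_reaction))),
    all_rxns)
  pathway_db(pathways, reaction_ec, proteins)
}

#' Default signal bit-score distribution (safely above the 50-bit floor)
#' @param n Number of draws.
#' @return Numeric vector of bit scores >= 60.
#' @export
signal_bitscores <- function(n) pmax(rnorm(n, mean = 200, sd = 50), 60)

#' Default noise bit-score distribution (mostly, not entirely, below 50)
#' @param n Number of draws.
#' @return Numeric vector of positive bit scores.
#' @export
noise_bitscores <- function(n) pmax(rnorm(n, mean = 35, sd = 12), 1)

#' Simulate a planted pathway study
#'
#' For each sample, each pathway is present with probability
#' `p_pathway_present`; a present pathway has a random fraction (at least
#' `min_encoded_frac`) of its reactions truly encoded. Every encoded
#' reaction receives 1 + Pois(`mean_extra_queries`) query translations whose
#' hits to the reaction's proteins draw from the signal distribution. Noise
#' adds `noise_rate` spurious queries per encoded reaction, hitting random
#' proteins with noise-distribution scores. Optionally, each sample is
#' paired with a noise-free "reference genome" column carrying the same
#' planted content, mirroring genome-vs-metagenome comparisons.
#'
#' @param spec A [pathway_db_spec()].
#' @param n_samples Number of metagenome samples.
#' @param seed Integer seed.
#' @param p_pathway_present Probability a pathway is present in a sample.
#' @param min_encoded_frac Minimum encoded fraction of a present pathway.
#' @param mean_extra_queries Poisson mean of extra queries per encoded
#'   reaction.
#' @param noise_rate Expected spurious queries per encoded reaction.
#' @param signal_dist,noise_dist Functions `n -> bit scores`.
#' @param paired_genomes Add one reference-genome column per sample with
#'   identical planted content (noise-free, signal hits only).
#' @return List: `db`, `hits` (data.frame `sample`, `query_id`,
#'   `protein_id`, `bitscore`), `indicators` (reaction x column 0/1 planted
#'   truth), `truth_counts` (reaction x column planted query counts),
#'   `planted_completeness` (pathway x column).
#' @export
simulate_pathway_study <- function(spec = pathway_db_spec(), n_samples = 5L,
                                   seed = 1L, p_pathway_present = 0.5,
                                   min_encoded_frac = 0.5,
                                   mean_extra_queries = 1,
                                   noise_rate = 0.3,
                                   signal_dist = signal_bitscores,
                                   noise_dist = noise_bitscores,
                                   paired_genomes = FALSE) {
  .assert(all(signal_dist(10) > 0) && all(noise_dist(10) > 0),
          "bit-score distributions must produce positive scores")
  db <- simulate_pathway_db(spec, derive_seed(seed, "pathway_db"))
  all_rxns <- db$reaction_ec$reaction_id
  all_prots <- unlist(db$reaction_proteins, use.names = FALSE)
  samples <- sprintf("S%02d", seq_len(n_samples))
  cols <- if (paired_genomes) c(samples, paste0(samples, "_genome")) else samples
  ind <- matrix(0L, nrow = length(all_rxns), ncol = length(cols),
                dimnames = list(all_rxns, cols))
  tc <- matrix(0L, nrow = length(all_rxns), ncol = length(cols),
               dimnames = list(all_rxns, cols))
  hit_rows <- list()
  for (si in seq_len(n_samples)) {
    s <- samples[si]
    set.seed(derive_seed(seed, paste0("content/", s)))
    encoded <- character(0)
    for (p in names(db$pathways)) {
      if (runif(1) < p_pathway_present) {
        rxns <- db$pathways[[p]]
        k <- max(1L, round(runif(1, min_encoded_frac, 1) * length(rxns)))
        encoded <- union(encoded, sample(rxns, k))
      }
    }
    ind[encoded, s] <- 1L
    if (paired_genomes) ind[encoded, paste0(s, "_genome")] <- 1L
    set.seed(derive_seed(seed, paste0("hits/", s)))
    qn <- 0L
    emit <- function(sample_col, rxn, n_q, scores_fun, noise = FALSE) {
      rows <- vector("list", n_q)
      for (q in seq_len(n_q)) {
        qn <<- qn + 1L
        qid <- sprintf("%s_q%05d", sample_col, qn)
        prots <- if (noise) {
          # spurious hits land on proteins of non-encoded reactions only,
          # so any count they cause is a genuine false positive
          pool <- unlist(db$reaction_proteins[setdiff(all_rxns, encoded)],
                         use.names = FALSE)
          if (!length(pool)) pool <- all_prots
          sample(pool, sample(1:2, 1))
        } else {
          pr <- db$reaction_proteins[[rxn]]
          pr[sample(length(pr), sample(length(pr), 1))]
        }
        rows[[q]] <- data.frame(sample = sample_col, query_id = qid,
                                protein_id = prots,
                                bitscore = scores_fun(length(prots)),
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    for (r in encoded) {
      n_q <- 1L + rpois(1, mean_extra_queries)
      tc[r, s] <- tc[r, s] + n_q
      hit_rows[[length(hit_rows) + 1L]] <- emit(s, r, n_q, signal_dist)
      if (paired_genomes) {
        tc[r, paste0(s, "_genome")] <- 1L
        hit_rows[[length(hit_rows) + 1L]] <-
          emit(paste0(s, "_genome"), r, 1L, signal_dist)
      }
    }
    n_noise <- rpois(1, noise_rate * length(encoded))
    if (n_noise > 0) {
      hit_rows[[length(hit_rows) + 1L]] <-
        emit(s, NULL, n_noise, noise_dist, noise = TRUE)
    }
  }
  hits <- do.call(rbind, hit_rows)
  rownames(hits) <- NULL
  planted <- score_matrix(ind, db, "completeness")
  list(db = db, hits = hits, indicators = ind, truth_counts = tc,
       planted_completeness = planted)
}
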