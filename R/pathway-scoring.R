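# Pathway completeness and activity scoring. The core computation: hits of
# clustered query translations against a reaction-associated protein
# database are filtered (bit > 50 and within 20% of the top hit), counted
# per reaction as unique query translations, and turned into two pathway x
# sample score matrices:
#
#   completeness  C_j = sum_{i in R_j} w_i * I_i / sum_{i in R_j} w_i
#   activity          = median unique-hit count over R_j (zeros included)
#
# with the reaction specificity weight
#
#   w_i = (n_totrxn_i / n_unirxn_i) / n_pw_i
#
# where n_pw_i is the number of distinct pathways containing reaction i,
# n_totrxn_i the total number of reactions in those pathways (with
# multiplicity) and n_unirxn_i the number of unique reactions in them. The
# ratio n_totrxn/n_unirxn equals n_pw when the containing pathways are
# identical, so duplicated pathway variants carry no penalty, while a
# reaction shared across genuinely different pathways is discounted.

# ---- database index helpers -------------------------------------------

# protein -> character vector of reaction ids (full/direct associations)
.protein_reactions <- function(db, partial = FALSE) {
  want <- db$reaction_ec$reaction_id[db$reaction_ec$partial == partial]
  pr <- db$reaction_proteins[names(db$reaction_proteins) %in% want]
  if (!length(pr)) return(list())
  prot <- unlist(pr, use.names = FALSE)
  rxn <- rep(names(pr), lengths(pr))
  split(rxn, prot)
}

#' Reaction specificity counts and weights for a pathway database
#'
#' @param db A [pathway_db()].
#' @return Data.frame `reaction_id`, `n_pw`, `n_totrxn`, `n_unirxn`,
#'   `weight`, one row per reaction that appears in at least one pathway.
#' @export
specificity_weights <- function(db) {
  rxn_by_pw <- db$pathways
  all_rxns <- unique(unlist(rxn_by_pw, use.names = FALSE))
  pw_sizes <- lengths(rxn_by_pw)
  # pathway membership per reaction
  pw_of <- split(rep(names(rxn_by_pw), pw_sizes),
                 unlist(rxn_by_pw, use.names = FALSE))
  rows <- lapply(all_rxns, function(r) {
    pws <- unique(pw_of[[r]])
    n_pw <- length(pws)
    n_tot <- sum(pw_sizes[pws])
    n_uni <- length(unique(unlist(rxn_by_pw[pws], use.names = FALSE)))
    data.frame(reaction_id = r, n_pw = n_pw, n_totrxn = n_tot,
               n_unirxn = n_uni,
               weight = (n_tot / n_uni) / n_pw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specificity weight of one reaction
#'
#' @param reaction_id Reaction id; must occur in at least one pathway.
#' @param db A [pathway_db()].
#' @return The weight `w_i` in `(0, 1]`.
#' @export
specificity_weight <- function(reaction_id, db) {
  w <- specificity_weights(db)
  i <- match(reaction_id, w$reaction_id)
  .assert(!is.na(i), "reaction '%s' occurs in no pathway", reaction_id)
  w$weight[i]
}

# ---- hit filtering and counting ---------------------------------------

#' Filter the hit list of one query translation
#'
#' Retains hits with bitscore strictly above `bit_floor` and at least
#' `(1 - window)` of the top retained-eligible bitscore. Hits to proteins
#' whose only reaction associations are through partial EC numbers are
#' suppressed whenever any fully-associated protein scored above the floor;
#' they are used only as a fallback when no full association passes.
#'
#' @param hits Data.frame with columns `protein_id`, `bitscore` (all rows
#'   one query).
#' @param db A [pathway_db()].
#' @param bit_floor Bit score floor (default 50, strict).
#' @param window Fractional window below the top bit score (default 0.20).
#' @return Data.frame `protein_id`, `bitscore`, `partial_only`,
#'   `reactions` (list column of reaction ids, full and partial pooled),
#'   zero rows if nothing survives.
#' @export
filtered_hit_list <- function(hits, db, bit_floor = 50, window = 0.20) {
  .filter_query(hits, .protein_reactions(db, FALSE),
                .protein_reactions(db, TRUE), bit_floor, window)
}

.filter_query <- function(hits, full_map, part_map, bit_floor, window) {
  partial_only <- !(hits$protein_id %in% names(full_map)) &
    hits$protein_id %in% names(part_map)
  above <- hits$bitscore > bit_floor
  use_partial <- !any(above & !partial_only)
  eligible <- above & (!partial_only | use_partial)
  if (!any(eligible)) {
    out <- data.frame(protein_id = character(), bitscore = numeric(),
                      partial_only = logical(), stringsAsFactors = FALSE)
    out$reactions <- list()
    return(out)
  }
  top <- max(hits$bitscore[eligible])
  keep <- eligible & hits$bitscore >= (1 - window) * top
  out <- data.frame(protein_id = hits$protein_id[keep],
                    bitscore = hits$bitscore[keep],
                    partial_only = partial_only[keep],
                    stringsAsFactors = FALSE)
  out$reactions <- lapply(out$protein_id, function(p)
    unique(c(full_map[[p]], part_map[[p]])))
  out
}

#' Count unique query translations per reaction and sample
#'
#' A query contributes at most once to a reaction however many of that
#' reaction's proteins its filtered hit list touches.
#'
#' @param hits Data.frame with columns `sample`, `query_id`, `protein_id`,
#'   `bitscore`.
#' @param db A [pathway_db()].
#' @inheritParams filtered_hit_list
#' @return Integer matrix reaction x sample of unique-translation counts
#'   (all db reactions as rows, zero-filled).
#' @export
reaction_hit_counts <- function(hits, db, bit_floor = 50, window = 0.20) {
  known <- unique(unlist(db$reaction_proteins, use.names = FALSE))
  bad <- setdiff(unique(hits$protein_id), known)
  .assert(length(bad) == 0, "hit references protein absent from db: %s",
          bad[1])
  all_rxns <- unique(unlist(db$pathways, use.names = FALSE))
  all_rxns <- union(all_rxns, db$reaction_ec$reaction_id)
  samples <- sort(unique(hits$sample))
  counts <- matrix(0L, nrow = length(all_rxns), ncol = length(samples),
                   dimnames = list(all_rxns, samples))
  full_map <- .protein_reactions(db, FALSE)
  part_map <- .protein_reactions(db, TRUE)
  for (s in samples) {
    hs <- hits[hits$sample == s, , drop = FALSE]
    for (q in unique(hs$query_id)) {
      fl <- .filter_query(hs[hs$query_id == q, , drop = FALSE],
                          full_map, part_map, bit_floor, window)
      rxns <- unique(unlist(fl$reactions, use.names = FALSE))
      rxns <- intersect(rxns, all_rxns)
      if (length(rxns)) counts[rxns, s] <- counts[rxns, s] + 1L
    }
  }
  counts
}

# ---- scores -----------------------------------------------------------

#' Pathway completeness score
#'
#' Weighted fraction of a pathway's reactions with at least one hit:
#' `C_j = sum w_i I_i / sum w_i` over the pathway's reaction set, with
#' specificity weights discounting promiscuous reactions. 1 iff every
#' reaction is present, 0 iff none is.
#'
#' @param pathway_id Pathway id in `db`.
#' @param indicators Named logical/0-1 vector over reaction ids (presence);
#'   reactions missing from the vector count as absent.
#' @param db A [pathway_db()].
#' @param weights Optional precomputed [specificity_weights()] table.
#' @return Completeness in `[0, 1]`.
#' @export
completeness_score <- function(pathway_id, indicators, db, weights = NULL) {
  if (is.null(weights)) weights <- specificity_weights(db)
  rxns <- db$pathways[[pathway_id]]
  .assert(!is.null(rxns), "unknown pathway '%s'", pathway_id)
  w <- weights$weight[match(rxns, weights$reaction_id)]
  ind <- as.numeric(indicators[rxns])
  ind[is.na(ind)] <- 0
  sum(w * ind) / sum(w)
}

#' Pathway activity score
#'
#' Median unique-translation hit count over *all* reactions of the pathway;
#' reactions without hits contribute zero. Even cardinality takes the mean
#' of the central pair.
#'
#' @param pathway_id Pathway id in `db`.
#' @param counts Named numeric vector of per-reaction hit counts (one
#'   sample); missing reactions count 0.
#' @param db A [pathway_db()].
#' @return Nonnegative median count.
#' @export
activity_score <- function(pathway_id, counts, db) {
  rxns <- db$pathways[[pathway_id]]
  .assert(!is.null(rxns), "unknown pathway '%s'", pathway_id)
  x <- as.numeric(counts[rxns])
  x[is.na(x)] <- 0
  median(x)
}

#' Pathway x sample score matrix
#'
#' @param counts Reaction x sample count matrix from
#'   [reaction_hit_counts()], or a 0/1 indicator matrix for
#'   completeness-from-truth columns.
#' @param db A [pathway_db()].
#' @param score_type `"completeness"` or `"activity"`.
#' @return Numeric matrix pathway x sample with attribute `score_type`.
#' @export
score_matrix <- function(counts, db,
                         score_type = c("completeness", "activity")) {
  score_type <- match.arg(score_type)
  weights <- specificity_weights(db)
  samples <- colnames(counts)
  pws <- names(db$pathways)
  m <- matrix(0, nrow = length(pws), ncol = length(samples),
              dimnames = list(pws, samples))
  for (s in samples) {
    v <- counts[, s]
    names(v) <- rownames(counts)
    for (p in pws) {
      m[p, s] <- if (score_type == "completeness") {
        completeness_score(p, v > 0, db, weights)
      } else {
        activity_score(p, v, db)
      }
    }
  }
  attr(m, "score_type") <- score_type
  m
}

# ---- key-pathway selection and two-way clustering ---------------------

#' Select key pathways by PCA contribution
#'
#' Pathways with fewer than `min_reactions` reactions are dropped first
#' (completeness mode only, by default). The remaining pathway x sample
#' matrix is decomposed by PCA with pathways as variables; each pathway's
#' contribution is the variance-weighted sum of its squared loadings on the
#' top `n_pc` components. The `top_k` highest-contribution pathways are
#' kept, then near-duplicate pathway variants (reaction sets differing by
#' at most one reaction, symmetric difference) are collapsed to the
#' higher-contribution member.
#'
#' @param scores Pathway x sample score matrix (rows named by pathway).
#' @param db A [pathway_db()].
#' @param n_pc Number of leading components (default 3).
#' @param top_k Number of pathways to keep before redundancy removal.
#' @param min_reactions Minimum pathway size (default 5).
#' @param apply_size_filter Apply the size filter (default TRUE for
#'   completeness matrices, FALSE for activity; resolved from the matrix's
#'   `score_type` attribute when `NULL`).
#' @return Character vector of selected pathway ids, highest contribution
#'   first.
#' @export
select_key_pathways <- function(scores, db, n_pc = 3L, top_k = 15L,
                                min_reactions = 5L,
                                apply_size_filter = NULL) {
  if (is.null(apply_size_filter)) {
    apply_size_filter <- !identical(attr(scores, "score_type"), "activity")
  }
  m <- scores
  if (apply_size_filter) {
    keep <- lengths(db$pathways[rownames(m)]) >= min_reactions
    m <- m[keep, , drop = FALSE]
  }
  .assert(ncol(m) >= n_pc + 1, "need at least n_pc + 1 sample columns")
  vr <- apply(m, 1, stats::var)
  .assert(any(vr > 0), "score matrix has no variance across samples")
  m <- m[vr > 0, , drop = FALSE]
  p <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(p$rotation))
  contrib <- as.numeric(
    p$rotation[, seq_len(k), drop = FALSE]^2 %*% (p$sdev[seq_len(k)]^2))
  names(contrib) <- rownames(m)
  sel <- names(sort(contrib, decreasing = TRUE))[seq_len(min(top_k,
                                                             length(contrib)))]
  # collapse near-duplicate pathway variants (symmetric difference <= 1)
  kept <- character(0)
  for (p_id in sel) {  # already in decreasing contribution order
    dup <- FALSE
    for (q_id in kept) {
      sd_size <- length(setdiff(db$pathways[[p_id]], db$pathways[[q_id]])) +
        length(setdiff(db$pathways[[q_id]], db$pathways[[p_id]]))
      if (sd_size <= 1L) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, p_id)
  }
  kept
}

#' Two-way average-linkage clustering of a score matrix
#'
#' Completeness matrices use Euclidean distance; activity matrices are
#' transformed `log(1 + x)` and use `1 - Pearson` correlation distance.
#' Zero-variance rows/columns under the correlation metric get maximal
#' distance (2) to everything, with a message.
#'
#' @param scores Pathway x sample score matrix.
#' @param score_type `"completeness"` or `"activity"`; resolved from the
#'   matrix attribute when `NULL`.
#' @return List with `pathways` and `samples`, each an [stats::hclust]
#'   average-linkage tree.
#' @export
cluster_score_matrix <- function(scores, score_type = NULL) {
  if (is.null(score_type)) {
    score_type <- attr(scores, "score_type")
    if (is.null(score_type)) score_type <- "completeness"
  }
  .assert(nrow(scores) >= 2 && ncol(scores) >= 2,
          "need at least 2 rows and 2 columns")
  dfun <- function(m) {
    if (score_type == "activity") {
      m <- log1p(m)
      cc <- suppressWarnings(cor(t(m)))
      bad <- apply(m, 1, sd) == 0
      if (any(bad)) message(sum(bad),
        " zero-variance row(s) under Pearson metric; using maximal distance")
      cc[is.na(cc)] <- -1
      diag(cc) <- 1
      stats::as.dist(1 - cc)
    } else {
      dist(m)
    }
  }
  list(pathways = hclust(dfun(scores), method = "average"),
       samples = hclust(dfun(t(scores)), method = "average"))
}

#' Write an hclust tree as Newick
#'
#' @param hc An [stats::hclust] object.
#' @param path Output path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
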