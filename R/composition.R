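# Nucleotide word-frequency signatures and their PCA. Word frequencies of
# lengths 1..L are a compositional signature that separates genomes without
# any reference database; PCA of the signatures recovers the source-genome
# structure of an assembly.

#' Word-frequency feature names for lengths 1..L
#'
#' Feature order is fixed: ascending word length, lexicographic (A<C<G<T)
#' within each length. For L = 5 this yields 4+16+64+256+1024 = 1364
#' features.
#'
#' @param L Maximum word length.
#' @return Character vector of words.
#' @export
word_features <- function(L = 5L) {
  unlist(lapply(seq_len(L), function(k) {
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  }), use.names = FALSE)
}

#' Word-frequency profile of one sequence
#'
#' Counts every overlapping word of each length 1..L and normalizes counts
#' *within* each word length, so each length contributes a probability
#' vector and lengths are comparable in scale. Windows containing `N` are
#' skipped. With `collapse_rc = TRUE` each word's count is pooled with its
#' reverse complement and both features carry the pooled frequency, making
#' the profile strand-invariant.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @param L Maximum word length (default 5).
#' @param collapse_rc Pool reverse-complement word pairs.
#' @return Named numeric vector over [word_features()] of length
#'   `sum(4^(1:L))`.
#' @export
word_frequency_profile <- function(seq, L = 5L, collapse_rc = FALSE) {
  .assert(nchar(seq) > L, "sequence shorter than maximum word length")
  .assert(grepl("^[ACGTN]+$", seq), "sequence has characters outside ACGTN")
  x <- Biostrings::DNAString(seq)
  out <- lapply(seq_len(L), function(k) {
    counts <- Biostrings::oligonucleotideFrequency(x, width = k)
    if (collapse_rc) {
      rc <- vapply(names(counts), reverse_complement, character(1))
      counts <- counts + counts[rc]
    }
    tot <- sum(counts)
    .assert(tot > 0, "no countable %d-mer windows after N filtering", k)
    counts / tot
  })
  unlist(out, use.names = TRUE)
}

#' Profile matrix for a set of contigs
#'
#' @param records Sequence records (contigs).
#' @param L Maximum word length.
#' @param collapse_rc See [word_frequency_profile()].
#' @return Numeric matrix, one row per contig (rownames = contig ids),
#'   columns [word_features()].
#' @export
profile_contigs <- function(records, L = 5L, collapse_rc = FALSE) {
  m <- t(vapply(records$seq, word_frequency_profile,
                numeric(sum(4^seq_len(L))), L = L,
                collapse_rc = collapse_rc, USE.NAMES = FALSE))
  rownames(m) <- records$id
  m
}

#' Filter contigs by minimum length
#'
#' Strictly-greater-than filter: a contig of exactly `min_length` bp is
#' dropped.
#'
#' @param records Sequence records.
#' @param min_length Length cutoff in bp (default 1500).
#' @return The records with `nchar(seq) > min_length`.
#' @export
filter_contigs <- function(records, min_length = 1500L) {
  records[nchar(records$seq) > min_length, , drop = FALSE]
}

#' PCA of word-frequency profiles
#'
#' Deterministic full-rank PCA by singular value decomposition of the
#' centered (optionally unit-variance standardized) profile matrix. Axis
#' signs are fixed by convention: the largest-magnitude loading on each
#' component is made positive, so coordinates are reproducible across runs
#' and input orders.
#'
#' @param profiles Matrix from [profile_contigs()] (rows = contigs).
#' @param n_components Number of axes to keep.
#' @param standardize Scale features to unit variance before PCA
#'   (zero-variance features are left centered only).
#' @return A list of class `pca_coordinates`: `coords` (contigs x
#'   components), `explained` (variance fractions, non-increasing),
#'   `loadings` (features x components).
#' @export
pca_profiles <- function(profiles, n_components = 3L, standardize = TRUE) {
  .assert(nrow(profiles) >= n_components + 1,
          "need at least n_components + 1 profiles")
  m <- profiles[order(rownames(profiles)), , drop = FALSE]
  if (standardize) {
    sds <- apply(m, 2, sd)
    sds[sds == 0 | is.na(sds)] <- 1  # constant features stay centered only
    p <- prcomp(m, center = TRUE, scale. = sds)
  } else {
    p <- prcomp(m, center = TRUE, scale. = FALSE)
  }
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(coords = scores[match(rownames(profiles), rownames(scores)), ,
                         drop = FALSE],
         explained = ev[seq_len(k)],
         loadings = rot),
    class = "pca_coordinates"
  )
}

#' @export
print.pca_coordinates <- function(x, ...) {
  cat(sprintf("pca_coordinates: %d points x %d components (%.1f%% variance)\n",
              nrow(x$coords), ncol(x$coords), 100 * sum(x$explained)))
  invisible(x)
}

#' Quantify cluster separation of PCA coordinates
#'
#' Turns the visual claim that sites form distinct clusters into two
#' numbers: the mean silhouette width of the true labels, and the adjusted
#' Rand index between the true labels and a k-means clustering at
#' k = number of classes.
#'
#' @param coords Numeric matrix of coordinates (e.g. `$coords` of
#'   [pca_profiles()]).
#' @param labels True class labels, one per row.
#' @param nstart k-means restarts (k-means is the only stochastic step;
#'   seed it with [set.seed()] for exact reproducibility).
#' @return A list with `silhouette` and `ari`, both in `[-1, 1]`.
#' @export
cluster_separation <- function(coords, labels, nstart = 25L) {
  labels <- as.character(labels)
  .assert(length(labels) == nrow(coords), "one label per coordinate row")
  k <- length(unique(labels))
  .assert(k >= 2, "need at least two label classes")
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(coords))
  km <- kmeans(coords, centers = k, nstart = nstart)
  list(
    silhouette = mean(sil[, "sil_width"]),
    ari = mclust::adjustedRandIndex(labels, km$cluster)
  )
}
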