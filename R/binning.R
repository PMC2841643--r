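# Taxonomic binning by best nucleotide hit, percent-identity banding, and
# fragment recruitment / fold-coverage estimation.

#' Default percent-identity band edges
#'
#' Spans the 47-100% identity range over which binned reads are categorized.
#' @export
DEFAULT_BAND_EDGES <- c(47, 50, 60, 70, 80, 90, 95, 100)

#' Bin reads to their closest reference by best hit
#'
#' Keeps, per read, only hits with `evalue < e_threshold` and assigns the
#' read to the subject of the highest-bitscore surviving hit. Ties on
#' bitscore are broken by lower evalue, then lexicographic subject id, so
#' binning is deterministic. Reads with no surviving hit are labeled
#' `Unassigned`.
#'
#' @param hits Alignment-hit data.frame.
#' @param e_threshold E-value cutoff (default `1e-10`; hits must score
#'   strictly below it).
#' @param band_edges Identity band edges passed to [identity_band()].
#' @return A data.frame with one row per read that had any hit: `read_id`,
#'   `subject_id` (or `"Unassigned"`), `pct_identity`, `band_label`,
#'   `evalue`, `bitscore` (NA for unassigned reads).
#' @export
best_hit_bin <- function(hits, e_threshold = 1e-10,
                         band_edges = DEFAULT_BAND_EDGES) {
  .assert(e_threshold > 0, "e_threshold must be positive")
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(), subject_id = character(),
                      pct_identity = numeric(), band_label = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  surviving <- hits[hits$evalue < e_threshold, , drop = FALSE]
  all_reads <- unique(hits$query_id)
  if (nrow(surviving)) {
    ord <- order(surviving$query_id, -surviving$bitscore, surviving$evalue,
                 surviving$subject_id)
    surviving <- surviving[ord, , drop = FALSE]
    best <- surviving[!duplicated(surviving$query_id), , drop = FALSE]
  } else {
    best <- surviving
  }
  assigned <- data.frame(
    read_id = best$query_id, subject_id = best$subject_id,
    pct_identity = best$pct_identity,
    band_label = identity_band(best$pct_identity, band_edges),
    evalue = best$evalue, bitscore = best$bitscore,
    stringsAsFactors = FALSE
  )
  un <- setdiff(all_reads, assigned$read_id)
  if (length(un)) {
    assigned <- rbind(assigned, data.frame(
      read_id = un, subject_id = "Unassigned", pct_identity = NA_real_,
      band_label = NA_character_, evalue = NA_real_, bitscore = NA_real_,
      stringsAsFactors = FALSE))
  }
  assigned[order(assigned$read_id), , drop = FALSE]
}

#' Label percent identities with identity bands
#'
#' Bands are half-open `[e_k, e_{k+1})`; the top band is closed at its upper
#' edge so 100% identity falls in the last band. Values below the first edge
#' get the below-range label `"<47"` (first edge).
#'
#' @param pct_identity Numeric vector of percent identities.
#' @param edges Strictly increasing band edges; conventionally from 47
#'   to 100.
#' @return Character vector of band labels like `"90-95"`.
#' @export
identity_band <- function(pct_identity, edges = DEFAULT_BAND_EDGES) {
  .assert(all(diff(edges) > 0), "band edges must be strictly increasing")
  .assert(length(edges) >= 2, "need at least two edges")
  labels <- paste0(edges[-length(edges)], "-", edges[-1])
  idx <- findInterval(pct_identity, edges, rightmost.closed = TRUE)
  out <- ifelse(idx == 0, paste0("<", edges[1]), labels[pmin(idx,
                length(labels))])
  # values above the top edge are out of range for percent identity
  out[pct_identity > edges[length(edges)]] <- NA_character_
  out
}

#' Fragment recruitment of hits to one reference
#'
#' One point per hit: the subject-position midpoint versus percent identity,
#' mirroring a recruitment plot. Mean fold-coverage is the total aligned
#' length divided by the reference length.
#'
#' @param hits Alignment-hit data.frame (all subjects; filtered internally).
#' @param subject_id Reference genome id to recruit against.
#' @param subject_length Reference length in bp.
#' @return A list of class `recruitment_profile` with `subject_id`,
#'   `points` (data.frame `position`, `pct_identity`, `read_id`) and
#'   `coverage_x`.
#' @export
recruit <- function(hits, subject_id, subject_length) {
  .assert(subject_length > 0, "subject_length must be positive")
  h <- hits[hits$subject_id == subject_id, , drop = FALSE]
  lo <- pmin(h$s_start, h$s_end)
  hi <- pmax(h$s_start, h$s_end)
  .assert(all(hi <= subject_length),
          "hit coordinates exceed subject length (%s)", subject_id)
  structure(
    list(subject_id = subject_id,
         points = data.frame(position = (lo + hi) / 2,
                             pct_identity = h$pct_identity,
                             read_id = h$query_id, stringsAsFactors = FALSE),
         coverage_x = sum(as.numeric(h$aln_len)) / subject_length),
    class = "recruitment_profile"
  )
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("recruitment_profile: %s, %d points, coverage %.2fx\n",
              x$subject_id, nrow(x$points), x$coverage_x))
  invisible(x)
}

#' Summarize bin assignments per reference
#'
#' Fractions are reported over two denominators: all reads (`fraction`,
#' Unassigned included) and binned reads only (`fraction_binned`), since
#' community percentages are quoted against either.
#'
#' @param bins Output of [best_hit_bin()].
#' @param total_reads Total reads in the sample (>= number of binned reads);
#'   reads absent from `bins` (no hits at all) count as Unassigned.
#' @return A data.frame `subject_id`, `n_reads`, `fraction`,
#'   `fraction_binned`, plus one `band_frac_*` column per identity band.
#' @export
bin_summary <- function(bins, total_reads = nrow(bins)) {
  .assert(total_reads >= nrow(bins),
          "total_reads smaller than number of binned reads")
  n_unassigned_extra <- total_reads - nrow(bins)
  counts <- table(bins$subject_id)
  if (n_unassigned_extra > 0 || !"Unassigned" %in% names(counts)) {
    counts["Unassigned"] <- sum(counts[names(counts) == "Unassigned"]) +
      n_unassigned_extra
  }
  subjects <- names(counts)
  n_binned <- sum(counts[subjects != "Unassigned"])
  out <- data.frame(
    subject_id = subjects,
    n_reads = as.integer(counts),
    fraction = as.numeric(counts) / total_reads,
    fraction_binned = ifelse(subjects == "Unassigned", NA_real_,
                             as.numeric(counts) / max(n_binned, 1L)),
    stringsAsFactors = FALSE
  )
  bands <- sort(unique(bins$band_label[!is.na(bins$band_label)]))
  for (b in bands) {
    col <- paste0("band_frac_", gsub("[^0-9A-Za-z<]+", "_", b))
    out[[col]] <- vapply(subjects, function(s) {
      rows <- bins$subject_id == s
      if (!any(rows) || s == "Unassigned") return(NA_real_)
      mean(bins$band_label[rows] == b, na.rm = FALSE)
    }, numeric(1), USE.NAMES = FALSE)
  }
  out <- out[order(-out$n_reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}
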