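# Fixture aligner. Because the mutation model is substitution-only, a read
# shed from genome G occupies the same coordinates on any reference derived
# from G by mutate_genome(), so an ungapped comparison at the truth interval
# is the exact optimal alignment. Scores use blastn-style ungapped match/
# mismatch scoring (+2/-3) converted to bits, with an idealized E-value
# E = m * n * 2^(-bitscore). Unrelated references (different source genome,
# ~25% identity) score below zero and produce no hit, as real blastn would
# report nothing. This is a test fixture generator, not an aligner for real
# data.

#' Align synthetic reads to reference genomes at their truth coordinates
#'
#' @param reads Sequence records from [shed_reads()].
#' @param truth Matching truth data.frame from [shed_reads()] (possibly
#'   row-bound across genomes).
#' @param references Sequence records of reference genomes. Every reference
#'   is compared against every read; reads whose truth interval exceeds the
#'   reference length are skipped for that reference.
#' @param match,mismatch Ungapped scoring parameters (the bitscore is
#'   `match * n_match + mismatch * n_mismatch`).
#' @param min_bitscore Hits below this bitscore are not reported.
#' @return An alignment-hit data.frame in the 12-column BLAST tabular layout.
#' @export
align_reads <- function(reads, truth, references,
                        match = 2, mismatch = -3, min_bitscore = 30) {
  db_len <- sum(nchar(references$seq))
  out <- vector("list", nrow(references))
  read_raw <- lapply(reads$seq, charToRaw)
  names(read_raw) <- reads$id
  ord <- match(truth$read_id, reads$id)
  .assert(!anyNA(ord), "truth references unknown read id")
  for (j in seq_len(nrow(references))) {
    ref_raw <- charToRaw(references$seq[j])
    rlen <- length(ref_raw)
    ok <- which(truth$end <= rlen)
    if (!length(ok)) next
    n_ok <- length(ok)
    qid <- character(n_ok); pid <- numeric(n_ok); alen <- integer(n_ok)
    mm <- integer(n_ok); ss <- integer(n_ok); se <- integer(n_ok)
    qe <- integer(n_ok); bs <- numeric(n_ok)
    for (i in seq_len(n_ok)) {
      k <- ok[i]
      rseq <- read_raw[[ord[k]]]
      refslice <- ref_raw[(truth$start[k] + 1L):truth$end[k]]
      if (truth$strand[k] == "-") {
        refslice <- charToRaw(reverse_complement(rawToChar(refslice)))
      }
      L <- min(length(rseq), length(refslice))
      nmat <- sum(rseq[seq_len(L)] == refslice[seq_len(L)])
      qid[i] <- truth$read_id[k]
      alen[i] <- L
      mm[i] <- L - nmat
      pid[i] <- 100 * nmat / L
      qe[i] <- L
      bs[i] <- match * nmat + mismatch * (L - nmat)
      if (truth$strand[k] == "+") {
        ss[i] <- truth$start[k] + 1L; se[i] <- truth$start[k] + L
      } else {
        ss[i] <- truth$end[k]; se[i] <- truth$end[k] - L + 1L
      }
    }
    keep <- bs >= min_bitscore
    if (!any(keep)) next
    out[[j]] <- data.frame(
      query_id = qid[keep], subject_id = references$id[j],
      pct_identity = pid[keep], aln_len = alen[keep], mismatches = mm[keep],
      gap_opens = 0L, q_start = 1L, q_end = qe[keep],
      s_start = ss[keep], s_end = se[keep],
      evalue = pmin(db_len * as.numeric(alen[keep]) * 2^(-bs[keep]), 10),
      bitscore = bs[keep], stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits)) return(empty_hits())
  rownames(hits) <- NULL
  validate_hits(hits)
  hits
}
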