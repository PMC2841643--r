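# Candidate ORF extraction from reads (six-frame, stop-bounded, run-on at
# read edges) and greedy longest-first dereplication of the translations.

#' Extract candidate ORFs from all six frames of a read
#'
#' Per frame, maximal stop-free codon stretches between stop codons (or the
#' read edges) are reported when at least `min_aa` codons long. Candidates
#' are stop-bounded, not start-bounded: they need not begin with a start
#' codon, and a stretch truncated by a read edge rather than a stop codon is
#' flagged partial at that end (run-on). A 5'-edge candidate that begins
#' with a start codon (`ATG`/`GTG`/`TTG`) is treated as complete at its 5'
#' end rather than run-on. With `require_start = TRUE`,
#' candidates are trimmed to the first start codon (`ATG/GTG/TTG`, genetic
#' code 11) and non-partial-5' candidates without one are dropped.
#'
#' @param read One-row sequence-record data.frame (nucleotide).
#' @param min_aa Minimum candidate length in amino acids.
#' @param translation_table NCBI genetic code id (default 11, bacterial and
#'   archaeal).
#' @param require_start Demand a start codon (off by default).
#' @return Data.frame with one row per candidate: `read_id`, `frame`
#'   (+1,+2,+3,-1,-2,-3), `nt_start`, `nt_end` (0-based half-open on the
#'   read's forward strand), `partial5`, `partial3`, `protein`.
#' @export
six_frame_orfs <- function(read, min_aa = 30L, translation_table = "11",
                           require_start = FALSE) {
  seq <- read$seq[1]
  .assert(grepl("^[ACGTN]+$", seq), "read has characters outside ACGTN")
  .assert(nchar(seq) >= 3 * min_aa, "read shorter than 3 * min_aa")
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  n <- nchar(seq)
  rc <- reverse_complement(seq)
  rows <- list()
  for (dir in c(1L, -1L)) {
    s <- if (dir == 1L) seq else rc
    for (off in 0:2) {
      frame_len <- ((n - off) %/% 3L) * 3L
      if (frame_len < 3L) next
      sub <- substr(s, off + 1L, off + frame_len)
      prot <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), genetic.code = code,
        if.fuzzy.codon = "solve", no.init.codon = TRUE)))
      prot <- gsub("[^A-Z*]", "X", prot)
      stops <- gregexpr("*", prot, fixed = TRUE)[[1]]
      stops <- stops[stops > 0]
      bounds <- c(0L, stops, nchar(prot) + 1L)  # aa positions of delimiters
      for (b in seq_len(length(bounds) - 1L)) {
        aa_start <- bounds[b] + 1L          # 1-based aa, inclusive
        aa_end <- bounds[b + 1L] - 1L
        len_aa <- aa_end - aa_start + 1L
        first_codon <- substr(sub, (aa_start - 1L) * 3L + 1L,
                              (aa_start - 1L) * 3L + 3L)
        partial5 <- bounds[b] == 0L &&
          !(first_codon %in% c("ATG", "GTG", "TTG"))
        partial3 <- bounds[b + 1L] == nchar(prot) + 1L
        pep <- substr(prot, aa_start, aa_end)
        if (require_start && len_aa > 0) {
          m <- regexpr("M", pep, fixed = TRUE)
          if (!partial5 || m > 1) {  # trim to first start if not run-on
            if (m < 0) next
            aa_start <- aa_start + as.integer(m) - 1L
            len_aa <- aa_end - aa_start + 1L
            pep <- substr(prot, aa_start, aa_end)
            partial5 <- FALSE
          }
        }
        if (len_aa < min_aa) next
        # frame-local nt interval (0-based half-open) on strand `s`
        fs <- off + (aa_start - 1L) * 3L
        fe <- off + aa_end * 3L
        if (dir == 1L) {
          nt_start <- fs; nt_end <- fe
        } else {
          nt_start <- n - fe; nt_end <- n - fs
        }
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = read$id[1],
          frame = dir * (off + 1L),
          nt_start = nt_start, nt_end = nt_end,
          partial5 = partial5, partial3 = partial3,
          protein = pep, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(read_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      partial5 = logical(), partial3 = logical(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract candidate ORFs from many reads
#'
#' @param reads Sequence records; reads shorter than `3 * min_aa` are
#'   skipped.
#' @inheritParams six_frame_orfs
#' @return Row-bound candidate table with globally unique `orf_id` column
#'   (`read_id|frame|nt_start`).
#' @export
call_orfs <- function(reads, min_aa = 30L, translation_table = "11",
                      require_start = FALSE) {
  keep <- nchar(reads$seq) >= 3 * min_aa
  out <- lapply(which(keep), function(i)
    six_frame_orfs(reads[i, , drop = FALSE], min_aa, translation_table,
                   require_start))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(read_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      partial5 = logical(), partial3 = logical(),
                      protein = character(), stringsAsFactors = FALSE)
  }
  out$orf_id <- sprintf("%s|%+d|%d", out$read_id, out$frame, out$nt_start)
  out
}

#' GC-bin reads
#'
#' Sorts reads by GC fraction (ties by id) and chunks them into consecutive
#' bins of `bin_size`; the last bin may be smaller. Mirrors per-bin
#' downstream processing of compositionally homogeneous read sets.
#'
#' @param reads Sequence records.
#' @param bin_size Reads per bin (default 10000).
#' @return A list of sequence-record data.frames ordered by GC.
#' @export
gc_bin_reads <- function(reads, bin_size = 10000L) {
  .assert(bin_size >= 1, "bin_size must be >= 1")
  if (nrow(reads) == 0L) return(list())
  gc <- vapply(reads$seq, .gc_fraction, numeric(1), USE.NAMES = FALSE)
  ord <- order(gc, reads$id)
  reads <- reads[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(reads)),
               ceiling(seq_len(nrow(reads)) / bin_size))
  lapply(unname(idx), function(i) reads[i, , drop = FALSE])
}

#' Greedy longest-first sequence clustering
#'
#' A deliberately simple reimplementation of the greedy incremental
#' clustering idea behind CD-HIT: sequences are sorted longest-first (ties
#' by id) and each joins the first earlier representative to which its
#' global-alignment identity (matches / alignment length, gaps included)
#' meets the threshold, else founds a new cluster. A shared-word prescreen
#' (distinct 4-mers) skips hopeless alignments; it is conservative at the
#' default thresholds (>= 0.9) and can be disabled.
#'
#' @param seqs Sequence records (protein or nucleotide).
#' @param identity_threshold Global identity in `(0, 1]`.
#' @param type `"protein"` or `"nucleotide"` (alignment scoring).
#' @param prescreen Use the shared 4-mer filter.
#' @return Data.frame `id`, `representative`, `identity` (1 for the
#'   representative itself); representatives are the longest members of
#'   their clusters.
#' @export
greedy_cluster <- function(seqs, identity_threshold,
                           type = c("protein", "nucleotide"),
                           prescreen = TRUE) {
  type <- match.arg(type)
  .assert(identity_threshold > 0 && identity_threshold <= 1,
          "identity_threshold must be in (0, 1]")
  n <- nrow(seqs)
  if (n == 0L) {
    return(data.frame(id = character(), representative = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  words <- lapply(seqs$seq, function(s) {
    if (nchar(s) < 4L) return(s)
    unique(substring(s, 1:(nchar(s) - 3L), 4:nchar(s)))
  })
  submat <- if (type == "protein") "BLOSUM62" else NULL
  reps <- integer(0)
  assigned_rep <- character(n)
  assigned_pid <- numeric(n)
  # prescreen bound: a fraction d of substituted positions destroys at most
  # 4d of distinct 4-mers; 6x margin keeps the filter conservative
  word_floor <- max(0, 1 - 6 * (1 - identity_threshold))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (r in reps) {
      if (nchar(seqs$seq[i]) < identity_threshold * nchar(seqs$seq[r])) next
      if (prescreen && word_floor > 0) {
        shared <- mean(words[[i]] %in% words[[r]])
        if (shared < word_floor) next
      }
      pid <- .global_identity(seqs$seq[i], seqs$seq[r], submat)
      if (pid >= identity_threshold) {
        assigned_rep[i] <- seqs$id[r]
        assigned_pid[i] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assigned_rep[i] <- seqs$id[i]
      assigned_pid[i] <- 1
    }
  }
  data.frame(id = seqs$id, representative = assigned_rep,
             identity = assigned_pid, stringsAsFactors = FALSE)
}

.global_identity <- function(a, b, submat) {
  if (a == b) return(1)
  if (is.null(submat)) {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1)
    a <- Biostrings::DNAString(a); b <- Biostrings::DNAString(b)
  } else {
    a <- Biostrings::AAString(gsub("\\*", "X", a))
    b <- Biostrings::AAString(gsub("\\*", "X", b))
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = submat)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}
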