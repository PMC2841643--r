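# File formats: FASTA, 12-column BLAST tabular, and the pathway-DB TSV
# dialect. Sequence records travel as plain data.frames (id, description,
# seq); alignment hits as data.frames with the canonical outfmt-6 columns;
# the pathway database as a small S3 object.

.BLAST_COLS <- c(
  "query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore"
)

#' Construct a set of sequence records
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of sequences (upper-cased on construction).
#' @param description Optional free-text descriptions.
#' @param mode `"nucleotide"` (alphabet `A,C,G,T,N`) or `"protein"`
#'   (amino-acid letters, `X` and `*`).
#' @return A data.frame with columns `id`, `description`, `seq`.
#' @export
sequence_records <- function(id, seq, description = "",
                             mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  rec <- data.frame(id = unname(as.character(id)),
                    description = unname(description),
                    seq = unname(seq), stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  validate_records(rec, mode)
  rec
}

#' Validate sequence records against an alphabet
#'
#' @param records Data.frame with `id` and `seq` columns.
#' @param mode `"nucleotide"` or `"protein"`.
#' @return The records, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  .assert(all(nzchar(records$id)), "sequence record with empty id")
  .assert(anyDuplicated(records$id) == 0, "duplicate sequence id: %s",
          records$id[duplicated(records$id)][1])
  empty <- !nzchar(records$seq)
  .assert(!any(empty), "empty sequence for record '%s'",
          records$id[empty][1])
  pat <- if (mode == "nucleotide") "^[ACGTN]+$" else "^[A-Z*]+$"
  bad <- !grepl(pat, records$seq)
  .assert(!any(bad), "illegal %s character in record '%s'", mode,
          records$id[bad][1])
  invisible(records)
}

#' Read a FASTA file
#'
#' Headers are split at the first whitespace into `id` and `description`;
#' sequence lines are concatenated and upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param mode Declared alphabet, `"nucleotide"` or `"protein"`.
#' @return A data.frame of sequence records (`id`, `description`, `seq`).
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  .assert(file.exists(path), "no such file: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  sequence_records(id, as.character(set), desc, mode)
}

#' Write sequence records as FASTA
#'
#' Round-trips with [read_fasta()] on `(id, seq)`.
#'
#' @param records Data.frame of sequence records.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  .assert(wrap >= 1, "wrap must be >= 1")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i])) {
      hdr <- paste(hdr, records$description[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a 12-column BLAST tabular hit file ("outfmt 6" dialect)
#'
#' Comment lines starting with `#` are skipped. Subject coordinates keep the
#' native 1-based inclusive convention; `s_start > s_end` marks a minus-strand
#' hit.
#'
#' @param path Path to the tab-separated hit table.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_blast_tabular <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(empty_hits())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  .assert(length(bad) == 0L,
          "line %d: expected 12 tab-separated fields, found %d",
          keep[bad[1]], nf[bad[1]])
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  num_bad <- which(!stats::complete.cases(hits[, 3:12]))
  .assert(length(num_bad) == 0L, "line %d: unparseable numeric field",
          keep[num_bad[1]])
  validate_hits(hits)
  hits
}

#' An empty alignment-hit table with the canonical columns
#' @return A zero-row hit data.frame.
#' @export
empty_hits <- function() {
  df <- data.frame(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_len = integer(), mismatches = integer(),
    gap_opens = integer(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), evalue = numeric(),
    bitscore = numeric(), stringsAsFactors = FALSE
  )
  df
}

#' Validate an alignment-hit table
#' @param hits Hit data.frame as from [read_blast_tabular()].
#' @return The hits, invisibly, if valid.
#' @export
validate_hits <- function(hits) {
  .assert(all(.BLAST_COLS %in% names(hits)), "missing hit column(s): %s",
          paste(setdiff(.BLAST_COLS, names(hits)), collapse = ", "))
  if (nrow(hits)) {
    .assert(all(hits$q_start <= hits$q_end), "hit with q_start > q_end")
    .assert(all(hits$pct_identity >= 0 & hits$pct_identity <= 100),
            "pct_identity outside [0,100]")
    .assert(all(hits$evalue >= 0), "negative evalue")
    .assert(all(hits$aln_len >= 1), "alignment length < 1")
  }
  invisible(hits)
}

#' Write an alignment-hit table in 12-column BLAST tabular format
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  validate_hits(hits)
  out <- hits[, .BLAST_COLS]
  out$pct_identity <- formatC(out$pct_identity, format = "f", digits = 2)
  out$evalue <- formatC(out$evalue, format = "g", digits = 3)
  out$bitscore <- formatC(out$bitscore, format = "f", digits = 1)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a pathway database
#'
#' A pathway database maps pathways to ordered sets of reactions, and
#' reactions to the reference protein sequences and EC numbers through which
#' sequence hits are associated with them. A reaction whose EC number is
#' incomplete (e.g. `1.1.-.-`) is flagged `partial`; hits associated only
#' through partial EC numbers are down-weighted by the hit filter.
#'
#' @param pathways Named list: pathway_id -> character vector of reaction ids.
#' @param reaction_ec Data.frame with columns `reaction_id`, `ec`, `partial`.
#' @param reaction_proteins Named list: reaction_id -> character vector of
#'   protein ids.
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(pathways, reaction_ec, reaction_proteins) {
  .assert(length(pathways) > 0 || nrow(reaction_ec) >= 0, "invalid pathways")
  .assert(anyDuplicated(names(pathways)) == 0, "duplicate pathway_id: %s",
          names(pathways)[duplicated(names(pathways))][1])
  sizes <- lengths(pathways)
  .assert(all(sizes > 0), "pathway '%s' has zero reactions",
          names(pathways)[sizes == 0][1])
  declared <- union(reaction_ec$reaction_id, names(reaction_proteins))
  referenced <- unique(unlist(pathways, use.names = FALSE))
  missing <- setdiff(referenced, declared)
  .assert(length(missing) == 0,
          "pathway references undeclared reaction: %s", missing[1])
  db <- structure(
    list(pathways = pathways,
         reaction_ec = reaction_ec,
         reaction_proteins = reaction_proteins),
    class = "pathway_db"
  )
  db
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d reactions, %d proteins\n",
              length(x$pathways), nrow(x$reaction_ec),
              length(unique(unlist(x$reaction_proteins)))))
  invisible(x)
}

#' Read a pathway database from the project TSV dialect
#'
#' Two record types, one per line:
#' \preformatted{
#' PATHWAY <tab> pathway_id <tab> rxn1,rxn2,...
#' REACTION <tab> reaction_id <tab> EC <tab> full|partial <tab> prot1,prot2,...
#' }
#' An EC number containing `-` is required to be flagged `partial`.
#'
#' @param path Path to the TSV file.
#' @return A [pathway_db()] object.
#' @export
read_pathway_db <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  pathways <- list()
  rx_id <- character(); rx_ec <- character(); rx_partial <- logical()
  proteins <- list()
  for (ln in keep) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (f[1] == "PATHWAY") {
      .assert(length(f) == 3, "line %d: PATHWAY record needs 3 fields", ln)
      .assert(is.null(pathways[[f[2]]]), "line %d: duplicate pathway_id %s",
              ln, f[2])
      rxns <- strsplit(f[3], ",", fixed = TRUE)[[1]]
      .assert(length(rxns) > 0 && all(nzchar(rxns)),
              "line %d: pathway '%s' has zero reactions", ln, f[2])
      pathways[[f[2]]] <- rxns
    } else if (f[1] == "REACTION") {
      .assert(length(f) %in% c(4L, 5L),
              "line %d: REACTION record needs 4 or 5 fields", ln)
      .assert(f[4] %in% c("full", "partial"),
              "line %d: EC flag must be 'full' or 'partial'", ln)
      rx_id <- c(rx_id, f[2]); rx_ec <- c(rx_ec, f[3])
      # an EC with unresolved fields (e.g. 1.1.-.-) is partial by definition
      rx_partial <- c(rx_partial, f[4] == "partial" || grepl("-", f[3], fixed = TRUE))
      prots <- if (length(f) == 5L && nzchar(f[5])) {
        strsplit(f[5], ",", fixed = TRUE)[[1]]
      } else character()
      proteins[[f[2]]] <- prots
    } else {
      stop(sprintf("line %d: unknown record type '%s'", ln, f[1]),
           call. = FALSE)
    }
  }
  reaction_ec <- data.frame(reaction_id = rx_id, ec = rx_ec,
                            partial = rx_partial, stringsAsFactors = FALSE)
  pathway_db(pathways, reaction_ec, proteins)
}

#' Write a pathway database in the project TSV dialect
#' @param db A [pathway_db()] object.
#' @param path Output path.
#' @export
write_pathway_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in names(db$pathways)) {
    writeLines(paste("PATHWAY", p,
                     paste(db$pathways[[p]], collapse = ","), sep = "\t"), con)
  }
  for (i in seq_len(nrow(db$reaction_ec))) {
    r <- db$reaction_ec$reaction_id[i]
    prots <- db$reaction_proteins[[r]]
    writeLines(paste("REACTION", r, db$reaction_ec$ec[i],
                     if (db$reaction_ec$partial[i]) "partial" else "full",
                     paste(prots, collapse = ","), sep = "\t"), con)
  }
  invisible(path)
}
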