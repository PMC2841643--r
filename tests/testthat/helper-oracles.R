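# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings, where the implementation uses it) so that
# agreement is a genuine cross-check.

# --- translation / ORF oracle ------------------------------------------

.CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(64); i <- 0
  aa <- unlist(strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), ""))
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1; codons[i] <- paste0(b1, b2, b3)
  }
  setNames(aa, codons)
})

oracle_translate <- function(dna) {
  n <- (nchar(dna) %/% 3) * 3
  if (n == 0) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

oracle_rc <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all six-frame stop-free stretches >= min_aa, as (frame, protein,
# partial5, partial3); coordinates not reproduced (checked separately)
oracle_six_frame <- function(seq, min_aa) {
  out <- list()
  for (dir in c(1, -1)) {
    s <- if (dir == 1) seq else oracle_rc(seq)
    for (off in 0:2) {
      frame_dna <- substr(s, off + 1, nchar(s))
      prot <- oracle_translate(frame_dna)
      if (!nzchar(prot)) next
      pieces <- strsplit(prot, "*", fixed = TRUE)[[1]]
      # trailing stops yield implicit empty last piece
      n_pieces <- length(pieces)
      ends_with_stop <- grepl("\\*$", prot)
      aa_pos <- 1
      for (j in seq_len(n_pieces)) {
        pep <- pieces[j]
        start_codon <- substr(frame_dna, (aa_pos - 1) * 3 + 1,
                              (aa_pos - 1) * 3 + 3)
        aa_pos <- aa_pos + nchar(pep) + 1  # skip the delimiting stop
        if (nchar(pep) < min_aa) next
        out[[length(out) + 1]] <- data.frame(
          frame = dir * (off + 1), protein = pep,
          partial5 = j == 1 &&
            !(start_codon %in% c("ATG", "GTG", "TTG")),
          partial3 = j == n_pieces && !ends_with_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(frame = integer(),
                                      protein = character(),
                                      partial5 = logical(),
                                      partial3 = logical()))
  do.call(rbind, out)
}

# --- pathway oracles ----------------------------------------------------

oracle_specificity <- function(db) {
  rxns <- unique(unlist(db$pathways))
  res <- data.frame(reaction_id = rxns, n_pw = NA, n_totrxn = NA,
                    n_unirxn = NA, weight = NA, stringsAsFactors = FALSE)
  for (i in seq_along(rxns)) {
    r <- rxns[i]
    holding <- Filter(function(p) r %in% p, db$pathways)
    n_pw <- length(holding)
    n_tot <- sum(vapply(holding, length, 1L))
    n_uni <- length(unique(unlist(holding)))
    res$n_pw[i] <- n_pw; res$n_totrxn[i] <- n_tot; res$n_unirxn[i] <- n_uni
    res$weight[i] <- (n_tot / n_uni) / n_pw
  }
  res
}

oracle_completeness <- function(rxns, present, weights_df) {
  num <- 0; den <- 0
  for (r in rxns) {
    w <- weights_df$weight[weights_df$reaction_id == r]
    den <- den + w
    if (r %in% present) num <- num + w
  }
  num / den
}

oracle_activity <- function(rxns, count_vec) {
  x <- numeric(length(rxns))
  for (i in seq_along(rxns)) {
    x[i] <- if (rxns[i] %in% names(count_vec)) count_vec[[rxns[i]]] else 0
  }
  sx <- sort(x); n <- length(sx)
  if (n %% 2 == 1) sx[(n + 1) / 2] else (sx[n / 2] + sx[n / 2 + 1]) / 2
}

# exhaustive filter oracle: loops over every hit and applies the written
# rules literally
oracle_filter <- function(protein_id, bitscore, partial_only, bit_floor,
                          window) {
  any_full_above <- FALSE
  for (i in seq_along(bitscore)) {
    if (!partial_only[i] && bitscore[i] > bit_floor) any_full_above <- TRUE
  }
  eligible <- logical(length(bitscore))
  for (i in seq_along(bitscore)) {
    eligible[i] <- bitscore[i] > bit_floor &&
      (!partial_only[i] || !any_full_above)
  }
  if (!any(eligible)) return(character(0))
  top <- max(bitscore[eligible])
  keep <- eligible & bitscore >= (1 - window) * top
  protein_id[keep]
}

# --- shared tiny fixtures ----------------------------------------------

tiny_db <- function() {
  pathway_db(
    pathways = list(P1 = c("R1", "R2", "R3", "R4", "R5"),
                    P2 = c("R5", "R6", "R7", "R8", "R9")),
    reaction_ec = data.frame(
      reaction_id = paste0("R", 1:9),
      ec = c(sprintf("1.1.1.%d", 1:8), "1.2.-.-"),
      partial = c(rep(FALSE, 8), TRUE), stringsAsFactors = FALSE),
    reaction_proteins = setNames(
      lapply(paste0("R", 1:9), function(r) paste0(r, c("_a", "_b"))),
      paste0("R", 1:9))
  )
}

random_db <- function(seed, n_pathways = 8, n_rxn_pool = 25) {
  set.seed(seed)
  pool <- sprintf("R%02d", seq_len(n_rxn_pool))
  pathways <- list()
  for (i in seq_len(n_pathways)) {
    pathways[[sprintf("P%02d", i)]] <- sample(pool, sample(2:8, 1))
  }
  used <- unique(unlist(pathways))
  pathway_db(
    pathways,
    reaction_ec = data.frame(reaction_id = used, ec = "1.1.1.1",
                             partial = FALSE, stringsAsFactors = FALSE),
    reaction_proteins = setNames(lapply(used, function(r) paste0(r, "_p")),
                                 used)
  )
}
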