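# Synthetic community generator: genome composition models, divergence
# mutation, paired Sanger-style read shedding, and contig sampling. All
# generators are deterministic under a fixed seed; the mutation model is
# substitution-only so pairwise identity against the parent equals 1 - d in
# expectation, which keeps the identity-band oracles analytic.

.BASES <- c("A", "C", "G", "T")

#' Describe a genome composition model
#'
#' A genome is drawn either from independent sites at a GC setpoint
#' (`P(G)=P(C)=gc/2`) or from an order-`k` Markov chain over `{A,C,G,T}`
#' whose transition matrix has one row per `k`-mer context.
#'
#' @param genome_id Genome identifier.
#' @param length Genome length in bases (must be at least 10 read lengths
#'   for read shedding to make sense).
#' @param gc GC setpoint in `(0,1)`; ignored when `markov` is given.
#' @param markov Optional transition matrix, `4^order` rows (contexts in
#'   lexicographic order) by 4 columns (A,C,G,T), rows summing to 1.
#' @param order Markov order `k` (default 3); used only with `markov`.
#' @param pathway_content Character vector of reaction ids truly encoded by
#'   this genome (ground truth for pathway scoring).
#' @param taxon_label Free-text taxon label.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(genome_id, length, gc = 0.5, markov = NULL,
                         order = 3L, pathway_content = character(),
                         taxon_label = genome_id) {
  .assert(length >= 1, "genome length must be positive")
  if (is.null(markov)) {
    .assert(gc > 0 && gc < 1, "gc setpoint must be in (0,1)")
  } else {
    .assert(nrow(markov) == 4^order && ncol(markov) == 4,
            "markov matrix must be 4^order x 4")
    rs <- rowSums(markov)
    .assert(all(abs(rs - 1) < 1e-9), "markov transition rows must sum to 1")
    .assert(all(markov >= 0), "negative transition probability")
  }
  structure(
    list(genome_id = genome_id, length = as.integer(length), gc = gc,
         markov = markov, order = as.integer(order),
         pathway_content = pathway_content, taxon_label = taxon_label),
    class = "genome_model"
  )
}

#' Simulate a genome sequence from a composition model
#'
#' @param model A [genome_model()].
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return A one-row sequence-record data.frame.
#' @export
simulate_genome <- function(model, seed) {
  stopifnot(inherits(model, "genome_model"))
  set.seed(seed)
  n <- model$length
  if (is.null(model$markov)) {
    p <- c((1 - model$gc) / 2, model$gc / 2, model$gc / 2, (1 - model$gc) / 2)
    seq <- paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
  } else {
    k <- model$order
    tm <- model$markov
    .assert(all(rowSums(tm) > 0), "degenerate transition matrix row")
    # integer state = k-mer context index; emit one base per step; the
    # first k bases are drawn from the chain's marginal emission profile
    out <- integer(n)
    marg <- colSums(tm) / sum(tm)
    out[seq_len(k)] <- sample.int(4L, k, replace = TRUE, prob = marg)
    ctx <- sum((out[seq_len(k)] - 1L) * 4L^((k - 1L):0L)) + 1L
    if (n > k) {
      u <- runif(n - k)
      cum <- t(apply(tm, 1, cumsum))
      for (i in (k + 1L):n) {
        b <- findInterval(u[i - k], cum[ctx, ], left.open = TRUE) + 1L
        out[i] <- b
        ctx <- (ctx - 1L) %% 4L^(k - 1L) * 4L + b
      }
    }
    seq <- paste(.BASES[out], collapse = "")
  }
  sequence_records(model$genome_id, seq,
                   description = model$taxon_label, mode = "nucleotide")
}

#' Mutate a genome at a fixed per-site substitution rate
#'
#' Each site is independently substituted with probability `divergence` to a
#' uniformly chosen *different* base; length is preserved (no indels), so
#' expected global identity to the parent is exactly `1 - divergence`.
#'
#' @param genome One-row sequence-record data.frame.
#' @param divergence Substitutions per site, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param id Identifier for the mutated copy.
#' @return A one-row sequence-record data.frame.
#' @export
mutate_genome <- function(genome, divergence, seed,
                          id = paste0(genome$id[1], "_d", divergence)) {
  .assert(divergence >= 0 && divergence <= 0.5,
          "divergence must be in [0, 0.5]")
  set.seed(seed)
  chars <- strsplit(genome$seq[1], "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    # pick one of the 3 other bases uniformly
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(.BASES, NULL))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- alt[cbind(match(chars[hit], .BASES), pick)]
  }
  sequence_records(id, paste(chars, collapse = ""),
                   description = genome$description[1], mode = "nucleotide")
}

#' Shed paired shotgun reads from a genome
#'
#' Emulates paired-end Sanger-style sequencing: clone inserts are placed
#' uniformly on the genome and the two mates are read inward from opposite
#' ends of the insert, on opposite strands. Per-base substitution errors are
#' applied at `error_rate`. A ground-truth record is emitted for every read.
#'
#' @param genome One-row sequence-record data.frame.
#' @param n_pairs Number of mate pairs.
#' @param read_len_mean,read_len_sd Read length distribution (bp); default
#'   800 bp trimmed-read average.
#' @param insert_mean Mean clone insert length; must be at least twice
#'   `read_len_mean`.
#' @param insert_sd Insert length standard deviation.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return A list with `reads` (sequence records) and `truth` (data.frame
#'   `read_id`, `source_genome`, `start`, `end` in 0-based half-open
#'   coordinates, `strand`, `mate_id`).
#' @export
shed_reads <- function(genome, n_pairs, read_len_mean = 800,
                       read_len_sd = 0, insert_mean = 2 * read_len_mean,
                       insert_sd = 0, error_rate = 0.005, seed = 1L,
                       prefix = paste0(genome$id[1], "_r")) {
  glen <- nchar(genome$seq[1])
  .assert(insert_mean >= 2 * read_len_mean,
          "insert_mean must be >= 2 * read_len_mean")
  .assert(glen > insert_mean, "genome shorter than insert")
  set.seed(seed)
  ins_len <- pmax(2 * read_len_mean,
                  round(rnorm(n_pairs, insert_mean, insert_sd)))
  ins_len <- pmin(ins_len, glen)
  ins_start <- floor(runif(n_pairs, 0, glen - ins_len + 1))  # 0-based
  rl <- function() pmax(30L, pmin(as.integer(round(
    rnorm(n_pairs, read_len_mean, read_len_sd))), as.integer(ins_len)))
  len_f <- rl(); len_r <- rl()

  gseq <- genome$seq[1]
  ids_f <- sprintf("%s%04d/1", prefix, seq_len(n_pairs))
  ids_r <- sprintf("%s%04d/2", prefix, seq_len(n_pairs))
  # forward mate reads the left insert edge on +; reverse mate the right on -
  st_f <- ins_start
  en_f <- ins_start + len_f
  en_r <- ins_start + ins_len
  st_r <- en_r - len_r
  sub_f <- substring(gseq, st_f + 1L, en_f)
  sub_r_fwd <- substring(gseq, st_r + 1L, en_r)
  sub_r <- vapply(sub_r_fwd, reverse_complement, character(1),
                  USE.NAMES = FALSE)
  seqs <- c(rbind(sub_f, sub_r))
  if (error_rate > 0) seqs <- .apply_read_errors(seqs, error_rate)
  ids <- c(rbind(ids_f, ids_r))
  reads <- sequence_records(ids, seqs, mode = "nucleotide")
  truth <- data.frame(
    read_id = ids,
    source_genome = genome$id[1],
    start = c(rbind(st_f, st_r)),
    end = c(rbind(en_f, en_r)),
    strand = c(rbind(rep("+", n_pairs), rep("-", n_pairs))),
    mate_id = c(rbind(ids_r, ids_f)),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}

.apply_read_errors <- function(seqs, error_rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < error_rate)
    if (length(hit)) {
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 4, byrow = TRUE, dimnames = list(.BASES, NULL))
      pick <- sample.int(3L, length(hit), replace = TRUE)
      idx <- match(ch[hit], .BASES)
      ok <- !is.na(idx)
      ch[hit[ok]] <- alt[cbind(idx[ok], pick[ok])]
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Sample assembly-like contigs from a genome
#'
#' Draws contig intervals uniformly from the genome; a convenience for
#' exercising the composition (word-frequency) module, which consumes
#' assembled contigs rather than reads.
#'
#' @param genome One-row sequence-record data.frame.
#' @param n Number of contigs.
#' @param length_mean,length_sd Contig length distribution (bp).
#' @param seed Integer seed.
#' @param prefix Contig id prefix.
#' @return A list with `contigs` (sequence records) and `truth` (data.frame
#'   `contig_id`, `source_genome`).
#' @export
simulate_contigs <- function(genome, n, length_mean = 3000, length_sd = 600,
                             seed = 1L, prefix = paste0(genome$id[1], "_c")) {
  glen <- nchar(genome$seq[1])
  set.seed(seed)
  len <- pmin(pmax(200L, as.integer(round(rnorm(n, length_mean, length_sd)))),
              glen)
  start <- floor(runif(n, 0, glen - len + 1))
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  contigs <- sequence_records(ids, substring(genome$seq[1], start + 1L,
                                             start + len),
                              mode = "nucleotide")
  list(contigs = contigs,
       truth = data.frame(contig_id = ids, source_genome = genome$id[1],
                          stringsAsFactors = FALSE))
}
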