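test_that("six-frame extraction is stop-bounded with run-on at edges", {
  r <- sequence_records("r1", "ATGAAATAA")
  o <- six_frame_orfs(r, min_aa = 2)
  f1 <- o[o$frame == 1, ]
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$protein, "MK")
  expect_false(f1$partial5); expect_false(f1$partial3)
  expect_equal(c(f1$nt_start, f1$nt_end), c(0L, 6L))  # stop excluded

  allA <- sequence_records("r2", strrep("A", 90))
  o2 <- six_frame_orfs(allA, min_aa = 10)
  plus1 <- o2[o2$frame == 1, ]
  expect_true(plus1$partial5 && plus1$partial3)
  expect_equal(plus1$protein, strrep("K", 30))

  expect_false(any(grepl("*", o2$protein, fixed = TRUE)))
  expect_true(all((o2$nt_end - o2$nt_start) %% 3 == 0))
  expect_true(all(nchar(o2$protein) == (o2$nt_end - o2$nt_start) / 3))
  expect_error(six_frame_orfs(sequence_records("x", "ACGTACGTA"),
                              min_aa = 30), "shorter")
})

test_that("six-frame candidates match the split-on-stop oracle", {
  set.seed(81)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
    r <- sequence_records(paste0("r", i), seq)
    got <- six_frame_orfs(r, min_aa = 25)
    want <- oracle_six_frame(seq, min_aa = 25)
    key <- function(d) sort(paste(d$frame, d$protein, d$partial5,
                                  d$partial3))
    expect_identical(key(got), key(want))
    # interval consistency: translating the interval reproduces the protein
    for (j in seq_len(nrow(got))) {
      sub <- substr(seq, got$nt_start[j] + 1, got$nt_end[j])
      if (got$frame[j] < 0) sub <- oracle_rc(sub)
      expect_identical(oracle_translate(sub), got$protein[j])
    }
  }
})

test_that("reverse frames equal forward frames of the reverse complement", {
  set.seed(82)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  r <- sequence_records("r", seq)
  rrc <- sequence_records("r", reverse_complement(seq))
  o <- six_frame_orfs(r, min_aa = 20)
  orc <- six_frame_orfs(rrc, min_aa = 20)
  fwd_of_rc <- sort(orc$protein[orc$frame > 0])
  rev_of_orig <- sort(o$protein[o$frame < 0])
  expect_identical(rev_of_orig, fwd_of_rc)
  # coordinates map through n - x
  n <- nchar(seq)
  a <- o[o$frame < 0, ]
  b <- orc[orc$frame > 0, ]
  expect_setequal(paste(a$protein, a$nt_start, a$nt_end),
                  paste(b$protein, n - b$nt_end, n - b$nt_start))
})

test_that("start-codon mode trims candidates to the first start", {
  # +1 frame: LLMK with stop at both ends
  r <- sequence_records("r", paste0("TAG", "CTTCTGATGAAA", "TAA"))
  o <- six_frame_orfs(r, min_aa = 2, require_start = TRUE)
  f1 <- o[o$frame == 1, ]
  expect_equal(f1$protein, "MK")
  o2 <- six_frame_orfs(r, min_aa = 2, require_start = FALSE)
  expect_true("LLMK" %in% o2$protein)
})

test_that("GC binning sorts then chunks", {
  set.seed(83)
  seqs <- vapply(1:25, function(i) {
    gc <- runif(1, 0.2, 0.8)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  reads <- sequence_records(sprintf("r%02d", 1:25), seqs)
  bins <- gc_bin_reads(reads, bin_size = 10)
  expect_equal(vapply(bins, nrow, 1L), c(10L, 10L, 5L))
  gc_of <- function(b) vapply(b$seq, function(s)
    lengths(regmatches(s, gregexpr("[GC]", s))) / nchar(s), numeric(1))
  for (k in 1:2) expect_lte(max(gc_of(bins[[k]])), min(gc_of(bins[[k + 1]])))
  expect_equal(vapply(gc_bin_reads(reads[1, ], 10), nrow, 1L), 1L)
  expect_equal(gc_bin_reads(reads[0, ], 10), list())
})

test_that("greedy clustering partitions input at the identity threshold", {
  seqs <- sequence_records(
    c("s1", "s2", "s3", "s4"),
    c("MKLVVDEERTAAGHKLVVDEERTAAGH",  # s1 == s2
      "MKLVVDEERTAAGHKLVVDEERTAAGH",
      "MKLVVDEERTAAGHKLVVDEERTAAGQ",  # 1 mismatch to s1 (96.3%)
      "WWWWWWWWWWYYYYYYYYYYGGGGGGG"),  # unrelated
    mode = "protein")
  cl97 <- greedy_cluster(seqs, 0.97, type = "protein")
  expect_equal(sort(unique(cl97$representative[cl97$id %in%
                                                 c("s1", "s2")])), "s1")
  expect_equal(cl97$representative[cl97$id == "s3"], "s3")
  cl90 <- greedy_cluster(seqs, 0.90, type = "protein")
  expect_equal(cl90$representative[cl90$id == "s3"], "s1")
  expect_equal(cl90$representative[cl90$id == "s4"], "s4")
  # partition: every input appears exactly once
  expect_setequal(cl97$id, seqs$id)
  # members meet the threshold to their representative
  expect_true(all(cl90$identity >= 0.90))
  # representative is the longest member (ties by id)
  long <- sequence_records(c("a", "b"), c("MKLVVDEERT", "MKLVVDEERTA"),
                           mode = "protein")
  cl <- greedy_cluster(long, 0.9, type = "protein")
  expect_equal(unique(cl$representative), "b")
  expect_equal(nrow(greedy_cluster(seqs[0, ], 0.9)), 0L)
  expect_error(greedy_cluster(seqs, 1.5), "identity_threshold")
})

test_that("nucleotide clustering dereplicates mutated copies", {
  g <- simulate_genome(genome_model("g", 2000, gc = 0.5), seed = 84)
  near <- mutate_genome(g, 0.02, seed = 85, id = "g_near")
  far <- mutate_genome(g, 0.40, seed = 86, id = "g_far")
  seqs <- rbind(g, near, far)
  cl <- greedy_cluster(seqs, 0.95, type = "nucleotide")
  expect_equal(cl$representative[cl$id == "g_near"],
               cl$representative[cl$id == "g"])
  expect_equal(cl$representative[cl$id == "g_far"], "g_far")
})
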