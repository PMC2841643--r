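mk_hit <- function(q, env, e, qlen_spanned, sample = "S01") {
  data.frame(query_id = q, subject_id = env, pct_identity = 80,
             aln_len = qlen_spanned, mismatches = 10L, gap_opens = 0L,
             q_start = 1L, q_end = qlen_spanned, s_start = 1L,
             s_end = 3L * qlen_spanned, evalue = e,
             bitscore = qlen_spanned * 2, sample = sample,
             stringsAsFactors = FALSE)
}

test_that("marker screening gates on E-value and dedups per env sequence", {
  reg <- default_marker_registry()
  hits <- rbind(mk_hit("Q_sqr", "env1", 1e-50, 344),
                mk_hit("Q_sqr", "env1", 1e-30, 200),
                mk_hit("Q_dsrA", "env2", 1e-8, 300))
  cand <- screen_markers(hits, reg)
  expect_equal(nrow(cand), 1L)  # env2 fails the 1e-10 gate; env1 deduped
  expect_equal(cand$env_id, "env1")
  expect_equal(cand$evalue, 1e-50)
  expect_equal(cand$coverage, 344 / 430)
  expect_error(screen_markers(mk_hit("Q_zzz", "e", 1e-50, 100), reg),
               "absent from marker registry")
})

test_that("validation applies the rejection rules in order", {
  reg <- default_marker_registry()
  cand <- rbind(
    data.frame(env_id = "e_self", gene_symbol = "sqr", sample = "S01",
               evalue = 1e-50, bitscore = 600, coverage = 0.8,
               stringsAsFactors = FALSE),
    data.frame(env_id = "e_family", gene_symbol = "doxB", sample = "S01",
               evalue = 1e-40, bitscore = 500, coverage = 0.8,
               stringsAsFactors = FALSE),
    data.frame(env_id = "e_function", gene_symbol = "sreA", sample = "S01",
               evalue = 1e-40, bitscore = 500, coverage = 0.8,
               stringsAsFactors = FALSE),
    data.frame(env_id = "e_blacklist", gene_symbol = "arsB", sample = "S01",
               evalue = 1e-40, bitscore = 500, coverage = 0.8,
               stringsAsFactors = FALSE),
    data.frame(env_id = "e_short", gene_symbol = "sqr", sample = "S01",
               evalue = 1e-40, bitscore = 500, coverage = 0.1,
               stringsAsFactors = FALSE),
    data.frame(env_id = "e_missing", gene_symbol = "sqr", sample = "S01",
               evalue = 1e-40, bitscore = 500, coverage = 0.8,
               stringsAsFactors = FALSE))
  reverse <- data.frame(
    env_id = c("e_self", "e_family", "e_function", "e_blacklist",
               "e_short"),
    label = c("sqr", "coxA", "Mo-pterin oxidoreductase (generic)",
              "misannot", "sqr"),
    process = c("sulfide oxidation", "oxygen reduction",
                "formate oxidation", "arsenite efflux",
                "sulfide oxidation"),
    stringsAsFactors = FALSE)
  expect_message(
    calls <- validate_markers(cand, reverse, reg, min_coverage = 0.3,
                              blacklist = "misannot",
                              label_families = c(coxA = "heme Cu oxidase")),
    "undetermined")
  got <- setNames(paste(calls$status, calls$reject_rule), calls$env_id)
  expect_equal(got[["e_self"]], "confirmed none")
  expect_equal(got[["e_family"]], "rejected i")
  expect_equal(got[["e_function"]], "rejected ii")
  expect_equal(got[["e_blacklist"]], "rejected iii")
  expect_equal(got[["e_short"]], "rejected coverage")
  expect_equal(got[["e_missing"]], "undetermined none")
  # confirmed calls always satisfy the confirmation contract
  conf <- calls[calls$status == "confirmed", ]
  expect_true(all(conf$evalue < 1e-10 & conf$coverage >= 0.3 &
                    conf$reject_rule == "none"))
})

test_that("count table counts distinct confirmed sequences per process", {
  reg <- default_marker_registry()
  study <- simulate_marker_study(reg, samples = c("S01", "S02"),
                                 plant_symbols = "doxB",
                                 plants_per_sample = 3L, seed = 9)
  cand <- screen_markers(study$hits, reg)
  calls <- validate_markers(cand, study$reverse, reg,
                            blacklist = study$blacklist,
                            label_families = study$label_families)
  tab <- marker_count_table(calls, reg)
  expect_equal(unname(tab["oxygen reduction", ]), c(3L, 3L))
  expect_true(all(tab[rownames(tab) != "oxygen reduction", ] == 0L))
  # empty calls give an all-zero table with the full frame
  empty <- calls[0, , drop = FALSE]
  tab0 <- marker_count_table(empty, reg, samples = c("S01", "S02"))
  expect_true(all(tab0 == 0L))
  expect_equal(dim(tab0), c(length(unique(reg$process)), 2L))
})

test_that("noise-free plants are recovered exactly and decoys rejected", {
  reg <- default_marker_registry()
  study <- simulate_marker_study(reg, samples = sprintf("S%02d", 1:5),
                                 plant_symbols = c("sqr", "dsrA"),
                                 plants_per_sample = 2L, decoys = TRUE,
                                 seed = 31)
  cand <- screen_markers(study$hits, reg)
  calls <- validate_markers(cand, study$reverse, reg,
                            blacklist = study$blacklist,
                            label_families = study$label_families)
  tab <- marker_count_table(calls, reg,
                            samples = colnames(study$truth),
                            processes = rownames(study$truth))
  expect_equal(tab, study$truth)
  rejected <- calls[grepl("_decoy_", calls$env_id), ]
  expect_true(all(rejected$status == "rejected"))
  expect_setequal(unique(rejected$reject_rule),
                  c("i", "ii", "iii", "coverage"))
})

test_that("tightening thresholds never increases any count cell", {
  reg <- default_marker_registry()
  study <- simulate_marker_study(reg, samples = sprintf("S%02d", 1:3),
                                 plants_per_sample = 3L, decoys = TRUE,
                                 seed = 17)
  count_at <- function(e_thr, min_cov) {
    cand <- screen_markers(study$hits, reg, e_threshold = e_thr)
    calls <- validate_markers(cand, study$reverse, reg,
                              min_coverage = min_cov,
                              blacklist = study$blacklist,
                              label_families = study$label_families)
    marker_count_table(calls, reg, samples = colnames(study$truth),
                       processes = rownames(study$truth))
  }
  base <- count_at(1e-10, 0.3)
  expect_true(all(count_at(1e-40, 0.3) <= base))
  expect_true(all(count_at(1e-10, 0.7) <= base))
  expect_true(all(count_at(1e-60, 0.9) <= count_at(1e-40, 0.5)))
})
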