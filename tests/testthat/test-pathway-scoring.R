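test_that("specificity weights follow the printed counting rules", {
  # reaction in exactly one pathway: w = 1
  db1 <- pathway_db(list(P1 = c("R1", "R2")),
                    data.frame(reaction_id = c("R1", "R2"), ec = "1.1.1.1",
                               partial = FALSE, stringsAsFactors = FALSE),
                    list(R1 = "p1", R2 = "p2"))
  expect_equal(specificity_weight("R1", db1), 1)

  # two identical 5-reaction pathways: no penalty, w = 1
  rxns <- paste0("R", 1:5)
  db2 <- pathway_db(list(P1 = rxns, P2 = rxns),
                    data.frame(reaction_id = rxns, ec = "1.1.1.1",
                               partial = FALSE, stringsAsFactors = FALSE),
                    setNames(as.list(paste0("p", 1:5)), rxns))
  w2 <- specificity_weights(db2)
  expect_equal(w2$n_pw, rep(2L, 5))
  expect_equal(w2$n_totrxn, rep(10L, 5))
  expect_equal(w2$n_unirxn, rep(5L, 5))
  expect_equal(w2$weight, rep(1, 5))

  # shared across two otherwise-disjoint 5-reaction pathways
  db3 <- pathway_db(
    list(P1 = c("S", paste0("A", 1:4)), P2 = c("S", paste0("B", 1:4))),
    data.frame(reaction_id = c("S", paste0("A", 1:4), paste0("B", 1:4)),
               ec = "1.1.1.1", partial = FALSE, stringsAsFactors = FALSE),
    setNames(as.list(paste0("p", 1:9)),
             c("S", paste0("A", 1:4), paste0("B", 1:4))))
  expect_equal(specificity_weight("S", db3), (10 / 9) / 2)
  expect_equal(specificity_weight("A1", db3), 1)
  expect_error(specificity_weight("ZZZ", db3), "no pathway")
})

test_that("weights match a brute-force recount on random databases", {
  for (s in 1:10) {
    db <- random_db(seed = 100 + s)
    got <- specificity_weights(db)
    want <- oracle_specificity(db)
    got <- got[order(got$reaction_id), ]
    want <- want[order(want$reaction_id), ]
    expect_equal(got$n_pw, want$n_pw)
    expect_equal(got$n_totrxn, want$n_totrxn)
    expect_equal(got$n_unirxn, want$n_unirxn)
    expect_equal(got$weight, want$weight)
  }
})

test_that("identical pathway copies carry no specificity penalty", {
  # the no-penalty identity: when every pathway containing a reaction is an
  # identical copy, n_totrxn/n_unirxn = n_pw and w = 1, at any multiplicity
  rxns <- paste0("R", 1:6)
  ec <- data.frame(reaction_id = rxns, ec = "1.1.1.1", partial = FALSE,
                   stringsAsFactors = FALSE)
  prots <- setNames(as.list(paste0("p", 1:6)), rxns)
  for (copies in c(2, 3, 7)) {
    pws <- setNames(rep(list(rxns), copies), paste0("P", seq_len(copies)))
    db <- pathway_db(pws, ec, prots)
    w <- specificity_weights(db)
    expect_equal(w$n_pw, rep(copies, 6))
    expect_equal(w$n_totrxn / w$n_unirxn, w$n_pw)
    expect_equal(w$weight, rep(1, 6), tolerance = 1e-12)
  }
  # duplicating a pathway never touches weights of reactions outside it
  for (s in 1:5) {
    db <- random_db(seed = 200 + s)
    w0 <- specificity_weights(db)
    p <- names(db$pathways)[1 + (s %% length(db$pathways))]
    db2 <- db
    db2$pathways[[paste0(p, "_dup")]] <- db2$pathways[[p]]
    w1 <- specificity_weights(db2)
    outside <- setdiff(w0$reaction_id, db$pathways[[p]])
    expect_equal(setNames(w1$weight, w1$reaction_id)[outside],
                 setNames(w0$weight, w0$reaction_id)[outside],
                 tolerance = 1e-12)
  }
})

test_that("completeness score normalizes weighted presence", {
  db <- tiny_db()  # P1 and P2 share R5
  w <- specificity_weights(db)
  all_on <- setNames(rep(1, 9), paste0("R", 1:9))
  expect_equal(completeness_score("P1", all_on, db), 1)
  expect_equal(completeness_score("P1", all_on * 0, db), 0)
  # 4 unit-weight reactions present, shared low-weight reaction absent
  ind <- setNames(c(1, 1, 1, 1, 0), paste0("R", 1:5))
  w5 <- specificity_weight("R5", db)
  expect_equal(w5, (10 / 9) / 2)
  expect_equal(completeness_score("P1", ind, db), 4 / (4 + w5))
  expect_equal(completeness_score("P1", ind, db), 0.878, tolerance = 1e-3)
  # flipping any indicator up never decreases the score
  for (r in paste0("R", 1:5)) {
    up <- ind; up[r] <- 1
    expect_gte(completeness_score("P1", up, db),
               completeness_score("P1", ind, db))
  }
  expect_error(completeness_score("nope", ind, db), "unknown pathway")
})

test_that("activity score is the median over all pathway reactions", {
  db <- pathway_db(
    list(P3 = c("X1", "X2", "X3"), P4 = c("Y1", "Y2", "Y3", "Y4"),
         P5 = c("Z1", "Z2")),
    data.frame(reaction_id = c(paste0("X", 1:3), paste0("Y", 1:4),
                               paste0("Z", 1:2)),
               ec = "1.1.1.1", partial = FALSE, stringsAsFactors = FALSE),
    setNames(as.list(paste0("p", 1:9)),
             c(paste0("X", 1:3), paste0("Y", 1:4), paste0("Z", 1:2))))
  expect_equal(activity_score("P3", c(X1 = 0, X2 = 2, X3 = 4), db), 2)
  expect_equal(activity_score("P4", c(Y4 = 8), db), 0)  # zeros included
  expect_equal(activity_score("P5", c(Z1 = 1, Z2 = 3), db), 2)
})

test_that("scores agree with brute-force evaluation on random configs", {
  set.seed(300)
  for (rep in 1:8) {
    db <- random_db(seed = 300 + rep)
    w <- specificity_weights(db)
    rxns <- w$reaction_id
    for (k in 1:25) {
      present <- sample(rxns, rbinom(1, length(rxns), 0.4))
      counts <- setNames(rpois(length(rxns), 2), rxns)
      ind <- setNames(as.numeric(rxns %in% present), rxns)
      p <- sample(names(db$pathways), 1)
      expect_equal(completeness_score(p, ind, db),
                   oracle_completeness(db$pathways[[p]], present, w),
                   tolerance = 1e-12)
      expect_equal(activity_score(p, counts, db),
                   oracle_activity(db$pathways[[p]], as.list(counts)),
                   tolerance = 1e-12)
      cj <- completeness_score(p, ind, db)
      expect_gte(cj, 0); expect_lte(cj, 1)
    }
  }
})

test_that("hit filtering applies the bit floor, top window and EC rule", {
  db <- tiny_db()  # R9 is partial-EC; others full
  hit <- function(p, b) data.frame(protein_id = p, bitscore = b,
                                   stringsAsFactors = FALSE)
  # 0.8 x 100 = 80 cutoff and the 50-bit floor
  fl <- filtered_hit_list(rbind(hit("R1_a", 100), hit("R2_a", 85),
                                hit("R3_a", 79), hit("R4_a", 45)), db)
  expect_setequal(fl$protein_id, c("R1_a", "R2_a"))
  # single hit just above the floor survives
  expect_equal(filtered_hit_list(hit("R1_a", 51), db)$protein_id, "R1_a")
  # boundary: exactly 50 fails the strict floor
  expect_equal(nrow(filtered_hit_list(hit("R1_a", 50), db)), 0L)
  # boundary: exactly 0.8 x top is retained
  fl2 <- filtered_hit_list(rbind(hit("R1_a", 100), hit("R2_a", 80)), db)
  expect_setequal(fl2$protein_id, c("R1_a", "R2_a"))
  # partial-EC-only protein suppressed when a full association passes
  fl3 <- filtered_hit_list(rbind(hit("R1_a", 60), hit("R9_a", 90)), db)
  expect_equal(fl3$protein_id, "R1_a")
  # ...but used as fallback when nothing full passes the floor
  fl4 <- filtered_hit_list(rbind(hit("R1_a", 40), hit("R9_a", 90)), db)
  expect_equal(fl4$protein_id, "R9_a")
})

test_that("hit filtering equals the exhaustive oracle on random hit sets", {
  db <- tiny_db()
  prots <- unlist(db$reaction_proteins, use.names = FALSE)
  partial_rxn <- db$reaction_ec$reaction_id[db$reaction_ec$partial]
  set.seed(310)
  for (k in 1:300) {
    n <- sample(1:8, 1)
    p <- sample(prots, n)
    # include exact boundary scores 50 and 0.8 x top with high probability
    b <- sample(c(50, 45, 51, 64, 80, 100, 120), n, replace = TRUE)
    fl <- filtered_hit_list(data.frame(protein_id = p, bitscore = b,
                                       stringsAsFactors = FALSE), db)
    partial_only <- sub("_.*", "", p) %in% partial_rxn
    want <- oracle_filter(p, b, partial_only, 50, 0.20)
    expect_setequal(fl$protein_id, want)
  }
})

test_that("reaction hit counts count unique query translations once", {
  db <- tiny_db()
  hits <- data.frame(
    sample = "S1",
    query_id = c("q1", "q1", "q1", "q2", "q3", "q3"),
    protein_id = c("R1_a", "R1_b", "R2_a", "R1_a", "R1_a", "R2_b"),
    bitscore = c(100, 95, 90, 80, 70, 60), stringsAsFactors = FALSE)
  counts <- reaction_hit_counts(hits, db)
  # q1 touches R1 via two proteins yet adds 1; q2 and q3 add one each
  expect_equal(counts["R1", "S1"], 3L)
  expect_equal(counts["R2", "S1"], 2L)  # q1 and q3 both touch R2
  expect_equal(counts["R3", "S1"], 0L)
  solo <- hits[hits$query_id == "q1" & grepl("^R1", hits$protein_id), ]
  expect_equal(reaction_hit_counts(solo, db)["R1", "S1"], 1L)
  bad <- hits; bad$protein_id[1] <- "nope"
  expect_error(reaction_hit_counts(bad, db), "absent from db")
})

test_that("key-pathway selection ranks by PC contribution and deduplicates", {
  rxns <- sprintf("K%02d", 1:40)
  pws <- list(Pvar = rxns[1:6], Pvar2 = rxns[1:5],
              Pc1 = rxns[7:12], Pc2 = rxns[13:18], Pc3 = rxns[19:24],
              Psmall = rxns[25:27])
  db <- pathway_db(pws,
                   data.frame(reaction_id = rxns, ec = "1.1.1.1",
                              partial = FALSE, stringsAsFactors = FALSE),
                   setNames(as.list(paste0("p", 1:40)), rxns))
  m <- matrix(0.5, nrow = 6, ncol = 6,
              dimnames = list(names(pws), paste0("S", 1:6)))
  m["Pvar", ] <- c(1, 1, 1, 0, 0, 0)
  m["Pvar2", ] <- c(1, 1, 1, 0, 0, 0)
  m["Psmall", ] <- c(1, 0, 1, 0, 1, 0)
  sel <- select_key_pathways(m, db, n_pc = 3, top_k = 3)
  # the only variable >=5-reaction pathways are the near-duplicate pair;
  # redundancy removal keeps one of them
  expect_equal(sum(c("Pvar", "Pvar2") %in% sel), 1L)
  # the <5-reaction pathway is filtered out in completeness mode
  expect_false("Psmall" %in% sel)
  attr(m, "score_type") <- "activity"
  sel2 <- select_key_pathways(m, db, n_pc = 3, top_k = 3)
  expect_true("Psmall" %in% sel2)
  expect_lte(length(sel2), 3L)
  m0 <- matrix(1, 3, 5, dimnames = list(names(pws)[1:3], paste0("S", 1:5)))
  expect_error(select_key_pathways(m0, db, n_pc = 3), "variance")
})

test_that("two-way clustering uses the right metric per score type", {
  m <- rbind(a = c(0, 0, 1, 1), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  colnames(m) <- paste0("S", 1:4)
  attr(m, "score_type") <- "completeness"
  cl <- cluster_score_matrix(m)
  hc <- cl$pathways
  # identical rows merge first at height 0; the opposed row joins last
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("a", "c"))
  expect_equal(hc$height[1], 0)
  expect_true(all(diff(hc$height) >= -1e-12))

  act <- rbind(a = c(1, 2, 30, 40), b = c(2, 4, 60, 80),
               z = c(5, 5, 5, 5))
  colnames(act) <- paste0("S", 1:4)
  attr(act, "score_type") <- "activity"
  expect_message(cl2 <- cluster_score_matrix(act), "zero-variance")
  hc2 <- cl2$pathways
  # a and b are perfectly correlated on the log scale: distance ~ 0
  first2 <- hc2$merge[1, ]
  expect_setequal(hc2$labels[-first2], c("a", "b"))
  expect_lt(hc2$height[1], 0.05)
  expect_error(cluster_score_matrix(m[1, , drop = FALSE]), "at least 2")
})
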