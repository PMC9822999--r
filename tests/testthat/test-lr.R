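test_that("the LR score follows the regularized geometric-mean formula", {
  me <- matrix(c(0, 4, 2,
                 9, 9, 2), nrow = 3,
               dimnames = list(c("LIGX", "RECX", "OTHER"), c("S", "R")))
  pairs <- data.frame(ligand = "LIGX", receptor = "RECX", annotation = "t")
  s <- lr_score(me, pairs, mu = 2)
  # sender S: ligand 0 -> score 0
  expect_equal(s$score[s$sender == "S" & s$receiver == "S"], 0)
  # sender R (ligand 4), receiver S (receptor 9): sqrt(36)/(2+6) = 0.75
  expect_equal(s$score[s$sender == "R" & s$receiver == "S"], 0.75)
  # l = r = mu: sqrt(mu^2)/(mu + mu) = 0.5
  me2 <- matrix(c(2, 2), 2, 1, dimnames = list(c("LIGX", "RECX"), "S"))
  s2 <- lr_score(me2, pairs, mu = 2)
  expect_equal(s2$score, 0.5)
  expect_equal(s2$mode, "autocrine")
  expect_error(lr_score(me, pairs, mu = -1), "mu")
})

test_that("scores are bounded in [0, 1) and monotone in both sides", {
  set.seed(101)
  for (i in 1:20) {
    l <- runif(1, 0, 50); r <- runif(1, 0, 50); mu <- runif(1, 0.1, 10)
    me <- matrix(c(l, r), 2, 1, dimnames = list(c("L", "R"), "T"))
    s <- lr_score(me, data.frame(ligand = "L", receptor = "R"), mu = mu)$score
    expect_gte(s, 0); expect_lt(s, 1)
    me2 <- matrix(c(l * 1.5, r), 2, 1, dimnames = list(c("L", "R"), "T"))
    s2 <- lr_score(me2, data.frame(ligand = "L", receptor = "R"), mu = mu)$score
    if (l > 0 && r > 0) expect_gt(s2, s) else expect_gte(s2, s)
  }
})

test_that("interaction counting applies the 0.4 threshold per type pair", {
  sc <- data.frame(sender = "A", receiver = "B",
                   ligand = c("L1", "L2", "L3"),
                   receptor = c("R1", "R2", "R3"),
                   pair = c("L1_R1", "L2_R2", "L3_R3"),
                   score = c(0.5, 0.45, 0.2), mode = "paracrine")
  expect_equal(count_interactions(sc)$n_interactions, 2L)
  sc$score <- c(0.1, 0.2, 0.39)
  expect_equal(count_interactions(sc)$n_interactions, 0L)
})

test_that("specificity selection matches hand enumeration on a toy matrix", {
  # 2 types (4 type pairs) x 3 LR pairs with known CVs
  types <- c("A", "B")
  grid <- expand.grid(sender = types, receiver = types,
                      stringsAsFactors = FALSE)
  mk <- function(p, scores) data.frame(
    sender = grid$sender, receiver = grid$receiver,
    ligand = p, receptor = "R", pair = paste0(p, "_R"),
    score = scores, mode = ifelse(grid$sender == grid$receiver,
                                  "autocrine", "paracrine"))
  sc <- rbind(mk("L1", c(0.9, 0.9, 0.9, 0.9)),     # constant: CV 0
              mk("L2", c(0.1, 0.8, 0.1, 0.1)),     # highly variable
              mk("L3", c(0.4, 0.5, 0.4, 0.5)))     # mildly variable
  sel <- specific_interactions(sc, top_n = 3, top_cv = 2)
  ab <- sel[sel$sender == "A" & sel$receiver == "B", ]
  # hand enumeration: CV(L2) > CV(L3) > CV(L1) = 0
  expect_equal(ab$pair, c("L2_R", "L3_R"))
  expect_false(any(sel$degenerate))
  # the constant pair is never selected ahead of a varying one
  expect_false("L1_R" %in% sel$pair[sel$cv > 0 | seq_len(nrow(sel)) == 1])
  # fully constant matrix: name-order fallback, flagged
  scc <- rbind(mk("L1", rep(0.5, 4)), mk("L2", rep(0.5, 4)))
  selc <- specific_interactions(scc, top_n = 2, top_cv = 1)
  expect_true(all(selc$degenerate))
  expect_equal(unique(selc$pair), "L1_R")
})

test_that("IE enrichment retains separated pairs and drops identical ones", {
  mkp <- function(pid, score) data.frame(
    sender = "myeloid", receiver = "T", ligand = "L", receptor = "R",
    pair = "L_R", score = score, mode = "paracrine", patient_id = pid)
  patients <- data.frame(patient_id = sprintf("P%02d", 1:14),
                         ie_label = rep(c("IE1", "IE2"), each = 7))
  hi <- c(0.9, 0.8, 0.85, 0.9, 0.8, 0.9, 0.85)
  lo <- c(0.1, 0.2, 0.15, 0.1, 0.2, 0.1, 0.15)
  ps <- do.call(rbind, lapply(1:14, function(i)
    mkp(patients$patient_id[i], c(hi, lo)[i])))
  en <- ie_enrichment(ps, patients)
  expect_equal(en$p, 2 / choose(14, 7), tolerance = 1e-12)
  expect_true(en$retained)
  expect_equal(en$direction, "IE1")
  # identical scores in both groups: p = 1, not retained
  ps2 <- ps; ps2$score <- 0.7
  en2 <- ie_enrichment(ps2, patients)
  expect_equal(en2$p, 1)
  expect_false(en2$retained)
})

test_that("planted IE1-boosted checkpoint pairs are recovered", {
  hits <- 0L
  boosted <- c("CD274_PDCD1", "CD80_CTLA4", "LGALS9_HAVCR2", "PVR_TIGIT")
  for (s in 1:3) {
    cfg <- sim_config(seed = 110 + s, n_patients_per_ie = 5,
                      images_per_patient = 1, cells_per_image = 1200,
                      include_genes = TRUE)
    out <- simulate_tme(cfg)
    ds <- out$dataset
    ps <- patient_lr_scores(ds, cell_types = c("tumor", "myeloid", "migDC",
                                               grep("^T_CD", ds$palette,
                                                    value = TRUE)))
    en <- ie_enrichment(ps, ds$patients)
    ret <- en[en$retained & en$direction == "IE1", ]
    if (any(boosted %in% ret$pair)) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("per-patient scoring skips sparse types and stays deterministic", {
  cfg <- sim_config(seed = 115, n_patients_per_ie = 2, images_per_patient = 1,
                    cells_per_image = 600, include_genes = TRUE)
  ds <- simulate_tme(cfg)$dataset
  a <- patient_lr_scores(ds, min_cells = 10)
  b <- patient_lr_scores(ds, min_cells = 10)
  expect_identical(a, b)
  # a very high threshold removes rare types from the score table
  strict <- patient_lr_scores(ds, min_cells = 200)
  expect_lt(length(unique(strict$sender)), length(unique(a$sender)))
})

test_that("pairs with unmeasured genes are skipped and recorded", {
  me <- matrix(c(1, 2), 2, 1, dimnames = list(c("L", "R"), "T"))
  pairs <- data.frame(ligand = c("L", "GHOST"), receptor = c("R", "R"))
  s <- lr_score(me, pairs, mu = 1)
  expect_equal(nrow(s), 1L)
  expect_equal(attr(s, "skipped")$ligand, "GHOST")
})
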