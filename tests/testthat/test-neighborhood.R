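test_that("a single-type image gives p_high = p_low = 1 for its self-pair", {
  cells <- random_image(60, seed = 70, types = "A")
  g <- contact_graph(cells)
  res <- pairwise_permutation_test(cells, g, n_perm = 200, seed = 1)
  expect_equal(res$p_high, 1)
  expect_equal(res$p_low, 1)
  expect_equal(res$call, "ns")
})

test_that("segregated type blocks are called avoidance across seeds", {
  seg <- toy_fixture("segregated_types")
  cells <- seg$dataset$cells
  g <- contact_graph(cells)
  for (s in 1:5) {
    res <- pairwise_permutation_test(cells, g, n_perm = 1000, seed = s)
    get <- function(a, b) res[res$type_a == a & res$type_b == b, ]
    expect_equal(get("tumor", "B")$call, "avoidance", info = paste("seed", s))
    expect_equal(get("tumor", "tumor")$call, "interaction")
    expect_equal(get("B", "B")$call, "interaction")
  }
})

test_that("permutation p-values respect their bounds and seed determinism", {
  cells <- random_image(300, seed = 71)
  g <- contact_graph(cells)
  a <- pairwise_permutation_test(cells, g, n_perm = 500, seed = 9)
  b <- pairwise_permutation_test(cells, g, n_perm = 500, seed = 9)
  expect_identical(a, b)
  ev <- a[a$evaluable, ]
  expect_true(all(ev$p_high >= 1 / 501 & ev$p_high <= 1))
  expect_true(all(ev$p_low >= 1 / 501 & ev$p_low <= 1))
  c2 <- pairwise_permutation_test(cells, g, n_perm = 500, seed = 10)
  expect_false(identical(a$p_high, c2$p_high))
})

test_that("absent types are recorded as not evaluable", {
  cells <- random_image(80, seed = 72, types = c("A", "B"))
  g <- contact_graph(cells)
  res <- pairwise_permutation_test(cells, g, n_perm = 100, seed = 1,
                                   types = c("A", "B", "Z"))
  z <- res[res$type_a == "Z" | res$type_b == "Z", ]
  expect_true(all(z$call == "not_evaluable"))
  expect_true(all(is.na(z$p_high)))
})

test_that("interaction_summary computes fractions and omits unseen pairs", {
  res <- data.frame(
    image_id = sprintf("img%03d", 1:4),
    type_a = "A", type_b = "B",
    observed = 1, p_high = c(0.001, 0.001, 0.001, 0.5),
    p_low = 1, call = c("interaction", "interaction", "interaction", "ns"),
    evaluable = TRUE, stringsAsFactors = FALSE)
  s <- interaction_summary(res)
  expect_equal(s$frac_interaction, 0.75)
  expect_equal(s$frac_avoidance, 0)
  expect_equal(s$net, 0.75)
  res$evaluable <- FALSE
  expect_equal(nrow(interaction_summary(res)), 0L)
})

test_that("knn composition profiles sum to one and match brute force", {
  out <- simulate_tme(small_cfg(seed = 73))
  ds <- out$dataset
  comp <- knn_composition(ds, k = 10,
                          query_subtypes = c("T_CD8_PD1high", "T_CD8_PD1low"),
                          stratify_by_tls = FALSE)
  for (qs in unique(comp$query_subtype)) {
    expect_equal(sum(comp$proportion[comp$query_subtype == qs]), 1,
                 tolerance = 1e-9)
  }
  # brute-force recomputation on one image
  iid <- ds$images$image_id[1]
  cells <- ds$cells[ds$cells$image_id == iid, ]
  qt <- "T_CD8_PD1low"
  qi <- which(cells$cell_type == qt)
  per_cell <- matrix(0, length(qi), length(unique(cells$cell_type)),
                     dimnames = list(NULL, sort(unique(cells$cell_type))))
  for (r in seq_along(qi)) {
    q <- qi[r]
    d <- sqrt((cells$x_um - cells$x_um[q])^2 + (cells$y_um - cells$y_um[q])^2)
    d[q] <- Inf
    nb <- order(d, cells$cell_id)[1:10]
    tb <- table(cells$cell_type[nb]) / 10
    per_cell[r, names(tb)] <- tb
  }
  want <- colMeans(per_cell)
  one <- knn_composition(
    tme_dataset(cells, ds$images[ds$images$image_id == iid, ],
                ds$patients, palette = ds$palette,
                cytokines = ds$cytokines),
    k = 10, query_subtypes = qt, stratify_by_tls = FALSE)
  got <- setNames(one$proportion, one$neighbor_type)
  for (tt in names(want)[want > 0])
    expect_equal(unname(got[tt]), unname(want[tt]), tolerance = 1e-9, label = tt)
})

test_that("planted migDC adjacency raises the migDC share around PD-1-high cells", {
  out <- simulate_tme(sim_config(seed = 74, n_patients_per_ie = 2,
                                 images_per_patient = 2,
                                 cells_per_image = 1500,
                                 include_genes = FALSE))
  comp <- knn_composition(out$dataset, k = 10,
                          query_subtypes = c("T_CD8_PD1high", "T_CD8_PD1low"),
                          stratify_by_tls = FALSE)
  mig <- comp[comp$neighbor_type == "migDC", ]
  hi <- mig$proportion[mig$query_subtype == "T_CD8_PD1high"]
  lo <- mig$proportion[mig$query_subtype == "T_CD8_PD1low"]
  expect_gt(hi, lo)
})

test_that("direct-neighbor fractions: degenerate and planted cases", {
  # patient whose cells never touch a migDC: both fractions zero
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:4), image_id = "img001",
    x_um = c(0, 500, 0, 500), y_um = c(0, 0, 500, 500), radius_um = 5,
    cell_type = c("T_CD8_PD1high", "T_CD8_PD1low", "migDC", "tumor"),
    stringsAsFactors = FALSE)
  ds <- tme_dataset(cells,
                    data.frame(image_id = "img001", patient_id = "P01",
                               width_um = 1000, height_um = 1000,
                               tls_status = "none"),
                    data.frame(patient_id = "P01", ie_label = "IE1"))
  r <- direct_neighbor_fraction(ds, "T_CD8_PD1high", "T_CD8_PD1low", "migDC")
  expect_equal(r$per_patient$frac_a, 0)
  expect_equal(r$per_patient$frac_b, 0)
  expect_true(is.na(r$p))  # fewer than 3 contributing patients

  # planted attraction: PD-1-high fraction exceeds PD-1-low for most patients
  out <- simulate_tme(sim_config(seed = 75, n_patients_per_ie = 3,
                                 images_per_patient = 2,
                                 cells_per_image = 1500,
                                 include_genes = FALSE))
  r2 <- direct_neighbor_fraction(out$dataset,
                                 c("T_CD4_PD1high", "T_CD8_PD1high"),
                                 c("T_CD4_PD1low", "T_CD8_PD1low"), "migDC")
  expect_gte(mean(r2$per_patient$frac_a > r2$per_patient$frac_b), 0.9)
  expect_lt(r2$p, 0.05)
})

test_that("identical paired fractions collapse to p = 1 with a warning", {
  expect_warning(r <- wilcoxon_signed_rank(rep(0.4, 6), rep(0.4, 6)), "zero")
  expect_equal(r$p, 1)
})

test_that("distance to nearest target matches direct computation", {
  t3 <- toy_fixture("three_cell_line")
  ds <- t3$dataset
  # middle cell to endpoints, when endpoints are the target type
  ds$cells$cell_type <- c("tumor", "T_CD4_PD1low", "tumor")
  d <- distance_to_nearest(ds, ds$cells$cell_id[2], "tumor")
  expect_equal(d$distance_um, 20)
  # no target in image: flagged, not an error
  d2 <- distance_to_nearest(ds, ds$cells$cell_id[2], "migDC")
  expect_false(d2$target_present)
  expect_true(is.na(d2$distance_um))
  # random-image oracle
  cells <- random_image(400, seed = 76)
  dsr <- tme_dataset(cells,
                     data.frame(image_id = "img001", patient_id = "P01",
                                width_um = 500, height_um = 500,
                                tls_status = "none"),
                     data.frame(patient_id = "P01", ie_label = "IE1"),
                     palette = c("A", "B", "C"))
  qs <- sample(cells$cell_id, 30)
  got <- distance_to_nearest(dsr, qs, "B")
  for (r in seq_along(qs)) {
    q <- match(qs[r], cells$cell_id)
    ti <- setdiff(which(cells$cell_type == "B"), q)
    want <- min(sqrt((cells$x_um[ti] - cells$x_um[q])^2 +
                     (cells$y_um[ti] - cells$y_um[q])^2))
    expect_equal(got$distance_um[r], want, tolerance = 1e-12)
  }
})

test_that("knn target proportions report candidate counts and flags", {
  # 4 candidate T cells, 1 flagged: proportion 0.25 with count 4
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:6), image_id = "img001",
    x_um = c(100, 110, 120, 130, 140, 400), y_um = 100, radius_um = 5,
    cell_type = c("myeloid", "T_CD8_PD1high", "T_CD8_PD1low",
                  "T_CD8_PD1low", "T_CD4_PD1low", "Treg"),
    stringsAsFactors = FALSE)
  ds <- tme_dataset(cells,
                    data.frame(image_id = "img001", patient_id = "P01",
                               width_um = 1000, height_um = 1000,
                               tls_status = "none"),
                    data.frame(patient_id = "P01", ie_label = "IE1"))
  tt <- grep("^T_CD", default_palette(), value = TRUE)
  r <- knn_target_proportion(ds, "c01", candidate_types = c(tt, "Treg"),
                             k = 10, exclude = "Treg",
                             flag_ids = c("T_CD8_PD1high", "T_CD4_PD1high"))
  expect_equal(r$n_candidates, 4L)
  expect_equal(r$proportion, 0.25)
  # zero candidates: undefined
  r0 <- knn_target_proportion(ds, "c01", candidate_types = "NKT", k = 10,
                              flag_ids = character(0))
  expect_equal(r0$n_candidates, 0L)
  expect_true(is.na(r0$proportion))
})

test_that("suppressive myeloid cells sit among more PD-1-high T cells", {
  # markers and spatial attraction are coupled in the generator: migDCs (all
  # counted suppressive-lineage) cluster with PD-1-high CD8 T cells
  out <- simulate_tme(sim_config(seed = 77, n_patients_per_ie = 2,
                                 images_per_patient = 2,
                                 cells_per_image = 1500,
                                 include_genes = FALSE))
  ds <- out$dataset
  tt <- grep("^T_CD", ds$palette, value = TRUE)
  mig <- ds$cells$cell_id[ds$cells$cell_type == "migDC"]
  oth <- ds$cells$cell_id[ds$cells$cell_type == "myeloid"]
  flag <- grep("PD1high$", ds$palette, value = TRUE)
  pm <- knn_target_proportion(ds, mig, candidate_types = tt, k = 10,
                              exclude = NULL, flag_ids = flag)
  po <- knn_target_proportion(ds, oth, candidate_types = tt, k = 10,
                              exclude = NULL, flag_ids = flag)
  expect_gt(mean(pm$proportion, na.rm = TRUE), mean(po$proportion, na.rm = TRUE))
})
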