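test_that("fisher_exact_2x2 reproduces hand-enumerated cases", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p, 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0)$p, 1)
  expect_equal(fisher_exact_2x2(5, 1, 1, 5)$p, fisher_enum(5, 1, 1, 5),
               tolerance = 1e-12)
  # degenerate margins: everything inside the milieu
  expect_equal(fisher_exact_2x2(3, 5, 0, 0)$p, 1)
  expect_error(fisher_exact_2x2(-1, 0, 0, 0), "domain")
  # odds ratio conventions
  expect_equal(fisher_exact_2x2(2, 1, 1, 2)$odds_ratio, 4)
  expect_true(is.infinite(fisher_exact_2x2(2, 0, 1, 2)$odds_ratio))
  expect_true(is.nan(fisher_exact_2x2(0, 0, 1, 0)$odds_ratio))
})

test_that("fisher_exact_2x2 equals enumeration on random small tables", {
  set.seed(14)
  for (i in 1:200) {
    tb <- rmultinom(1, sample(0:40, 1), prob = runif(4, 0.05, 1))
    got <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p
    expect_equal(got, fisher_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12, info = paste(tb, collapse = ","))
  }
})

test_that("patch detection on the toy line respects min_size", {
  t3 <- toy_fixture("three_cell_line")
  cells <- t3$dataset$cells
  calls <- calls_from_truth(t3$dataset, t3$truth)
  g <- radius_graph(cells, 25)
  p <- detect_patches(calls, g, kind = "CXCL13")
  expect_equal(length(unique(p$patch_id)), 1L)
  expect_setequal(p$cell_id, cells$cell_id)
  # middle cell silenced: two singletons, no patch
  calls2 <- calls; calls2$expressed[calls2$cell_id == cells$cell_id[2]] <- FALSE
  expect_equal(nrow(detect_patches(calls2, g, kind = "CXCL13")), 0L)
  # general patches see the same qualifying set here
  pg <- detect_patches(calls, g, kind = "general")
  expect_setequal(pg$cell_id, cells$cell_id)
})

test_that("two planted patches are recovered exactly and isolated cells excluded", {
  tp <- toy_fixture("two_patch_image")
  calls <- calls_from_truth(tp$dataset, tp$truth)
  g <- radius_graph(tp$dataset$cells, 25)
  p <- detect_patches(calls, g, kind = "CXCL13")
  expect_equal(length(unique(p$patch_id)), 2L)
  expect_setequal(p$cell_id, tp$truth$planted_patch_members$cell_id)
  # membership partition matches the planted clusters
  got <- split(p$cell_id, p$patch_id)
  want <- split(tp$truth$planted_patch_members$cell_id,
                tp$truth$planted_patch_members$cluster)
  expect_true(all(vapply(got, function(g1)
    any(vapply(want, function(w) setequal(g1, w), logical(1))), logical(1))))
})

test_that("patch detection equals the union-find oracle on random images", {
  for (s in 1:10) {
    cells <- random_image(250, seed = 40 + s)
    expressed <- runif(250) < 0.25
    calls <- data.frame(cell_id = cells$cell_id, cytokine = "CXCL9",
                        d = NA, p = 0, q = 0, expressed = expressed)
    g <- radius_graph(cells, 25)
    p <- detect_patches(calls, g, kind = "CXCL9")
    # oracle: union-find over the induced subgraph
    qual <- which(cells$cell_id %in% calls$cell_id[calls$expressed])
    e <- g$edges[g$edges$i %in% qual & g$edges$j %in% qual, ]
    comp <- uf_components(nrow(cells), e$i, e$j)
    comp[-qual] <- NA
    sizes <- table(comp[qual])
    keep <- names(sizes)[sizes >= 3]
    oracle_members <- sort(cells$cell_id[!is.na(comp) & comp %in% as.integer(keep)])
    expect_identical(sort(unique(p$cell_id)), oracle_members, info = paste("seed", s))
    # component partition must agree too
    if (nrow(p)) {
      got <- lapply(split(p$cell_id, p$patch_id), sort)
      want <- lapply(split(cells$cell_id[!is.na(comp)][comp[qual] %in% as.integer(keep)],
                           comp[qual][comp[qual] %in% as.integer(keep)]), sort)
      expect_setequal(unname(vapply(got, paste, "", collapse = "|")),
                      unname(vapply(want, paste, "", collapse = "|")))
    }
  }
})

test_that("milieus include cells within 30 um of a member and nothing farther", {
  # patch members at x = 0, 20, 40; candidates at 60 (in) and 80 (out)
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:5), image_id = "img001",
    x_um = c(0, 20, 40, 60, 80), y_um = 0, radius_um = 5,
    cell_type = "tumor", stringsAsFactors = FALSE)
  patches <- data.frame(patch_id = "p1", image_id = "img001", kind = "CXCL13",
                        cell_id = cells$cell_id[1:3])
  m <- build_milieus(patches, cells, dilation = 30)
  expect_true("c04" %in% m$cell_id)
  expect_false("c05" %in% m$cell_id)
  expect_true(all(patches$cell_id %in% m$cell_id))
})

test_that("milieu superset and 30-um invariants hold on random instances", {
  out <- simulate_tme(small_cfg(seed = 44))
  ds <- out$dataset
  calls <- calls_from_truth(ds, out$truth)
  pm <- patches_and_milieus(ds, calls)
  expect_gt(nrow(pm$patches), 0)
  for (pid in unique(pm$patches$patch_id)) {
    pmem <- pm$patches$cell_id[pm$patches$patch_id == pid]
    mmem <- pm$milieus$cell_id[pm$milieus$patch_id == pid]
    expect_true(all(pmem %in% mmem))
    cc <- ds$cells[ds$cells$cell_id %in% mmem, ]
    pc <- ds$cells[ds$cells$cell_id %in% pmem, ]
    dmin <- apply(cc[, c("x_um", "y_um")], 1, function(pt)
      min(sqrt((pc$x_um - pt[1])^2 + (pc$y_um - pt[2])^2)))
    expect_true(all(dmin <= 30 + 1e-9))
  }
  # every cytokine-specific patch is contained in some general patch
  gen <- pm$patches[pm$patches$kind == "general", ]
  spec <- pm$patches[pm$patches$kind != "general", ]
  if (nrow(spec)) {
    gsets <- split(gen$cell_id, gen$patch_id)
    for (pid in unique(spec$patch_id)) {
      smem <- spec$cell_id[spec$patch_id == pid]
      expect_true(any(vapply(gsets, function(gset) all(smem %in% gset),
                             logical(1))), label = pid)
    }
  }
})

test_that("milieu enrichment calls direction and summarizes across images", {
  # build one image where type X is concentrated inside the milieu
  set.seed(5)
  n <- 300
  inm <- rep(c(TRUE, FALSE), c(100, 200))
  type <- ifelse(inm, sample(c("B", "tumor"), n, TRUE, c(0.8, 0.2)),
                 sample(c("B", "tumor"), n, TRUE, c(0.1, 0.9)))[1:n]
  cells <- data.frame(cell_id = sprintf("c%03d", 1:n), image_id = "img001",
                      x_um = ifelse(inm, runif(n, 0, 100), runif(n, 500, 1000)),
                      y_um = runif(n, 0, 1000), radius_um = 5,
                      cell_type = type, stringsAsFactors = FALSE)
  ds <- tme_dataset(cells,
                    data.frame(image_id = "img001", patient_id = "P01",
                               width_um = 1000, height_um = 1000,
                               tls_status = "none"),
                    data.frame(patient_id = "P01", ie_label = "IE1"))
  milieus <- data.frame(patch_id = "p1", image_id = "img001", kind = "CXCL13",
                        cell_id = cells$cell_id[inm])
  enr <- milieu_enrichment(ds, milieus, alpha = 0.01)
  b <- enr$per_image[enr$per_image$cell_type == "B", ]
  tu <- enr$per_image[enr$per_image$cell_type == "tumor", ]
  expect_equal(b$call, "enriched")
  expect_equal(tu$call, "depleted")
  expect_equal(enr$summary$net_pct[enr$summary$cell_type == "B"], 100)
  expect_equal(enr$summary$net_pct[enr$summary$cell_type == "tumor"], -100)
})

test_that("patch membership proportions follow the two-patch fixture", {
  tp <- toy_fixture("two_patch_image")
  calls <- calls_from_truth(tp$dataset, tp$truth)
  pm <- patches_and_milieus(tp$dataset, calls, kinds = "CXCL13")
  st <- patch_membership_stats(calls, pm$patches, tp$dataset,
                               cell_type_filter = c("T_CD4_PD1low"),
                               cytokine = "CXCL13")
  expect_equal(st$per_image$n_expressing, 15L)
  expect_equal(st$per_image$n_in_patch, 10L)
  expect_equal(st$per_image$proportion, 10 / 15)
  # no qualifying expressers: image excluded
  st2 <- patch_membership_stats(calls, pm$patches, tp$dataset,
                                cell_type_filter = "NK", cytokine = "CXCL13")
  expect_equal(nrow(st2$per_image), 0L)
})

test_that("expressing fractions handle degenerate and grouped inputs", {
  t3 <- toy_fixture("three_cell_line")
  calls <- calls_from_truth(t3$dataset, t3$truth)
  calls$expressed <- FALSE
  fr <- expressing_fractions(calls, t3$dataset, "ie_label")
  expect_equal(fr$fraction, 0)
  out <- simulate_tme(small_cfg(seed = 46))
  calls <- calls_from_truth(out$dataset, out$truth)
  fr <- expressing_fractions(calls, out$dataset, c("ie_label", "cell_class"))
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  expect_true(all(c("T_NK", "myeloid", "tumor") %in% fr$cell_class))
})
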