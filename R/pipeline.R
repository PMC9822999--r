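# deterministic per-stage substream: root seed + stage-name hash, kept
# inside the 32-bit integer range
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(root) * 48271 + h) %% 2147483629)
}

#' Pipeline run configuration
#'
#' Bundles every stage parameter with its default: the 25 um patch neighbor
#' radius, 30 um milieu dilation, 8 um contact expansion, k = 10 neighbors,
#' 1000 permutations at p < 0.01, LR threshold 0.4 with enrichment p < 0.05,
#' and cytokine-calling FDR 0.01. One root seed drives every stochastic
#' stage through named substreams.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed root seed.
#' @param sim a [sim_config()] used when `input_dir` is `NULL`; its own seed
#'   is replaced by the `simulate` substream of `seed`.
#' @param input_dir optional directory with an existing dataset
#'   ([read_dataset()] format); overrides simulation.
#' @param stages character vector of stages to run, in dependency order,
#'   from: simulate, call, patches, neighborhoods, signatures, lr, compare.
#' @param call_alpha cytokine-calling FDR threshold.
#' @param patch_radius,patch_min_size,milieu_dilation patch/milieu geometry.
#' @param enrich_alpha milieu-enrichment Fisher threshold.
#' @param contact_expansion contact-graph expansion (um).
#' @param n_perm,perm_alpha permutation-test parameters.
#' @param knn_k neighbors for composition profiles.
#' @param lr_threshold,lr_alpha,lr_min_mean LR-stage thresholds.
#' @param lr_types cell types included in per-patient LR analysis.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("spatmilieu_run_"),
                       seed = 1L,
                       sim = sim_config(),
                       input_dir = NULL,
                       stages = c("simulate", "call", "patches",
                                  "neighborhoods", "signatures", "lr",
                                  "compare"),
                       call_alpha = 0.01,
                       patch_radius = 25, patch_min_size = 3,
                       milieu_dilation = 30,
                       enrich_alpha = 0.01,
                       contact_expansion = 8,
                       n_perm = 1000, perm_alpha = 0.01,
                       knn_k = 10,
                       lr_threshold = 0.4, lr_alpha = 0.05,
                       lr_min_mean = 0.4,
                       lr_types = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

write_out <- function(df, cfg, file) {
  utils::write.csv(df, file.path(cfg$out_dir, file), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated or
#' a loaded dataset, writes each stage's tidy tables plus a summary into
#' `cfg$out_dir`, and returns the result bundle invisibly. Re-running with
#' an identical configuration reproduces the outputs byte-identically.
#'
#' Stage outputs: `calls.csv`, `patches.csv`, `milieus.csv`,
#' `enrichment.csv`, `enrichment_summary.csv`, `expressing_fractions.csv`,
#' `patch_membership.csv`, `interactions.csv`, `interaction_summary.csv`,
#' `composition.csv`, `paired_fractions.csv`, `signature_scores.csv`,
#' `signature_correlations.csv`, `lr_scores.csv`, `lr_counts.csv`,
#' `lr_specific.csv`, `ie_enriched.csv`, `ie_compare.csv`, and
#' `run_config.yaml`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a named list with every computed table plus the
#'   dataset and ground truth (when simulated).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t0 <- Sys.time()
  log_ <- function(...) message(sprintf("[spatmilieu +%.1fs] ",
                                        as.numeric(Sys.time() - t0, "secs")),
                                ...)
  need <- function(stage, dep, obj) {
    if (is.null(obj)) stop("dependency error: stage '", stage,
                           "' requires output of stage '", dep, "'")
    obj
  }

  if ("simulate" %in% cfg$stages && is.null(cfg$input_dir)) {
    log_("simulate (seed substream ", stage_seed(cfg$seed, "simulate"), ")")
    sim <- cfg$sim
    sim$seed <- stage_seed(cfg$seed, "simulate")
    out <- simulate_tme(sim)
    res$dataset <- out$dataset; res$truth <- out$truth
    write_dataset(out$dataset, file.path(cfg$out_dir, "dataset"))
  } else if (!is.null(cfg$input_dir)) {
    log_("loading dataset from ", cfg$input_dir)
    res$dataset <- read_dataset(cfg$input_dir)
  }
  ds <- res$dataset

  if ("call" %in% cfg$stages) {
    need("call", "simulate", ds)
    log_("cytokine calling (alpha = ", cfg$call_alpha, ")")
    res$calls <- call_cytokines(ds, alpha = cfg$call_alpha)
    write_out(res$calls, cfg, "calls.csv")
  }

  if ("patches" %in% cfg$stages) {
    calls <- need("patches", "call", res$calls)
    log_("patch/milieu detection and enrichment")
    pm <- patches_and_milieus(ds, calls, r = cfg$patch_radius,
                              min_size = cfg$patch_min_size,
                              dilation = cfg$milieu_dilation)
    res$patches <- pm$patches; res$milieus <- pm$milieus
    write_out(pm$patches, cfg, "patches.csv")
    write_out(pm$milieus, cfg, "milieus.csv")
    enr <- milieu_enrichment(ds, pm$milieus, alpha = cfg$enrich_alpha)
    res$enrichment <- enr
    write_out(enr$per_image, cfg, "enrichment.csv")
    if (!is.null(enr$summary)) write_out(enr$summary, cfg, "enrichment_summary.csv")
    fr <- rbind(
      cbind(expressing_fractions(calls, ds, "ie_label"), cell_class = "all"),
      expressing_fractions(calls, ds, c("ie_label", "cell_class")))
    res$expressing_fractions <- fr
    write_out(fr, cfg, "expressing_fractions.csv")
    tsub <- grep("^T_CD", ds$palette, value = TRUE)
    pms <- patch_membership_stats(calls, pm$patches, ds,
                                  cell_type_filter = tsub,
                                  cytokine = "CXCL13")
    res$patch_membership <- pms
    write_out(pms$per_image, cfg, "patch_membership.csv")
  }

  if ("neighborhoods" %in% cfg$stages) {
    need("neighborhoods", "simulate", ds)
    log_("pairwise permutation tests (", cfg$n_perm, " permutations/image)")
    rows <- list()
    for (iid in ds$images$image_id) {
      cells <- image_cells(ds, iid)
      g <- contact_graph(cells, expansion = cfg$contact_expansion)
      rows[[iid]] <- pairwise_permutation_test(
        cells, g, n_perm = cfg$n_perm, alpha = cfg$perm_alpha,
        seed = stage_seed(cfg$seed, paste0("perm_", iid)))
    }
    res$interactions <- do.call(rbind, rows)
    rownames(res$interactions) <- NULL
    write_out(res$interactions, cfg, "interactions.csv")
    res$interaction_summary <- interaction_summary(res$interactions)
    write_out(res$interaction_summary, cfg, "interaction_summary.csv")
    tsub <- grep("^T_CD", ds$palette, value = TRUE)
    res$composition <- knn_composition(ds, k = cfg$knn_k,
                                       query_subtypes = c(tsub, "Treg"))
    write_out(res$composition, cfg, "composition.csv")
    dnf <- direct_neighbor_fraction(
      ds, query_type_a = grep("PD1high$", ds$palette, value = TRUE),
      query_type_b = grep("PD1low$", ds$palette, value = TRUE),
      target_type = "migDC", expansion = cfg$contact_expansion)
    res$paired_fractions <- dnf
    write_out(dnf$per_patient, cfg, "paired_fractions.csv")
  }

  if ("signatures" %in% cfg$stages && length(gene_cols(ds$cells))) {
    log_("signature scoring")
    sigs <- default_signatures()
    universe <- sub("^gx_", "", gene_cols(ds$cells))
    sigs$random_control <- random_signature(
      universe, size = 8, seed = stage_seed(cfg$seed, "random_signature"),
      exclude = unlist(lapply(sigs, function(s) s$genes)))
    myel <- c("myeloid", "migDC")
    sc <- do.call(rbind, lapply(sigs, function(s)
      score_signature(ds, s, cell_types = myel)))
    rownames(sc) <- NULL
    res$signature_scores <- sc
    write_out(sc, cfg, "signature_scores.csv")
    res$signature_correlations <- signature_correlations(sc)
    write_out(res$signature_correlations, cfg, "signature_correlations.csv")
  }

  if ("lr" %in% cfg$stages && length(gene_cols(ds$cells))) {
    log_("ligand-receptor analysis")
    me <- type_mean_expression(ds$cells)
    sc <- lr_score(me)
    res$lr_scores <- sc
    write_out(sc, cfg, "lr_scores.csv")
    res$lr_counts <- count_interactions(sc, threshold = cfg$lr_threshold)
    write_out(res$lr_counts, cfg, "lr_counts.csv")
    res$lr_specific <- specific_interactions(sc)
    write_out(res$lr_specific, cfg, "lr_specific.csv")
    ps <- patient_lr_scores(ds, cell_types = cfg$lr_types)
    res$ie_enriched <- ie_enrichment(ps, ds$patients, alpha = cfg$lr_alpha,
                                     min_mean = cfg$lr_min_mean)
    write_out(res$ie_enriched, cfg, "ie_enriched.csv")
  }

  if ("compare" %in% cfg$stages && !is.null(res$calls)) {
    log_("IE comparison (sample-averaged Wilcoxon)")
    per_img <- expressing_fractions(res$calls, ds, "image_id")
    feat <- data.frame(image_id = per_img$image_id, value = per_img$fraction)
    res$ie_compare <- ie_compare(feat, ds, feature = "expressing_fraction")
    write_out(res$ie_compare, cfg, "ie_compare.csv")
  }

  cfg_ser <- cfg
  cfg_ser$out_dir <- NULL  # the bundle's location is not part of the run plan
  cfg_ser$sim <- unclass(cfg_ser$sim)
  cfg_ser$sim$attraction_pairs <- as.list(cfg_ser$sim$attraction_pairs)
  cfg_ser$sim$avoidance_pairs <- as.list(cfg_ser$sim$avoidance_pairs)
  yaml::write_yaml(unclass(cfg_ser), file.path(cfg$out_dir, "run_config.yaml"))
  log_("done")
  invisible(res)
}

#' Compare a per-image feature between immune environments
#'
#' The sample-averaged comparison used throughout the reporting: per-image
#' feature values are averaged within each patient, and the patient means
#' are compared between IE1 and IE2 with the exact two-sided Wilcoxon
#' rank-sum test. Group medians and interquartile ranges accompany the
#' p-value. Patients with no defined value are excluded.
#'
#' @param feature_table data.frame(image_id, value).
#' @param ds a `tme_dataset` (for the image-to-patient and IE mapping).
#' @param feature label recorded in the output row.
#' @return one-row data.frame(feature, n_ie1, n_ie2, median_ie1, median_ie2,
#'   iqr_ie1, iqr_ie2, p).
#' @export
ie_compare <- function(feature_table, ds, feature = "feature") {
  pid <- ds$images$patient_id[match(feature_table$image_id, ds$images$image_id)]
  if (any(is.na(pid))) stop("feature table references unknown image_id(s)")
  keep <- is.finite(feature_table$value)
  if (!all(keep)) message("ie_compare: excluding ", sum(!keep),
                          " image value(s) that are missing")
  pm <- tapply(feature_table$value[keep], pid[keep], mean)
  ie <- ds$patients$ie_label[match(names(pm), ds$patients$patient_id)]
  x <- pm[ie == "IE1"]; y <- pm[ie == "IE2"]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 patients per IE group")
  p <- if (length(unique(c(x, y))) == 1) 1 else wilcoxon_rank_sum(x, y)$p
  data.frame(feature = feature,
             n_ie1 = length(x), n_ie2 = length(y),
             median_ie1 = stats::median(x), median_ie2 = stats::median(y),
             iqr_ie1 = stats::IQR(x), iqr_ie2 = stats::IQR(y),
             p = p, stringsAsFactors = FALSE)
}
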