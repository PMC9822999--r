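#' Permutation test for pairwise cell-type interaction and avoidance
#'
#' For every ordered cell-type pair (A, B) present in the image, the observed
#' statistic is the mean, over A cells, of the number of B neighbors in the
#' contact graph (A cells without neighbors contribute 0). The null is
#' generated by permuting the cell-type labels uniformly over the image's
#' cells with the graph held fixed — this conditions on the type counts and
#' is what "correcting for relative cell-type frequency" means here. All
#' pairs are evaluated on one shared permutation stream. With add-one
#' smoothing, `p_high = (1 + #\{perm >= obs\}) / (1 + n_perm)` and `p_low`
#' analogously with `<=`; comparisons are made on integer neighbor-count
#' totals (the per-pair denominator is permutation-invariant), so no
#' floating-point tolerance is needed. A pair is called `interaction` when
#' `p_high < alpha`, `avoidance` when `p_low < alpha` (when both, the smaller
#' p wins; exact ties give `ns`).
#'
#' @param cells data.frame of one image's cells.
#' @param contact a `neighbor_graph` for the same image (normally
#'   [contact_graph()]).
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance threshold (default 0.01).
#' @param seed integer seed for the permutation stream.
#' @param types cell types to evaluate; pairs with an absent type are
#'   reported as `not_evaluable`. Default: the types present in the image.
#' @param statistic `"mean"` (mean B-neighbor count per A cell, default) or
#'   `"total"` (total A-B neighbor links); the two give identical p-values
#'   since they differ by a permutation-invariant factor.
#' @return data.frame(image_id, type_a, type_b, observed, p_high, p_low,
#'   call, evaluable).
#' @export
pairwise_permutation_test <- function(cells, contact, n_perm = 1000,
                                      alpha = 0.01, seed = 1,
                                      types = NULL,
                                      statistic = c("mean", "total")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(contact, "neighbor_graph"),
            identical(contact$cell_ids, cells$cell_id))
  if (is.null(types)) types <- sort(unique(cells$cell_type))
  n <- nrow(cells)
  ti <- match(cells$cell_type, types)
  K <- length(types)
  n_t <- tabulate(ti, K)
  e <- contact$edges
  src <- c(e$i, e$j); dst <- c(e$j, e$i)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cmat <- function(lab) tabulate((lab[src] - 1L) * K + lab[dst], K * K)
  c_obs <- cmat(ti)
  ge <- integer(K * K); le <- integer(K * K)
  for (b in seq_len(n_perm)) {
    cp <- cmat(ti[sample.int(n)])
    ge <- ge + (cp >= c_obs)
    le <- le + (cp <= c_obs)
  }
  p_high <- (1 + ge) / (1 + n_perm)
  p_low <- (1 + le) / (1 + n_perm)
  grid <- expand.grid(a = seq_len(K), b = seq_len(K))
  idx <- (grid$a - 1L) * K + grid$b
  evaluable <- n_t[grid$a] > 0 & n_t[grid$b] > 0
  observed <- ifelse(evaluable,
                     c_obs[idx] / if (statistic == "mean") n_t[grid$a] else 1,
                     NA_real_)
  ph <- ifelse(evaluable, p_high[idx], NA_real_)
  pl <- ifelse(evaluable, p_low[idx], NA_real_)
  call <- rep("not_evaluable", nrow(grid))
  ev <- which(evaluable)
  call[ev] <- ifelse(
    ph[ev] < alpha & (pl[ev] >= alpha | ph[ev] < pl[ev]), "interaction",
    ifelse(pl[ev] < alpha & (ph[ev] >= alpha | pl[ev] < ph[ev]), "avoidance",
           "ns"))
  data.frame(image_id = contact$image_id,
             type_a = types[grid$a], type_b = types[grid$b],
             observed = observed, p_high = ph, p_low = pl,
             call = call, evaluable = evaluable, stringsAsFactors = FALSE)
}

#' Summarize pairwise interaction calls across images
#'
#' @param results row-bound output of [pairwise_permutation_test()] over
#'   several images.
#' @param min_images minimum number of evaluable images for a pair to be
#'   reported (default 1).
#' @return data.frame(type_a, type_b, n_images, frac_interaction,
#'   frac_avoidance, net): `net` (interaction minus avoidance fraction) is
#'   the heat-map statistic. Pairs never evaluable are absent.
#' @export
interaction_summary <- function(results, min_images = 1) {
  ev <- results[results$evaluable, , drop = FALSE]
  if (!nrow(ev)) return(data.frame(type_a = character(0), type_b = character(0),
                                   n_images = integer(0),
                                   frac_interaction = numeric(0),
                                   frac_avoidance = numeric(0), net = numeric(0)))
  sp <- split(ev, list(ev$type_a, ev$type_b), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(df) data.frame(
    type_a = df$type_a[1], type_b = df$type_b[1], n_images = nrow(df),
    frac_interaction = mean(df$call == "interaction"),
    frac_avoidance = mean(df$call == "avoidance"),
    net = mean(df$call == "interaction") - mean(df$call == "avoidance"),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[out$n_images >= min_images, , drop = FALSE]
}

#' k-nearest-neighbor cell-type composition profiles
#'
#' For each query cell the cell-type proportions among its (at most) k
#' nearest neighbors are computed; profiles are then averaged, unweighted,
#' over the query cells of each query subtype within each stratum (non-TLS
#' images versus TLS images, i.e. immature or mature). Per-cell proportions
#' sum to one over the neighbor types present, so each profile row sums to
#' one.
#'
#' @param ds a `tme_dataset`.
#' @param k neighbors per query cell (default 10).
#' @param query_subtypes character vector of query cell types (e.g. the
#'   T-cell subtypes).
#' @param stratify_by_tls split images into non-TLS and TLS strata (default
#'   `TRUE`); otherwise a single `all` stratum.
#' @return data.frame(stratum, query_subtype, neighbor_type, proportion,
#'   n_query_cells). Subtypes absent from a stratum are omitted.
#' @export
knn_composition <- function(ds, k = 10, query_subtypes, stratify_by_tls = TRUE) {
  acc <- list()
  for (iid in ds$images$image_id) {
    cells <- image_cells(ds, iid)
    if (!any(cells$cell_type %in% query_subtypes)) next
    g <- knn_lists(cells, k = k, query_types = query_subtypes)
    lens <- lengths(g$nn$idx)
    keep <- lens > 0
    if (!any(keep)) next
    ntype <- cells$cell_type[unlist(g$nn$idx[keep])]
    qrow <- rep(seq_along(g$nn$query_ids)[keep], lens[keep])
    w <- 1 / lens[keep][match(qrow, which(keep))]  # per-cell normalization
    tls <- ds$images$tls_status[ds$images$image_id == iid]
    stratum <- if (!stratify_by_tls) "all" else if (tls == "none") "non_TLS" else "TLS"
    acc[[length(acc) + 1L]] <- data.frame(
      stratum = stratum, query_subtype = g$nn$query_types[qrow],
      query_uid = paste(iid, qrow), neighbor_type = ntype, w = w,
      stringsAsFactors = FALSE)
  }
  if (!length(acc)) return(data.frame(stratum = character(0),
                                      query_subtype = character(0),
                                      neighbor_type = character(0),
                                      proportion = numeric(0),
                                      n_query_cells = integer(0)))
  long <- do.call(rbind, acc)
  sp <- split(long, list(long$stratum, long$query_subtype), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(df) {
    nq <- length(unique(df$query_uid))
    agg <- rowsum(df$w, df$neighbor_type) / nq
    data.frame(stratum = df$stratum[1], query_subtype = df$query_subtype[1],
               neighbor_type = rownames(agg), proportion = agg[, 1],
               n_query_cells = nq, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of cells with at least one direct neighbor of a target type
#'
#' The paired contrast behind the "PD-1-high versus PD-1-low T cells touching
#' a migDC" comparison: per patient (pooling the patient's images), the
#' fraction of type-a cells with at least one contact-graph neighbor of the
#' target type, the same for type-b, and an exact two-sided Wilcoxon
#' signed-rank test over the patient-level pairs. A patient contributes only
#' if it has cells of both query types and the target type. With fewer than
#' 3 contributing patients the p-value is reported as `NA`.
#'
#' @param ds a `tme_dataset`.
#' @param query_type_a,query_type_b character vectors of cell types forming
#'   the two sides of the pair (e.g. the PD-1-high vs PD-1-low T subtypes).
#' @param target_type character vector of target cell types (e.g. `"migDC"`).
#' @param expansion contact-graph expansion in micrometers (default 8).
#' @return list(per_patient, p, n_pairs, test).
#' @export
direct_neighbor_fraction <- function(ds, query_type_a, query_type_b,
                                     target_type, expansion = 8) {
  rows <- list()
  for (pid in ds$patients$patient_id) {
    imgs <- ds$images$image_id[ds$images$patient_id == pid]
    a_touch <- logical(0); b_touch <- logical(0); has_target <- FALSE
    for (iid in imgs) {
      cells <- image_cells(ds, iid)
      if (!nrow(cells)) next
      has_target <- has_target || any(cells$cell_type %in% target_type)
      g <- contact_graph(cells, expansion = expansion)
      is_t <- cells$cell_type %in% target_type
      touches <- rep(FALSE, nrow(cells))
      if (nrow(g$edges)) {
        src <- c(g$edges$i, g$edges$j); dst <- c(g$edges$j, g$edges$i)
        touches[unique(src[is_t[dst]])] <- TRUE
      }
      a_touch <- c(a_touch, touches[cells$cell_type %in% query_type_a])
      b_touch <- c(b_touch, touches[cells$cell_type %in% query_type_b])
    }
    if (!length(a_touch) || !length(b_touch) || !has_target) next
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = pid,
      ie_label = ds$patients$ie_label[ds$patients$patient_id == pid],
      frac_a = mean(a_touch), frac_b = mean(b_touch),
      n_a = length(a_touch), n_b = length(b_touch), stringsAsFactors = FALSE)
  }
  per_patient <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), ie_label = character(0),
               frac_a = numeric(0), frac_b = numeric(0),
               n_a = integer(0), n_b = integer(0))
  if (nrow(per_patient) >= 3) {
    test <- wilcoxon_signed_rank(per_patient$frac_a, per_patient$frac_b)
    p <- test$p
  } else {
    test <- NULL; p <- NA_real_
  }
  list(per_patient = per_patient, p = p, n_pairs = nrow(per_patient),
       test = test)
}

#' Distance from query cells to the nearest cell of a target type
#'
#' Exact euclidean centroid distance to the closest target-type cell in the
#' same image (the query cell itself is excluded when it belongs to the
#' target type). Queries in images without any target cell are flagged
#' (`target_present = FALSE`, distance `NA`) and should be excluded from
#' comparisons.
#'
#' @param ds a `tme_dataset`.
#' @param query_ids character vector of query `cell_id`s.
#' @param target_type character vector of target cell types.
#' @return data.frame(cell_id, image_id, distance_um, target_present).
#' @export
distance_to_nearest <- function(ds, query_ids, target_type) {
  cells <- ds$cells
  qall <- match(query_ids, cells$cell_id)
  if (any(is.na(qall))) stop("unknown query cell_id(s)")
  out <- data.frame(cell_id = query_ids, image_id = cells$image_id[qall],
                    distance_um = NA_real_, target_present = FALSE,
                    stringsAsFactors = FALSE)
  for (iid in unique(out$image_id)) {
    ic <- image_cells(ds, iid)
    qi <- match(out$cell_id[out$image_id == iid], ic$cell_id)
    ti <- which(ic$cell_type %in% target_type)
    if (!length(ti)) next
    res <- knn_query(ic$x_um[qi], ic$y_um[qi], ic$x_um[ti], ic$y_um[ti],
                     ic$cell_id[ti], k = 1, self_idx = match(qi, ti))
    d <- vapply(res$d, function(v) if (length(v)) v[1] else NA_real_, numeric(1))
    out$distance_um[out$image_id == iid] <- d
    out$target_present[out$image_id == iid] <- !is.na(d)
  }
  out
}

#' Proportion of flagged cells among the k nearest candidate cells
#'
#' For each query cell, finds the k closest cells of the candidate types
#' (optionally excluding some types, e.g. regulatory T cells) and reports the
#' proportion of those that carry a flag (e.g. PD-1-high status), together
#' with the number of candidates found. Queries with zero candidates are
#' returned with `NA` proportion.
#'
#' @param ds a `tme_dataset`.
#' @param query_ids character vector of query `cell_id`s.
#' @param candidate_types character vector of candidate cell types.
#' @param k candidates per query (default 10).
#' @param exclude candidate types to drop (default `NULL`).
#' @param flag_ids character vector of `cell_id`s considered flagged, or a
#'   character vector of cell types (auto-detected by overlap with the
#'   palette).
#' @return data.frame(cell_id, image_id, n_candidates, proportion).
#' @export
knn_target_proportion <- function(ds, query_ids, candidate_types, k = 10,
                                  exclude = NULL, flag_ids) {
  cells <- ds$cells
  if (all(flag_ids %in% ds$palette))
    flag_ids <- cells$cell_id[cells$cell_type %in% flag_ids]
  qall <- match(query_ids, cells$cell_id)
  if (any(is.na(qall))) stop("unknown query cell_id(s)")
  out <- data.frame(cell_id = query_ids, image_id = cells$image_id[qall],
                    n_candidates = 0L, proportion = NA_real_,
                    stringsAsFactors = FALSE)
  for (iid in unique(out$image_id)) {
    ic <- image_cells(ds, iid)
    sel <- out$image_id == iid
    qi <- match(out$cell_id[sel], ic$cell_id)
    ci <- which(ic$cell_type %in% setdiff(candidate_types, exclude))
    if (!length(ci)) next
    res <- knn_query(ic$x_um[qi], ic$y_um[qi], ic$x_um[ci], ic$y_um[ci],
                     ic$cell_id[ci], k = k, self_idx = match(qi, ci))
    flagged <- ic$cell_id[ci] %in% flag_ids
    out$n_candidates[sel] <- vapply(res$idx, length, integer(1))
    out$proportion[sel] <- vapply(res$idx, function(v)
      if (length(v)) mean(flagged[v]) else NA_real_, numeric(1))
  }
  out
}
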