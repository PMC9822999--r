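#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test with both margins fixed: the two-sided
#' p-value is the total probability of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' `1 + 1e-7` relative tolerance on the comparison, the usual guard against
#' floating-point ties). The returned odds ratio is the sample odds ratio
#' `ad / bc` (`Inf` when `bc = 0` and `ad > 0`; `NaN` when both products are
#' zero).
#'
#' @param a,b,c,d non-negative integer cell counts: `a` = X in Y, `b` = non-X
#'   in Y, `c` = X outside Y, `d` = non-X outside Y.
#' @return list(odds_ratio, p).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("domain error: counts must be non-negative integers")
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf else NaN
  N <- a + b + c + d
  if (N == 0) return(list(odds_ratio = or, p = 1))
  m <- a + b; k <- a + c
  lo <- max(0, k - (c + d)); hi <- min(k, m)
  supp <- lo:hi
  probs <- stats::dhyper(supp, m, c + d, k)
  pobs <- stats::dhyper(a, m, c + d, k)
  p <- sum(probs[probs <= pobs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Detect cytokine patches in one image
#'
#' A patch is a set of at least `min_size` cells, all expressing at least one
#' cytokine (general patch) or all expressing the named cytokine (specific
#' patch), that form a connected component of the neighbor graph restricted
#' to those qualifying cells. "Neighboring" is read as chain connectivity
#' (connected components), not mutual cliques.
#'
#' @param calls a cytokine call table ([call_cytokines()] or
#'   [calls_from_truth()]) covering the image's cells.
#' @param graph a `neighbor_graph` for the image, normally
#'   `radius_graph(cells, r = 25)`.
#' @param min_size minimum patch size (default 3).
#' @param kind `"general"` or a cytokine name.
#' @return data.frame(patch_id, image_id, kind, cell_id); zero rows when no
#'   patch qualifies.
#' @export
detect_patches <- function(calls, graph, min_size = 3, kind = "general") {
  stopifnot(inherits(graph, "neighbor_graph"))
  expressed <- calls[calls$expressed, , drop = FALSE]
  qual_ids <- if (kind == "general") unique(expressed$cell_id)
              else unique(expressed$cell_id[expressed$cytokine == kind])
  qual <- which(graph$cell_ids %in% qual_ids)
  empty <- data.frame(patch_id = character(0), image_id = character(0),
                      kind = character(0), cell_id = character(0),
                      stringsAsFactors = FALSE)
  if (!length(qual)) return(empty)
  e <- graph$edges
  keep <- e$i %in% qual & e$j %in% qual
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$i[keep]), to = as.character(e$j[keep])),
    directed = FALSE,
    vertices = data.frame(name = as.character(qual)))
  comp <- igraph::components(g)
  memb <- comp$membership
  keep_comp <- which(comp$csize >= min_size)
  if (!length(keep_comp)) return(empty)
  rows <- list()
  pid <- 0L
  # deterministic patch order: by smallest member row index
  first <- vapply(keep_comp, function(cc)
    min(as.integer(names(memb)[memb == cc])), integer(1))
  for (cc in keep_comp[order(first)]) {
    pid <- pid + 1L
    members <- sort(as.integer(names(memb)[memb == cc]))
    rows[[pid]] <- data.frame(
      patch_id = sprintf("%s_%s_p%03d", graph$image_id, kind, pid),
      image_id = graph$image_id, kind = kind,
      cell_id = graph$cell_ids[members], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Dilate patches into milieus
#'
#' The milieu of a patch contains the patch members plus every cell of the
#' image whose centroid lies within `dilation` micrometers of at least one
#' patch-member centroid.
#'
#' @param patches patch table from [detect_patches()] (one image).
#' @param cells the image's cells.
#' @param dilation dilation radius in micrometers (default 30).
#' @return data.frame(patch_id, image_id, kind, cell_id).
#' @export
build_milieus <- function(patches, cells, dilation = 30) {
  if (!nrow(patches)) return(patches)
  stopifnot(length(unique(patches$image_id)) == 1,
            all(cells$image_id == patches$image_id[1]))
  out <- vector("list", length(unique(patches$patch_id)))
  slot <- 0L
  for (pid in unique(patches$patch_id)) {
    pp <- patches[patches$patch_id == pid, , drop = FALSE]
    mi <- match(pp$cell_id, cells$cell_id)
    # exact min distance from every cell to the patch member set
    inside <- rep(FALSE, nrow(cells))
    inside[mi] <- TRUE
    for (m in mi) {
      d2 <- (cells$x_um - cells$x_um[m])^2 + (cells$y_um - cells$y_um[m])^2
      inside <- inside | d2 <= dilation^2
    }
    slot <- slot + 1L
    out[[slot]] <- data.frame(patch_id = pid, image_id = pp$image_id[1],
                              kind = pp$kind[1],
                              cell_id = cells$cell_id[inside],
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Detect patches and milieus across a whole dataset
#'
#' Convenience wrapper running [radius_graph()], [detect_patches()] and
#' [build_milieus()] per image for the requested patch kinds.
#'
#' @param ds a `tme_dataset`.
#' @param calls matching cytokine call table.
#' @param kinds patch kinds (default: `"general"` plus every cytokine).
#' @param r patch neighbor radius in micrometers (default 25).
#' @param min_size minimum patch size (default 3).
#' @param dilation milieu dilation in micrometers (default 30).
#' @return list(patches, milieus), both data.frames over all images.
#' @export
patches_and_milieus <- function(ds, calls, kinds = NULL, r = 25,
                                min_size = 3, dilation = 30) {
  if (is.null(kinds)) kinds <- c("general", ds$cytokines)
  prows <- list(); mrows <- list()
  for (iid in ds$images$image_id) {
    cells <- image_cells(ds, iid)
    if (!nrow(cells)) next
    g <- radius_graph(cells, r = r)
    ic <- calls[calls$cell_id %in% cells$cell_id, , drop = FALSE]
    for (kind in kinds) {
      pt <- detect_patches(ic, g, min_size = min_size, kind = kind)
      if (!nrow(pt)) next
      prows[[length(prows) + 1L]] <- pt
      mrows[[length(mrows) + 1L]] <- build_milieus(pt, cells, dilation = dilation)
    }
  }
  empty <- data.frame(patch_id = character(0), image_id = character(0),
                      kind = character(0), cell_id = character(0))
  list(patches = if (length(prows)) do.call(rbind, prows) else empty,
       milieus = if (length(mrows)) do.call(rbind, mrows) else empty)
}

#' Cell-type enrichment and depletion in cytokine milieus
#'
#' For every image and every (cell type X, milieu kind Y) combination where
#' the image contains both (at least one X cell and at least one milieu of
#' kind Y), the milieus of kind Y are merged into a single in-milieu
#' indicator and the 2x2 table (X/non-X by in/out of milieu) is tested with
#' the two-sided Fisher's exact test. Calls are `enriched` (p < alpha, OR >
#' 1), `depleted` (p < alpha, OR < 1) or `ns`. The cross-image summary per
#' (X, Y) is the percentage of eligible images with an `enriched` call minus
#' the percentage with a `depleted` call.
#'
#' @param ds a `tme_dataset`.
#' @param milieus milieu table from [patches_and_milieus()].
#' @param alpha significance threshold (default 0.01).
#' @return list(per_image, summary).
#' @export
milieu_enrichment <- function(ds, milieus, alpha = 0.01) {
  rows <- list()
  for (iid in unique(milieus$image_id)) {
    cells <- image_cells(ds, iid)
    mi <- milieus[milieus$image_id == iid, , drop = FALSE]
    for (kind in unique(mi$kind)) {
      inm <- cells$cell_id %in% mi$cell_id[mi$kind == kind]
      for (X in unique(cells$cell_type)) {
        isx <- cells$cell_type == X
        a <- sum(isx & inm); b <- sum(!isx & inm)
        cc <- sum(isx & !inm); dd <- sum(!isx & !inm)
        ft <- if ((a + b) == 0 || (cc + dd) == 0 || (a + cc) == 0 || (b + dd) == 0)
          list(odds_ratio = NaN, p = 1) else fisher_exact_2x2(a, b, cc, dd)
        call <- if (ft$p < alpha && is.finite(ft$odds_ratio) && ft$odds_ratio > 1 ||
                    ft$p < alpha && is.infinite(ft$odds_ratio)) "enriched"
                else if (ft$p < alpha && !is.nan(ft$odds_ratio) && ft$odds_ratio < 1) "depleted"
                else "ns"
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = iid, cell_type = X, milieu_kind = kind,
          a = a, b = b, c = cc, d = dd,
          odds_ratio = ft$odds_ratio, p = ft$p, call = call,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_image <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), cell_type = character(0),
               milieu_kind = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), odds_ratio = numeric(0),
               p = numeric(0), call = character(0))
  summary <- NULL
  if (nrow(per_image)) {
    sp <- split(per_image, list(per_image$cell_type, per_image$milieu_kind),
                drop = TRUE)
    summary <- do.call(rbind, lapply(sp, function(df) data.frame(
      cell_type = df$cell_type[1], milieu_kind = df$milieu_kind[1],
      n_images = nrow(df),
      pct_enriched = 100 * mean(df$call == "enriched"),
      pct_depleted = 100 * mean(df$call == "depleted"),
      net_pct = 100 * (mean(df$call == "enriched") - mean(df$call == "depleted")),
      stringsAsFactors = FALSE)))
    rownames(summary) <- NULL
  }
  list(per_image = per_image, summary = summary)
}

#' Proportion of expressing cells that sit inside a cytokine-specific patch
#'
#' Per image: among cells of the filtered types that express the named
#' cytokine, the proportion that belong to a specific patch of that cytokine.
#' Images with no qualifying expressing cell are excluded from aggregation.
#' Aggregation is by the image's TLS status, reporting both the pooled
#' proportion (summed numerators/denominators) and the unweighted mean of
#' per-image proportions.
#'
#' @param calls cytokine call table.
#' @param patches patch table from [patches_and_milieus()].
#' @param ds a `tme_dataset`.
#' @param cell_type_filter character vector of query cell types (e.g. the
#'   four PD-1-split T subtypes); `NULL` for all types.
#' @param cytokine cytokine name (e.g. `"CXCL13"`).
#' @return list(per_image, by_tls).
#' @export
patch_membership_stats <- function(calls, patches, ds,
                                   cell_type_filter = NULL,
                                   cytokine = "CXCL13") {
  cells <- ds$cells
  keep <- if (is.null(cell_type_filter)) rep(TRUE, nrow(cells))
          else cells$cell_type %in% cell_type_filter
  expr_ids <- calls$cell_id[calls$expressed & calls$cytokine == cytokine]
  member_ids <- patches$cell_id[patches$kind == cytokine]
  rows <- list()
  for (iid in ds$images$image_id) {
    ii <- cells$image_id == iid & keep & cells$cell_id %in% expr_ids
    denom <- sum(ii)
    if (denom == 0) next
    numer <- sum(cells$cell_id[ii] %in% member_ids)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = iid,
      tls_status = ds$images$tls_status[ds$images$image_id == iid],
      n_expressing = denom, n_in_patch = numer,
      proportion = numer / denom, stringsAsFactors = FALSE)
  }
  per_image <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), tls_status = character(0),
               n_expressing = integer(0), n_in_patch = integer(0),
               proportion = numeric(0))
  by_tls <- NULL
  if (nrow(per_image)) {
    sp <- split(per_image, per_image$tls_status)
    by_tls <- do.call(rbind, lapply(sp, function(df) data.frame(
      tls_status = df$tls_status[1], n_images = nrow(df),
      pooled_proportion = sum(df$n_in_patch) / sum(df$n_expressing),
      mean_proportion = mean(df$proportion), stringsAsFactors = FALSE)))
    rownames(by_tls) <- NULL
  }
  list(per_image = per_image, by_tls = by_tls)
}

#' Coarse cell-type classes
#'
#' Maps palette labels to the compartments used for reporting expressing
#' fractions: `T_NK`, `myeloid`, `stromal`, `tumor`, `B_plasma`, `other`.
#'
#' @param cell_type character vector of palette labels.
#' @return character vector of class labels.
#' @export
cell_class <- function(cell_type) {
  cls <- rep("other", length(cell_type))
  cls[cell_type %in% c("Treg", "NK", "NKT", "T_CD4_PD1high", "T_CD4_PD1low",
                       "T_CD8_PD1high", "T_CD8_PD1low")] <- "T_NK"
  cls[cell_type %in% c("myeloid", "migDC", "pDC")] <- "myeloid"
  cls[cell_type %in% c("fibroblast", "endothelial")] <- "stromal"
  cls[cell_type == "tumor"] <- "tumor"
  cls[cell_type %in% c("B", "plasma")] <- "B_plasma"
  cls
}

#' Fractions of cytokine-expressing cells by group
#'
#' A cell is "expressing" when it is called positive for at least one
#' cytokine. Fractions are reported per grouping variable combination; the
#' key headline contrast of the pipeline is the IE1 : IE2 ratio of these
#' fractions.
#'
#' @param calls cytokine call table.
#' @param ds a `tme_dataset`.
#' @param group_by character vector of grouping variables among `"ie_label"`,
#'   `"cell_class"`, `"cell_type"`, `"patient_id"`, `"image_id"`.
#' @return data.frame with the grouping columns plus `n_cells`,
#'   `n_expressing`, `fraction`.
#' @export
expressing_fractions <- function(calls, ds, group_by = "ie_label") {
  cells <- ds$cells
  expr_ids <- unique(calls$cell_id[calls$expressed])
  expressing <- cells$cell_id %in% expr_ids
  idx_img <- match(cells$image_id, ds$images$image_id)
  meta <- data.frame(
    image_id = cells$image_id,
    patient_id = ds$images$patient_id[idx_img],
    cell_type = cells$cell_type,
    cell_class = cell_class(cells$cell_type),
    stringsAsFactors = FALSE)
  meta$ie_label <- ds$patients$ie_label[match(meta$patient_id, ds$patients$patient_id)]
  bad <- setdiff(group_by, names(meta))
  if (length(bad)) stop("unknown grouping variable(s): ", paste(bad, collapse = ", "))
  key <- interaction(meta[group_by], drop = TRUE, sep = "\r")
  sp <- split(seq_len(nrow(cells)), key)
  out <- do.call(rbind, lapply(sp, function(ii) {
    g <- meta[ii[1], group_by, drop = FALSE]
    data.frame(g, n_cells = length(ii), n_expressing = sum(expressing[ii]),
               fraction = mean(expressing[ii]), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
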