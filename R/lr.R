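#' Mean normalized expression per cell type
#'
#' Normalizes each cell's gene counts to counts-per-`scale` of its total and
#' averages within cell type, the expression summary consumed by
#' [lr_score()]. Types with fewer than `min_cells` cells are skipped.
#'
#' @param cells cells data.frame (or a `tme_dataset`) with `gx_` columns.
#' @param min_cells minimum cells per type (default 10).
#' @param scale normalization scale (default 1e4).
#' @return matrix genes x cell types of mean normalized expression.
#' @export
type_mean_expression <- function(cells, min_cells = 10, scale = 1e4) {
  if (inherits(cells, "tme_dataset")) cells <- cells$cells
  gc <- gene_cols(cells)
  if (!length(gc)) stop("schema error: no gx_ gene-count columns")
  total <- rowSums(cells[, gc, drop = FALSE])
  keep <- total > 0
  cells <- cells[keep, , drop = FALSE]; total <- total[keep]
  norm <- as.matrix(cells[, gc, drop = FALSE]) * (scale / total)
  types <- cells$cell_type
  tab <- table(types)
  use <- names(tab)[tab >= min_cells]
  m <- vapply(use, function(tt) colMeans(norm[types == tt, , drop = FALSE]),
              numeric(length(gc)))
  rownames(m) <- sub("^gx_", "", gc)
  m
}

#' Regularized ligand-receptor interaction scores
#'
#' For every ordered (sender, receiver) cell-type pair and every
#' ligand-receptor pair, the score is the regularized geometric mean of the
#' ligand's mean expression `l` in the sender and the receptor's mean
#' expression `r` in the receiver:
#' `score = sqrt(l * r) / (mu + sqrt(l * r))`,
#' bounded in `[0, 1)`, zero when either side is zero, and monotone
#' increasing in both. The regularizer `mu` defaults to the global mean of
#' the expression matrix, so a score of 0.5 marks interactions at the
#' typical expression intensity. Pairs with a gene absent from the matrix
#' are skipped and recorded in the `skipped` attribute.
#'
#' @param mean_expr genes x cell-types matrix (see
#'   [type_mean_expression()]).
#' @param pairs data.frame(ligand, receptor, ...), e.g.
#'   [default_lr_pairs()].
#' @param mu regularizer; must be positive.
#' @return data.frame(sender, receiver, ligand, receptor, pair, score, mode)
#'   with `mode` `"autocrine"` when sender == receiver, else `"paracrine"`.
#' @export
lr_score <- function(mean_expr, pairs = default_lr_pairs(), mu = NULL) {
  if (is.null(mu)) mu <- mean(mean_expr)
  if (!is.finite(mu) || mu <= 0) stop("domain error: mu must be positive")
  have <- pairs$ligand %in% rownames(mean_expr) &
          pairs$receptor %in% rownames(mean_expr)
  skipped <- pairs[!have, , drop = FALSE]
  pairs <- pairs[have, , drop = FALSE]
  types <- colnames(mean_expr)
  grid <- expand.grid(sender = types, receiver = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    l <- mean_expr[pairs$ligand, grid$sender[i]]
    r <- mean_expr[pairs$receptor, grid$receiver[i]]
    s <- sqrt(l * r)
    data.frame(sender = grid$sender[i], receiver = grid$receiver[i],
               ligand = pairs$ligand, receptor = pairs$receptor,
               pair = paste(pairs$ligand, pairs$receptor, sep = "_"),
               score = s / (mu + s),
               mode = if (grid$sender[i] == grid$receiver[i]) "autocrine"
                      else "paracrine",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "mu") <- mu
  res
}

#' Count "true" interactions per cell-type pair
#'
#' @param scores output of [lr_score()].
#' @param threshold minimum score for a pair to count (default 0.4).
#' @return data.frame(sender, receiver, n_interactions).
#' @export
count_interactions <- function(scores, threshold = 0.4) {
  sp <- split(scores, list(scores$sender, scores$receiver), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(df) data.frame(
    sender = df$sender[1], receiver = df$receiver[1],
    n_interactions = sum(df$score >= threshold), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Cell-type-pair-specific interactions by coefficient of variation
#'
#' Separates pair-specific from ubiquitous interactions: for each
#' (sender, receiver) pair the `top_n` highest-scoring LR pairs are taken
#' (ties broken by pair name), the coefficient of variation (sd/mean) of
#' each of those LR pairs' scores across *all* cell-type pairs is computed,
#' and the `top_cv` LR pairs with the highest CV are returned. An LR pair
#' scoring identically everywhere has CV 0 and is never selected ahead of a
#' varying one. A fully constant score matrix degenerates to name order and
#' is flagged.
#'
#' @param scores output of [lr_score()] on a common LR-pair universe.
#' @param top_n number of top-scoring pairs to consider (default 100).
#' @param top_cv number of pairs to retain (default 5).
#' @return data.frame(sender, receiver, pair, ligand, receptor, score, cv,
#'   degenerate).
#' @export
specific_interactions <- function(scores, top_n = 100, top_cv = 5) {
  cv_tab <- tapply(scores$score, scores$pair, function(v) {
    m <- mean(v)
    if (m == 0) 0 else stats::sd(v) / m
  })
  sp <- split(scores, list(scores$sender, scores$receiver), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(df) {
    df <- df[order(-df$score, df$pair), , drop = FALSE]
    top <- utils::head(df, top_n)
    cv <- cv_tab[top$pair]
    degenerate <- all(cv == 0) || all(is.na(cv))
    sel <- order(-cv, top$pair)[seq_len(min(top_cv, nrow(top)))]
    data.frame(top[sel, c("sender", "receiver", "pair", "ligand", "receptor",
                          "score")],
               cv = unname(cv[sel]), degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-patient LR scores
#'
#' Runs [type_mean_expression()] and [lr_score()] on each patient's cells
#' separately, restricted to the given cell types (types with fewer than
#' `min_cells` cells in a patient are skipped for that patient). The
#' regularizer `mu` is computed per patient unless supplied.
#'
#' @param ds a `tme_dataset` with gene counts.
#' @param pairs LR pair table.
#' @param cell_types cell types to include (default: all).
#' @param min_cells minimum cells per type per patient (default 10).
#' @param mu optional fixed regularizer shared across patients.
#' @return data.frame as [lr_score()] plus a `patient_id` column.
#' @export
patient_lr_scores <- function(ds, pairs = default_lr_pairs(),
                              cell_types = NULL, min_cells = 10, mu = NULL) {
  cells <- ds$cells
  if (!is.null(cell_types)) cells <- cells[cells$cell_type %in% cell_types, , drop = FALSE]
  pid_of <- ds$images$patient_id[match(cells$image_id, ds$images$image_id)]
  out <- list()
  for (pid in unique(ds$patients$patient_id)) {
    pc <- cells[pid_of == pid, , drop = FALSE]
    if (!nrow(pc)) next
    me <- type_mean_expression(pc, min_cells = min_cells)
    if (is.null(dim(me)) || ncol(me) == 0) next
    sc <- lr_score(me, pairs, mu = mu)
    sc$patient_id <- pid
    out[[length(out) + 1L]] <- sc
  }
  do.call(rbind, out)
}

#' Immune-environment enrichment of LR interactions
#'
#' For every (sender, receiver, LR pair) combination, the per-patient scores
#' are compared between IE1 and IE2 patients with the exact two-sided
#' Wilcoxon rank-sum test. Combinations with `p < alpha` (uncorrected, as a
#' screening analysis) and overall mean score above `min_mean` are flagged
#' as retained; the direction column says which IE has the larger mean.
#'
#' @param pscores output of [patient_lr_scores()].
#' @param patients patient table with `patient_id` and `ie_label`.
#' @param alpha significance threshold (default 0.05).
#' @param min_mean minimum overall mean score (default 0.4).
#' @return data.frame(sender, receiver, pair, ligand, receptor, n_ie1,
#'   n_ie2, mean_ie1, mean_ie2, mean_all, direction, p, retained).
#' @export
ie_enrichment <- function(pscores, patients, alpha = 0.05, min_mean = 0.4) {
  ie <- patients$ie_label[match(pscores$patient_id, patients$patient_id)]
  sp <- split(seq_len(nrow(pscores)),
              list(pscores$sender, pscores$receiver, pscores$pair), drop = TRUE)
  out <- lapply(sp, function(ii) {
    s <- pscores$score[ii]; g <- ie[ii]
    x <- s[g == "IE1"]; y <- s[g == "IE2"]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    p <- if (length(unique(c(x, y))) == 1) 1 else wilcoxon_rank_sum(x, y)$p
    m1 <- mean(x); m2 <- mean(y); ma <- mean(s)
    data.frame(sender = pscores$sender[ii[1]],
               receiver = pscores$receiver[ii[1]],
               pair = pscores$pair[ii[1]],
               ligand = pscores$ligand[ii[1]],
               receptor = pscores$receptor[ii[1]],
               n_ie1 = length(x), n_ie2 = length(y),
               mean_ie1 = m1, mean_ie2 = m2, mean_all = ma,
               direction = if (m1 >= m2) "IE1" else "IE2",
               p = p, retained = p < alpha && ma > min_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
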