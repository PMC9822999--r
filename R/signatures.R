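#' Define a gene signature
#'
#' @param name signature name.
#' @param genes non-empty character vector of unique gene symbols.
#' @param seed optional; recorded when the signature was drawn at random
#'   ([random_signature()]).
#' @return object of class `signature_def`.
#' @export
signature_def <- function(name, genes, seed = NULL) {
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("domain error: empty signature")
  if (anyDuplicated(genes)) stop("domain error: duplicated signature genes")
  structure(list(name = name, genes = genes, seed = seed),
            class = "signature_def")
}

#' Draw a random control signature
#'
#' Samples `size` genes uniformly from a gene universe. Scored like any other
#' signature, a random control should show no correlation with the
#' functional signatures; a systematic correlation would indicate a
#' normalization or coverage bias.
#'
#' @param universe character vector of gene symbols to draw from.
#' @param size number of genes.
#' @param seed integer seed, recorded in the signature.
#' @param exclude genes removed from the universe first — normally the union
#'   of the functional signatures' genes, so the control is disjoint from
#'   what it is a control for.
#' @return a `signature_def` named `random_control`.
#' @export
random_signature <- function(universe, size = 8, seed = 1, exclude = NULL) {
  universe <- setdiff(universe, exclude)
  if (length(universe) < size) stop("domain error: universe smaller than size")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  signature_def("random_control", sample(universe, size), seed = seed)
}

#' Score a gene signature per cell
#'
#' Each signature gene's count is normalized by the cell's total gene count,
#' scaled to counts-per-`scale`, log-transformed with pseudocount 1 (natural
#' log) to damp dominant genes, and summed:
#' `score_c = sum_g log(1 + scale * count_gc / total_c)`.
#' The score is invariant to uniform per-cell count scaling and strictly
#' increasing in any signature-gene count at fixed total. Signature genes
#' absent from the count table contribute 0 and are reported via the
#' `missing_genes` attribute; cells with zero total count are excluded with
#' a warning.
#'
#' @param ds a `tme_dataset` whose cells carry `gx_` gene-count columns, or a
#'   bare cells data.frame.
#' @param sig a `signature_def`.
#' @param scale normalization scale (default 1e4, counts per 10k).
#' @param cell_types optional character vector restricting scoring to these
#'   cell types.
#' @return data.frame(cell_id, signature, score) with attribute
#'   `missing_genes`.
#' @export
score_signature <- function(ds, sig, scale = 1e4, cell_types = NULL) {
  stopifnot(inherits(sig, "signature_def"))
  cells <- if (inherits(ds, "tme_dataset")) ds$cells else ds
  if (!is.null(cell_types)) cells <- cells[cells$cell_type %in% cell_types, , drop = FALSE]
  gc <- gene_cols(cells)
  if (!length(gc)) stop("schema error: no gx_ gene-count columns")
  total <- rowSums(cells[, gc, drop = FALSE])
  zero <- total == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total gene count excluded from scoring")
    cells <- cells[!zero, , drop = FALSE]
    total <- total[!zero]
  }
  want <- paste0("gx_", sig$genes)
  present <- want[want %in% gc]
  missing <- sub("^gx_", "", setdiff(want, gc))
  score <- if (length(present)) {
    m <- as.matrix(cells[, present, drop = FALSE])
    rowSums(log1p(scale * m / total))
  } else rep(0, nrow(cells))
  out <- data.frame(cell_id = cells$cell_id, signature = sig$name,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- missing
  out
}

#' Correlations between signature scores
#'
#' Spearman rank correlation between every pair of signatures, computed at
#' the requested grouping level: per cell, or on unweighted group means per
#' cluster/patient/image. Two-tailed p-values come from [stats::cor.test()]
#' (exact for small n without ties, t-approximation otherwise). Pairs with a
#' constant score vector are reported with `NA` correlation.
#'
#' @param scores row-bound output of [score_signature()] for two or more
#'   signatures on the same cells.
#' @param grouping `"cell"` (default) or the name of a column in `groups`.
#' @param groups optional data.frame(cell_id, <grouping>) mapping cells to
#'   groups when `grouping != "cell"`.
#' @return data.frame(signature_a, signature_b, n, rho, p).
#' @export
signature_correlations <- function(scores, grouping = "cell", groups = NULL) {
  wide <- split(scores, scores$signature)
  sig_names <- names(wide)
  if (length(sig_names) < 2) stop("need at least two signatures")
  ids <- Reduce(intersect, lapply(wide, function(df) df$cell_id))
  mat <- vapply(wide, function(df) df$score[match(ids, df$cell_id)],
                numeric(length(ids)))
  if (grouping != "cell") {
    if (is.null(groups)) stop("groups mapping required for grouping != 'cell'")
    g <- groups[[grouping]][match(ids, groups$cell_id)]
    keep <- !is.na(g)
    mat <- apply(mat[keep, , drop = FALSE], 2, function(v) {
      tapply(v, g[keep], mean)
    })
  }
  if (nrow(mat) < 3) stop("need at least 3 units for correlation")
  cmb <- utils::combn(sig_names, 2)
  out <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- mat[, cmb[1, i]]; b <- mat[, cmb[2, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(signature_a = cmb[1, i], signature_b = cmb[2, i],
                        n = nrow(mat), rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    data.frame(signature_a = cmb[1, i], signature_b = cmb[2, i],
               n = nrow(mat), rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
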