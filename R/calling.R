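#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in input
#' order. Delegates to [stats::p.adjust()], which implements exactly this.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("domain error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call per-cell cytokine expression against the DapB background
#'
#' For each cytokine k and cell i the difference
#' `d_ik = count_ik - count_i,DapB` between the cytokine probe and the
#' negative-control probe is computed. Under exchangeable probe noise a
#' non-expressing cell has `d` symmetric about zero, so the null distribution
#' of `d` is estimated per cytokine from the empirical differences by
#' symmetrizing the non-positive tail (`{d <= 0}` together with its mirror
#' `{-d : d <= 0}`). The p-value is the upper-tail probability of `d_ik`
#' under this empirical null with add-one smoothing (minimum attainable p is
#' `1/(n_null + 1)`). Benjamini-Hochberg correction is applied per cytokine
#' across all cells of the dataset, and a cell is called expressing when
#' `q < alpha`.
#'
#' @param ds a `tme_dataset` whose cells carry `cy_DapB` and at least one
#'   other `cy_` probe column.
#' @param alpha FDR threshold for the expression call (default 0.01).
#' @param per_image estimate the null and apply BH within each image instead
#'   of pooling the whole dataset (default `FALSE`, pooled).
#' @return data.frame (`CytokineCallTable`) with columns `cell_id`,
#'   `cytokine`, `d`, `p`, `q`, `expressed`.
#' @export
call_cytokines <- function(ds, alpha = 0.01, per_image = FALSE) {
  stopifnot(inherits(ds, "tme_dataset"))
  cells <- ds$cells
  if (!("cy_DapB" %in% names(cells)))
    stop("schema error: cy_DapB column required for cytokine calling")
  if (!length(ds$cytokines))
    stop("schema error: no cytokine probe columns besides cy_DapB")
  groups <- if (per_image) split(seq_len(nrow(cells)), cells$image_id)
            else list(all = seq_len(nrow(cells)))
  out <- vector("list", length(groups) * length(ds$cytokines))
  slot <- 0L
  for (g in groups) {
    dapb <- cells$cy_DapB[g]
    for (ck in ds$cytokines) {
      d <- cells[[paste0("cy_", ck)]][g] - dapb
      if (length(d) && max(d) == min(d))
        warning("cytokine ", ck, ": zero variance in differences; all p = 1")
      p <- empirical_upper_p(d)
      q <- benjamini_hochberg(p)
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        cell_id = cells$cell_id[g], cytokine = ck, d = d, p = p, q = q,
        expressed = q < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(slot)])
}

# upper-tail empirical p of each d under the symmetrized non-positive-tail
# null, with add-one smoothing: p_i = (1 + #{null >= d_i}) / (1 + n_null)
empirical_upper_p <- function(d) {
  neg <- d[d <= 0]
  null <- c(neg, -neg)
  n_null <- length(null)
  if (!n_null) return(rep(1, length(d)))
  sn <- sort(null)
  n_ge <- n_null - findInterval(d, sn, left.open = TRUE)
  pmin(1, (1 + n_ge) / (1 + n_null))
}

#' Write a cytokine call table to CSV
#'
#' @param calls a call table from [call_cytokines()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_calls <- function(calls, file) {
  utils::write.csv(calls, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
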