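# Internal geometry kernels.
#
# All neighbor structures in the package reduce to two primitives on one
# image's centroids: (1) all pairs within a cutoff distance, found with a
# uniform grid index so cost scales with the number of true pairs rather than
# n^2; (2) k-nearest-neighbor queries, done by blocked exact distance
# computation. Both are exact (no approximation), matching the brute-force
# definitions used as oracles in the test suite.

# All unordered pairs (i < j) with euclidean distance <= r.
# Returns data.frame(i, j, d). Grid bucketing with cell size r: a qualifying
# pair can only span adjacent buckets, so comparing each bucket with itself
# and 4 of its 8 neighbors covers every pair exactly once.
pairs_within <- function(x, y, r) {
  n <- length(x)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (n < 2) return(empty)
  if (r <= 0) stop("domain error: search radius must be positive")
  gx <- floor(x / r); gy <- floor(y / r)
  gx <- gx - min(gx); gy <- gy - min(gy)
  ncol_g <- max(gx) + 1L
  key <- gx + gy * ncol_g
  buckets <- split(seq_len(n), key)
  bkeys <- as.numeric(names(buckets))
  bmap <- new.env(hash = TRUE, size = length(buckets))
  for (b in seq_along(bkeys)) assign(as.character(bkeys[b]), b, envir = bmap)
  # offsets covering each unordered bucket pair once: self, E, SW, S, SE
  offs <- list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  out_i <- vector("list", length(buckets) * length(offs))
  out_j <- out_i; out_d <- out_i
  slot <- 0L
  r2 <- r * r
  for (b in seq_along(buckets)) {
    ii <- buckets[[b]]
    bx <- bkeys[b] %% ncol_g; by <- bkeys[b] %/% ncol_g
    for (o in offs) {
      nx <- bx + o[1]; ny <- by + o[2]
      if (nx < 0 || nx >= ncol_g || ny < 0) next
      if (identical(o, c(0, 0))) {
        if (length(ii) < 2) next
        cmb <- utils::combn(ii, 2)
        pi_ <- cmb[1, ]; pj <- cmb[2, ]
      } else {
        kb <- get0(as.character(nx + ny * ncol_g), envir = bmap)
        if (is.null(kb)) next
        jj <- buckets[[kb]]
        pi_ <- rep(ii, each = length(jj)); pj <- rep(jj, times = length(ii))
      }
      d2 <- (x[pi_] - x[pj])^2 + (y[pi_] - y[pj])^2
      keep <- d2 <= r2
      if (any(keep)) {
        slot <- slot + 1L
        out_i[[slot]] <- pi_[keep]; out_j[[slot]] <- pj[keep]
        out_d[[slot]] <- sqrt(d2[keep])
      }
    }
  }
  if (slot == 0L) return(empty)
  i <- unlist(out_i[seq_len(slot)]); j <- unlist(out_j[seq_len(slot)])
  d <- unlist(out_d[seq_len(slot)])
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], d = d[ord])
}

# k nearest candidates for each query point, exact, ties broken by ascending
# candidate id. qx/qy: query coords; cx/cy: candidate coords; cand_id:
# character ids used for tie-breaking and reporting; self_idx: optional
# integer vector mapping each query to the candidate row that is the same
# cell (excluded), NA if none. Returns list(idx = list of integer vectors
# into the candidate set, d = list of distances).
knn_query <- function(qx, qy, cx, cy, cand_id, k, self_idx = NULL,
                      block = 2e6) {
  nq <- length(qx); nc <- length(cx)
  idx <- vector("list", nq); dd <- vector("list", nq)
  if (nq == 0) return(list(idx = idx, d = dd))
  ord_id <- order(cand_id)  # rank of each candidate id for tie-breaking
  id_rank <- integer(nc); id_rank[ord_id] <- seq_len(nc)
  rows_per_block <- max(1L, floor(block / max(nc, 1L)))
  for (start in seq(1L, nq, by = rows_per_block)) {
    end <- min(nq, start + rows_per_block - 1L)
    qs <- start:end
    dx <- outer(qx[qs], cx, "-"); dy <- outer(qy[qs], cy, "-")
    dm <- sqrt(dx * dx + dy * dy)
    for (r in seq_along(qs)) {
      q <- qs[r]
      dv <- dm[r, ]
      if (!is.null(self_idx) && !is.na(self_idx[q])) dv[self_idx[q]] <- Inf
      avail <- which(is.finite(dv))
      if (!length(avail)) { idx[[q]] <- integer(0); dd[[q]] <- numeric(0); next }
      take <- min(k, length(avail))
      o <- avail[order(dv[avail], id_rank[avail])][seq_len(take)]
      idx[[q]] <- o; dd[[q]] <- dv[o]
    }
  }
  list(idx = idx, d = dd)
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
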