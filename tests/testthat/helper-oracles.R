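# Independent oracles for the statistical and spatial primitives.
# Everything here is deliberately naive (brute force, full enumeration,
# union-find) and shares no code with the implementation paths it checks.

# all pairs within distance r, O(n^2)
brute_pairs <- function(x, y, r) {
  dm <- as.matrix(stats::dist(cbind(x, y)))
  idx <- which(upper.tri(dm) & dm <= r, arr.ind = TRUE)
  data.frame(i = unname(idx[, 1]), j = unname(idx[, 2]))
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

# naive quadratic BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of element i (stable for ties via order)
    q[i] <- min(1, min(p[o[r:m]] * m / (r:m)))
  }
  q
}

# Fisher two-sided p by explicit enumeration with choose() (no dhyper)
fisher_enum <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(1)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  tab_p <- function(aa) choose(m, aa) * choose(n, k - aa) / choose(N, k)
  pobs <- tab_p(a)
  sum(vapply(lo:hi, function(aa) {
    pp <- tab_p(aa)
    if (pp <= pobs * (1 + 1e-7)) pp else 0
  }, numeric(1)))
}

# connected components of an edge list by union-find
uf_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(v) { while (parent[v] != v) { parent[v] <<- parent[parent[v]]; v <- parent[v] }; v }
  for (e in seq_along(edges_i)) {
    ri <- find(edges_i[e]); rj <- find(edges_j[e])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# exact two-sided rank-sum p by enumerating all choose(N, n1) subsets
ranksum_enum <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  subs <- utils::combn(N, n1)
  ws <- apply(subs, 2, function(s) sum(r[s]))
  pl <- mean(ws <= w + 1e-9); pu <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pl, pu))
}

# exact two-sided signed-rank p by enumerating all 2^n sign vectors
signrank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  pl <- mean(vs <= v + 1e-9); pu <- mean(vs >= v - 1e-9)
  min(1, 2 * min(pl, pu))
}

# a random single-image cell table
random_image <- function(n, seed, types = c("A", "B", "C"), size = 500) {
  set.seed(seed)
  data.frame(
    cell_id = sprintf("c%04d", sample(seq_len(n))),
    image_id = "img001",
    x_um = stats::runif(n, 0, size), y_um = stats::runif(n, 0, size),
    radius_um = stats::runif(n, 2, 10),
    cell_type = sample(types, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# small simulation config for fast tests
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_patients_per_ie = 2, images_per_patient = 2,
             cells_per_image = 600, include_genes = FALSE, ...)
}
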