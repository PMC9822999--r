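#' Neighbor graphs for one image
#'
#' The three neighbor structures consumed by the spatial analyses are all
#' built per image and represented by a common `neighbor_graph` object:
#' \describe{
#'   \item{contact}{cells touch after expanding each disk by `expansion` um:
#'     edge iff `dist(i, j) <= radius_i + radius_j + 2 * expansion`. This
#'     mirrors mask expansion in segmentation pipelines where every cell's
#'     circumference is grown before overlap is tested.}
#'   \item{radius}{edge iff centroid distance `<= r` (boundary inclusive).}
#'   \item{knn}{for each query cell the `k` nearest other cells by centroid
#'     distance, ties broken by ascending `cell_id`.}
#' }
#' Contact and radius graphs are symmetric and irreflexive; knn lists are
#' ordered and have length `min(k, candidates)`.
#'
#' @param cells data.frame of cells from a single image (rows of
#'   `ds$cells`).
#' @param expansion per-cell expansion in micrometers (default 8). Both cells
#'   of a pair are expanded, i.e. the combined slack is `2 * expansion`; set
#'   `combined = FALSE` to use `expansion` as total slack instead.
#' @param combined logical; see `expansion`.
#' @return A `neighbor_graph` object.
#' @name neighbor-graphs
NULL

new_neighbor_graph <- function(image_id, rule, params, cell_ids, edges = NULL,
                               nn = NULL) {
  structure(list(image_id = image_id, rule = rule, params = params,
                 cell_ids = cell_ids, edges = edges, nn = nn),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  nedge <- if (!is.null(x$edges)) nrow(x$edges)
           else sum(lengths(x$nn$idx))
  cat(sprintf("neighbor_graph [%s] image %s: %d cells, %d %s\n",
              x$rule, x$image_id, length(x$cell_ids), nedge,
              if (x$rule == "knn") "directed links" else "edges"))
  invisible(x)
}

check_one_image <- function(cells) {
  if (nrow(cells) && length(unique(cells$image_id)) != 1)
    stop("graphs are image-scoped: pass the cells of exactly one image")
  if (nrow(cells)) cells$image_id[1] else NA_character_
}

#' @rdname neighbor-graphs
#' @export
contact_graph <- function(cells, expansion = 8, combined = TRUE) {
  iid <- check_one_image(cells)
  slack <- if (combined) 2 * expansion else expansion
  n <- nrow(cells)
  if (n < 2) {
    return(new_neighbor_graph(iid, "contact",
                              list(expansion = expansion, combined = combined),
                              cells$cell_id,
                              edges = data.frame(i = integer(0), j = integer(0),
                                                 d = numeric(0))))
  }
  rmax <- max(cells$radius_um)
  cand <- pairs_within(cells$x_um, cells$y_um, 2 * rmax + slack)
  keep <- cand$d <= cells$radius_um[cand$i] + cells$radius_um[cand$j] + slack
  new_neighbor_graph(iid, "contact",
                     list(expansion = expansion, combined = combined),
                     cells$cell_id, edges = cand[keep, , drop = FALSE])
}

#' @rdname neighbor-graphs
#' @param r neighbor radius in micrometers (default 25).
#' @export
radius_graph <- function(cells, r = 25) {
  if (r <= 0) stop("domain error: radius must be positive")
  iid <- check_one_image(cells)
  edges <- if (nrow(cells) >= 2) pairs_within(cells$x_um, cells$y_um, r)
           else data.frame(i = integer(0), j = integer(0), d = numeric(0))
  new_neighbor_graph(iid, "radius", list(r = r), cells$cell_id, edges = edges)
}

#' @rdname neighbor-graphs
#' @param k number of nearest neighbors (default 10).
#' @param restrict_to optional character vector: only cells of these types
#'   are eligible as neighbors.
#' @param exclude optional character vector of cell types removed from the
#'   candidate set (applied after `restrict_to`).
#' @param query_types optional character vector: build lists only for query
#'   cells of these types (all cells by default).
#' @export
knn_lists <- function(cells, k = 10, restrict_to = NULL, exclude = NULL,
                      query_types = NULL) {
  if (k < 1) stop("domain error: k must be >= 1")
  iid <- check_one_image(cells)
  qi <- seq_len(nrow(cells))
  if (!is.null(query_types)) qi <- qi[cells$cell_type %in% query_types]
  ci <- seq_len(nrow(cells))
  if (!is.null(restrict_to)) ci <- ci[cells$cell_type %in% restrict_to]
  if (!is.null(exclude)) ci <- ci[!(cells$cell_type[ci] %in% exclude)]
  self_idx <- match(qi, ci)  # NA when the query is not itself a candidate
  res <- knn_query(cells$x_um[qi], cells$y_um[qi],
                   cells$x_um[ci], cells$y_um[ci],
                   cells$cell_id[ci], k, self_idx = self_idx)
  nn <- list(query_ids = cells$cell_id[qi],
             query_types = cells$cell_type[qi],
             idx = lapply(res$idx, function(v) ci[v]),
             d = res$d,
             n_candidates = vapply(seq_along(qi), function(r) {
               length(ci) - as.integer(!is.na(self_idx[r]))
             }, integer(1)))
  new_neighbor_graph(iid, "knn",
                     list(k = k, restrict_to = restrict_to, exclude = exclude),
                     cells$cell_id, nn = nn)
}

#' Adjacency of a neighbor graph as cell-id lists
#'
#' @param g a `neighbor_graph`.
#' @return Named list: for contact/radius graphs, per cell the sorted set of
#'   neighbor cell_ids; for knn graphs, per query cell the ordered neighbor
#'   list.
#' @export
graph_neighbors <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$rule == "knn") {
    out <- lapply(g$nn$idx, function(v) g$cell_ids[v])
    names(out) <- g$nn$query_ids
    return(out)
  }
  out <- rep(list(character(0)), length(g$cell_ids))
  names(out) <- g$cell_ids
  if (nrow(g$edges)) {
    src <- c(g$edges$i, g$edges$j); dst <- c(g$edges$j, g$edges$i)
    sp <- split(g$cell_ids[dst], g$cell_ids[src])
    out[names(sp)] <- lapply(sp, sort)
  }
  out
}

#' Export a neighbor graph as an edge list
#'
#' @param g a `neighbor_graph`.
#' @param file optional path; when given the edge list is also written as
#'   CSV.
#' @return data.frame(image_id, source, target, distance_um); for knn graphs
#'   one row per directed link in rank order.
#' @export
graph_edges <- function(g, file = NULL) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$rule == "knn") {
    lens <- lengths(g$nn$idx)
    df <- data.frame(
      image_id = g$image_id,
      source = rep(g$nn$query_ids, lens),
      target = g$cell_ids[unlist(g$nn$idx)],
      distance_um = unlist(g$nn$d), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(image_id = g$image_id,
                     source = g$cell_ids[g$edges$i],
                     target = g$cell_ids[g$edges$j],
                     distance_um = g$edges$d, stringsAsFactors = FALSE)
  }
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  df
}
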