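# Semi-metric network analysis: distance conversion, all-pairs shortest
# paths, semi-metricity ratios and labels, semi-metric percentage (SMP)
# at global and regional level, and shared-path accounting.
#
# An edge (i, j) is semi-metric when its direct distance l_ij exceeds the
# shortest indirect route l'_ij (a triangle-inequality violation in the
# distance graph); the metric backbone (edges with s_ij = l_ij / l'_ij = 1)
# alone reproduces every shortest-path length.

#' Convert a coherence matrix to a distance graph
#'
#' Distance conversion `l_ij = 1 / x_ij - 1`, mapping coherence 1 to
#' distance 0 and coherence 0.5 to distance 1. Weights below `eps` are
#' clamped to `eps` (a very long but finite edge) so the edge count of the
#' complete network is preserved.
#'
#' @param fc An [fc_matrix()] (or a plain symmetric weight matrix).
#' @param eps Clamp floor for near-zero weights (default `1e-6`).
#' @return A `distance_graph`: list with `lengths` (matrix, diagonal 0),
#'   `node_ids`, `n`.
#' @export
to_distance <- function(fc, eps = 1e-6) {
  if (eps <= 0) stop("eps must be positive")
  w <- if (inherits(fc, "fc_matrix")) fc$weights else as.matrix(fc)
  ids <- if (inherits(fc, "fc_matrix")) fc$channel_ids else
    (rownames(w) %||% paste0("n", seq_len(nrow(w))))
  off <- w[row(w) != col(w)]
  if (any(off < 0 | off > 1, na.rm = TRUE)) {
    ij <- which((w < 0 | w > 1) & row(w) != col(w), arr.ind = TRUE)[1, ]
    stop(sprintf("weight outside [0,1] at pair (%s, %s)",
                 ids[ij[1]], ids[ij[2]]))
  }
  l <- 1 / pmax(w, eps) - 1
  diag(l) <- 0
  dimnames(l) <- list(ids, ids)
  structure(list(lengths = l, node_ids = ids, n = nrow(l)),
            class = "distance_graph")
}

#' All-pairs shortest paths
#'
#' Exact all-pairs shortest-path lengths on a non-negative symmetric
#' distance graph, with one reconstructed path per pair. Uses
#' Floyd-Warshall with strict-improvement updates applied in ascending
#' intermediate-node order, which makes path reconstruction (and hence the
#' shared-path histogram) deterministic.
#'
#' @param dg A `distance_graph` from [to_distance()].
#' @return A `shortest_path_result`: `dist` (matrix `l'_ij`), `hops`
#'   (edge count of the reconstructed path), `via` (last improving
#'   intermediate node, 0 = direct edge), `node_ids`, `n`.
#' @export
all_pairs_shortest <- function(dg) {
  stopifnot(inherits(dg, "distance_graph"))
  d <- dg$lengths
  if (any(d < 0)) stop("negative edge length")
  n <- dg$n
  via <- matrix(0L, n, n)
  for (k in seq_len(n)) {
    nd <- outer(d[, k], d[k, ], "+")
    upd <- nd < d
    upd[k, ] <- FALSE; upd[, k] <- FALSE; diag(upd) <- FALSE
    if (any(upd)) {
      d[upd] <- nd[upd]
      via[upd] <- k
    }
  }
  hops <- matrix(1L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- length(reconstruct_path(via, i, j)) - 1L
    hops[i, j] <- hops[j, i] <- h
  }
  diag(hops) <- 0L
  dimnames(d) <- dimnames(dg$lengths)
  structure(list(dist = d, hops = hops, via = via,
                 node_ids = dg$node_ids, n = n),
            class = "shortest_path_result")
}

#' Reconstruct one shortest path
#'
#' @param sp_or_via A `shortest_path_result` (or its `via` matrix).
#' @param i,j Node indices.
#' @return Integer vector of node indices from `i` to `j`.
#' @export
reconstruct_path <- function(sp_or_via, i, j) {
  via <- if (is.matrix(sp_or_via)) sp_or_via else sp_or_via$via
  rec <- function(a, b) {
    k <- via[a, b]
    if (k == 0L) return(c(a, b))
    left <- rec(a, k)
    c(left[-length(left)], rec(k, b))
  }
  rec(i, j)
}

#' Semi-metricity ratios and edge labels
#'
#' Ratio `s_ij = l_ij / l'_ij` per edge; edges with `s_ij > 1 + tol` are
#' semi-metric (their direct route is beaten by an indirect one), the rest
#' form the metric backbone. Ties count as metric.
#'
#' @param dg A `distance_graph`.
#' @param sp The matching [all_pairs_shortest()] result.
#' @param tol Relative tolerance of the label test (default `1e-9`).
#' @return A `semimetric_result`: `ratio` matrix, `labels` character
#'   matrix (`"metric"`/`"semi_metric"`, diagonal `NA`), `n_semimetric`,
#'   `E` (unordered edge count), `smp_global`, `hops`, plus the inputs'
#'   node ids.
#' @export
semimetric_ratio <- function(dg, sp, tol = 1e-9) {
  stopifnot(inherits(dg, "distance_graph"),
            inherits(sp, "shortest_path_result"))
  l <- dg$lengths; lp <- sp$dist
  if (any(lp == 0 & l > 0 & row(l) != col(l)))
    stop("internal error: zero shortest path for a positive-length pair")
  s <- matrix(1, dg$n, dg$n)
  pos <- lp > 0
  s[pos] <- l[pos] / lp[pos]
  diag(s) <- NA_real_
  labels <- matrix(ifelse(s > 1 + tol, "semi_metric", "metric"),
                   dg$n, dg$n)
  diag(labels) <- NA_character_
  up <- upper.tri(s)
  n_semi <- sum(labels[up] == "semi_metric")
  E <- sum(up)
  dimnames(s) <- dimnames(labels) <- dimnames(l)
  structure(list(ratio = s, labels = labels, n_semimetric = n_semi, E = E,
                 smp_global = n_semi / E, hops = sp$hops,
                 node_ids = dg$node_ids, n = dg$n, tol = tol),
            class = "semimetric_result")
}

#' Semi-metric percentage
#'
#' Fraction of edges that are semi-metric: count of `s_ij > 1` over the
#' total number of connections `E` in the original network.
#'
#' @param res A `semimetric_result`.
#' @return Scalar in `[0, 1]`.
#' @export
smp <- function(res) {
  stopifnot(inherits(res, "semimetric_result"))
  if (res$E == 0) stop("network has no edges")
  res$smp_global
}

#' Regional semi-metric percentage
#'
#' SMP restricted to edges with both endpoints inside an ROI (denominator
#' = intra-ROI edge count). Channels listed in `exclusions` are dropped
#' before counting, as done for hemispheric contrasts.
#'
#' @param res A `semimetric_result`.
#' @param roi_map Named character vector: node id -> ROI label.
#' @param exclusions Node ids to drop (default none).
#' @return Named numeric vector, one SMP per ROI.
#' @export
regional_smp <- function(res, roi_map, exclusions = character()) {
  stopifnot(inherits(res, "semimetric_result"))
  rois <- unique(roi_map)
  out <- stats::setNames(numeric(length(rois)), rois)
  for (r in rois) {
    members <- setdiff(names(roi_map)[roi_map == r], exclusions)
    idx <- match(members, res$node_ids)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2)
      stop(sprintf("ROI '%s' has fewer than 2 member nodes after exclusions", r))
    sub <- res$labels[idx, idx]
    up <- upper.tri(sub)
    out[r] <- sum(sub[up] == "semi_metric") / sum(up)
  }
  out
}

#' Shared-path histogram
#'
#' Histogram of the number of nodes in each pair's reconstructed shortest
#' path. Paths with more than two nodes route information through
#' intermediate channels ("shared paths"); their fraction summarizes how
#' much of the network's information flow is indirect.
#'
#' @param sp An [all_pairs_shortest()] result (a `semimetric_result` also
#'   works, via its stored hop counts).
#' @return List with `counts` (named vector, names = nodes per path),
#'   `fraction_gt2` (fraction of pairs whose path has > 2 nodes),
#'   `n_pairs`.
#' @export
shared_path_histogram <- function(sp) {
  hops <- sp$hops
  up <- upper.tri(hops)
  nodes_per_path <- hops[up] + 1L
  counts <- table(factor(nodes_per_path, levels = sort(unique(nodes_per_path))))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       fraction_gt2 = mean(nodes_per_path > 2),
       n_pairs = sum(up))
}

#' Full semi-metric analysis of a connectivity matrix
#'
#' Chains [to_distance()], [all_pairs_shortest()], [semimetric_ratio()],
#' [regional_smp()] (when an ROI map is available) and
#' [shared_path_histogram()].
#'
#' @param fc An [fc_matrix()].
#' @param eps,tol See [to_distance()] and [semimetric_ratio()].
#' @return List with `distance`, `shortest`, `result`, `smp_global`,
#'   `smp_regional` (or `NULL`), `histogram`.
#' @export
semimetric_analysis <- function(fc, eps = 1e-6, tol = 1e-9) {
  dg <- to_distance(fc, eps = eps)
  sp <- all_pairs_shortest(dg)
  res <- semimetric_ratio(dg, sp, tol = tol)
  reg <- NULL
  if (inherits(fc, "fc_matrix") && !is.null(fc$roi_map))
    reg <- regional_smp(res, fc$roi_map, exclusions = fc$hemisphere_excluded)
  list(distance = dg, shortest = sp, result = res,
       smp_global = res$smp_global, smp_regional = reg,
       histogram = shared_path_histogram(sp))
}

#' Edge table of a semi-metric analysis
#'
#' @param dg A `distance_graph`.
#' @param sp The matching shortest-path result.
#' @param res The matching `semimetric_result`.
#' @param weights Optional original weight matrix to include as column `x`.
#' @return Data frame with one row per unordered edge: `i`, `j`, `x`,
#'   `l`, `l_prime`, `s`, `label`.
#' @export
semimetric_edge_table <- function(dg, sp, res, weights = NULL) {
  up <- which(upper.tri(dg$lengths), arr.ind = TRUE)
  data.frame(
    i = dg$node_ids[up[, 1]],
    j = dg$node_ids[up[, 2]],
    x = if (is.null(weights)) NA_real_ else weights[up],
    l = dg$lengths[up],
    l_prime = sp$dist[up],
    s = res$ratio[up],
    label = res$labels[up],
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
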