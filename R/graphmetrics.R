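# Weighted graph-theory benchmark on the unthresholded connectivity
# network: clustering coefficient, characteristic path length, global,
# local and nodal efficiency, globally and per ROI.
#
# Distances default to the same coherence-to-distance conversion
# (l = 1/x - 1) used by the semi-metric branch; `length_method =
# "inverse"` (l = 1/x) is available for parity with binary-graph
# conventions, where a weight of 1 is a unit-length edge.

graph_weights <- function(fc) {
  w <- if (inherits(fc, "fc_matrix")) fc$weights else as.matrix(fc)
  diag(w) <- 0
  w
}

graph_distances <- function(w, length_method = c("coherence", "inverse"),
                            eps = 1e-6) {
  length_method <- match.arg(length_method)
  l <- if (length_method == "coherence") 1 / pmax(w, eps) - 1
       else 1 / pmax(w, eps)
  l[w <= 0] <- Inf        # absent edge
  diag(l) <- 0
  l
}

# Floyd-Warshall on a plain length matrix (tolerates Inf)
fw_dist <- function(l) {
  n <- nrow(l)
  d <- l
  for (k in seq_len(n)) {
    nd <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, nd)
  }
  d
}

#' Weighted clustering coefficient
#'
#' Per-node clustering via geometric-mean triangle intensity on weights
#' normalized by the network maximum:
#' `C_i = sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))` with
#' `w' = w / max(w)` and `k_i` the number of neighbors. On a binary graph
#' this reduces to the classical `2m / (k_i (k_i - 1))` triangle count.
#' Nodes with fewer than 2 neighbors score 0.
#'
#' @param fc An [fc_matrix()] or weight matrix.
#' @return List with `cc` (network mean) and `per_node`.
#' @export
clustering_coefficient <- function(fc) {
  w <- graph_weights(fc)
  n <- nrow(w)
  if (n < 3) stop("clustering needs at least 3 nodes")
  mx <- max(w)
  if (mx <= 0) return(list(cc = 0, per_node = numeric(n)))
  wn <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wn %*% wn %*% wn)          # 2 x sum of triangle intensities
  per <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  list(cc = mean(per), per_node = per)
}

#' Characteristic path length
#'
#' Mean over nodes of the mean shortest-path distance to every other
#' node: `lambda = (1/N) sum_i sum_{j != i} d_ij / (N - 1)`.
#'
#' @param sp An [all_pairs_shortest()] result, or a distance matrix.
#' @return Scalar distance.
#' @export
characteristic_path_length <- function(sp) {
  d <- if (inherits(sp, "shortest_path_result")) sp$dist else as.matrix(sp)
  n <- nrow(d)
  off <- d[row(d) != col(d)]
  if (any(!is.finite(off))) {
    bad <- which(!is.finite(d) & row(d) != col(d), arr.ind = TRUE)
    stop("disconnected pairs: ",
         paste(apply(bad[seq_len(min(5, nrow(bad))), , drop = FALSE], 1,
                     paste, collapse = "-"), collapse = ", "))
  }
  mean(rowSums(d) / (n - 1))
}

#' Global efficiency
#'
#' Inverse of the harmonic mean of shortest-path lengths:
#' `E_global = (1/(N(N-1))) sum_{i != j} 1 / d_ij`. Zero-distance pairs
#' (coherence exactly 1 before clamping) contribute through the declared
#' `cap`; disconnected pairs contribute 0.
#'
#' @param sp Shortest-path result or distance matrix.
#' @param cap Upper bound on any single `1/d` term (default `1/1e-6`,
#'   the inverse of the weight clamp's distance floor).
#' @return Scalar.
#' @export
global_efficiency <- function(sp, cap = 1e6) {
  d <- if (inherits(sp, "shortest_path_result")) sp$dist else as.matrix(sp)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  inv <- 1 / d
  inv[!is.finite(inv) | inv > cap] <- cap
  inv[!is.finite(d)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's
#' neighbor-induced subgraph, with distances recomputed inside the
#' subgraph. Nodes with fewer than 2 neighbors contribute 0.
#'
#' @param fc An [fc_matrix()] or weight matrix.
#' @param length_method `"coherence"` (default, `l = 1/x - 1`) or
#'   `"inverse"` (`l = 1/x`).
#' @return Scalar.
#' @export
local_efficiency <- function(fc, length_method = "coherence") {
  w <- graph_weights(fc)
  n <- nrow(w)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    sub <- w[nb, nb, drop = FALSE]
    dsub <- fw_dist(graph_distances(sub, length_method))
    per[i] <- global_efficiency(dsub)
  }
  mean(per)
}

#' Nodal efficiency
#'
#' Per node, `E_nodal(i) = (1/(N-1)) sum_{j != i} 1 / d_ij` on the full
#' graph; ROI values are means over member nodes after exclusions.
#'
#' @param sp Shortest-path result or distance matrix.
#' @param roi_map Optional named character vector node id -> ROI.
#' @param exclusions Node ids dropped from ROI means.
#' @param cap As in [global_efficiency()].
#' @return List with `per_node` and (when `roi_map` given) `regional`.
#' @export
nodal_efficiency <- function(sp, roi_map = NULL, exclusions = character(),
                             cap = 1e6) {
  d <- if (inherits(sp, "shortest_path_result")) sp$dist else as.matrix(sp)
  ids <- if (inherits(sp, "shortest_path_result")) sp$node_ids else
    (rownames(d) %||% paste0("n", seq_len(nrow(d))))
  n <- nrow(d)
  inv <- 1 / d
  inv[!is.finite(inv) | inv > cap] <- cap
  inv[!is.finite(d)] <- 0
  diag(inv) <- 0
  per <- rowSums(inv) / (n - 1)
  names(per) <- ids
  out <- list(per_node = per)
  if (!is.null(roi_map)) {
    rois <- unique(roi_map)
    reg <- stats::setNames(numeric(length(rois)), rois)
    for (r in rois) {
      members <- setdiff(names(roi_map)[roi_map == r], exclusions)
      members <- intersect(members, ids)
      if (!length(members)) stop(sprintf("ROI '%s' is empty", r))
      reg[r] <- mean(per[members])
    }
    out$regional <- reg
  }
  out
}

#' Global and regional graph-metric benchmark
#'
#' Computes the weighted graph-theory indices on the unthresholded
#' network: global clustering coefficient, characteristic path length,
#' global and local efficiency; and per ROI (induced subgraphs for CC and
#' lambda; full-graph nodal efficiency averaged over members, exclusions
#' applied).
#'
#' @param fc An [fc_matrix()].
#' @param length_method See [local_efficiency()].
#' @param eps Weight clamp floor for the distance conversion.
#' @return A `graph_metrics_result`: list with `global` (named list `cc`,
#'   `lambda`, `e_global`, `e_local`) and `regional` (per-ROI named lists
#'   `cc`, `lambda`, `e_nodal`) when an ROI map is available.
#' @export
graph_metrics <- function(fc, length_method = "coherence", eps = 1e-6) {
  stopifnot(inherits(fc, "fc_matrix"))
  w <- graph_weights(fc)
  d <- fw_dist(graph_distances(w, length_method, eps = eps))
  glob <- list(
    cc = clustering_coefficient(w)$cc,
    lambda = characteristic_path_length(d),
    e_global = global_efficiency(d),
    e_local = local_efficiency(w, length_method))
  regional <- NULL
  if (!is.null(fc$roi_map)) {
    ids <- fc$channel_ids
    dimnames(d) <- list(ids, ids)
    ne <- nodal_efficiency(structure(list(dist = d, node_ids = ids, n = nrow(d)),
                                     class = "shortest_path_result"),
                           roi_map = fc$roi_map,
                           exclusions = fc$hemisphere_excluded)
    regional <- list()
    for (r in unique(fc$roi_map)) {
      members <- setdiff(names(fc$roi_map)[fc$roi_map == r],
                         fc$hemisphere_excluded)
      idx <- match(intersect(members, ids), ids)
      sub <- w[idx, idx, drop = FALSE]
      dsub <- fw_dist(graph_distances(sub, length_method, eps = eps))
      regional[[r]] <- list(
        cc = clustering_coefficient(sub)$cc,
        lambda = characteristic_path_length(dsub),
        e_nodal = unname(ne$regional[r]))
    }
  }
  structure(list(global = glob, regional = regional),
            class = "graph_metrics_result")
}
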