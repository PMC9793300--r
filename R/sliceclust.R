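#' Per-slice clustering parameters
#'
#' @param clustering_threshold dendrogram cut height for average-linkage
#'   clustering of tunnel pathways (Angstrom, default 3.0)
#' @param n_resample_points number of arc-length-uniform points each pathway
#'   is resampled to before distances are computed
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(clustering_threshold = 3.0,
                           n_resample_points = 20L) {
  stopifnot(clustering_threshold > 0, n_resample_points >= 2)
  structure(list(clustering_threshold = clustering_threshold,
                 n_resample_points = as.integer(n_resample_points),
                 linkage = "average"),
            class = "cluster_params")
}

#' Resample a pathway to k arc-length-uniform points
#'
#' Linear interpolation along the polyline; endpoints are preserved exactly.
#' Radii, when present, are interpolated the same way.
#'
#' @param profile list with `nodes` (m x 3) and optionally `radii`
#' @param k number of output points (>= 2)
#' @return List with `nodes` (k x 3) and `radii` (length k, or NULL).
#' @export
resample_path <- function(profile, k = 20L) {
  stopifnot(k >= 2L)
  nodes <- profile$nodes
  s <- cumulative_length(nodes)
  L <- s[length(s)]
  target <- seq(0, L, length.out = k)
  if (L == 0) {
    out <- nodes[rep(1L, k), , drop = FALSE]
    r <- if (!is.null(profile$radii)) rep(profile$radii[1], k) else NULL
    return(list(nodes = out, radii = r))
  }
  out <- vapply(1:3, function(d) approx(s, nodes[, d], xout = target,
                                        ties = "ordered")$y,
                numeric(k))
  r <- if (!is.null(profile$radii))
    approx(s, profile$radii, xout = target, ties = "ordered")$y else NULL
  list(nodes = matrix(out, ncol = 3L), radii = r)
}

#' Pathway distance between two tunnels
#'
#' Mean Euclidean distance between order-aligned resampled points, both paths
#' oriented start-to-exit. Symmetric, non-negative, zero for identical paths.
#' This is the metric under the per-slice clustering threshold.
#'
#' @param a,b `tunnel` objects (or lists with `nodes`)
#' @param k number of resample points
#' @return Distance in Angstrom.
#' @export
tunnel_distance <- function(a, b, k = 20L) {
  pa <- resample_path(a, k)$nodes
  pb <- resample_path(b, k)$nodes
  mean(sqrt(rowSums((pa - pb)^2)))
}

# flatten a list of tunnels into an n x 3k resampled-path matrix
.resampled_matrix <- function(tunnels, k) {
  t(vapply(tunnels, function(tu) as.vector(t(resample_path(tu, k)$nodes)),
           numeric(3L * k)))
}

# dist object of pairwise path distances (C++ kernel)
.path_dist <- function(tunnels, k) {
  n <- length(tunnels)
  v <- .path_distmat_cpp(.resampled_matrix(tunnels, k))
  attributes(v) <- list(Size = n, Diag = FALSE, Upper = FALSE,
                        method = "mean_point", class = "dist")
  v
}

#' Construct a tunnel cluster
#'
#' A slice-scoped set of tunnels. Per-frame statistics use one representative
#' tunnel per frame: the highest-throughput member in that frame. The
#' representative path is the point-wise mean of the members' resampled
#' pathways.
#'
#' @param tunnels non-empty list of `tunnel` objects
#' @param slice_index slice the cluster belongs to
#' @param cluster_id 1-based id within the slice
#' @param k resample points for the representative path
#' @return Object of class `tunnel_cluster` with fields `tunnels`,
#'   `frames_present`, `table` (per-frame representative stats),
#'   `representative_path` (list nodes/radii).
#' @export
new_tunnel_cluster <- function(tunnels, slice_index = 1L, cluster_id = 1L,
                               k = 20L) {
  stopifnot(length(tunnels) >= 1L)
  tab <- data.frame(
    frame = vapply(tunnels, `[[`, integer(1), "frame_number"),
    bottleneck = vapply(tunnels, `[[`, numeric(1), "bottleneck"),
    length = vapply(tunnels, `[[`, numeric(1), "length"),
    cost = vapply(tunnels, `[[`, numeric(1), "cost"),
    throughput = vapply(tunnels, `[[`, numeric(1), "throughput"))
  # per-frame representative: highest throughput, ties by original order
  ord <- order(tab$frame, -tab$throughput)
  rep_rows <- ord[!duplicated(tab$frame[ord])]
  rs <- lapply(tunnels, resample_path, k = k)
  rp_nodes <- Reduce(`+`, lapply(rs, `[[`, "nodes")) / length(rs)
  rp_radii <- Reduce(`+`, lapply(rs, `[[`, "radii")) / length(rs)
  structure(list(slice_index = as.integer(slice_index),
                 cluster_id = as.integer(cluster_id),
                 tunnels = tunnels,
                 frames_present = sort(unique(tab$frame)),
                 table = tab,
                 representative_rows = rep_rows,
                 representative_path = list(nodes = rp_nodes,
                                            radii = rp_radii)),
            class = "tunnel_cluster")
}

#' @export
print.tunnel_cluster <- function(x, ...) {
  cat(sprintf("tunnel_cluster %d (slice %d): %d tunnels in %d frames\n",
              x$cluster_id, x$slice_index, length(x$tunnels),
              length(x$frames_present)))
  invisible(x)
}

# per-frame representative stats of a cluster (one row per frame)
.rep_table <- function(cluster) {
  cluster$table[cluster$representative_rows, , drop = FALSE]
}

#' Cluster the tunnels of one slice
#'
#' Average-linkage agglomerative clustering on the pathway distance
#' ([tunnel_distance()]), with the dendrogram cut at `clustering_threshold`.
#' Clusters are numbered 1..m by descending raw priority over the slice's
#' frames (before any filtering). The result is invariant to the input order:
#' tunnels are sorted by (frame_number, input index) first.
#'
#' @param tunnels list of `tunnel` objects, all from one slice
#' @param params a [cluster_params()] object
#' @param slice_index slice index recorded on the clusters
#' @param n_slice_frames number of frames in the slice (used for the raw
#'   priority that orders cluster ids); defaults to the number of distinct
#'   frames seen
#' @return List of `tunnel_cluster` objects, ids 1..m by descending priority.
#' @export
cluster_slice <- function(tunnels, params = cluster_params(),
                          slice_index = 1L, n_slice_frames = NULL) {
  if (length(tunnels) == 0L) return(list())
  frames <- vapply(tunnels, `[[`, integer(1), "frame_number")
  tunnels <- tunnels[order(frames, seq_along(tunnels))]
  if (is.null(n_slice_frames)) n_slice_frames <- length(unique(frames))
  k <- params$n_resample_points
  if (length(tunnels) == 1L) {
    memb <- 1L
  } else {
    d <- .path_dist(tunnels, k)
    memb <- cutree(hclust(d, method = "average"),
                   h = params$clustering_threshold)
  }
  groups <- split(seq_along(tunnels), memb)
  clusters <- lapply(groups, function(ix)
    new_tunnel_cluster(tunnels[ix], slice_index = slice_index, k = k))
  pri <- vapply(clusters, priority, numeric(1), n = n_slice_frames)
  first_fr <- vapply(clusters, function(cl) cl$frames_present[1], integer(1))
  ord <- order(-pri, first_fr)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i
  clusters
}

#' @importFrom stats approx
NULL
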