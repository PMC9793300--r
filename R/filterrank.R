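#' Relative presence of a cluster in its slice
#'
#' Fraction of the slice's frames in which the cluster has at least one
#' tunnel. This is the filtering statistic: clusters made of sporadic
#' single-tunnel detections have near-zero presence and are noise.
#'
#' @param cluster a `tunnel_cluster`
#' @param n_slice_frames number of frames in the slice (> 0)
#' @return Fraction in `[0, 1]`.
#' @export
presence <- function(cluster, n_slice_frames) {
  n_slice_frames <- as.integer(n_slice_frames)
  if (n_slice_frames <= 0L) stop("n_slice_frames must be positive", call. = FALSE)
  if (length(cluster$frames_present) > n_slice_frames)
    stop("cluster spans more frames than the slice has", call. = FALSE)
  length(cluster$frames_present) / n_slice_frames
}

#' Priority of a cluster: mean throughput over frames
#'
#' `P_i = (sum_j T_j) / n`, where `T_j` is the throughput of the cluster's
#' representative (highest-throughput) tunnel in frame j and `n` is the total
#' number of frames in the scope being ranked; a frame where the cluster has
#' no tunnel contributes 0. The scope is the slice for per-slice ranking and
#' the whole trajectory for merged ranking.
#'
#' @param cluster a `tunnel_cluster` (or `super_cluster`)
#' @param n number of frames in the ranking scope (>= 1)
#' @return Priority in `[0, 1]`.
#' @export
priority <- function(cluster, n) {
  stopifnot(n >= 1)
  sum(.rep_table(cluster)$throughput) / n
}

#' Filter clusters by minimum presence
#'
#' Keeps clusters whose presence is at least `min_presence` (inclusive:
#' a cluster fails only when it does not reach the threshold). Order is
#' preserved. The default 2% is the standard exploratory threshold.
#'
#' @param clusters list of `tunnel_cluster` objects
#' @param min_presence presence threshold in `[0, 1]`
#' @param n_slice_frames number of frames in the slice
#' @return The kept sublist.
#' @export
filter_clusters <- function(clusters, min_presence = 0.02, n_slice_frames) {
  stopifnot(min_presence >= 0, min_presence <= 1)
  keep <- vapply(clusters, function(cl)
    presence(cl, n_slice_frames) >= min_presence, logical(1))
  clusters[keep]
}

#' Renumber clusters by descending priority
#'
#' After filtering, surviving clusters are renumbered 1..m by rank: new id 1
#' is the highest-priority cluster. Ties are broken by ascending old id. The
#' old-to-new id mapping is returned alongside the renumbered clusters.
#'
#' @param clusters list of `tunnel_cluster` objects (the kept set)
#' @param n number of frames in the ranking scope
#' @param n_presence_frames number of frames used for the reported presence
#'   (defaults to `n`)
#' @return List with `clusters` (reordered, `cluster_id` rewritten; the
#'   previous id is kept in `$old_id`) and `map`, a data frame with columns
#'   `old_id`, `new_id`, `presence`, `priority`.
#' @export
renumber_by_priority <- function(clusters, n, n_presence_frames = n) {
  if (length(clusters) == 0L)
    return(list(clusters = list(),
                map = data.frame(old_id = integer(), new_id = integer(),
                                 presence = numeric(), priority = numeric())))
  old_id <- vapply(clusters, `[[`, integer(1), "cluster_id")
  pri <- vapply(clusters, priority, numeric(1), n = n)
  pres <- vapply(clusters, presence, numeric(1),
                 n_slice_frames = n_presence_frames)
  ord <- order(-pri, old_id)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$old_id <- old_id[ord][i]
    clusters[[i]]$cluster_id <- i
  }
  list(clusters = clusters,
       map = data.frame(old_id = old_id[ord], new_id = seq_along(ord),
                        presence = pres[ord], priority = pri[ord]))
}
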