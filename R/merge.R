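#' Distance between two tunnel clusters
#'
#' Mean Euclidean distance between the order-aligned resampled representative
#' paths of the two clusters (both oriented start-to-exit). This is the metric
#' the Ward merge operates on.
#'
#' @param a,b `tunnel_cluster` (or `super_cluster`) objects whose
#'   representative paths were computed with the same number of points
#' @return Distance in Angstrom.
#' @export
cluster_pair_distance <- function(a, b) {
  pa <- a$representative_path$nodes
  pb <- b$representative_path$nodes
  stopifnot(nrow(pa) == nrow(pb))
  mean(sqrt(rowSums((pa - pb)^2)))
}

#' Construct a supercluster from member clusters
#'
#' Members typically come from different slices, whose frame sets are
#' disjoint by construction. Per-frame statistics use the representative
#' (highest-throughput) tunnel over all members, so a frame never contributes
#' twice even if two same-slice clusters were merged.
#'
#' @param members non-empty list of `tunnel_cluster` objects
#' @param super_id 1-based id (assigned by descending priority)
#' @return Object of class `super_cluster`.
#' @export
new_super_cluster <- function(members, super_id = 1L) {
  stopifnot(length(members) >= 1L)
  tab <- do.call(rbind, lapply(members, `[[`, "table"))
  ord <- order(tab$frame, -tab$throughput)
  rep_rows <- ord[!duplicated(tab$frame[ord])]
  rp_n <- Reduce(`+`, lapply(members, function(m) m$representative_path$nodes)) /
    length(members)
  rp_r <- Reduce(`+`, lapply(members, function(m) m$representative_path$radii)) /
    length(members)
  structure(list(super_id = as.integer(super_id), members = members,
                 frames_present = sort(unique(tab$frame)),
                 table = tab, representative_rows = rep_rows,
                 representative_path = list(nodes = rp_n, radii = rp_r)),
            class = "super_cluster")
}

#' @export
print.super_cluster <- function(x, ...) {
  st <- compute_stats(x)
  cat(sprintf(
    "super_cluster %d: %d members, %d frames, avg bottleneck %.3f A, avg length %.2f A\n",
    x$super_id, length(x$members), st$n_frames, st$avg_bottleneck,
    st$avg_length))
  invisible(x)
}

#' Merge per-slice clusters into superclusters
#'
#' Ward-linkage hierarchical clustering (Lance-Williams update on squared
#' distances, `stats::hclust` method `ward.D2`) on the pairwise
#' representative-path distances ([cluster_pair_distance()]), with the
#' dendrogram cut at `cutoff` (default 1.0 Angstrom). Superclusters are
#' numbered by descending priority computed over the TOTAL frame count of the
#' trajectory. The result does not depend on the order clusters are supplied
#' in: they are sorted by (slice_index, cluster_id) first.
#'
#' @param clusters list of kept `tunnel_cluster` objects from all slices
#' @param cutoff Ward dendrogram cut height (Angstrom)
#' @param total_frames total number of frames in the trajectory (priority
#'   scope)
#' @return List of `super_cluster` objects ordered by descending priority,
#'   each with a `priority` field.
#' @export
merge_superclusters <- function(clusters, cutoff = 1.0, total_frames) {
  if (length(clusters) == 0L) return(list())
  stopifnot(total_frames >= 1)
  ord <- order(vapply(clusters, `[[`, integer(1), "slice_index"),
               vapply(clusters, `[[`, integer(1), "cluster_id"))
  clusters <- clusters[ord]
  n <- length(clusters)
  if (n == 1L) {
    memb <- 1L
  } else {
    reps <- t(vapply(clusters,
                     function(cl) as.vector(t(cl$representative_path$nodes)),
                     numeric(3L * nrow(clusters[[1]]$representative_path$nodes))))
    v <- .path_distmat_cpp(reps)
    attributes(v) <- list(Size = n, Diag = FALSE, Upper = FALSE,
                          method = "mean_point", class = "dist")
    memb <- cutree(hclust(v, method = "ward.D2"), h = cutoff)
  }
  groups <- split(seq_len(n), memb)
  scs <- lapply(groups, function(ix) new_super_cluster(clusters[ix]))
  pri <- vapply(scs, priority, numeric(1), n = total_frames)
  first_fr <- vapply(scs, function(s) s$frames_present[1], integer(1))
  o <- order(-pri, first_fr)
  scs <- scs[o]
  for (i in seq_along(scs)) {
    scs[[i]]$super_id <- i
    scs[[i]]$priority <- pri[o][i]
  }
  scs
}

#' Summary statistics of a supercluster
#'
#' Computed over the per-frame representative tunnels of all members:
#' `n_frames` distinct frames, mean bottleneck, mean length, and maximal
#' bottleneck (the familiar per-cluster summary-table columns).
#'
#' @param sc a `super_cluster` (or `tunnel_cluster`)
#' @return Data frame row with columns `n_frames`, `avg_bottleneck`,
#'   `avg_length`, `max_bottleneck`.
#' @export
compute_stats <- function(sc) {
  rt <- .rep_table(sc)
  data.frame(n_frames = nrow(rt), avg_bottleneck = mean(rt$bottleneck),
             avg_length = mean(rt$length), max_bottleneck = max(rt$bottleneck))
}

#' Match two clusterings of the same ensemble
#'
#' Many-to-many correspondence: a reference cluster and an other cluster
#' match when their representative paths lie within `tol` of each other
#' ([cluster_pair_distance()]); each match reports the Jaccard overlap of the
#' two frame sets. Used to check that a sliced run reproduces a full run,
#' where one reference cluster may legitimately map to several superclusters.
#'
#' @param reference,other lists of `super_cluster` / `tunnel_cluster` objects
#' @param tol match tolerance in Angstrom (default: the usual merge cutoff)
#' @return Data frame with columns `ref_id`, `other_id`, `distance`,
#'   `jaccard`, one row per matched pair.
#' @export
match_clusterings <- function(reference, other, tol = 1.0) {
  out <- data.frame(ref_id = integer(), other_id = integer(),
                    distance = numeric(), jaccard = numeric())
  id_of <- function(x) if (!is.null(x$super_id)) x$super_id else x$cluster_id
  for (a in reference) for (b in other) {
    d <- cluster_pair_distance(a, b)
    if (d <= tol) {
      fa <- a$frames_present; fb <- b$frames_present
      j <- length(intersect(fa, fb)) / length(union(fa, fb))
      out <- rbind(out, data.frame(ref_id = id_of(a), other_id = id_of(b),
                                   distance = d, jaccard = j))
    }
  }
  out
}
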