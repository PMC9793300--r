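# Independent brute-force oracles. These deliberately re-derive every step
# from first principles (naive O(n^3) agglomeration, union-find flood fill)
# and share no code with the implementation they check.

# average-linkage agglomeration on a distance matrix, merging while the
# smallest between-cluster mean distance is <= h; returns memberships
oracle_average_cut <- function(D, h) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  repeat {
    if (length(groups) == 1L) break
    best <- c(Inf, 0, 0)
    for (i in seq_along(groups)[-1]) for (j in seq_len(i - 1L)) {
      lk <- mean(D[groups[[i]], groups[[j]]])
      if (lk < best[1]) best <- c(lk, j, i)
    }
    if (best[1] > h) break
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  memb <- integer(n)
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  memb
}

# Ward agglomeration via the Lance-Williams recursion on squared distances
# (the ward.D2 convention: merge heights are the square roots); merges while
# the smallest merge height is <= h
oracle_ward_cut <- function(D, h) {
  n <- nrow(D)
  W <- D^2
  groups <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- seq_len(n)
  repeat {
    if (length(active) == 1L) break
    best <- c(Inf, 0, 0)
    for (ii in seq_along(active)[-1]) for (jj in seq_len(ii - 1L)) {
      a <- active[ii]; b <- active[jj]
      if (sqrt(W[a, b]) < best[1]) best <- c(sqrt(W[a, b]), b, a)
    }
    if (best[1] > h) break
    i <- best[2]; j <- best[3]
    # Lance-Williams update of squared distances for Ward
    for (kk in active) {
      if (kk == i || kk == j) next
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[kk]
      W[i, kk] <- W[kk, i] <-
        ((ni + nk) * W[i, kk] + (nj + nk) * W[j, kk] - nk * W[i, j]) /
        (ni + nj + nk)
    }
    groups[[i]] <- c(groups[[i]], groups[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  memb <- integer(n)
  for (g in seq_along(active)) memb[groups[[active[g]]]] <- g
  memb
}

# max-min-clearance flood fill on a dense grid: the widest probe that can
# travel from `start` to any point with x > x_exit inside the box. Clearance
# is evaluated exactly per grid point; connectivity is 6-neighbour via
# union-find over nodes activated in order of decreasing clearance.
oracle_grid_bottleneck <- function(coords, vdw, start, box_lo, box_hi,
                                   x_exit, step = 0.25) {
  ax <- lapply(1:3, function(d) seq(box_lo[d], box_hi[d], by = step))
  dims <- lengths(ax)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  cl <- clearance_at(coords, vdw, pts)
  nid <- function(i, j, k) (k - 1L) * dims[1] * dims[2] + (j - 1L) * dims[1] + i
  start_i <- vapply(1:3, function(d) which.min(abs(ax[[d]] - start[d])), integer(1))
  start_id <- nid(start_i[1], start_i[2], start_i[3])
  exit_ids <- which(pts[, 1] > x_exit)
  parent <- seq_len(nrow(pts))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  active <- logical(nrow(pts))
  ord <- order(cl, decreasing = TRUE)
  exit_mark <- logical(nrow(pts)); exit_mark[exit_ids] <- TRUE
  # virtual exit super-node: index 0 handled by unioning to first active exit
  exit_root <- NA_integer_
  idx3 <- arrayInd(seq_len(nrow(pts)), .dim = dims)  # i,j,k per node
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  for (o in ord) {
    if (cl[o] <= 0) break
    active[o] <- TRUE
    ijk <- idx3[o, ]
    for (r in 1:6) {
      nb <- ijk + offs[r, ]
      if (any(nb < 1L) || any(nb > dims)) next
      nbid <- nid(nb[1], nb[2], nb[3])
      if (active[nbid]) parent[find(o)] <- find(nbid)
    }
    if (exit_mark[o]) {
      if (is.na(exit_root)) exit_root <- o
      else parent[find(o)] <- find(exit_root)
    }
    if (active[start_id] && !is.na(exit_root) &&
        find(start_id) == find(exit_root)) return(cl[o])
  }
  NA_real_
}
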