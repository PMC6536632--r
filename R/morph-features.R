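#' Canonical names of the 23 global morphometric features
#'
#' @return Character vector of length 23.
#' @export
morph_feature_names <- function() {
  c("n_nodes", "soma_surface_um2", "n_stems", "n_bifurcations", "n_branches",
    "n_tips", "height_um", "width_um", "depth_um", "avg_diameter_um",
    "total_length_um", "total_volume_um3", "max_euclidean_um", "max_path_um",
    "max_branch_order", "avg_contraction", "avg_fragmentation",
    "avg_parent_daughter_ratio", "avg_local_amp_angle_deg",
    "avg_remote_amp_angle_deg", "sholl_30", "sholl_50", "spine_density_per_um")
}

# working node set for geometry: spines always excluded, axon optionally
morph_working <- function(tree, include_axon = FALSE) {
  keep <- tree$nodes$type != 8
  if (!include_axon) keep <- keep & tree$nodes$type != 2
  keep
}

# children indices within the working set, as a list indexed by row
working_children <- function(tree, keep) {
  n <- nrow(tree$nodes)
  pidx <- tree$parent_idx
  ok <- which(keep & !is.na(pidx) & keep[pmax(pidx, 1)])
  split(ok, factor(pidx[ok], levels = seq_len(n)))
}

#' Global morphometric features of a reconstruction
#'
#' Computes the 23 features used for unsupervised morphological
#' classification: topological counts (nodes, stems, bifurcations, branches,
#' tips, branch order), spatial extents (95% height/width/depth, maximum
#' Euclidean and path distance), size measures (average diameter, total
#' length, total volume, spherical soma surface), branch statistics
#' (contraction, fragmentation, parent-daughter diameter ratio, local and
#' remote bifurcation amplitude angles), Sholl intersections at 30 and 50 um
#' (2D), and spine density. Spine nodes contribute only to spine density;
#' axon nodes are excluded by default.
#'
#' @param tree a [neuron_tree()].
#' @param include_axon include axon (type 2) nodes in the geometry.
#' @return One-row tibble with the 23 features (see [morph_feature_names()]).
#' @examples
#' tree <- generate_swc(morph_archetype(), seed = 1)
#' global_morph_features(tree)[, 1:6]
#' @export
global_morph_features <- function(tree, include_axon = FALSE) {
  stopifnot(inherits(tree, "neuron_tree"))
  nd <- tree$nodes
  keep <- morph_working(tree, include_axon)
  pidx <- tree$parent_idx
  kids <- working_children(tree, keep)
  n_kids <- lengths(kids)
  iroot <- which(nd$parent == -1)

  is_work <- which(keep)
  nonroot <- setdiff(is_work, iroot)
  n_nodes <- length(is_work)
  soma_surface <- 4 * pi * nd$radius[iroot]^2
  n_stems <- unname(n_kids[iroot])
  bif <- setdiff(which(n_kids >= 2), iroot)
  tips <- setdiff(is_work[n_kids[is_work] == 0], iroot)
  n_bif <- length(bif)
  n_tips <- length(tips)
  n_branches <- n_bif + n_tips

  q <- function(v) unname(diff(quantile(v, c(0.025, 0.975))))
  height <- q(nd$y[is_work]); width <- q(nd$x[is_work]); depth <- q(nd$z[is_work])

  avg_diam <- mean(2 * nd$radius[nonroot])
  total_len <- sum(nd$comp_length[nonroot])
  r1 <- nd$radius[pidx[nonroot]]
  r2 <- nd$radius[nonroot]
  total_vol <- sum(pi / 3 * nd$comp_length[nonroot] * (r1^2 + r1 * r2 + r2^2))
  max_euc <- max(nd$euclid_dist[is_work])
  max_path <- max(nd$path_dist[is_work])

  # branch decomposition: walk up from each branch endpoint (bif or tip) to
  # the previous endpoint (bif or root)
  stops <- c(iroot, bif)
  branch_of <- function(end) {
    path <- end
    p <- pidx[end]
    while (!is.na(p) && !(p %in% stops)) {
      path <- c(path, p)
      p <- pidx[p]
    }
    c(path, p) # endpoint..start, inclusive
  }
  branches <- lapply(c(bif, tips), branch_of)

  contraction <- vapply(branches, function(b) {
    e <- b[1]; s <- b[length(b)]
    plen <- nd$path_dist[e] - nd$path_dist[s]
    if (plen <= 0) return(NA_real_)
    eu <- sqrt((nd$x[e] - nd$x[s])^2 + (nd$y[e] - nd$y[s])^2 +
               (nd$z[e] - nd$z[s])^2)
    eu / plen
  }, numeric(1))
  fragmentation <- vapply(branches, function(b) length(b) - 1, numeric(1))

  # branch order: number of endpoints (stem start counts as 1) on the path
  order_of <- rep(NA_real_, nrow(nd))
  order_of[iroot] <- 0
  frontier <- iroot
  while (length(frontier) > 0) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    if (length(nxt) == 0) break
    p <- pidx[nxt]
    order_of[nxt] <- order_of[p] + ifelse(p %in% c(iroot, bif), 1, 0)
    frontier <- nxt
  }
  max_order <- max(order_of[is_work], na.rm = TRUE)

  # parent-daughter diameter ratio at bifurcations
  pd <- unlist(lapply(bif, function(b) {
    2 * nd$radius[kids[[b]]] / (2 * nd$radius[b])
  }))
  pd <- pd[is.finite(pd)]

  angles <- bifurcation_angles(nd, kids, bif, stops)

  tibble::tibble(
    n_nodes = n_nodes, soma_surface_um2 = soma_surface, n_stems = n_stems,
    n_bifurcations = n_bif, n_branches = n_branches, n_tips = n_tips,
    height_um = height, width_um = width, depth_um = depth,
    avg_diameter_um = avg_diam, total_length_um = total_len,
    total_volume_um3 = total_vol, max_euclidean_um = max_euc,
    max_path_um = max_path, max_branch_order = max_order,
    avg_contraction = mean(contraction, na.rm = TRUE),
    avg_fragmentation = mean(fragmentation),
    avg_parent_daughter_ratio = if (length(pd)) mean(pd) else NA_real_,
    avg_local_amp_angle_deg = angles$local,
    avg_remote_amp_angle_deg = angles$remote,
    sholl_30 = sholl_profile(tree, 30, include_axon = include_axon)$intersections,
    sholl_50 = sholl_profile(tree, 50, include_axon = include_axon)$intersections,
    spine_density_per_um = spine_density(tree)
  )
}

angle_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cu))) * 180 / pi
}

bifurcation_angles <- function(nd, kids, bif, stops) {
  if (length(bif) == 0) return(list(local = NA_real_, remote = NA_real_))
  pos <- function(i) c(nd$x[i], nd$y[i], nd$z[i])
  # next endpoint (bifurcation or tip) downstream of node i
  next_endpoint <- function(i) {
    repeat {
      ch <- kids[[i]]
      if (length(ch) != 1) return(i)
      i <- ch[1]
    }
  }
  loc <- rem <- numeric(length(bif))
  for (k in seq_along(bif)) {
    b <- bif[k]
    ch <- kids[[b]][1:2]
    loc[k] <- angle_deg(pos(ch[1]) - pos(b), pos(ch[2]) - pos(b))
    e1 <- next_endpoint(ch[1]); e2 <- next_endpoint(ch[2])
    rem[k] <- angle_deg(pos(e1) - pos(b), pos(e2) - pos(b))
  }
  list(local = mean(loc), remote = mean(rem))
}

#' Spine density of a reconstruction
#'
#' Number of spine nodes (type 8) per micrometre of dendrite (type 3
#' compartments; spine stubs do not count toward the length).
#'
#' @param tree a [neuron_tree()].
#' @return Spines per um; `NA` when the dendritic length is zero.
#' @export
spine_density <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  nd <- tree$nodes
  dend_len <- sum(nd$comp_length[nd$type == 3])
  if (dend_len <= 0) return(NA_real_)
  sum(nd$type == 8) / dend_len
}
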