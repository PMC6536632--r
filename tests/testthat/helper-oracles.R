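# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive per-element loops and direct
# formulas, not the package's code paths.

# ---- Ward clustering oracle -------------------------------------------------

# greedy Ward merges from raw points: at every step merge the pair of
# clusters whose union minimally increases the total within-cluster sum of
# squares; report heights on the ward.D2 scale, sqrt(2 * delta ESS)
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(scale(x[idx, , drop = FALSE], scale = FALSE)^2)
  }
  heights <- numeric(n - 1)
  memberships <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(2 * best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    lab <- integer(n)
    for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
    memberships[[step]] <- lab
  }
  list(heights = heights, memberships = memberships)
}

same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(table(a, b) %in% c(0, table(a)))
}

# ---- silhouette oracle ------------------------------------------------------

# direct O(n^2) evaluation of s(i) = (b - a) / max(a, b); singletons get 0
oracle_silhouette <- function(labels, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  dm <- as.matrix(dist(x))
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dm[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# ---- morphometry oracle -----------------------------------------------------

# plain recursive traversal over the SWC node table (spines/axon excluded),
# one quantity at a time
oracle_morph <- function(tree) {
  nd <- as.data.frame(tibble::as_tibble(tree))
  nd <- nd[nd$type != 8 & nd$type != 2, ]
  root <- nd$id[nd$parent == -1]
  kids_of <- function(id) nd$id[nd$parent == id]
  pos <- function(id) {
    r <- nd[nd$id == id, ]
    c(r$x, r$y, r$z)
  }
  rad <- function(id) nd$radius[nd$id == id]
  edist <- function(a, b) sqrt(sum((pos(a) - pos(b))^2))

  n_children <- vapply(nd$id, function(id) length(kids_of(id)), numeric(1))
  names(n_children) <- nd$id
  is_bif <- nd$id[n_children[as.character(nd$id)] >= 2 & nd$id != root]
  tips <- nd$id[n_children[as.character(nd$id)] == 0 & nd$id != root]
  starts <- unlist(lapply(c(root, is_bif), kids_of))

  # recursive path/euclid/branch-order maxima
  max_path <- 0; max_euc <- 0; max_order <- 0
  walk <- function(id, plen, order) {
    max_path <<- max(max_path, plen)
    max_euc <<- max(max_euc, edist(id, root))
    max_order <<- max(max_order, order)
    for (ch in kids_of(id)) {
      walk(ch, plen + edist(id, ch),
           order + if (id %in% c(root, is_bif)) 1 else 0)
    }
  }
  old <- options(expressions = 500000); on.exit(options(old))
  walk(root, 0, 0)

  total_len <- 0; total_vol <- 0
  for (id in setdiff(nd$id, root)) {
    p <- nd$parent[nd$id == id]
    l <- edist(id, p)
    total_len <- total_len + l
    r1 <- rad(p); r2 <- rad(id)
    total_vol <- total_vol + pi / 3 * l * (r1^2 + r1 * r2 + r2^2)
  }

  # per-branch walks for contraction and fragmentation
  contraction <- c(); fragmentation <- c()
  for (s in starts) {
    path_len <- 0; n_comp <- 0
    start_parent <- nd$parent[nd$id == s]
    cur <- s; prev <- start_parent
    repeat {
      path_len <- path_len + edist(prev, cur)
      n_comp <- n_comp + 1
      if (!(length(kids_of(cur)) == 1)) break
      prev <- cur; cur <- kids_of(cur)
    }
    contraction <- c(contraction,
                     if (path_len > 0) edist(start_parent, cur) / path_len
                     else NA)
    fragmentation <- c(fragmentation, n_comp)
  }

  list(
    n_nodes = nrow(nd), n_stems = length(kids_of(root)),
    n_bifurcations = length(is_bif), n_tips = length(tips),
    n_branches = length(starts),
    max_path = max_path, max_euclidean = max_euc, max_order = max_order,
    total_length = total_len, total_volume = total_vol,
    avg_contraction = mean(contraction, na.rm = TRUE),
    avg_fragmentation = mean(fragmentation)
  )
}

# per-segment circle-crossing count (2D, XY), one radius at a time
oracle_sholl <- function(tree, radius) {
  nd <- as.data.frame(tibble::as_tibble(tree))
  keep <- nd$type != 8 & nd$type != 2
  root <- nd[nd$parent == -1, ]
  count <- 0
  for (i in which(keep & nd$parent != -1)) {
    p <- nd[nd$id == nd$parent[i], ]
    if (!(p$type != 8 && p$type != 2)) next
    d1 <- sqrt((p$x - root$x)^2 + (p$y - root$y)^2)
    d2 <- sqrt((nd$x[i] - root$x)^2 + (nd$y[i] - root$y)^2)
    if (min(d1, d2) < radius && radius <= max(d1, d2)) count <- count + 1
  }
  count
}

# total frustum lateral area, straight summation
oracle_lateral_area <- function(tree) {
  nd <- as.data.frame(tibble::as_tibble(tree))
  keep <- nd$type != 8 & nd$type != 2
  total <- 0
  for (i in which(keep & nd$parent != -1)) {
    j <- which(nd$id == nd$parent[i])
    if (!keep[j]) next
    l <- sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
              (nd$z[i] - nd$z[j])^2)
    total <- total + pi * (nd$radius[i] + nd$radius[j]) *
      sqrt(l^2 + (nd$radius[i] - nd$radius[j])^2)
  }
  total
}

# ---- fixture builders -------------------------------------------------------

# straight chain of `n` dendrite segments along +x
chain_tree <- function(n = 10, seg = 10, radius = 1, soma_r = 5) {
  neuron_tree(tibble::tibble(
    id = 1:(n + 1),
    type = c(1, rep(3, n)),
    x = seq(0, n * seg, by = seg), y = 0, z = 0,
    radius = c(soma_r, rep(radius, n)),
    parent = c(-1, 1:n)
  ))
}

# one stem bifurcating once: soma -> stem node -> two daughters
y_tree <- function(stem = 20, arm = 30) {
  s2 <- arm / sqrt(2)
  neuron_tree(tibble::tibble(
    id = 1:4, type = c(1, 3, 3, 3),
    x = c(0, stem, stem + s2, stem + s2),
    y = c(0, 0, s2, -s2), z = 0,
    radius = c(5, 1, 0.8, 0.8),
    parent = c(-1, 1, 2, 2)
  ))
}

# small stochastic tree spec for oracle sweeps
random_morph_spec <- function(seed) {
  set.seed(seed)
  morph_archetype(
    n_stems = sample(1:5, 1),
    branch_prob_per_um = runif(1, 0, 0.02),
    mean_branch_len = runif(1, 40, 150),
    taper = runif(1, 0.7, 1),
    spine_density = sample(c(0, runif(1, 0.1, 0.6)), 1),
    soma_radius = runif(1, 4, 8),
    tree_extent = runif(1, 60, 140)
  )
}

# minimal trace_set built by hand from closed-form sweeps
flat_trace_set <- function(currents = c(-100, -50, 0), rmp = -70,
                           r_in = 100, rate = 5000, dur = 1) {
  time <- seq(-0.1, dur + 0.2, by = 1 / rate)
  v <- vapply(currents, function(I) {
    vv <- rep(rmp, length(time))
    on <- time >= 0 & time < dur
    vv[on] <- rmp + I * r_in / 1000
    vv
  }, numeric(length(time)))
  trace_set("synthetic_cell", time, v, currents, step_duration = dur,
            metadata = list(series_resistance_MOhm = 10, rmp_mV = rmp,
                            drift_fraction = 0.02))
}

fast_protocol <- function(rate = 20000) {
  make_protocol(sampling_rate = rate)
}
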