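#' Parameters of a synthetic dendritic-tree archetype
#'
#' Controls the stochastic recursive growth used by [generate_swc()]:
#' number of primary dendrites, bifurcation rate per micrometre of growth,
#' mean unbranched segment length, diameter taper across bifurcations, spine
#' density (0 encodes an aspiny type) and the radial extent of the tree.
#'
#' @param n_stems number of primary dendrites (> 0).
#' @param branch_prob_per_um probability of a bifurcation per um grown.
#' @param mean_branch_len mean length of an unbranched stretch (um).
#' @param taper daughter/parent radius ratio at bifurcations, in (0, 1].
#' @param spine_density spines per um of dendrite (>= 0).
#' @param soma_radius radius of the spherical soma node (um).
#' @param tree_extent maximum path distance from the soma (um).
#' @param stem_radius radius of primary dendrites at the soma (um).
#' @return A `morph_archetype` list.
#' @export
morph_archetype <- function(n_stems = 4, branch_prob_per_um = 0.01,
                            mean_branch_len = 80, taper = 0.85,
                            spine_density = 0, soma_radius = 7,
                            tree_extent = 150, stem_radius = 0.8) {
  if (n_stems < 1) abort("`n_stems` must be at least 1.")
  check_number(branch_prob_per_um, "branch_prob_per_um", lower = 0, upper = 1)
  check_positive(mean_branch_len, "mean_branch_len")
  check_number(taper, "taper", lower = 0.1, upper = 1)
  check_number(spine_density, "spine_density", lower = 0)
  check_positive(soma_radius, "soma_radius")
  check_positive(tree_extent, "tree_extent")
  check_positive(stem_radius, "stem_radius")
  structure(
    list(n_stems = as.integer(n_stems),
         branch_prob_per_um = branch_prob_per_um,
         mean_branch_len = mean_branch_len, taper = taper,
         spine_density = spine_density, soma_radius = soma_radius,
         tree_extent = tree_extent, stem_radius = stem_radius),
    class = "morph_archetype"
  )
}

# random unit vector, flattened in z to resemble a slice-confined arbor
random_direction <- function(flatten = 0.35) {
  v <- c(rnorm(2), rnorm(1) * flatten)
  v / sqrt(sum(v^2))
}

perturb_direction <- function(d, sd = 0.18) {
  v <- d + rnorm(3, 0, sd)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic neuron reconstruction
#'
#' Grows a dendritic tree by stochastic recursion in 5-um compartments:
#' each compartment may terminate (at rate `1 / mean_branch_len`) or
#' bifurcate (at rate `branch_prob_per_um`), daughters taper and diverge,
#' and growth stops at `tree_extent`. Spines are emitted as single-node
#' leaves of SWC type 8 attached to dendrite nodes, at Poisson rate
#' `spine_density` per um.
#'
#' @param spec a [morph_archetype()].
#' @param seed integer seed.
#' @param step compartment length (um).
#' @param max_nodes safety cap on tree size.
#' @return A `neuron_tree` (see [neuron_tree()]).
#' @examples
#' tree <- generate_swc(morph_archetype(spine_density = 0.5), seed = 1)
#' @export
generate_swc <- function(spec, seed = 1, step = 5, max_nodes = 20000) {
  stopifnot(inherits(spec, "morph_archetype"))
  with_seed(derive_seed(seed, "swc"), {
    nodes <- list(list(id = 1, type = 1, x = 0, y = 0, z = 0,
                       r = spec$soma_radius, parent = -1))
    nid <- 1
    p_term <- step / spec$mean_branch_len
    p_bif <- spec$branch_prob_per_um * step

    # iterative frontier of growing tips
    frontier <- lapply(seq_len(spec$n_stems), function(i) {
      list(parent = 1, dir = random_direction(),
           pos = c(0, 0, 0), radius = spec$stem_radius, path = 0)
    })
    while (length(frontier) > 0 && nid < max_nodes) {
      tip <- frontier[[1]]
      frontier <- frontier[-1]
      dir <- perturb_direction(tip$dir)
      pos <- tip$pos + dir * step
      nid <- nid + 1
      nodes[[nid]] <- list(id = nid, type = 3, x = pos[1], y = pos[2],
                           z = pos[3], r = tip$radius, parent = tip$parent)
      path <- tip$path + step
      if (path >= spec$tree_extent) next
      u <- runif(1)
      if (u < p_term) next
      if (u < p_term + p_bif) {
        # bifurcate: daughters diverge around the parent direction
        ax <- random_direction()
        ortho <- ax - sum(ax * dir) * dir
        ortho <- ortho / sqrt(sum(ortho^2))
        ang <- runif(1, 0.35, 0.75) # half-angle, rad
        for (sgn in c(-1, 1)) {
          d2 <- cos(ang) * dir + sin(ang) * sgn * ortho
          frontier <- c(frontier, list(list(
            parent = nid, dir = d2 / sqrt(sum(d2^2)), pos = pos,
            radius = tip$radius * spec$taper, path = path
          )))
        }
      } else {
        frontier <- c(frontier, list(list(
          parent = nid, dir = dir, pos = pos,
          radius = tip$radius, path = path
        )))
      }
    }

    df <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
    names(df) <- c("id", "type", "x", "y", "z", "radius", "parent")

    if (spec$spine_density > 0) {
      dend <- df[df$type == 3, ]
      n_sp <- rpois(nrow(dend), spec$spine_density * step)
      host <- rep(dend$id, n_sp)
      if (length(host) > 0) {
        off <- matrix(rnorm(3 * length(host)), ncol = 3)
        off <- off / sqrt(rowSums(off^2))
        hx <- df$x[match(host, df$id)]
        hy <- df$y[match(host, df$id)]
        hz <- df$z[match(host, df$id)]
        spines <- tibble::tibble(
          id = max(df$id) + seq_along(host), type = 8,
          x = hx + off[, 1], y = hy + off[, 2], z = hz + off[, 3],
          radius = 0.3, parent = host
        )
        df <- dplyr::bind_rows(df, spines)
      }
    }
    neuron_tree(df)
  })
}
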