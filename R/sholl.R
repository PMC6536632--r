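#' Sholl intersection profile
#'
#' Counts neurite crossings of concentric circles (2D, XY projection of the
#' classic analysis) or spheres (3D) centred on the soma: a compartment
#' crosses radius r when its endpoints' distances from the soma straddle r.
#'
#' @param tree a [neuron_tree()].
#' @param radii circle/sphere radii (um).
#' @param mode `"2D"` (XY projection) or `"3D"`.
#' @param include_axon include axon nodes.
#' @return Tibble `radius_um`, `intersections`.
#' @examples
#' tree <- generate_swc(morph_archetype(), seed = 1)
#' sholl_profile(tree, radii = c(30, 50))
#' @export
sholl_profile <- function(tree, radii = seq(10, 200, by = 10),
                          mode = c("2D", "3D"), include_axon = FALSE) {
  stopifnot(inherits(tree, "neuron_tree"))
  mode <- match.arg(mode)
  if (any(radii <= 0)) abort("radii must be positive.")
  nd <- tree$nodes
  keep <- morph_working(tree, include_axon)
  pidx <- tree$parent_idx
  seg <- which(keep & !is.na(pidx) & keep[pmax(pidx, 1L)])
  iroot <- which(nd$parent == -1)
  dist_of <- function(i) {
    if (mode == "2D") {
      sqrt((nd$x[i] - nd$x[iroot])^2 + (nd$y[i] - nd$y[iroot])^2)
    } else {
      nd$euclid_dist[i]
    }
  }
  d1 <- dist_of(pidx[seg])
  d2 <- dist_of(seg)
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  tibble::tibble(
    radius_um = radii,
    intersections = vapply(radii, function(r) sum(lo < r & r <= hi),
                           numeric(1))
  )
}

#' Neurite surface area as a function of path distance
#'
#' Assigns each compartment's frustum lateral area
#' `pi * (r1 + r2) * slant` to the bin of its midpoint path distance from
#' the soma; the bins sum to the total neurite lateral area. Surface area is
#' roughly proportional to synapse counts, making this a functionally
#' weighted alternative to Sholl counts.
#'
#' @param tree a [neuron_tree()].
#' @param bin_width bin width (um).
#' @param include_axon include axon nodes.
#' @return Tibble `bin_start_um`, `bin_mid_um`, `area_um2`.
#' @export
surface_area_profile <- function(tree, bin_width = 10, include_axon = FALSE) {
  stopifnot(inherits(tree, "neuron_tree"))
  check_positive(bin_width, "bin_width")
  nd <- tree$nodes
  keep <- morph_working(tree, include_axon)
  pidx <- tree$parent_idx
  seg <- which(keep & !is.na(pidx) & keep[pmax(pidx, 1L)])
  if (length(seg) == 0) {
    return(tibble::tibble(bin_start_um = numeric(0), bin_mid_um = numeric(0),
                          area_um2 = numeric(0)))
  }
  r1 <- nd$radius[pidx[seg]]
  r2 <- nd$radius[seg]
  len <- nd$comp_length[seg]
  slant <- sqrt(len^2 + (r1 - r2)^2)
  area <- pi * (r1 + r2) * slant
  mid <- (nd$path_dist[pidx[seg]] + nd$path_dist[seg]) / 2
  bin <- floor(mid / bin_width)
  agg <- tapply(area, bin, sum)
  bins <- as.numeric(names(agg))
  tibble::tibble(
    bin_start_um = bins * bin_width,
    bin_mid_um = (bins + 0.5) * bin_width,
    area_um2 = as.numeric(agg)
  )
}

#' Plot a Sholl or surface-area profile
#'
#' @param profile tibble from [sholl_profile()] or [surface_area_profile()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  if ("intersections" %in% names(profile)) {
    ggplot2::ggplot(profile,
                    ggplot2::aes(.data$radius_um, .data$intersections)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "radius (um)", y = "Sholl intersections") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(profile,
                    ggplot2::aes(.data$bin_mid_um, .data$area_um2)) +
      ggplot2::geom_col(width = if (nrow(profile) > 1)
        diff(profile$bin_start_um[1:2]) else 10) +
      ggplot2::labs(x = "path distance (um)", y = "surface area (um^2)") +
      ggplot2::theme_minimal()
  }
}
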