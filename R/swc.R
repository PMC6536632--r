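#' Construct and validate a neuron tree
#'
#' A `neuron_tree` wraps a node table in the 7-column SWC convention
#' (`id`, `type`, `x`, `y`, `z`, `radius`, `parent`; type 1 soma, 2 axon,
#' 3 dendrite, 8 spine by this package's convention). Validation enforces a
#' single root, unique ids, resolvable parents and acyclicity, and
#' precomputes per-node path and Euclidean distances to the soma.
#'
#' @param nodes data frame with the seven SWC columns.
#' @return A `neuron_tree` object.
#' @export
neuron_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    abort(paste("node table must have columns:", paste(need, collapse = ", ")),
          class = "swc_parse_error")
  }
  nodes <- nodes[need]
  if (anyDuplicated(nodes$id)) {
    abort("duplicate node ids.", class = "swc_parse_error")
  }
  if (any(nodes$radius < 0)) {
    abort("negative radius.", class = "swc_parse_error")
  }
  if (any(nodes$id == nodes$parent)) {
    abort("cycle: node is its own parent.", class = "swc_parse_error")
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) == 0) abort("no root node.", class = "swc_parse_error")
  if (length(roots) > 1) {
    abort("multiple root nodes.", class = "swc_parse_error")
  }
  pidx <- match(nodes$parent, nodes$id)
  orphan <- is.na(pidx) & nodes$parent != -1
  if (any(orphan)) {
    abort(sprintf("orphan parent id(s): %s",
                  paste(unique(nodes$parent[orphan]), collapse = ", ")),
          class = "swc_parse_error")
  }

  # breadth-first from the root: detects cycles/disconnection and yields
  # cumulative distances in one pass
  n <- nrow(nodes)
  children <- split(seq_len(n), factor(pidx, levels = seq_len(n)))
  path <- rep(NA_real_, n)
  comp_len <- rep(0, n)
  path[roots] <- 0
  frontier <- roots
  while (length(frontier) > 0) {
    nxt <- unlist(children[frontier], use.names = FALSE)
    if (length(nxt) == 0) break
    pl <- pidx[nxt]
    comp_len[nxt] <- sqrt((nodes$x[nxt] - nodes$x[pl])^2 +
                          (nodes$y[nxt] - nodes$y[pl])^2 +
                          (nodes$z[nxt] - nodes$z[pl])^2)
    path[nxt] <- path[pl] + comp_len[nxt]
    frontier <- nxt
  }
  if (anyNA(path)) {
    abort("cycle or disconnected component detected.",
          class = "swc_parse_error")
  }
  nodes$comp_length <- comp_len
  nodes$path_dist <- path
  nodes$euclid_dist <- sqrt((nodes$x - nodes$x[roots])^2 +
                            (nodes$y - nodes$y[roots])^2 +
                            (nodes$z - nodes$z[roots])^2)
  # spines must sit on dendrites and be leaves
  sp <- which(nodes$type == 8)
  if (length(sp) > 0) {
    if (any(nodes$type[pidx[sp]] != 3)) {
      abort("spine nodes must attach to dendrite nodes.",
            class = "swc_parse_error")
    }
    if (any(pidx %in% sp, na.rm = TRUE)) {
      abort("spine nodes must be leaves.", class = "swc_parse_error")
    }
  }
  structure(list(nodes = nodes, root = nodes$id[roots], parent_idx = pidx),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes (%d spines), extent %.1f um\n",
              nrow(x$nodes), sum(x$nodes$type == 8),
              max(x$nodes$euclid_dist)))
  invisible(x)
}

#' @export
as_tibble.neuron_tree <- function(x, ...) x$nodes

#' Read / write SWC reconstruction files
#'
#' Standard whitespace-delimited 7-column SWC with `#` comments. Reading
#' validates the tree (single root, unique ids, no cycles or orphans).
#'
#' @param path file path.
#' @return `read_swc()` a [neuron_tree()]; `write_swc()` the path, invisibly.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty SWC file.", class = "swc_parse_error")
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) != 7)) {
    abort("every SWC record needs 7 fields.", class = "swc_parse_error")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) abort("non-numeric SWC field.", class = "swc_parse_error")
  neuron_tree(tibble::tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  ))
}

#' @rdname read_swc
#' @param tree a [neuron_tree()].
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  nd <- tree$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# generated by striocell (id type x y z radius parent)", con)
  writeLines(sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent),
             con)
  invisible(path)
}

#' Plot the XY projection of a reconstruction
#'
#' @param object a [neuron_tree()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.neuron_tree <- function(object, ...) {
  nd <- object$nodes
  pi_ <- object$parent_idx
  has_par <- which(!is.na(pi_) & nd$type != 8)
  seg <- tibble::tibble(
    x = nd$x[pi_[has_par]], y = nd$y[pi_[has_par]],
    xend = nd$x[has_par], yend = nd$y[has_par]
  )
  spines <- nd[nd$type == 8, ]
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (nrow(spines) > 0) {
    p <- p + ggplot2::geom_point(data = spines,
                                 ggplot2::aes(.data$x, .data$y),
                                 size = 0.2, colour = "red3")
  }
  p
}
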