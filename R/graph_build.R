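# Bond inference, particle size, and core/shell classification.

#' Infer the bond graph of a structure
#'
#' An edge is drawn between atoms i and j when their distance does not exceed
#' `tolerance * (r_cov(i) + r_cov(j))`, with covalent radii from the packaged
#' table. XYZ carries no bond information, so this distance criterion is the
#' only source of connectivity.
#'
#' @param structure a [nano_structure()].
#' @param tolerance dimensionless cutoff scale factor, default 1.15.
#' @return object of class `bond_graph`: `n_atoms`, `edges` (two-column
#'   matrix of 1-based index pairs, i < j), `degree`, `coord_O` and `coord_M`
#'   (per-atom counts of oxygen / non-oxygen neighbours).
#' @export
infer_bonds <- function(structure, tolerance = 1.15) {
  stopifnot(inherits(structure, "nano_structure"))
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance <= 0) {
    stop("tolerance must be a positive scalar", call. = FALSE)
  }
  n <- n_atoms(structure)
  radii <- covalent_radius(structure$elements)
  d <- as.matrix(stats::dist(structure$coords))
  cutoff <- outer(radii, radii, "+") * tolerance
  adj <- d <= cutoff
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2)
  colnames(edges) <- NULL
  bond_graph_from_edges(n, edges, structure$elements)
}

# Assemble a bond_graph from an explicit edge list (also used for the
# shell-restricted subgraph).
bond_graph_from_edges <- function(n, edges, elements) {
  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  is_o <- elements == "O"
  coord_O <- integer(n)
  coord_M <- integer(n)
  if (nrow(edges) > 0) {
    ends <- rbind(edges, edges[, 2:1, drop = FALSE])  # both directions
    nbr_is_o <- is_o[ends[, 2]]
    coord_O <- tabulate(ends[nbr_is_o, 1], nbins = n)
    coord_M <- tabulate(ends[!nbr_is_o, 1], nbins = n)
  }
  structure(
    list(n_atoms = n, edges = edges, degree = as.integer(degree),
         coord_O = as.integer(coord_O), coord_M = as.integer(coord_M)),
    class = "bond_graph"
  )
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("<bond_graph: %d atoms, %d bonds, max degree %d>\n",
              x$n_atoms, nrow(x$edges), if (x$n_atoms) max(x$degree) else 0L))
  invisible(x)
}

#' Particle size
#'
#' The size of a nanocompound is the maximum pairwise distance between its
#' atoms (the diameter, for a spherical particle).
#'
#' @param structure a [nano_structure()].
#' @return length in Angstrom; 0 with a warning for a single atom.
#' @export
compute_size <- function(structure) {
  stopifnot(inherits(structure, "nano_structure"))
  if (n_atoms(structure) < 2) {
    warning("size of a single-atom structure is 0")
    return(0)
  }
  max(stats::dist(structure$coords))
}

#' Classify atoms into core and shell
#'
#' The shell is the radial band of the given thickness below the particle's
#' outer radius: atom i is a shell atom iff its distance from the center is
#' at least `outer_radius - thickness` (closed boundary). The center is the
#' centroid of all atomic positions. A thickness of at least half the particle
#' size puts every atom in the shell.
#'
#' @param structure a [nano_structure()].
#' @param thickness shell thickness in Angstrom, > 0.
#' @return object of class `shell_assignment`: `center`, `outer_radius`,
#'   `thickness`, logical `is_shell`.
#' @export
assign_shell <- function(structure, thickness) {
  stopifnot(inherits(structure, "nano_structure"))
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0) {
    stop("thickness must be a positive scalar (Angstrom)", call. = FALSE)
  }
  center <- colMeans(structure$coords)
  r <- sqrt(rowSums(sweep(structure$coords, 2, center)^2))
  outer_radius <- max(r)
  structure(
    list(center = center, outer_radius = outer_radius, thickness = thickness,
         is_shell = r >= outer_radius - thickness),
    class = "shell_assignment"
  )
}

#' @export
print.shell_assignment <- function(x, ...) {
  cat(sprintf("<shell_assignment: %d/%d atoms in shell (R=%.2f A, t=%.2f A)>\n",
              sum(x$is_shell), length(x$is_shell), x$outer_radius, x$thickness))
  invisible(x)
}

#' Transfer a shell assignment onto another structure by atom index
#'
#' When comparing an optimised structure against its bulk-cut precursor, the
#' shell membership is decided once on the reference and frozen: the same atom
#' indices are shell atoms in both, so the number of atoms in the shell region
#' is identical and fingerprint differences reflect rebonding, not membership
#' churn. No geometry is recomputed.
#'
#' @param reference a `shell_assignment` computed on the reference structure.
#' @param structure a [nano_structure()] with the same atom count and order.
#' @return a `shell_assignment` carrying the reference's `is_shell`.
#' @export
freeze_shell <- function(reference, structure) {
  stopifnot(inherits(reference, "shell_assignment"),
            inherits(structure, "nano_structure"))
  if (length(reference$is_shell) != n_atoms(structure)) {
    stop(sprintf("atom count mismatch: reference assignment covers %d atoms, structure has %d",
                 length(reference$is_shell), n_atoms(structure)), call. = FALSE)
  }
  structure(
    list(center = reference$center, outer_radius = reference$outer_radius,
         thickness = reference$thickness, is_shell = reference$is_shell,
         frozen = TRUE),
    class = "shell_assignment"
  )
}

# Restrict a bond graph to edges with BOTH endpoints in the shell; coordination
# counts are then those of the shell subgraph. Boundary-crossing bonds (one
# endpoint core) are excluded so all fingerprint sections stay internally
# consistent within the shell subgraph.
shell_subgraph <- function(bg, shell, elements) {
  keep <- shell$is_shell[bg$edges[, 1]] & shell$is_shell[bg$edges[, 2]]
  bond_graph_from_edges(bg$n_atoms, bg$edges[keep, , drop = FALSE], elements)
}
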