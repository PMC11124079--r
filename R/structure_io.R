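# Structure containers and the three text formats the toolkit touches:
# plain XYZ, core/shell-labelled XYZ (XYZ + 5th column), and the GRF
# labelled-graph dialect used for search queries.

#' Construct a nanoparticle structure
#'
#' A `nano_structure` is an ordered list of atoms: element symbols plus
#' Cartesian coordinates in Angstrom. Atom order is significant (it is the
#' file order, and shell assignments are transferred by index).
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param comment free-text comment (XYZ line 2), kept verbatim.
#' @param source provenance string, a file path or `"synthetic"`.
#' @return object of class `nano_structure` with fields `elements`, `coords`,
#'   `atomic_numbers`, `comment`, `source`.
#' @export
nano_structure <- function(elements, coords, comment = "", source = "synthetic") {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3) {
    stop("coords must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  if (length(elements) != nrow(coords)) {
    stop("elements and coords disagree on atom count", call. = FALSE)
  }
  if (length(elements) < 1) stop("structure must contain at least one atom", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  zs <- atomic_number(elements)  # errors on unknown symbols
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(elements = as.character(elements), coords = coords,
         atomic_numbers = zs, comment = as.character(comment)[1],
         source = source),
    class = "nano_structure"
  )
}

#' @export
print.nano_structure <- function(x, ...) {
  cat(sprintf("<nano_structure: %d atoms (%s), source: %s>\n",
              n_atoms(x),
              paste(sprintf("%s:%d", names(table(x$elements)), table(x$elements)),
                    collapse = ", "),
              x$source))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `nano_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) length(structure$elements)

# Split a structure into oxygen + single metal species; domain error otherwise.
# Used by fingerprinting, which is defined only for binary metal oxides.
check_binary_oxide <- function(structure) {
  els <- unique(structure$elements)
  metals <- setdiff(els, "O")
  if (!"O" %in% els) stop("structure contains no oxygen: not a metal oxide", call. = FALSE)
  if (length(metals) == 0) stop("structure contains no metal species", call. = FALSE)
  if (length(metals) > 1) {
    stop("structure contains more than one metal species (",
         paste(metals, collapse = ", "), "); fingerprints are defined for binary oxides",
         call. = FALSE)
  }
  metals
}

#' Read a structure from an XYZ file
#'
#' Standard XYZ convention: line 1 is the atom count, line 2 a free comment,
#' then one `Symbol x y z` line per atom. Extra per-line columns (e.g. the
#' core/shell label written by [write_labeled_xyz()]) are ignored, as are
#' trailing blank lines and trailing whitespace.
#'
#' @param path path to an XYZ file.
#' @return a [nano_structure()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; internal blanks are malformed atom lines
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 3) stop("XYZ file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("line 1 of ", path, " is not a positive atom count", call. = FALSE)
  comment <- lines[2]
  atom_lines <- lines[-(1:2)]
  if (length(atom_lines) != n) {
    stop(sprintf("atom count mismatch in %s: header declares %d, found %d atom lines",
                 path, n, length(atom_lines)), call. = FALSE)
  }
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(atom_lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) < 4) {
      stop(sprintf("malformed atom line %d of %s: '%s'", i + 2L, path, atom_lines[i]),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("malformed coordinate on line %d of %s: '%s'", i + 2L, path, atom_lines[i]),
           call. = FALSE)
    }
    elements[i] <- toks[1]
    coords[i, ] <- xyz
  }
  bad <- !is_known_element(elements)
  if (any(bad)) {
    stop(sprintf("unknown element symbol '%s' on line %d of %s",
                 elements[which(bad)[1]], which(bad)[1] + 2L, path), call. = FALSE)
  }
  nano_structure(elements, coords, comment = comment, source = path)
}

#' Write a structure to an XYZ file
#'
#' @param structure a [nano_structure()].
#' @param path output path.
#' @param digits coordinate precision (decimal places), default 6.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, digits = 6) {
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  lines <- c(
    as.character(n_atoms(structure)),
    structure$comment,
    sprintf(fmt, structure$elements,
            structure$coords[, 1], structure$coords[, 2], structure$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a core/shell-labelled XYZ file
#'
#' Standard XYZ with a trailing per-atom label column whose values are
#' `"core"` or `"shell"`. [read_xyz()] tolerates the extra column.
#'
#' @param structure a [nano_structure()].
#' @param shell a [assign_shell()] result covering every atom.
#' @param path output path.
#' @param digits coordinate precision, default 6.
#' @return `path`, invisibly.
#' @export
write_labeled_xyz <- function(structure, shell, path, digits = 6) {
  if (length(shell$is_shell) != n_atoms(structure)) {
    stop("shell assignment length does not match atom count", call. = FALSE)
  }
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df %%s", digits, digits, digits)
  lab <- ifelse(shell$is_shell, "shell", "core")
  lines <- c(
    as.character(n_atoms(structure)),
    structure$comment,
    sprintf(fmt, structure$elements,
            structure$coords[, 1], structure$coords[, 2], structure$coords[, 3], lab)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a labelled query graph
#'
#' The query object for subcomponent search: element-labelled nodes plus an
#' undirected edge list. No self-loops or duplicate edges.
#'
#' @param nodes character vector of element labels, one per node.
#' @param edges two-column integer matrix of 1-based node index pairs
#'   (unordered); may have zero rows.
#' @return object of class `pattern_graph`.
#' @export
pattern_graph <- function(nodes, edges = matrix(integer(0), 0, 2)) {
  nodes <- as.character(nodes)
  edges <- matrix(as.integer(edges), ncol = 2)
  n <- length(nodes)
  if (n < 1) stop("pattern graph needs at least one node", call. = FALSE)
  if (nrow(edges) > 0) {
    if (any(edges < 1 | edges > n)) stop("edge references out-of-range node", call. = FALSE)
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed", call. = FALSE)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edge in pattern graph", call. = FALSE)
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  }
  structure(list(nodes = nodes, edges = edges), class = "pattern_graph")
}

#' @export
print.pattern_graph <- function(x, ...) {
  cat(sprintf("<pattern_graph: %d nodes (%s), %d edges>\n",
              length(x$nodes), paste(x$nodes, collapse = ","), nrow(x$edges)))
  invisible(x)
}

#' Read a query graph from a GRF file
#'
#' GRF is a minimal plain-text labelled-graph dialect: line 1 holds the node
#' and edge counts `N M`; the next `N` lines hold `index element` (0-based
#' indices); the next `M` lines hold one `i j` edge each (0-based, unordered).
#' Blank lines and `#` comment lines are ignored.
#'
#' @param path path to a GRF file.
#' @return a [pattern_graph()].
#' @export
read_grf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1) stop("empty GRF file: ", path, call. = FALSE)
  head_toks <- strsplit(lines[1], "[[:space:]]+")[[1]]
  counts <- suppressWarnings(as.integer(head_toks))
  if (length(counts) != 2 || anyNA(counts) || counts[1] < 1 || counts[2] < 0) {
    stop("GRF line 1 must be 'N M' with N >= 1: ", path, call. = FALSE)
  }
  n <- counts[1]; m <- counts[2]
  if (length(lines) != 1 + n + m) {
    stop(sprintf("GRF %s declares %d nodes + %d edges but has %d content lines",
                 path, n, m, length(lines) - 1L), call. = FALSE)
  }
  nodes <- character(n)
  for (i in seq_len(n)) {
    toks <- strsplit(lines[1 + i], "[[:space:]]+")[[1]]
    if (length(toks) < 2) stop("malformed GRF node line: '", lines[1 + i], "'", call. = FALSE)
    idx <- suppressWarnings(as.integer(toks[1]))
    if (is.na(idx) || idx < 0 || idx >= n) {
      stop("GRF node index out of range: '", lines[1 + i], "'", call. = FALSE)
    }
    nodes[idx + 1L] <- toks[2]
  }
  if (any(!nzchar(nodes))) stop("GRF node list does not cover 0..N-1: ", path, call. = FALSE)
  if (any(!is_known_element(nodes))) {
    stop("unknown element label(s) in GRF: ",
         paste(unique(nodes[!is_known_element(nodes)]), collapse = ", "), call. = FALSE)
  }
  edges <- matrix(integer(0), 0, 2)
  if (m > 0) {
    edges <- matrix(NA_integer_, m, 2)
    for (k in seq_len(m)) {
      toks <- suppressWarnings(as.integer(strsplit(lines[1 + n + k], "[[:space:]]+")[[1]]))
      if (length(toks) != 2 || anyNA(toks)) {
        stop("malformed GRF edge line: '", lines[1 + n + k], "'", call. = FALSE)
      }
      if (any(toks < 0) || any(toks >= n)) {
        stop("GRF edge references out-of-range node: '", lines[1 + n + k], "'", call. = FALSE)
      }
      edges[k, ] <- toks + 1L
    }
  }
  pattern_graph(nodes, edges)
}

#' Write a query graph to a GRF file
#'
#' @param graph a [pattern_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grf <- function(graph, path) {
  n <- length(graph$nodes)
  m <- nrow(graph$edges)
  lines <- c(
    sprintf("%d %d", n, m),
    sprintf("%d %s", seq_len(n) - 1L, graph$nodes),
    if (m > 0) sprintf("%d %d", graph$edges[, 1] - 1L, graph$edges[, 2] - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Convert a structure to a query graph via bond inference
#'
#' Lets an XYZ file serve as a search query: bonds are inferred with the same
#' covalent-radius criterion used for targets, then the geometry is dropped.
#'
#' @param structure a [nano_structure()].
#' @param tolerance bond-inference tolerance factor, see [infer_bonds()].
#' @return a [pattern_graph()].
#' @export
structure_to_pattern <- function(structure, tolerance = 1.15) {
  bg <- infer_bonds(structure, tolerance)
  pattern_graph(structure$elements, bg$edges)
}
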