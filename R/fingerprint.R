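# The NanoFingerprint: a fixed-layout count vector over local coordination
# environments in a particle's shell.
#
# Layout (1-based positions into the full vector; W = MAX + 1, B = W^2):
#   section 1, positions 1..6: thickness (A), MAX, size (A), metal atomic
#     number, n oxygen atoms in shell, n metal atoms in shell.
#   section 2, 2*MAX values: O(c) for c = 1..MAX, then M(c) — atoms by total
#     coordination in the shell subgraph.
#   section 3, 2*W^2 values: O(x,y) row-major over x,y in 0..MAX, then
#     M(x,y) — atoms by (oxygen-neighbour, metal-neighbour) counts.
#   section 4, 3*B^2 values: bonded environment pairs O-O, M-M, O-M; the
#     symmetric O-O and M-M blocks are canonicalised (lexicographically
#     smaller environment first) so each bond is counted exactly once.
# Atoms whose shell-subgraph degree exceeds MAX are dropped from sections
# 2-4 (they still count in section-1 slots 5/6), as are bonds touching them.

#' Length of a fingerprint vector
#'
#' Two conventions exist for the counting sections. The normative layout bins
#' coordination pairs over `0..MAX` inclusive, giving
#' `6 + 2*MAX + 2*(MAX+1)^2 + 3*(MAX+1)^4`; this is the length of every vector
#' this package builds. The `"positive-only"` convention uses `MAX` in place
#' of `MAX+1` (`6 + 2*MAX + 2*MAX^2 + 3*MAX^4`), reproducing the arithmetic of
#' the commonly quoted MAX = 10 example value 30,226; it is provided for
#' reference only and never describes a stored vector.
#'
#' @param max_bonds maximum number of bonds per atom (MAX), >= 1.
#' @param convention `"inclusive-zero"` (default, normative) or
#'   `"positive-only"`.
#' @return integer vector length.
#' @export
fingerprint_length <- function(max_bonds, convention = c("inclusive-zero", "positive-only")) {
  convention <- match.arg(convention)
  m <- as.integer(max_bonds)
  if (is.na(m) || m < 1) stop("max_bonds must be an integer >= 1", call. = FALSE)
  if (convention == "inclusive-zero") {
    as.integer(6L + 2L * m + 2L * (m + 1L)^2 + 3L * (m + 1L)^4)
  } else {
    as.integer(6L + 2L * m + 2L * m^2 + 3L * m^4)
  }
}

# --- label arithmetic ------------------------------------------------------

# Labels are the field's notation as strings: "O(2)", "M(1,0)",
# "O(0,1)-M(2,0)". parse_label turns one into a list(kind, ...).
parse_label <- function(label) {
  label <- gsub("[[:space:]]", "", label)
  pair_re <- "^([OM])\\((\\d+),(\\d+)\\)-([OM])\\((\\d+),(\\d+)\\)$"
  env_re  <- "^([OM])\\((\\d+),(\\d+)\\)$"
  atom_re <- "^([OM])\\((\\d+)\\)$"
  if (grepl(pair_re, label)) {
    m <- regmatches(label, regexec(pair_re, label))[[1]]
    list(kind = "pair", el1 = m[2], x1 = as.integer(m[3]), y1 = as.integer(m[4]),
         el2 = m[5], x2 = as.integer(m[6]), y2 = as.integer(m[7]))
  } else if (grepl(env_re, label)) {
    m <- regmatches(label, regexec(env_re, label))[[1]]
    list(kind = "env", el = m[2], x = as.integer(m[3]), y = as.integer(m[4]))
  } else if (grepl(atom_re, label)) {
    m <- regmatches(label, regexec(atom_re, label))[[1]]
    list(kind = "atom", el = m[2], c = as.integer(m[3]))
  } else {
    stop("cannot parse pattern label: '", label, "'", call. = FALSE)
  }
}

#' Position of a local-structure label in the fingerprint vector
#'
#' Maps a label in the field's notation — `"O(c)"` / `"M(c)"` (section 2),
#' `"O(x,y)"` / `"M(x,y)"` (section 3), `"O(x,y)-M(x',y')"` etc. (section 4) —
#' to its 1-based position in the packed vector for a given `max_bonds`.
#' Symmetric section-4 labels (`O-O`, `M-M`) are canonicalised, so
#' `"O(0,1)-O(1,0)"` and `"O(1,0)-O(0,1)"` name the same slot; mixed pairs are
#' always stored with the oxygen environment first.
#'
#' @param label a label string (or a vector of them).
#' @param max_bonds MAX used for the layout.
#' @return integer position(s), 1-based.
#' @export
index_of <- function(label, max_bonds) {
  vapply(label, function(l) as.integer(.index_of_one(l, max_bonds = as.integer(max_bonds))),
         integer(1), USE.NAMES = FALSE)
}

.index_of_one <- function(label, max_bonds) {
  m <- max_bonds
  w <- m + 1L
  lab <- parse_label(label)
  chk <- function(v, lo, hi, what) {
    if (any(v < lo | v > hi)) {
      stop(sprintf("%s out of range [%d,%d] in label '%s'", what, lo, hi, label),
           call. = FALSE)
    }
  }
  if (lab$kind == "atom") {
    chk(lab$c, 1L, m, "coordination")
    base <- 6L + if (lab$el == "M") m else 0L
    return(base + lab$c)                      # O(c) at 6+c, 1-based
  }
  if (lab$kind == "env") {
    chk(c(lab$x, lab$y), 0L, m, "coordination pair")
    b3 <- 6L + 2L * m
    base <- b3 + if (lab$el == "M") w^2 else 0L
    return(base + lab$x * w + lab$y + 1L)     # row-major over (x,y)
  }
  # pair
  chk(c(lab$x1, lab$y1, lab$x2, lab$y2), 0L, m, "coordination pair")
  b4 <- 6L + 2L * m + 2L * w^2
  bb <- w^2                                   # environments per element
  p1 <- lab$x1 * w + lab$y1
  p2 <- lab$x2 * w + lab$y2
  if (lab$el1 == lab$el2) {
    lo <- min(p1, p2); hi <- max(p1, p2)      # canonical order
    block <- if (lab$el1 == "O") 0L else 1L
    b4 + block * bb^2 + lo * bb + hi + 1L
  } else {
    # O environment indexes the row regardless of written order
    po <- if (lab$el1 == "O") p1 else p2
    pm <- if (lab$el1 == "O") p2 else p1
    b4 + 2L * bb^2 + po * bb + pm + 1L
  }
}

#' Label of a fingerprint position
#'
#' Inverse of [index_of()] for positions in sections 2-4; section-1 positions
#' return their slot names. For a symmetric section-4 slot the canonical
#' (sorted) label is returned.
#'
#' @param position 1-based position(s) in the packed vector.
#' @param max_bonds MAX used for the layout.
#' @return character label(s).
#' @export
label_of <- function(position, max_bonds) {
  vapply(position, .label_of_one, character(1), max_bonds = as.integer(max_bonds),
         USE.NAMES = FALSE)
}

.label_of_one <- function(pos, max_bonds) {
  m <- max_bonds
  w <- m + 1L
  bb <- w^2
  b3 <- 6L + 2L * m
  b4 <- b3 + 2L * bb
  total <- fingerprint_length(m)
  if (pos < 1 || pos > total) stop("position out of range: ", pos, call. = FALSE)
  if (pos <= 6L) {
    return(c("thickness", "max_bonds", "size", "metal_atomic_number",
             "n_O_shell", "n_M_shell")[pos])
  }
  if (pos <= b3) {
    k <- pos - 6L
    if (k <= m) return(sprintf("O(%d)", k))
    return(sprintf("M(%d)", k - m))
  }
  if (pos <= b4) {
    k <- pos - b3 - 1L
    el <- if (k < bb) "O" else "M"
    k <- k %% bb
    return(sprintf("%s(%d,%d)", el, k %/% w, k %% w))
  }
  k <- pos - b4 - 1L
  block <- k %/% bb^2
  k <- k %% bb^2
  p1 <- k %/% bb
  p2 <- k %% bb
  els <- switch(block + 1L, c("O", "O"), c("M", "M"), c("O", "M"))
  sprintf("%s(%d,%d)-%s(%d,%d)", els[1], p1 %/% w, p1 %% w, els[2], p2 %/% w, p2 %% w)
}

# --- construction ----------------------------------------------------------

#' Build the fingerprint of a structure
#'
#' Runs the full pipeline: infer bonds from covalent radii, classify atoms
#' into core/shell by radial thickness, restrict the bond graph to shell-shell
#' edges, and count local coordination environments into the packed vector.
#' Shell atoms whose (shell-subgraph) degree exceeds `max_bonds` are counted
#' in section-1 slots 5/6 but excluded from sections 2-4; it is the caller's
#' responsibility to pick `max_bonds` large enough that few atoms are dropped.
#'
#' @param structure a [nano_structure()] of a binary metal oxide (O + one
#'   metal species).
#' @param thickness shell thickness, Angstrom.
#' @param max_bonds MAX, the maximum per-atom coordination counted.
#' @param tolerance bond-inference tolerance factor, see [infer_bonds()].
#' @param shell optional precomputed `shell_assignment` (e.g. from
#'   [freeze_shell()]); when supplied, `thickness` is taken from it.
#' @return object of class `nano_fingerprint`: the section-1 scalars as named
#'   fields, the full packed `vector`, `max_bonds`, and the `shell` and
#'   `bond_graph` used.
#' @export
build_fingerprint <- function(structure, thickness, max_bonds, tolerance = 1.15,
                              shell = NULL) {
  stopifnot(inherits(structure, "nano_structure"))
  metal <- check_binary_oxide(structure)
  m <- as.integer(max_bonds)
  if (is.na(m) || m < 1) stop("max_bonds must be an integer >= 1", call. = FALSE)
  if (is.null(shell)) {
    shell <- assign_shell(structure, thickness)
  } else {
    stopifnot(inherits(shell, "shell_assignment"))
    if (length(shell$is_shell) != n_atoms(structure)) {
      stop("supplied shell assignment does not cover the structure", call. = FALSE)
    }
    thickness <- shell$thickness
  }

  bg_full <- infer_bonds(structure, tolerance)
  bg <- shell_subgraph(bg_full, shell, structure$elements)

  is_o <- structure$elements == "O"
  in_shell <- shell$is_shell
  size <- compute_size(structure)

  vec <- numeric(fingerprint_length(m))
  vec[1] <- thickness
  vec[2] <- m
  vec[3] <- size
  vec[4] <- atomic_number(metal)
  vec[5] <- sum(in_shell & is_o)
  vec[6] <- sum(in_shell & !is_o)

  counted <- in_shell & bg$degree <= m       # shell atoms kept in sections 2-4
  w <- m + 1L
  b3 <- 6L + 2L * m
  bb <- w^2
  b4 <- b3 + 2L * bb

  # section 2: total coordination c in 1..MAX
  for (i in which(counted)) {
    d <- bg$degree[i]
    if (d >= 1L) {
      vec[6L + (if (is_o[i]) 0L else m) + d] <- vec[6L + (if (is_o[i]) 0L else m) + d] + 1
    }
  }
  # section 3: (x, y) = (oxygen neighbours, metal neighbours), 0..MAX each
  for (i in which(counted)) {
    off <- bg$coord_O[i] * w + bg$coord_M[i] + 1L
    base <- b3 + if (is_o[i]) 0L else bb
    vec[base + off] <- vec[base + off] + 1
  }
  # section 4: one count per shell-shell bond between counted atoms
  if (nrow(bg$edges) > 0) {
    for (k in seq_len(nrow(bg$edges))) {
      i <- bg$edges[k, 1]; j <- bg$edges[k, 2]
      if (!counted[i] || !counted[j]) next
      pi_ <- bg$coord_O[i] * w + bg$coord_M[i]
      pj_ <- bg$coord_O[j] * w + bg$coord_M[j]
      if (is_o[i] == is_o[j]) {
        lo <- min(pi_, pj_); hi <- max(pi_, pj_)
        block <- if (is_o[i]) 0L else 1L
        pos <- b4 + block * bb^2 + lo * bb + hi + 1L
      } else {
        po <- if (is_o[i]) pi_ else pj_
        pm <- if (is_o[i]) pj_ else pi_
        pos <- b4 + 2L * bb^2 + po * bb + pm + 1L
      }
      vec[pos] <- vec[pos] + 1
    }
  }

  structure(
    list(thickness = thickness, max_bonds = m, size = size,
         metal = metal, metal_atomic_number = atomic_number(metal),
         n_O_shell = as.integer(vec[5]), n_M_shell = as.integer(vec[6]),
         vector = vec, shell = shell, bond_graph = bg,
         tolerance = tolerance),
    class = "nano_fingerprint"
  )
}

#' @export
print.nano_fingerprint <- function(x, ...) {
  cat(sprintf("<nano_fingerprint: %s, MAX=%d, length %d>\n",
              paste0(x$metal, "-O"), x$max_bonds, length(x$vector)))
  cat(sprintf("  section 1: thickness=%.4g A, MAX=%d, size=%.4g A, Z=%d, O_shell=%d, M_shell=%d\n",
              x$thickness, x$max_bonds, x$size, x$metal_atomic_number,
              x$n_O_shell, x$n_M_shell))
  nz <- which(x$vector[-(1:6)] != 0) + 6L
  cat(sprintf("  %d non-zero counting entries", length(nz)))
  if (length(nz) > 0) {
    show <- utils::head(nz, 8)
    cat(": ", paste(sprintf("%s=%g", label_of(show, x$max_bonds), x$vector[show]),
                    collapse = ", "))
    if (length(nz) > 8) cat(", ...")
  }
  cat("\n")
  invisible(x)
}

#' Look up counts by label
#'
#' @param fp a `nano_fingerprint`.
#' @param label label string(s), see [index_of()].
#' @return numeric count(s).
#' @export
fp_count <- function(fp, label) {
  stopifnot(inherits(fp, "nano_fingerprint"))
  fp$vector[index_of(label, fp$max_bonds)]
}

#' Difference of two fingerprints
#'
#' Element-wise `a - b` over the counting sections (2-4). Section 1 is not
#' subtracted: its scalars are reported side by side, since parameters and
#' global geometry are not counts. Both fingerprints must share `max_bonds`.
#'
#' @param a,b `nano_fingerprint` objects with equal `max_bonds`.
#' @return object of class `nano_fingerprint_diff`: signed `delta` vector
#'   (positions 1-6 are NA), `section1` two-row matrix, `max_bonds`.
#' @export
diff_fingerprints <- function(a, b) {
  stopifnot(inherits(a, "nano_fingerprint"), inherits(b, "nano_fingerprint"))
  if (a$max_bonds != b$max_bonds || length(a$vector) != length(b$vector)) {
    stop("fingerprints differ in max_bonds/length; cannot subtract", call. = FALSE)
  }
  delta <- a$vector - b$vector
  delta[1:6] <- NA_real_
  s1 <- rbind(a = a$vector[1:6], b = b$vector[1:6])
  colnames(s1) <- c("thickness", "max_bonds", "size", "metal_atomic_number",
                    "n_O_shell", "n_M_shell")
  structure(list(delta = delta, section1 = s1, max_bonds = a$max_bonds),
            class = "nano_fingerprint_diff")
}

#' @export
print.nano_fingerprint_diff <- function(x, ...) {
  cat(sprintf("<nano_fingerprint_diff: MAX=%d>\n", x$max_bonds))
  nz <- which(!is.na(x$delta) & x$delta != 0)
  cat(sprintf("  %d changed entries\n", length(nz)))
  for (p in utils::head(nz, 12)) {
    cat(sprintf("  %-24s %+g\n", label_of(p, x$max_bonds), x$delta[p]))
  }
  if (length(nz) > 12) cat("  ...\n")
  invisible(x)
}

# --- serialisation ---------------------------------------------------------

#' Write a fingerprint as sparse text
#'
#' Header lines carry the six section-1 values; then one `position value
#' # label` line per non-zero counting entry (1-based positions into the
#' packed vector). Zero entries are omitted — at realistic MAX almost all of
#' the vector is zero.
#'
#' @param fp a `nano_fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  stopifnot(inherits(fp, "nano_fingerprint"))
  hdr <- c(
    "# nano_fingerprint v1 (sparse; 1-based positions)",
    sprintf("thickness %.10g", fp$thickness),
    sprintf("max_bonds %d", fp$max_bonds),
    sprintf("size %.10g", fp$size),
    sprintf("metal_atomic_number %d", fp$metal_atomic_number),
    sprintf("n_O_shell %d", fp$n_O_shell),
    sprintf("n_M_shell %d", fp$n_M_shell)
  )
  nz <- which(fp$vector != 0)
  nz <- nz[nz > 6]
  body <- sprintf("%d %.10g # %s", nz, fp$vector[nz], label_of(nz, fp$max_bonds))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sparse-text fingerprint
#'
#' @param path path written by [write_fingerprint()].
#' @return a `nano_fingerprint` (without `shell`/`bond_graph`, which are not
#'   serialised).
#' @export
read_fingerprint <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  get_hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(ln) != 1) stop("missing/duplicated header '", key, "' in ", path, call. = FALSE)
    as.numeric(strsplit(ln, "[[:space:]]+")[[1]][2])
  }
  thickness <- get_hdr("thickness")
  m <- as.integer(get_hdr("max_bonds"))
  size <- get_hdr("size")
  z <- as.integer(get_hdr("metal_atomic_number"))
  n_o <- as.integer(get_hdr("n_O_shell"))
  n_m <- as.integer(get_hdr("n_M_shell"))
  vec <- numeric(fingerprint_length(m))
  vec[1:6] <- c(thickness, m, size, z, n_o, n_m)
  body <- lines[grepl("^[0-9]+ ", lines)]
  for (ln in body) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    pos <- as.integer(toks[1])
    if (is.na(pos) || pos < 7 || pos > length(vec)) {
      stop("bad position line in ", path, ": '", ln, "'", call. = FALSE)
    }
    vec[pos] <- as.numeric(toks[2])
  }
  tab <- element_table()
  metal <- tab$symbol[match(z, tab$atomic_number)]
  structure(
    list(thickness = thickness, max_bonds = m, size = size,
         metal = metal, metal_atomic_number = z,
         n_O_shell = n_o, n_M_shell = n_m,
         vector = vec, shell = NULL, bond_graph = NULL, tolerance = NA_real_),
    class = "nano_fingerprint"
  )
}

#' Export a fingerprint as dense CSV
#'
#' One row per vector position: `position, label, value`.
#'
#' @param fp a `nano_fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_csv <- function(fp, path) {
  stopifnot(inherits(fp, "nano_fingerprint"))
  pos <- seq_along(fp$vector)
  utils::write.csv(
    data.frame(position = pos, label = label_of(pos, fp$max_bonds),
               value = fp$vector),
    path, row.names = FALSE)
  invisible(path)
}
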