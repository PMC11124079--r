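# Independent oracles, written naively on purpose: explicit loops and
# adjacency matrices, no reuse of the package's graph/fingerprint internals.
# They share only the covalent-radius table (the packaged radii are part of
# the stated bond criterion).

# Naive shell-restricted bond graph: full distance loops, centroid shell rule,
# adjacency matrix representation.
naive_shell_graph <- function(s, thickness, tolerance = 1.15) {
  n <- n_atoms(s)
  co <- s$coords
  el <- s$elements
  rad <- covalent_radius(el)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        dij <- sqrt(sum((co[i, ] - co[j, ])^2))
        if (dij <= tolerance * (rad[i] + rad[j])) {
          adj[i, j] <- TRUE
          adj[j, i] <- TRUE
        }
      }
    }
  }
  center <- c(mean(co[, 1]), mean(co[, 2]), mean(co[, 3]))
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sqrt(sum((co[i, ] - center)^2))
  shell <- r >= max(r) - thickness
  sadj <- adj & outer(shell, shell, "&")
  deg <- rowSums(sadj)
  nO <- as.integer(sadj %*% (el == "O"))
  list(adj = sadj, full_adj = adj, shell = shell, deg = deg,
       nO = nO, nM = as.integer(deg - nO), el = el, radial = r)
}

# Naive fingerprint counter: returns a named count vector over label strings
# ("O(1)", "M(2,1)", "O(0,1)-M(2,0)", ...) plus the section-1 scalars.
naive_fp_counts <- function(s, thickness, max_bonds, tolerance = 1.15) {
  g <- naive_shell_graph(s, thickness, tolerance)
  m <- max_bonds
  w <- m + 1L
  is_o <- g$el == "O"
  counts <- numeric(0)
  bump <- function(lab) {
    counts[lab] <<- (if (lab %in% names(counts)) counts[[lab]] else 0) + 1
  }
  counted <- g$shell & g$deg <= m
  for (i in which(counted)) {
    kind <- if (is_o[i]) "O" else "M"
    if (g$deg[i] >= 1) bump(sprintf("%s(%d)", kind, g$deg[i]))
    bump(sprintf("%s(%d,%d)", kind, g$nO[i], g$nM[i]))
  }
  n <- n_atoms(s)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && g$adj[i, j] && counted[i] && counted[j]) {
        pi_ <- g$nO[i] * w + g$nM[i]
        pj_ <- g$nO[j] * w + g$nM[j]
        if (is_o[i] == is_o[j]) {
          kind <- if (is_o[i]) "O" else "M"
          ps <- sort(c(pi_, pj_))
          bump(sprintf("%s(%d,%d)-%s(%d,%d)", kind, ps[1] %/% w, ps[1] %% w,
                       kind, ps[2] %/% w, ps[2] %% w))
        } else {
          po <- if (is_o[i]) pi_ else pj_
          pm <- if (is_o[i]) pj_ else pi_
          bump(sprintf("O(%d,%d)-M(%d,%d)", po %/% w, po %% w, pm %/% w, pm %% w))
        }
      }
    }
  }
  list(counts = counts,
       n_O_shell = sum(g$shell & is_o),
       n_M_shell = sum(g$shell & !is_o))
}

# Compare a packed fingerprint against naive label counts, both directions.
expect_fp_matches_naive <- function(fp, naive) {
  expect_identical(fp$n_O_shell, as.integer(naive$n_O_shell))
  expect_identical(fp$n_M_shell, as.integer(naive$n_M_shell))
  nz <- which(fp$vector != 0)
  nz <- nz[nz > 6]
  packed <- stats::setNames(fp$vector[nz], label_of(nz, fp$max_bonds))
  naive_nz <- naive$counts[naive$counts != 0]
  expect_identical(length(packed), length(naive_nz))
  if (length(packed) > 0) {
    expect_setequal(names(packed), names(naive_nz))
    expect_equal(packed[sort(names(packed))], naive_nz[sort(names(naive_nz))])
  }
}

# Naive subcomponent counter: enumerate every injective label-consistent
# assignment (cartesian product + filters) and count distinct atom sets.
naive_sub_count <- function(target, query, thickness, tolerance = 1.15) {
  g <- naive_shell_graph(target, thickness, tolerance)
  k <- length(query$nodes)
  cands <- lapply(seq_len(k), function(u) which(g$shell & g$el == query$nodes[u]))
  if (any(lengths(cands) == 0)) return(0L)
  grid <- as.matrix(expand.grid(cands, KEEP.OUT.ATTRS = FALSE))
  keep <- !apply(grid, 1, anyDuplicated)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(query$edges) > 0) {
    for (e in seq_len(nrow(query$edges))) {
      u <- query$edges[e, 1]; v <- query$edges[e, 2]
      ok <- g$adj[cbind(grid[, u], grid[, v])]
      grid <- grid[ok, , drop = FALSE]
      if (nrow(grid) == 0) return(0L)
    }
  }
  sets <- apply(grid, 1, function(r) paste(sort(r), collapse = ","))
  length(unique(sets))
}

# Seed-deterministic small random particle (<= max_atoms), drawn from the
# three lattice families with a little positional jitter.
random_small_particle <- function(seed, max_atoms = 60) {
  set.seed(seed)
  fam <- sample(3, 1)
  spec <- switch(fam,
    lattice_spec("rocksalt", 4.18, "Ni", stats::runif(1, 8.5, 10.5)),
    lattice_spec("fluorite", 5.5, "Ti", stats::runif(1, 11, 12.5)),
    lattice_spec("defective-rocksalt", 4.2, "Al", stats::runif(1, 8.5, 11)))
  s <- make_particle(spec, seed = seed, jitter = 0.08)
  while (n_atoms(s) > max_atoms) {
    spec$diameter <- spec$diameter * 0.92
    s <- make_particle(spec, seed = seed, jitter = 0.08)
  }
  s
}

# Random rigid motion (proper rotation + translation) of a structure.
rigid_motion <- function(s, seed = 1) {
  set.seed(seed)
  qrd <- qr(matrix(stats::rnorm(9), 3))
  rot <- qr.Q(qrd)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- stats::rnorm(3, sd = 5)
  nano_structure(s$elements, sweep(s$coords %*% rot, 2, -shift),
                 comment = s$comment, source = s$source)
}

# Section index ranges of the packed vector (1-based), for sum invariants.
fp_section_positions <- function(max_bonds) {
  m <- max_bonds
  w <- m + 1L
  list(
    s1 = 1:6,
    s2_O = 6L + 1:m, s2_M = 6L + m + 1:m,
    s3_O = 6L + 2L * m + 1:(w^2), s3_M = 6L + 2L * m + w^2 + 1:(w^2),
    s4_OO = 6L + 2L * m + 2L * w^2 + 1:(w^4),
    s4_MM = 6L + 2L * m + 2L * w^2 + w^4 + 1:(w^4),
    s4_OM = 6L + 2L * m + 2L * w^2 + 2L * w^4 + 1:(w^4)
  )
}

# A particle with dangling (singly coordinated) shell oxygens: a rocksalt
# cutout plus a few O atoms attached outward to single surface metals.
particle_with_dangling_o <- function(n_dangle = 4, seed = 1) {
  s <- make_particle(lattice_spec("rocksalt", 4.18, "Ni", 12), seed = seed)
  bg <- infer_bonds(s)
  surf_m <- which(s$elements != "O" & bg$degree <= 4)
  set.seed(seed)
  pick <- surf_m[sample.int(length(surf_m), min(n_dangle, length(surf_m)))]
  center <- colMeans(s$coords)
  extra <- t(vapply(pick, function(i) {
    dir <- s$coords[i, ] - center
    dir <- dir / sqrt(sum(dir^2))
    s$coords[i, ] + dir * 2.0           # within Ni-O cutoff of i only
  }, numeric(3)))
  nano_structure(c(s$elements, rep("O", nrow(extra))), rbind(s$coords, extra),
                 comment = "rocksalt cutout with dangling O", source = "synthetic")
}
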