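# Synthetic fixtures: spherical particles cut from ideal cubic lattices, a
# coordination-raising "optimisation" surrogate, and QSAR tables with planted
# effects. The lattices are idealised — rocksalt MO is exact; MO2 uses the
# fluorite geometry and M2O3 a defective-rocksalt cutout — because the tests
# only need controllable stoichiometry and coordination statistics, not
# mineralogical fidelity.

#' Lattice specification for a synthetic particle
#'
#' @param lattice `"rocksalt"` (MO, 6/6 coordination), `"fluorite"`
#'   (MO2: metal fcc, oxygen in all tetrahedral holes, 8/4 coordination) or
#'   `"defective-rocksalt"` (M2O3: rocksalt with one third of the metal sites
#'   vacated by a deterministic congruence).
#' @param lattice_constant cubic cell edge, Angstrom.
#' @param metal metal element symbol.
#' @param diameter particle diameter, Angstrom (must be at least two lattice
#'   constants).
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(lattice = c("rocksalt", "fluorite", "defective-rocksalt"),
                         lattice_constant, metal, diameter) {
  lattice <- match.arg(lattice)
  if (!is_known_element(metal) || metal == "O") {
    stop("metal must be a known metal element symbol", call. = FALSE)
  }
  if (diameter < 2 * lattice_constant) {
    stop("diameter must be at least 2 lattice constants", call. = FALSE)
  }
  structure(list(lattice = lattice, lattice_constant = lattice_constant,
                 metal = metal, diameter = diameter),
            class = "lattice_spec")
}

#' Cut a spherical particle from an ideal lattice
#'
#' Enumerates all lattice sites within `diameter / 2` of the origin and
#' returns them as a structure. Deterministic for a given spec; `jitter > 0`
#' adds a seeded uniform positional perturbation (Angstrom) for
#' roughened fixtures.
#'
#' @param spec a [lattice_spec()].
#' @param seed integer seed (used only when `jitter > 0`).
#' @param jitter per-coordinate uniform displacement half-width, Angstrom.
#' @return a [nano_structure()].
#' @export
make_particle <- function(spec, seed = 1, jitter = 0) {
  stopifnot(inherits(spec, "lattice_spec"))
  a <- spec$lattice_constant
  r_max <- spec$diameter / 2
  k <- ceiling(r_max / (a / 2)) + 1L

  if (spec$lattice %in% c("rocksalt", "defective-rocksalt")) {
    # sites at (i,j,k) * a/2; parity of i+j+k picks the species
    g <- as.matrix(expand.grid(i = -k:k, j = -k:k, k = -k:k))
    pos <- g * (a / 2)
    parity <- (g[, 1] + g[, 2] + g[, 3]) %% 2
    el <- ifelse(parity == 0, spec$metal, "O")
    if (spec$lattice == "defective-rocksalt") {
      # vacate 1/3 of metal sites: congruence on the site indices
      vac <- parity == 0 & ((g[, 1] - g[, 2] + 2 * g[, 3]) %% 6) %in% c(0, 2)
      keep_site <- !vac
      pos <- pos[keep_site, , drop = FALSE]
      el <- el[keep_site]
    }
  } else {                                   # fluorite MO2
    g <- as.matrix(expand.grid(i = -k:k, j = -k:k, k = -k:k))
    fcc <- g[(g[, 1] + g[, 2] + g[, 3]) %% 2 == 0, , drop = FALSE]
    m_pos <- fcc * (a / 2)
    # oxygen at the 8 tetrahedral holes: (odd, odd, odd)/4 positions
    og <- as.matrix(expand.grid(i = seq(-2 * k - 1, 2 * k + 1, by = 2),
                                j = seq(-2 * k - 1, 2 * k + 1, by = 2),
                                k = seq(-2 * k - 1, 2 * k + 1, by = 2)))
    o_pos <- og * (a / 4)
    pos <- rbind(m_pos, o_pos)
    el <- c(rep(spec$metal, nrow(m_pos)), rep("O", nrow(o_pos)))
  }

  r <- sqrt(rowSums(pos^2))
  keep <- r <= r_max
  if (!any(keep)) stop("diameter too small: no lattice site inside the sphere", call. = FALSE)
  pos <- pos[keep, , drop = FALSE]
  el <- el[keep]
  if (!any(el == "O") || !any(el != "O")) {
    stop("diameter too small to contain a formula unit", call. = FALSE)
  }
  if (jitter > 0) {
    set.seed(seed)
    pos <- pos + matrix(stats::runif(length(pos), -jitter, jitter), nrow(pos))
  }
  nano_structure(el, pos,
                 comment = sprintf("synthetic %s %s-O particle, d=%.3g A, a=%.3g A",
                                   spec$lattice, spec$metal, spec$diameter, a),
                 source = "synthetic")
}

#' Surrogate for crystalline optimisation
#'
#' Emulates the effect of relaxing a bulk-cut particle: a seeded fraction of
#' the undercoordinated shell oxygen atoms (degree <= 1 under default bond
#' inference) is displaced to the midpoint of its nearest two metal atoms, so
#' re-inferring bonds yields higher coordination. Atom count and order are
#' unchanged, which is what lets shell membership be frozen across the pair.
#'
#' @param structure a [nano_structure()].
#' @param rewire_fraction fraction of undercoordinated shell O atoms to move,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @param thickness shell thickness used to locate shell atoms, Angstrom.
#' @param tolerance bond-inference tolerance factor.
#' @return a [nano_structure()] with identical atoms and modified coordinates.
#' @export
perturb_optimise <- function(structure, rewire_fraction, seed = 1,
                             thickness = 5, tolerance = 1.15) {
  stopifnot(inherits(structure, "nano_structure"))
  if (rewire_fraction < 0 || rewire_fraction > 1) {
    stop("rewire_fraction must be in [0, 1]", call. = FALSE)
  }
  if (rewire_fraction == 0) return(structure)
  bg <- infer_bonds(structure, tolerance)
  shell <- assign_shell(structure, thickness)
  is_o <- structure$elements == "O"
  under <- which(is_o & shell$is_shell & bg$degree <= 1)
  if (length(under) == 0) return(structure)
  set.seed(seed)
  n_move <- max(1L, round(rewire_fraction * length(under)))
  move <- under[sample.int(length(under), min(n_move, length(under)))]
  metals <- which(!is_o)
  coords <- structure$coords
  for (i in move) {
    d <- sqrt(colSums((t(coords[metals, , drop = FALSE]) - coords[i, ])^2))
    nn <- metals[order(d)[1:2]]
    coords[i, ] <- colMeans(coords[nn, , drop = FALSE])
  }
  nano_structure(structure$elements, coords,
                 comment = paste(structure$comment, "(surrogate-optimised)"),
                 source = structure$source)
}

#' Generate a QSAR dataset with planted effects
#'
#' Features are i.i.d. standard normal. For `kind = "linear"`,
#' `y = X beta + N(0, noise^2)`; for `kind = "logistic"`,
#' `P(y = 1) = plogis(intercept + X beta)` with `intercept` available to plant
#' class imbalance. Deterministic given `seed`.
#'
#' @param n samples.
#' @param p features (must satisfy `n > p`).
#' @param beta coefficient vector of length `p`.
#' @param noise residual standard deviation (linear kind only).
#' @param kind `"linear"` or `"logistic"`.
#' @param seed integer seed.
#' @param intercept logit intercept for the logistic kind, default 0.
#' @return a [qsar_dataset()].
#' @export
make_qsar_dataset <- function(n, p, beta, noise = 1, kind = c("linear", "logistic"),
                              seed = 1, intercept = 0) {
  kind <- match.arg(kind)
  n <- as.integer(n); p <- as.integer(p)
  if (n <= p) stop("need n > p", call. = FALSE)
  if (length(beta) != p) stop("beta must have length p", call. = FALSE)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- paste0("x", seq_len(p))
  eta <- as.numeric(x %*% beta)
  y <- if (kind == "linear") {
    eta + stats::rnorm(n, 0, noise)
  } else {
    stats::rbinom(n, 1, stats::plogis(intercept + eta))
  }
  qsar_dataset(x, y)
}
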