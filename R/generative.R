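# Generative model: predict a whole fingerprint from (metal, size) without a
# 3D structure. Each vector position in the counting sections (plus the two
# shell-count slots) gets a least-squares fit of log(1 + count) on
# [1, log(size), metal indicators]; prediction inverts the transform, clamps
# at zero and rounds. Shell populations scale as powers of the particle size,
# so a log-log linear model is the natural low-parameter choice, and with few
# training structures anything richer overfits.

#' Fit a fingerprint generator
#'
#' @param training list of entries, each a list with fields `metal` (symbol
#'   or atomic number), `size` (Angstrom) and `fingerprint` (a
#'   `nano_fingerprint`). All fingerprints must share `max_bonds` and
#'   `thickness`. At least two distinct sizes per metal are required.
#' @return object of class `fp_generator`: `max_bonds`, `thickness`,
#'   `metals`, coefficient matrix, hard-zero mask, training metadata.
#' @export
fit_generator <- function(training) {
  if (length(training) < 2) stop("need at least 2 training structures", call. = FALSE)
  fps <- lapply(training, `[[`, "fingerprint")
  maxes <- vapply(fps, function(f) f$max_bonds, integer(1))
  if (length(unique(maxes)) != 1) stop("training fingerprints have mixed max_bonds", call. = FALSE)
  th <- vapply(fps, function(f) f$thickness, numeric(1))
  if (length(unique(round(th, 9))) != 1) {
    stop("training fingerprints have mixed shell thickness", call. = FALSE)
  }
  m <- maxes[1]
  sizes <- vapply(training, function(e) as.numeric(e$size), numeric(1))
  metals <- vapply(training, function(e) {
    mt <- e$metal
    if (is.numeric(mt)) {
      tab <- element_table()
      mt <- tab$symbol[match(as.integer(mt), tab$atomic_number)]
    }
    as.character(mt)
  }, character(1))
  for (mt in unique(metals)) {
    if (length(unique(sizes[metals == mt])) < 2) {
      stop("need at least 2 distinct training sizes for metal ", mt, call. = FALSE)
    }
  }

  total <- fingerprint_length(m)
  count_pos <- c(5L, 6L, 7L:total)            # shell counts + sections 2-4
  y <- t(vapply(fps, function(f) f$vector[count_pos], numeric(length(count_pos))))
  ylog <- log1p(y)

  metal_levels <- sort(unique(metals))
  x <- cbind(intercept = 1, log_size = log(sizes))
  if (length(metal_levels) > 1) {             # indicators, first level = baseline
    for (lvl in metal_levels[-1]) x <- cbind(x, as.numeric(metals == lvl))
    colnames(x)[-(1:2)] <- paste0("metal_", metal_levels[-1])
  }
  coef <- qr.solve(qr(x), ylog)               # p x L coefficient matrix
  hard_zero <- colSums(y) == 0                # never seen -> never predicted

  structure(
    list(max_bonds = m, thickness = th[1], metals = metal_levels,
         predictors = colnames(x), coefficients = coef,
         hard_zero = hard_zero, count_pos = count_pos,
         n_train = length(training), train_sizes = sizes),
    class = "fp_generator"
  )
}

#' @export
print.fp_generator <- function(x, ...) {
  cat(sprintf("<fp_generator: MAX=%d, thickness=%.3g A, metals {%s}, %d training structures>\n",
              x$max_bonds, x$thickness, paste(x$metals, collapse = ","), x$n_train))
  invisible(x)
}

#' Predict a fingerprint from metal and size
#'
#' Section-1 slots 1-4 echo the requested parameters; every count slot is
#' `round(max(0, expm1(linear prediction)))`. Positions that were zero across
#' all training data stay zero.
#'
#' @param gen a `fp_generator`.
#' @param metal element symbol or atomic number (must have been seen in
#'   training).
#' @param size particle size, Angstrom.
#' @return a `nano_fingerprint` (with no `shell`/`bond_graph`).
#' @export
predict_fingerprint <- function(gen, metal, size) {
  stopifnot(inherits(gen, "fp_generator"))
  tab <- element_table()
  if (is.numeric(metal)) metal <- tab$symbol[match(as.integer(metal), tab$atomic_number)]
  if (is.na(metal) || !metal %in% gen$metals) {
    stop("metal not seen in training: ", metal, call. = FALSE)
  }
  if (!is.numeric(size) || size <= 0) stop("size must be positive (Angstrom)", call. = FALSE)

  x <- c(1, log(size))
  if (length(gen$metals) > 1) {
    x <- c(x, as.numeric(gen$metals[-1] == metal))
  }
  pred <- as.numeric(x %*% gen$coefficients)
  counts <- round(pmax(0, expm1(pred)))
  counts[gen$hard_zero] <- 0

  m <- gen$max_bonds
  vec <- numeric(fingerprint_length(m))
  vec[1] <- gen$thickness
  vec[2] <- m
  vec[3] <- size
  vec[4] <- atomic_number(metal)
  vec[gen$count_pos] <- counts
  structure(
    list(thickness = gen$thickness, max_bonds = m, size = size,
         metal = metal, metal_atomic_number = atomic_number(metal),
         n_O_shell = as.integer(vec[5]), n_M_shell = as.integer(vec[6]),
         vector = vec, shell = NULL, bond_graph = NULL, tolerance = NA_real_,
         generated = TRUE),
    class = "nano_fingerprint"
  )
}

#' Serialise a generator to JSON
#'
#' @param gen a `fp_generator`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_generator <- function(gen, path) {
  stopifnot(inherits(gen, "fp_generator"))
  obj <- list(
    format = "fp_generator.v1",
    max_bonds = gen$max_bonds, thickness = gen$thickness,
    metals = gen$metals, predictors = gen$predictors,
    coefficients = gen$coefficients,     # p x L matrix -> nested arrays
    hard_zero = gen$hard_zero,
    count_pos = gen$count_pos,
    n_train = gen$n_train, train_sizes = gen$train_sizes
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a generator from JSON
#'
#' @param path path written by [write_generator()].
#' @return a `fp_generator`.
#' @export
read_generator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fp_generator.v1")) {
    stop("not a fp_generator file: ", path, call. = FALSE)
  }
  structure(
    list(max_bonds = as.integer(obj$max_bonds), thickness = obj$thickness,
         metals = obj$metals, predictors = obj$predictors,
         coefficients = matrix(as.numeric(obj$coefficients),
                               nrow = length(obj$predictors)),
         hard_zero = as.logical(obj$hard_zero),
         count_pos = as.integer(obj$count_pos),
         n_train = obj$n_train, train_sizes = obj$train_sizes),
    class = "fp_generator"
  )
}
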