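# Element data: symbol -> atomic number, covalent radius (Angstrom).
# Radii follow the Cordero 2008 single-bond consensus values; the table is
# also shipped as inst/extdata/covalent_radii.csv so the bond criterion is
# inspectable and versioned independently of the code.

.nanofp_env <- new.env(parent = emptyenv())

.element_table_builtin <- function() {
  data.frame(
    symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S",
               "Cl", "K", "Ca", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni",
               "Cu", "Zn", "Zr", "Ag", "Sn", "Ce", "W", "Au"),
    atomic_number = c(1L, 6L, 7L, 8L, 9L, 11L, 12L, 13L, 14L, 15L, 16L,
                      17L, 19L, 20L, 22L, 23L, 24L, 25L, 26L, 27L, 28L,
                      29L, 30L, 40L, 47L, 50L, 58L, 74L, 79L),
    covalent_radius = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.21,
                        1.11, 1.07, 1.05, 1.02, 2.03, 1.76, 1.60, 1.53,
                        1.39, 1.50, 1.52, 1.38, 1.24, 1.32, 1.22, 1.75,
                        1.45, 1.39, 2.04, 1.62, 1.36),
    stringsAsFactors = FALSE
  )
}

element_table <- function() {
  tab <- .nanofp_env$elements
  if (is.null(tab)) {
    path <- system.file("extdata", "covalent_radii.csv", package = "nanofp")
    tab <- if (nzchar(path)) {
      utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      .element_table_builtin()
    }
    .nanofp_env$elements <- tab
  }
  tab
}

#' Atomic number of an element symbol
#'
#' @param symbol character vector of element symbols (e.g. `"Ti"`).
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(symbol) {
  tab <- element_table()
  idx <- match(symbol, tab$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tab$atomic_number[idx]
}

#' Covalent radius of an element symbol
#'
#' @inheritParams atomic_number
#' @return numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(symbol) {
  tab <- element_table()
  idx <- match(symbol, tab$symbol)
  if (anyNA(idx)) {
    stop("no covalent radius for element(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tab$covalent_radius[idx]
}

is_known_element <- function(symbol) symbol %in% element_table()$symbol
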