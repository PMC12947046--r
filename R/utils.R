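#' @keywords internal
"_PACKAGE"

# Element symbols indexed by atomic number (1..118).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Convert element symbols to atomic numbers
#'
#' @param symbols character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return integer vector of atomic numbers.
#' @export
symbol_to_z <- function(symbols) {
  z <- match(symbols, .ELEMENTS)
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  as.integer(z)
}

#' Convert atomic numbers to element symbols
#'
#' @param z integer vector of atomic numbers in 1..118.
#' @return character vector of symbols.
#' @export
z_to_symbol <- function(z) {
  if (any(z < 1L | z > length(.ELEMENTS))) {
    stop("atomic number out of range 1..", length(.ELEMENTS))
  }
  .ELEMENTS[z]
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  All seeded operations in the package go
# through this so the global stream is never perturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# logistic function, overflow-safe
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

# Pairwise Euclidean distance matrix for an n x 3 coordinate matrix.
distance_matrix <- function(positions) {
  as.matrix(stats::dist(positions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
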