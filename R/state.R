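#' Spatial state of the seven model species
#'
#' A `species_state` holds the concentration profile (g/cm^3) of each species
#' over the nodes of the cartilage strip at one time point.
#'
#' @param x_grid strictly increasing node positions (cm), starting at 0 and
#'   ending at the strip width.
#' @param C,Cs,Ch,Cc,MP,L2,D concentration vectors, one value per node.
#'   Scalars are recycled to the grid length.
#' @return An object of class `species_state`.
#' @examples
#' st <- species_state(seq(0, 0.2, length.out = 5), C = 0.03, Cs = 4.5e-3,
#'                     Ch = 2.7e-4, Cc = 0, MP = 2.6e-7, L2 = 1.7e-4, D = 0)
#' @export
species_state <- function(x_grid, C, Cs, Ch, Cc, MP, L2, D) {
  n <- length(x_grid)
  rec <- function(v) if (length(v) == 1L) rep(as.numeric(v), n) else as.numeric(v)
  st <- structure(
    list(x_grid = as.numeric(x_grid),
         C = rec(C), Cs = rec(Cs), Ch = rec(Ch), Cc = rec(Cc),
         MP = rec(MP), L2 = rec(L2), D = rec(D)),
    class = "species_state")
  validate_state(st)
  st
}

#' Default age-50 initial state on a grid
#'
#' Uniform profiles at the published initial concentrations.
#'
#' @param x_grid node positions (cm).
#' @return A [species_state()].
#' @export
initial_state <- function(x_grid) {
  iv <- .oa_initial_values
  species_state(x_grid, C = iv["C"], Cs = iv["Cs"], Ch = iv["Ch"],
                Cc = iv["Cc"], MP = iv["MP"], L2 = iv["L2"], D = iv["D"])
}

#' Validate a species state
#'
#' Checks that all concentrations are finite and non-negative, that every
#' species vector has the grid's length, and that the grid is strictly
#' increasing starting at 0.
#'
#' @param state a `species_state`.
#' @return `state`, invisibly, if valid.
#' @export
validate_state <- function(state) {
  if (!inherits(state, "species_state")) stop("not a 'species_state' object")
  x <- state$x_grid
  n <- length(x)
  if (n < 2L) stop("x_grid needs at least 2 nodes")
  if (any(diff(x) <= 0)) stop("x_grid must be strictly increasing")
  if (abs(x[1L]) > 1e-12) stop("x_grid must start at 0")
  for (s in .oa_species) {
    v <- state[[s]]
    if (length(v) != n) stop("species ", s, " length differs from x_grid")
    if (any(is.na(v)) || any(!is.finite(v))) stop("NaN/Inf in species ", s)
    if (any(v < 0)) stop("negative concentration in species ", s)
  }
  invisible(state)
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state>", length(x$x_grid), "nodes on [0,",
      max(x$x_grid), "] cm\n")
  m <- sapply(.oa_species, function(s) mean(x[[s]]))
  print(signif(m, 4))
  invisible(x)
}

# matrix view used by the solver: nodes x species, column order .oa_species
state_matrix <- function(state) {
  sapply(.oa_species, function(s) state[[s]])
}

matrix_state <- function(m, x_grid) {
  species_state(x_grid, C = m[, 1], Cs = m[, 2], Ch = m[, 3], Cc = m[, 4],
                MP = m[, 5], L2 = m[, 6], D = m[, 7])
}
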