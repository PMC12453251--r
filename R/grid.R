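#' Spatial/temporal discretisation settings
#'
#' Uniform grid on the cartilage strip `[0, h]` with centred second
#' differences and ghost-node boundary treatment; first-order IMEX time
#' stepping (diffusion implicit, reactions explicit).
#'
#' @param n_nodes number of grid nodes (>= 3); default 41.
#' @param h strip width in cm; default 0.2.
#' @param dt_days time step in days; default 0.05 (sub-daily so 2-day drug
#'   pulses are resolved).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_nodes = 41L, h = 0.2, dt_days = 0.05) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  if (dt_days <= 0) stop("dt_days must be > 0")
  if (h <= 0) stop("h must be > 0")
  structure(list(n_nodes = n_nodes, h = h, dt_days = dt_days,
                 x = seq(0, h, length.out = n_nodes),
                 dx = h / (n_nodes - 1L),
                 method = "imex_euler"),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>", x$n_nodes, "nodes, dx =", signif(x$dx, 4),
      "cm, dt =", x$dt_days, "d,", x$method, "\n")
  invisible(x)
}

#' Discrete diffusion term with boundary conditions
#'
#' Applies `delta * d^2/dx^2` to a nodal field with the model's boundary
#' conditions: zero flux (ghost-node reflection) for cells, or the Robin
#' leak `dX/dn + alpha X = 0` for proteins and drug. Interior nodes use the
#' standard centred second difference.
#'
#' @param field numeric vector over the grid nodes.
#' @param species_kind `"cell"` (zero flux) or `"protein_or_drug"` (Robin).
#' @param grid a [grid_spec()].
#' @param delta diffusivity, cm^2/d (>= 0; 0 returns the zero vector).
#' @param bc_leak_alpha Robin leak rate, 1/cm (used for proteins/drug only).
#' @return vector of `delta * Laplacian(field)` values, g/cm^3/d.
#' @examples
#' g <- grid_spec(11)
#' laplacian_with_bc(rep(1, 11), "cell", g, 1e-3)  # flat field: all zero
#' @export
laplacian_with_bc <- function(field,
                              species_kind = c("cell", "protein_or_drug"),
                              grid, delta, bc_leak_alpha = NULL) {
  species_kind <- match.arg(species_kind)
  n <- grid$n_nodes
  if (length(field) != n) stop("field length does not match grid")
  if (delta < 0) stop("delta must be >= 0")
  if (delta == 0) return(numeric(n))
  dx <- grid$dx
  out <- numeric(n)
  out[2:(n - 1)] <- field[1:(n - 2)] - 2 * field[2:(n - 1)] + field[3:n]
  if (species_kind == "cell") {
    out[1] <- 2 * field[2] - 2 * field[1]
    out[n] <- 2 * field[n - 1] - 2 * field[n]
  } else {
    if (is.null(bc_leak_alpha) || bc_leak_alpha < 0)
      stop("bc_leak_alpha must be supplied (>= 0) for protein/drug fields")
    a <- bc_leak_alpha
    out[1] <- 2 * field[2] - (2 + 2 * dx * a) * field[1]
    out[n] <- 2 * field[n - 1] - (2 + 2 * dx * a) * field[n]
  }
  delta * out / dx^2
}
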