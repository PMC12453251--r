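# Model parameters: rate constants, diffusivities, drug constants, sex flag.
# Units: concentrations g/cm^3, lengths cm, time days unless noted.

.oa_param_defaults <- list(
  # cell kinetics (1/d unless noted)
  A           = 1.41e-3,   # chondrocyte source, g/cm^3/d
  lambda_CCs  = 6e-3,      # C -> Cs transition
  lambda_CCh  = 3.26e-2,   # C -> Ch transition (modulated by collagen II)
  lambda_ChCc = 1e4,       # calcified-cartilage bookkeeping multiplier (dimensionless)
  lambda_CsMP = 6.013e-5,  # MMP13 production by senescent chondrocytes
  lambda_CL2  = 1.87e-8,   # collagen II secretion by chondrocytes
  mu_C        = 0.03,      # chondrocyte death
  mu_Cs0      = 0.04,      # senescent-cell clearance at age 50
  mu_Ch       = 2.77,      # hypertrophic chondrocyte elimination
  mu_MP       = 13.86,     # MMP13 degradation
  mu_L2       = 1.62e-5,   # collagen II degradation
  mu_L2MP     = 4.897e4,   # elimination of MMP13 by collagen II, cm^3/g/d
  mu_MPL2     = 100.2,     # elimination of collagen II by MMP13, cm^3/g/d
  mu_DCs      = 3e2,       # absorption of fisetin by senescent cells, cm^3/g/d
  mu_CsD      = 1e3,       # elimination of senescent cells by fisetin, cm^3/g/d
  # diffusivities (cm^2/d)
  delta_C     = 8.64e-7,   # chondrocytes (all three cell states)
  delta_Cc    = 0,         # calcified cartilage (immobile)
  delta_MP    = 6.6e-2,    # MMP13
  delta_L2    = 4.78e-2,   # collagen II
  delta_D     = 0.3782,    # fisetin (Young scaling at 286.24 Da, see young_diffusion)
  # saturation / drug-effect constants
  K_L2        = 1.7e-4,    # half-saturation of collagen II block, g/cm^3
  alpha_D     = 2e6,       # fisetin effect on MMP13 production, cm^3/g
  alpha_U2    = 0.05,      # scaling of UC-II source into collagen II
  # postmenopausal terms
  alpha_w_MP  = 2.5,       # amplitude acting on MMP13, 1/d
  alpha_w_L2  = 2.5e-4,    # amplitude acting on collagen II, 1/d
  T_w_MP      = 12,        # time scale, years
  T_w_L2      = 12,        # time scale, years
  # drug inputs
  gamma_D     = 1.52e-6,   # fisetin dose density, g/cm^3/d
  gamma_U2    = 6.1e-7,    # UC-II dose density, g/cm^3/d
  mu_D        = 5.55,      # fisetin degradation (3 h terminal half-life), 1/d
  omega_D     = 0.01,      # fisetin washout, 1/d
  # geometry and numerics-facing constants
  h             = 0.2,     # cartilage strip width, cm
  bc_leak_alpha = 4.9e-4,  # Robin leak rate for proteins/drug, 1/cm (see vignette)
  days_per_year = 365
)

# Initial spatial profiles at age 50 (uniform across the strip), g/cm^3.
.oa_initial_values <- c(
  C = 3e-2, Cs = 4.5e-3, Ch = 2.7e-4, Cc = 0,
  MP = 2.6e-7, L2 = 1.7e-4, D = 0
)

.oa_species <- c("C", "Cs", "Ch", "Cc", "MP", "L2", "D")

#' Model parameters for the osteoarthritis simulator
#'
#' Builds the full parameter set of the cartilage reaction-diffusion model:
#' rate constants, diffusivities, drug constants, the cartilage width, the
#' Robin boundary leak rate, the sex flag and structural options. Defaults
#' are the published parameter table; any value can be overridden by name.
#'
#' @param sex `"male"` or `"female"`. Females have the additional
#'   postmenopausal terms `+dp_MP(t)*MP` and `-dp_L2(t)*L2` in the MMP13 and
#'   collagen II equations.
#' @param ... named overrides of any default parameter (see
#'   [oa_param_defaults()] for names and units).
#' @param ch_calcification_sink How the calcification term
#'   `lambda_ChCc * dCh/dt` enters the hypertrophic-chondrocyte equation:
#'   `"none"` (default) keeps the Ch equation free of the term, so Ch relaxes
#'   at rate `mu_Ch` (the ~1-day lifespan used to calibrate `mu_Ch`) and the
#'   term acts purely as the source of calcified cartilage; `"algebraic"`
#'   moves it to the left-hand side, dividing the whole Ch rate by
#'   `(1 + lambda_ChCc)`. See the methods vignette for why `"none"` is the
#'   default.
#' @param mu_cs_aging Direction of the age dependence of senescent-cell
#'   clearance: `"increasing"` (default), `mu_Cs0 * (1 + t/90y)`, or
#'   `"decreasing"`, `mu_Cs0 / (1 + t/90y)`.
#' @param cc_source_clamp If `TRUE`, only the positive part of the
#'   calcification source feeds calcified cartilage. Default `FALSE`
#'   (literal equations; the positivity clip of the solver still keeps
#'   concentrations non-negative).
#' @param initial_state optional [species_state()] used as the age-50 initial
#'   condition. Defaults to the published uniform initial profiles; the
#'   spatial grid of a supplied state must match the grid used in
#'   [oa_simulate()].
#'
#' @return An object of class `oa_params` (a named list).
#' @examples
#' p <- oa_params("female", bc_leak_alpha = 1e-3)
#' p$mu_Ch
#' @export
oa_params <- function(sex = c("male", "female"), ...,
                      ch_calcification_sink = c("none", "algebraic"),
                      mu_cs_aging = c("increasing", "decreasing"),
                      cc_source_clamp = FALSE,
                      initial_state = NULL) {
  sex <- match.arg(sex)
  ch_calcification_sink <- match.arg(ch_calcification_sink)
  mu_cs_aging <- match.arg(mu_cs_aging)
  p <- .oa_param_defaults
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$sex <- sex
  p$ch_calcification_sink <- ch_calcification_sink
  p$mu_cs_aging <- mu_cs_aging
  p$cc_source_clamp <- isTRUE(cc_source_clamp)
  p$initial_state <- initial_state
  structure(p, class = "oa_params")
}

#' Default parameter values
#'
#' @return Named list of the default numeric parameters (no sex flag or
#'   structural options), with names matching the configuration file
#'   `system.file("extdata", "table7.yaml", package = "oasim")`.
#' @export
oa_param_defaults <- function() .oa_param_defaults

#' Default initial concentrations at age 50
#'
#' @return Named numeric vector (g/cm^3) for species C, Cs, Ch, Cc, MP, L2, D.
#' @export
oa_initial_values <- function() .oa_initial_values

#' Validate a parameter object
#'
#' Checks non-negativity of all rates, diffusivities and doses, positivity of
#' `h`, `K_L2` and `bc_leak_alpha`, and the sex flag.
#'
#' @param params an `oa_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "oa_params")) stop("not an 'oa_params' object")
  num <- names(.oa_param_defaults)
  vals <- unlist(params[num])
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  if (any(vals < 0))
    stop("negative parameter(s): ",
         paste(num[vals < 0], collapse = ", "))
  if (params$h <= 0) stop("h must be > 0")
  if (params$K_L2 <= 0) stop("K_L2 must be > 0")
  if (params$bc_leak_alpha <= 0) stop("bc_leak_alpha must be > 0")
  if (!params$sex %in% c("male", "female")) stop("sex must be male or female")
  if (!is.null(params$initial_state)) validate_state(params$initial_state)
  invisible(params)
}

#' @export
print.oa_params <- function(x, ...) {
  cat("<oa_params> sex =", x$sex,
      "| ch sink =", x$ch_calcification_sink,
      "| mu_Cs(t)", x$mu_cs_aging, "\n")
  num <- names(.oa_param_defaults)
  v <- unlist(x[num])
  out <- data.frame(parameter = num, value = signif(v, 6))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Read a parameter configuration file
#'
#' Reads a flat key/value YAML (or JSON) file of parameter overrides, such as
#' the bundled `table7.yaml`, and returns the corresponding `oa_params`.
#' Unknown keys are rejected.
#'
#' @param path file path to a YAML or JSON mapping of parameter names to
#'   values.
#' @param sex,... passed to [oa_params()].
#' @return An `oa_params` object.
#' @export
read_params_config <- function(path, sex = "male", ...) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- lapply(vals, as.numeric)
  do.call(oa_params, c(list(sex = sex), vals, list(...)))
}

#' Path to the bundled default parameter configuration
#' @return Path of `table7.yaml` inside the installed package.
#' @export
default_params_file <- function() {
  system.file("extdata", "table7.yaml", package = "oasim", mustWork = TRUE)
}
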