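# Non-diffusive (reaction) right-hand sides and their time-varying
# coefficients. All rates returned in g/cm^3/d.

#' Age-dependent senescent-cell clearance rate
#'
#' The clearance rate of senescent chondrocytes drifts with age over the
#' 50-90 year cohort: `mu_Cs0 * (1 + t / 90y)` in the default `"increasing"`
#' form, or `mu_Cs0 / (1 + t / 90y)` in the `"decreasing"` variant (immune
#' clearance weakening with age).
#'
#' @param t_days days since age 50 (non-negative).
#' @param params an [oa_params()] object.
#' @return clearance rate(s), 1/d; vectorised over `t_days`.
#' @examples
#' mu_cs(0, oa_params())                 # 0.04
#' mu_cs(90 * 365, oa_params())          # doubled
#' @export
mu_cs <- function(t_days, params) {
  if (any(t_days < 0)) stop("t_days must be >= 0")
  s <- t_days / (90 * params$days_per_year)
  if (identical(params$mu_cs_aging, "decreasing")) params$mu_Cs0 / (1 + s)
  else params$mu_Cs0 * (1 + s)
}

#' Postmenopausal decay coefficients
#'
#' Time-dependent coefficients `dp_X(t) = alpha_w_X / (1 + t^2 / T_w_X^2)`
#' (t and T_w in years) that, for females, add `+dp_MP(t)*MP` to the MMP13
#' equation and `-dp_L2(t)*L2` to the collagen II equation. Strictly
#' decreasing in age from `alpha_w_X` at age 50.
#'
#' @param t_days days since age 50 (non-negative).
#' @param species `"MP"` or `"L2"`.
#' @param params an [oa_params()] object.
#' @return coefficient(s), 1/d; vectorised over `t_days`.
#' @examples
#' dp_menopause(0, "MP", oa_params())    # 2.5
#' @export
dp_menopause <- function(t_days, species, params) {
  if (any(t_days < 0)) stop("t_days must be >= 0")
  if (!species %in% c("MP", "L2")) stop("species must be 'MP' or 'L2'")
  a <- if (species == "MP") params$alpha_w_MP else params$alpha_w_L2
  Tw <- if (species == "MP") params$T_w_MP else params$T_w_L2
  ty <- t_days / params$days_per_year
  a / (1 + ty^2 / Tw^2)
}

#' Reaction terms of the model (non-diffusive right-hand sides)
#'
#' Evaluates, nodewise, the reaction part of every species equation,
#' including drug couplings and (for females) the postmenopausal terms.
#' The hypertrophic-chondrocyte rate is returned as the solved time
#' derivative: under the default structural option the calcification term
#' does not act as a sink on Ch, and the calcified-cartilage rate is
#' `lambda_ChCc` times the Ch rate; under `"algebraic"` the Ch rate is
#' divided by `(1 + lambda_ChCc)`.
#'
#' Note the Ch/Cc entries returned here are the reaction-only parts; in the
#' solver the calcified-cartilage update uses the full Ch change including
#' diffusion.
#'
#' @param state a [species_state()].
#' @param t_days days since age 50.
#' @param params an [oa_params()] object.
#' @param u2_input UC-II source `gamma_U2 * h_U2(t)` (g/cm^3/d, scalar or
#'   per-node).
#' @param d_input fisetin source `gamma_D * h_D(t)` (g/cm^3/d, scalar or
#'   per-node).
#' @return named list of per-species rate vectors (g/cm^3/d).
#' @examples
#' g <- seq(0, 0.2, length.out = 5)
#' st <- species_state(g, 0, 0, 0, 0, 0, 0, 0)
#' reaction_terms(st, 0, oa_params())$C  # equals the source A everywhere
#' @export
reaction_terms <- function(state, t_days, params, u2_input = 0, d_input = 0) {
  validate_state(state)
  if (t_days < 0) stop("t_days must be >= 0")
  p <- params
  C <- state$C; Cs <- state$Cs; Ch <- state$Ch
  MP <- state$MP; L2 <- state$L2; D <- state$D

  fem <- identical(p$sex, "female")
  muCs <- mu_cs(t_days, p)
  block <- 1 / (1 + L2 / p$K_L2)
  hyp <- p$lambda_CCh * C * block

  fC  <- p$A - p$lambda_CCs * C - hyp - p$mu_C * C
  fCs <- p$lambda_CCs * C - muCs * Cs - p$mu_CsD * Cs * D
  div <- if (identical(p$ch_calcification_sink, "algebraic"))
    1 + p$lambda_ChCc else 1
  fCh <- (hyp - p$mu_Ch * Ch) / div
  fCc <- p$lambda_ChCc * (if (p$cc_source_clamp) pmax(fCh, 0) else fCh)
  fMP <- p$lambda_CsMP * Cs / (1 + p$alpha_D * D) -
    p$mu_L2MP * MP * L2 - p$mu_MP * MP
  fL2 <- p$alpha_U2 * u2_input + p$lambda_CL2 * C -
    p$mu_MPL2 * L2 * MP - p$mu_L2 * L2
  if (fem) {
    fMP <- fMP + dp_menopause(t_days, "MP", p) * MP
    fL2 <- fL2 - dp_menopause(t_days, "L2", p) * L2
  }
  fD <- d_input - p$mu_DCs * D * Cs - p$omega_D * D

  n <- length(state$x_grid)
  expand <- function(v) if (length(v) == 1L) rep(v, n) else v
  list(C = expand(fC), Cs = expand(fCs), Ch = expand(fCh), Cc = expand(fCc),
       MP = expand(fMP), L2 = expand(fL2), D = expand(fD))
}
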