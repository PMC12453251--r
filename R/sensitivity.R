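# Global sensitivity analysis: Latin Hypercube Sampling over +/-50% ranges
# and partial rank correlation coefficients (PRCC) of the calcified-cartilage
# density after one year of disease progression.

.oa_sens_params <- c("lambda_CCs", "lambda_CCh", "lambda_ChCc", "lambda_CsMP",
                     "lambda_CL2", "mu_C", "mu_Cs0", "mu_Ch", "mu_L2MP",
                     "mu_MP", "mu_MPL2", "mu_L2", "A")

#' Specification of a sensitivity analysis
#'
#' @param parameters parameter names to perturb; default the 13 kinetic
#'   constants of the progression model (the age drift of senescent-cell
#'   clearance is perturbed through its age-50 scalar `mu_Cs0`).
#' @param range_fraction half-width of the uniform sampling range as a
#'   fraction of the baseline (default 0.5, i.e. +/-50%).
#' @param n_samples number of LHS rows; must exceed the number of parameters
#'   plus 2 (degrees of freedom of the partial correlation).
#' @param rng_seed integer seed making the design reproducible.
#' @param horizon_days output time (default 1 year).
#' @return An object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(parameters = .oa_sens_params,
                             range_fraction = 0.5, n_samples = 200,
                             rng_seed = 1, horizon_days = 365) {
  base <- unlist(.oa_param_defaults[parameters])
  if (any(is.na(base))) stop("unknown parameter in 'parameters'")
  if (range_fraction <= 0 || range_fraction >= 1)
    stop("range_fraction must be in (0, 1)")
  if (n_samples <= length(parameters) + 2)
    stop("n_samples must exceed number of parameters + 2")
  if (any(base * (1 - range_fraction) <= 0))
    stop("sampling range must be strictly positive")
  structure(list(parameters = parameters, baseline = base,
                 range_fraction = range_fraction,
                 n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed),
                 horizon_days = horizon_days),
            class = "sensitivity_spec")
}

#' Latin Hypercube sample of the parameter space
#'
#' One stratified uniform draw per equiprobable stratum and parameter over
#' `[(1-f) * base, (1+f) * base]`, reproducible under the spec's seed.
#'
#' @param spec a [sensitivity_spec()].
#' @return numeric matrix `n_samples x n_parameters` with named columns.
#' @export
lhs_sample <- function(spec) {
  if (spec$n_samples < 2) stop("n_samples must be >= 2")
  k <- length(spec$parameters)
  set.seed(spec$rng_seed)
  u <- lhs::randomLHS(spec$n_samples, k)
  lo <- spec$baseline * (1 - spec$range_fraction)
  hi <- spec$baseline * (1 + spec$range_fraction)
  m <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(m) <- spec$parameters
  m
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms inputs and output; for each parameter, correlates the
#' residuals of its ranks and the output's ranks after linearly regressing
#' out the ranks of all other parameters. P-values from the t-statistic with
#' `n - p - 2` degrees of freedom (`p` = number of controlled parameters).
#'
#' @param samples matrix of sampled inputs (rows = runs).
#' @param outputs numeric vector of model outputs, one per row.
#' @return `data.frame` with `parameter`, `prcc`, `p_value`, `n`.
#' @export
prcc <- function(samples, outputs) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  k <- ncol(samples)
  if (length(outputs) != n) stop("outputs length must match sample rows")
  const <- apply(samples, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant sample column(s): ",
         paste(colnames(samples)[const], collapse = ", "))
  if (diff(range(outputs)) == 0) stop("outputs are constant")
  R <- apply(samples, 2, rank)
  ry <- rank(outputs)
  df <- n - (k - 1) - 2
  if (df < 1) stop("too few samples for the number of parameters")
  out <- lapply(seq_len(k), function(j) {
    others <- R[, -j, drop = FALSE]
    rx <- stats::lm.fit(cbind(1, others), R[, j])$residuals
    rz <- stats::lm.fit(cbind(1, others), ry)$residuals
    r <- stats::cor(rx, rz)
    tstat <- r * sqrt(df / (1 - r^2))
    data.frame(parameter = colnames(samples)[j], prcc = r,
               p_value = 2 * stats::pt(-abs(tstat), df), n = n)
  })
  do.call(rbind, out)
}

#' Full LHS/PRCC sensitivity analysis of disease progression
#'
#' Samples the kinetic parameters with [lhs_sample()], runs the untreated
#' male model for each row over the spec's horizon, takes the
#' calcified-cartilage spatial average as output, and returns its PRCC per
#' parameter. A coarse grid (21 nodes) is the default: rank-based sensitivity
#' signs are grid-robust.
#'
#' @param spec a [sensitivity_spec()].
#' @param grid a [grid_spec()].
#' @return list with `prcc` (data.frame, columns `parameter, prcc, p_value,
#'   n` plus the seed), `samples` and `outputs`.
#' @export
oa_sensitivity <- function(spec = sensitivity_spec(),
                           grid = grid_spec(n_nodes = 21)) {
  m <- lhs_sample(spec)
  horizon_age <- 50 + spec$horizon_days / .oa_param_defaults$days_per_year
  outputs <- vapply(seq_len(nrow(m)), function(i) {
    ov <- as.list(m[i, ])
    p <- do.call(oa_params, c(list(sex = "male"), ov))
    sim <- oa_simulate(p, NULL, end_age = horizon_age, grid = grid,
                       record_every_days = spec$horizon_days)
    unname(sim$averages[nrow(sim$averages), "Cc"])
  }, numeric(1))
  res <- prcc(m, outputs)
  res$seed <- spec$rng_seed
  list(prcc = res, samples = m, outputs = outputs, spec = spec)
}
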