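#' Simulate the cartilage model over an age window
#'
#' Integrates the full reaction-diffusion system. Every simulation starts
#' internally at age 50 from the published initial condition (or
#' `params$initial_state`), so a run is reproducible from the single printed
#' initial state; treatment simply switches drug sources on inside the
#' schedule's window.
#'
#' @param params an [oa_params()] object.
#' @param schedule a [dose_schedule()] or `NULL` for no treatment.
#' @param start_age lower bound of the (treatment) window, years; the system
#'   itself is always integrated from age 50.
#' @param end_age final age, years (<= 90 by convention of the cohort; ages
#'   outside 50-90 are rejected).
#' @param grid a [grid_spec()].
#' @param record_every_days spacing of recorded snapshots in days; must be a
#'   multiple of the time step.
#' @return An object of class `oa_sim` with elements `times` (days since age
#'   50), `averages` (matrix, one row per recorded time, one column per
#'   species: trapezoidal spatial means over the strip), `profiles` (array
#'   nodes x species x times), `x_grid`, `clip_max` (largest negativity
#'   excursion removed per species) and the run settings.
#' @examples
#' sim <- oa_simulate(oa_params(), end_age = 51, grid = grid_spec(11),
#'                    record_every_days = 30)
#' species_average(sim, "Cc", age = 51)
#' @export
oa_simulate <- function(params, schedule = NULL, start_age = 50,
                        end_age = 90, grid = grid_spec(),
                        record_every_days = 30) {
  validate_params(params)
  if (start_age < 50 || end_age > 90 || start_age > end_age)
    stop("ages must satisfy 50 <= start_age <= end_age <= 90")
  if (is.null(schedule)) schedule <- no_treatment()
  dpy <- params$days_per_year
  total_days <- (end_age - 50) * dpy
  dt <- grid$dt_days
  n_steps <- round(total_days / dt)
  if (abs(n_steps * dt - total_days) > 1e-9)
    stop("dt_days must divide the simulated time span")
  rec_steps <- round(record_every_days / dt)
  if (rec_steps < 1 || abs(rec_steps * dt - record_every_days) > 1e-9)
    stop("record_every_days must be a positive multiple of dt_days")

  st <- if (is.null(params$initial_state)) initial_state(grid$x)
        else params$initial_state
  if (length(st$x_grid) != grid$n_nodes ||
      max(abs(st$x_grid - grid$x)) > 1e-12)
    stop("initial_state grid does not match grid_spec")

  iv <- schedule$u2_intervals
  if (is.null(iv)) iv <- matrix(numeric(0), ncol = 2)
  if (schedule$gamma_U2 == 0) iv <- matrix(numeric(0), ncol = 2)
  dd <- schedule$d_dose_days
  if (is.null(dd) || schedule$gamma_D == 0) dd <- numeric(0)

  cpar <- params[names(.oa_param_defaults)]
  cpar$gamma_U2 <- schedule$gamma_U2
  cpar$gamma_D <- schedule$gamma_D
  cpar$female <- as.integer(identical(params$sex, "female"))
  cpar$mu_cs_decreasing <-
    as.integer(identical(params$mu_cs_aging, "decreasing"))
  cpar$cc_clamp <- as.integer(isTRUE(params$cc_source_clamp))
  cpar$ch_div <- if (identical(params$ch_calcification_sink, "algebraic"))
    1 + params$lambda_ChCc else 1

  if (n_steps == 0) {
    m <- state_matrix(st)
    res <- list(times = 0,
                averages = matrix(apply(m, 2, .trap_mean, dx = grid$dx,
                                        h = grid$h), nrow = 1),
                profiles = array(m, dim = c(grid$n_nodes, 7, 1)),
                clip_max = numeric(7))
  } else {
    res <- .oa_step_core(state_matrix(st), cpar, grid$dx, dt,
                         as.integer(n_steps), as.integer(rec_steps),
                         iv, dd)
  }
  colnames(res$averages) <- .oa_species
  names(res$clip_max) <- .oa_species
  bad <- res$clip_max[setdiff(.oa_species, "Cc")]
  if (any(bad > 1e-12))
    warning("negative-concentration excursions clipped (max ",
            signif(max(bad), 3), " in ",
            names(bad)[which.max(bad)],
            "); consider a smaller dt_days")
  structure(list(times = as.numeric(res$times), averages = res$averages,
                 profiles = res$profiles, x_grid = grid$x,
                 clip_max = res$clip_max, params = params,
                 schedule = schedule, grid = grid,
                 start_age = start_age, end_age = end_age),
            class = "oa_sim")
}

.trap_mean <- function(v, dx, h) {
  (sum(v) - 0.5 * (v[1] + v[length(v)])) * dx / h
}

#' @export
print.oa_sim <- function(x, ...) {
  cat("<oa_sim>", x$params$sex, "| ages 50 -", x$end_age, "|",
      length(x$times), "snapshots |", x$grid$n_nodes, "nodes\n")
  cat("final spatial averages (g/cm^3):\n")
  print(signif(x$averages[nrow(x$averages), ], 4))
  invisible(x)
}

#' Spatial-average trajectory or point value of one species
#'
#' @param sim an [oa_simulate()] result.
#' @param species one of `"C"`, `"Cs"`, `"Ch"`, `"Cc"`, `"MP"`, `"L2"`,
#'   `"D"`.
#' @param age if supplied, the age (years) at which to evaluate; must match a
#'   recorded snapshot.
#' @return The full trajectory (named by time in days) or, with `age`, one
#'   value.
#' @export
species_average <- function(sim, species, age = NULL) {
  if (!species %in% .oa_species) stop("unknown species: ", species)
  v <- sim$averages[, species]
  if (is.null(age)) {
    names(v) <- sim$times
    return(v)
  }
  t_target <- (age - 50) * sim$params$days_per_year
  i <- which(abs(sim$times - t_target) < 1e-6)
  if (length(i) != 1L)
    stop("age ", age, " was not recorded; adjust record_every_days")
  v[i]
}

#' Recorded state at a given age
#'
#' @param sim an [oa_simulate()] result.
#' @param age age in years matching a recorded snapshot.
#' @return A [species_state()].
#' @export
state_at <- function(sim, age) {
  t_target <- (age - 50) * sim$params$days_per_year
  i <- which(abs(sim$times - t_target) < 1e-6)
  if (length(i) != 1L) stop("age ", age, " was not recorded")
  matrix_state(sim$profiles[, , i], sim$x_grid)
}

#' Tidy data frame of a simulation
#'
#' @param x an `oa_sim` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @param profiles if `TRUE`, emit the full nodewise profiles (columns
#'   `time_days, age_years, species, x_cm, value`); otherwise one row per
#'   time and species with the spatial average.
#' @return A `data.frame` in long format.
#' @export
as.data.frame.oa_sim <- function(x, row.names = NULL, optional = FALSE,
                                 profiles = FALSE, ...) {
  dpy <- x$params$days_per_year
  if (!profiles) {
    out <- expand.grid(time_days = x$times, species = .oa_species,
                       stringsAsFactors = FALSE)
    out$age_years <- 50 + out$time_days / dpy
    out$value <- as.vector(x$averages)
    return(out[, c("time_days", "age_years", "species", "value")])
  }
  out <- expand.grid(x_cm = x$x_grid, species = .oa_species,
                     time_days = x$times, stringsAsFactors = FALSE)
  out$age_years <- 50 + out$time_days / dpy
  out$value <- as.vector(x$profiles)
  out[, c("time_days", "age_years", "species", "x_cm", "value")]
}

#' Write a simulation to CSV (+ JSON metadata sidecar)
#'
#' Writes the spatial-averages table (and optionally full profiles) as tidy
#' CSV, plus a `.meta.json` sidecar describing the run (parameters, grid,
#' boundary leak rate, schedule).
#'
#' @param sim an `oa_sim` object.
#' @param path output CSV path.
#' @param profiles include nodewise profiles instead of averages.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path, profiles = FALSE) {
  df <- as.data.frame(sim, profiles = profiles)
  utils::write.csv(format(df, digits = 6, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(
    sex = sim$params$sex,
    end_age = sim$end_age,
    n_nodes = sim$grid$n_nodes,
    dt_days = sim$grid$dt_days,
    bc_leak_alpha = sim$params$bc_leak_alpha,
    ch_calcification_sink = sim$params$ch_calcification_sink,
    mu_cs_aging = sim$params$mu_cs_aging,
    drug = sim$schedule$drug,
    params = sim$params[names(.oa_param_defaults)])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
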