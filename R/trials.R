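# Treatment efficacy, clinical scenarios T1-T4 and in-silico trial matrices.

#' Treatment efficacy (relative calcified-cartilage reduction)
#'
#' `100 * (control - treated) / control`, the percent reduction of the
#' spatial-average calcified-cartilage density under treatment relative to
#' the untreated run at the same age.
#'
#' @param cc_treated,cc_control spatial averages of calcified cartilage at
#'   the evaluation age (g/cm^3); `cc_control` must be positive (efficacy is
#'   undefined before any calcification).
#' @return efficacy in percent.
#' @examples
#' efficacy(0.05, 0.10)  # 50
#' @export
efficacy <- function(cc_treated, cc_control) {
  if (any(cc_control <= 0))
    stop("efficacy undefined: control calcified cartilage is not positive")
  100 * (cc_control - cc_treated) / cc_control
}

#' Count-weighted efficacy for a mixed male/female cohort
#'
#' @param eff_male,eff_female sex-specific efficacies, percent.
#' @param n_male,n_female participant counts (>= 0, not both 0).
#' @return the weighted average, percent.
#' @examples
#' e_efficacy(10, 20, 30, 22)
#' @export
e_efficacy <- function(eff_male, eff_female, n_male, n_female) {
  if (n_male < 0 || n_female < 0) stop("counts must be >= 0")
  if (n_male + n_female <= 0) stop("need at least one participant")
  if (!all(is.finite(c(eff_male, eff_female)))) stop("efficacies must be finite")
  (n_male * eff_male + n_female * eff_female) / (n_male + n_female)
}

# registry of the four UC-II clinical studies: male/female counts and the
# average participant age at which the 90-day treatment ends
.oa_scenarios <- list(
  T1 = list(n_male = 30, n_female = 22, avg_age = 63),
  T2 = list(n_male = 89, n_female = 97, avg_age = 63),
  T3 = list(n_male = 36, n_female = 69, avg_age = 70),
  T4 = list(n_male = 0,  n_female = 39, avg_age = 65)
)

#' Scenario registry for treatments T1-T4
#' @return Named list with male/female counts and average cohort age.
#' @export
oa_scenarios <- function() .oa_scenarios

#' Replicate one of the clinical UC-II treatments T1-T4
#'
#' Simulates both sexes with the 90-day daily UC-II protocol ending at the
#' scenario's average cohort age, computes the per-sex efficacy against the
#' matched no-drug run at that age, and weights by the study's male/female
#' counts.
#'
#' @param name `"T1"`, `"T2"`, `"T3"` or `"T4"`.
#' @param params_m,params_f male and female parameter sets.
#' @param grid a [grid_spec()].
#' @return list with `e_efficacy` (percent), per-sex efficacies, counts and
#'   the evaluation age.
#' @export
run_treatment_scenario <- function(name, params_m = oa_params("male"),
                                   params_f = oa_params("female"),
                                   grid = grid_spec()) {
  sc <- .oa_scenarios[[name]]
  if (is.null(sc)) stop("unknown scenario: ", name)
  age <- sc$avg_age
  sched <- make_schedule("t1_t4_daily_90d", 50, age)
  eff_one <- function(params) {
    ctrl <- oa_simulate(params, NULL, end_age = age, grid = grid,
                        record_every_days = 5)
    trt <- oa_simulate(params, sched, end_age = age, grid = grid,
                       record_every_days = 5)
    efficacy(species_average(trt, "Cc", age),
             species_average(ctrl, "Cc", age))
  }
  eff_m <- if (sc$n_male > 0) eff_one(params_m) else 0
  eff_f <- if (sc$n_female > 0) eff_one(params_f) else 0
  list(scenario = name,
       e_efficacy = e_efficacy(eff_m, eff_f, sc$n_male, sc$n_female),
       eff_male = eff_m, eff_female = eff_f,
       n_male = sc$n_male, n_female = sc$n_female,
       eval_age = age)
}

.arm_schedule <- function(arm, init_age, end_age, fisetin_pattern) {
  u2 <- if (arm %in% c("UC-II", "UC-II+D"))
    make_schedule("uc2_6mo_cycle", init_age, end_age) else NULL
  d <- if (arm %in% c("D", "UC-II+D"))
    make_schedule(paste0("fisetin_", fisetin_pattern), init_age, end_age)
  else NULL
  combine_schedules(u2, d)
}

#' In-silico trial matrix over initiation and end ages
#'
#' For every pair `init <= end` of ages and every treatment arm, simulates
#' treatment over `[init, end]` and evaluates [efficacy()] at the evaluation
#' age (by default the end age) against the same-sex untreated run. Diagonal
#' cells (`init == end`, an empty treatment window) are 0 by definition.
#'
#' @param sex `"male"` or `"female"`.
#' @param arms subset of `c("UC-II", "D", "UC-II+D")`.
#' @param init_ages,end_ages age vectors (years, within 50-90).
#' @param fisetin_pattern `"monthly_2d"`, `"weekly_2d"` or `"7on7off"`.
#' @param grid a [grid_spec()].
#' @param params parameter set for the chosen sex; defaults to
#'   `oa_params(sex)`.
#' @param evaluate_at `NULL` to evaluate each cell at its end age, or a
#'   fixed age (e.g. 90).
#' @return An object of class `trial_grid`: a long `data.frame`
#'   (`arm, init_age, end_age, efficacy`) plus attributes.
#' @export
trial_matrix <- function(sex, arms = c("UC-II", "D", "UC-II+D"),
                         init_ages = seq(50, 90, by = 5),
                         end_ages = seq(50, 90, by = 5),
                         fisetin_pattern = "monthly_2d",
                         grid = grid_spec(), params = NULL,
                         evaluate_at = NULL) {
  arms <- match.arg(arms, c("UC-II", "D", "UC-II+D"), several.ok = TRUE)
  if (is.null(params)) params <- oa_params(sex)
  if (!identical(params$sex, sex)) stop("params$sex does not match sex")
  max_age <- if (is.null(evaluate_at)) max(end_ages) else
    max(evaluate_at, end_ages)
  ctrl <- oa_simulate(params, NULL, end_age = max_age, grid = grid,
                      record_every_days = 5)
  rows <- list()
  for (arm in arms) for (a0 in init_ages) for (a1 in end_ages) {
    if (a0 > a1) next
    eval_age <- if (is.null(evaluate_at)) a1 else evaluate_at
    if (a0 == a1) {
      eff <- 0
    } else {
      sched <- .arm_schedule(arm, a0, a1, fisetin_pattern)
      trt <- oa_simulate(params, sched, start_age = a0, end_age = eval_age,
                         grid = grid, record_every_days = 5)
      eff <- efficacy(species_average(trt, "Cc", eval_age),
                      species_average(ctrl, "Cc", eval_age))
    }
    rows[[length(rows) + 1L]] <-
      data.frame(arm = arm, init_age = a0, end_age = a1, efficacy = eff)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("trial_grid", "data.frame"), sex = sex,
            fisetin_pattern = fisetin_pattern,
            bc_leak_alpha = params$bc_leak_alpha,
            evaluate_at = evaluate_at)
}

#' @export
print.trial_grid <- function(x, ...) {
  cat("<trial_grid>", attr(x, "sex"), "| fisetin", attr(x, "fisetin_pattern"),
      "| efficacy (%) by [arm, end age x initiation age]\n")
  for (arm in unique(x$arm)) {
    cat("arm:", arm, "\n")
    sub <- x[x$arm == arm, ]
    ia <- sort(unique(sub$init_age)); ea <- sort(unique(sub$end_age))
    m <- matrix(NA_real_, length(ea), length(ia),
                dimnames = list(end_age = ea, init_age = ia))
    m[cbind(match(sub$end_age, ea), match(sub$init_age, ia))] <- sub$efficacy
    print(round(m, 2), na.print = "")
  }
  invisible(x)
}

#' Write a trial grid as wide CSV (one block per arm) and tidy CSV
#'
#' @param grid_result a [trial_matrix()] result.
#' @param path base CSV path; the tidy long table is written at `path` and a
#'   wide, table-style layout at `<path>_wide.csv`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(grid_result, path) {
  utils::write.csv(as.data.frame(grid_result), path, row.names = FALSE)
  wide <- stats::reshape(as.data.frame(grid_result),
                         idvar = c("arm", "end_age"),
                         timevar = "init_age", direction = "wide")
  utils::write.csv(wide, sub("\\.csv$", "_wide.csv", path), row.names = FALSE)
  invisible(path)
}
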