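# Treatment schedules and drug input functions.
#
# UC-II acts as a constant-rate source (gamma_U2, g/cm^3/d) on every dosing
# day; fisetin doses are exponential impulses decaying at the drug's
# degradation rate mu_D. Calendar constants: month = 30 d, week = 7 d,
# 6 months = 182 d, year = 364 d for on/off cycling (documented, since the
# clinical schedules never define them).

.oa_month_days <- 30
.oa_week_days <- 7
.oa_halfyear_days <- 182

#' Treatment schedule
#'
#' Describes which drug(s) are given and when. Times are expressed in days
#' since age 50, the simulator's time origin.
#'
#' @param drug `"U2"` (UC-II), `"D"` (fisetin) or `"both"`.
#' @param u2_intervals two-column matrix of `[start, end)` day intervals
#'   during which UC-II is given daily (constant source), or `NULL`.
#' @param d_dose_days sorted vector of fisetin administration days, or
#'   `NULL`.
#' @param start_age,end_age treatment window in years of age (50-90); dosing
#'   must fall inside the window.
#' @param gamma_U2,gamma_D dose densities, g/cm^3/d. Defaults are the
#'   standard 40 mg/day UC-II and 100 mg/day fisetin doses divided by body
#'   volume (see [dose_density()]).
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(drug = c("U2", "D", "both"),
                          u2_intervals = NULL, d_dose_days = NULL,
                          start_age = 50, end_age = 90,
                          gamma_U2 = .oa_param_defaults$gamma_U2,
                          gamma_D = .oa_param_defaults$gamma_D) {
  drug <- match.arg(drug)
  if (gamma_U2 < 0 || gamma_D < 0) stop("dose densities must be >= 0")
  if (start_age > end_age) stop("start_age must be <= end_age")
  dpy <- .oa_param_defaults$days_per_year
  lo <- (start_age - 50) * dpy
  hi <- (end_age - 50) * dpy
  if (!is.null(u2_intervals)) {
    u2_intervals <- matrix(as.numeric(u2_intervals), ncol = 2)
    if (any(u2_intervals[, 1] >= u2_intervals[, 2]))
      stop("u2_intervals must have start < end")
    o <- order(u2_intervals[, 1])
    u2_intervals <- u2_intervals[o, , drop = FALSE]
    if (any(u2_intervals[, 1] < lo - 1e-9) ||
        any(u2_intervals[, 2] > hi + 1e-9))
      stop("UC-II dosing outside the [start_age, end_age] window")
  }
  if (!is.null(d_dose_days)) {
    d_dose_days <- sort(unique(as.numeric(d_dose_days)))
    if (any(d_dose_days < lo - 1e-9) || any(d_dose_days > hi + 1e-9))
      stop("fisetin dosing outside the [start_age, end_age] window")
  }
  structure(list(drug = drug, u2_intervals = u2_intervals,
                 d_dose_days = d_dose_days,
                 start_age = start_age, end_age = end_age,
                 gamma_U2 = gamma_U2, gamma_D = gamma_D),
            class = "dose_schedule")
}

#' Empty (no-drug) schedule
#' @return A `dose_schedule` with no dosing.
#' @export
no_treatment <- function() {
  dose_schedule("U2", NULL, NULL, 50, 90)
}

#' @export
print.dose_schedule <- function(x, ...) {
  n_iv <- if (is.null(x$u2_intervals)) 0 else nrow(x$u2_intervals)
  n_dd <- length(x$d_dose_days)
  cat("<dose_schedule>", x$drug, "| ages", x$start_age, "-", x$end_age,
      "|", n_iv, "UC-II interval(s),", n_dd, "fisetin dose day(s)\n")
  invisible(x)
}

#' UC-II dosing indicator
#'
#' 1 on days when UC-II is administered (daily constant-rate source), 0
#' otherwise. The UC-II input into the collagen II equation is
#' `alpha_U2 * gamma_U2 * h_u2(t)`.
#'
#' @param t_days time(s) in days since age 50.
#' @param schedule a [dose_schedule()].
#' @return 0/1 vector matching `t_days`.
#' @export
h_u2 <- function(t_days, schedule) {
  iv <- schedule$u2_intervals
  if (is.null(iv) || nrow(iv) == 0L) return(rep(0, length(t_days)))
  vapply(t_days, function(t)
    as.numeric(any(t >= iv[, 1] & t < iv[, 2])), numeric(1))
}

#' Fisetin input factor
#'
#' Superposition of exponentially decaying impulses, one per administration
#' day `td <= t`: `h_d(t) = sum exp(-mu_D (t - td))`. Each dose contributes 1
#' at its administration instant and decays at the drug degradation rate;
#' with two doses at `t0 < t1` this reduces to the two-branch
#' `exp(-mu_D (t-t0)) [+ exp(-mu_D (t-t1))]` form. The fisetin source is
#' `gamma_D * h_d(t)`.
#'
#' @param t_days time(s) in days since age 50.
#' @param schedule a [dose_schedule()].
#' @param mu_D drug degradation rate, 1/d (> 0).
#' @return non-negative vector matching `t_days`.
#' @export
h_d <- function(t_days, schedule, mu_D = .oa_param_defaults$mu_D) {
  if (mu_D <= 0) stop("mu_D must be > 0")
  dd <- schedule$d_dose_days
  if (is.null(dd) || length(dd) == 0L) return(rep(0, length(t_days)))
  vapply(t_days, function(t) {
    past <- dd[dd <= t]
    if (!length(past)) 0 else sum(exp(-mu_D * (t - past)))
  }, numeric(1))
}

#' Build a named treatment schedule
#'
#' Constructs the dosing patterns used in the clinical studies and in-silico
#' trials:
#' \describe{
#'   \item{`uc2_6mo_cycle`}{UC-II daily for 6 months (182 d), 6 months off,
#'     repeated from treatment initiation.}
#'   \item{`fisetin_monthly_2d`}{fisetin on the first two days of each
#'     30-day month.}
#'   \item{`fisetin_weekly_2d`}{fisetin on the first two days of each week.}
#'   \item{`fisetin_7on7off`}{fisetin daily for 7 days, 7 days off.}
#'   \item{`fisetin_trial_2d_28d`}{two consecutive days, a 28-day break,
#'     then two more days (the phase-1 senolytic trial protocol).}
#'   \item{`t1_t4_daily_90d`}{UC-II daily for the 90 days ending at
#'     `end_age` (the protocol of clinical treatments T1-T4).}
#' }
#'
#' @param pattern_name one of the names above.
#' @param start_age,end_age treatment window, years of age.
#' @param gamma_U2,gamma_D dose densities, passed to [dose_schedule()].
#' @return A [dose_schedule()].
#' @examples
#' s <- make_schedule("fisetin_monthly_2d", 50, 51)
#' length(s$d_dose_days)
#' @export
make_schedule <- function(pattern_name, start_age, end_age,
                          gamma_U2 = .oa_param_defaults$gamma_U2,
                          gamma_D = .oa_param_defaults$gamma_D) {
  dpy <- .oa_param_defaults$days_per_year
  d0 <- (start_age - 50) * dpy
  d1 <- (end_age - 50) * dpy
  # dosing windows are half-open [start, end): a 360-day year of monthly
  # two-day blocks holds exactly 24 dose days
  two_day_blocks <- function(period) {
    starts <- seq(d0, d1, by = period)
    dd <- sort(c(starts, starts + 1))
    dd[dd < d1 - 1e-9]
  }
  switch(pattern_name,
    uc2_6mo_cycle = {
      cyc <- seq(d0, d1, by = 2 * .oa_halfyear_days)
      iv <- cbind(cyc, pmin(cyc + .oa_halfyear_days, d1))
      iv <- iv[iv[, 1] < iv[, 2], , drop = FALSE]
      dose_schedule("U2", u2_intervals = iv, start_age = start_age,
                    end_age = end_age, gamma_U2 = gamma_U2, gamma_D = gamma_D)
    },
    fisetin_monthly_2d = dose_schedule("D",
      d_dose_days = two_day_blocks(.oa_month_days), start_age = start_age,
      end_age = end_age, gamma_U2 = gamma_U2, gamma_D = gamma_D),
    fisetin_weekly_2d = dose_schedule("D",
      d_dose_days = two_day_blocks(.oa_week_days), start_age = start_age,
      end_age = end_age, gamma_U2 = gamma_U2, gamma_D = gamma_D),
    fisetin_7on7off = {
      starts <- seq(d0, d1, by = 2 * .oa_week_days)
      dd <- sort(as.vector(outer(0:6, starts, `+`)))
      dose_schedule("D", d_dose_days = dd[dd < d1 - 1e-9], start_age = start_age,
                    end_age = end_age, gamma_U2 = gamma_U2, gamma_D = gamma_D)
    },
    fisetin_trial_2d_28d = {
      dd <- d0 + c(0, 1, 30, 31)
      dose_schedule("D", d_dose_days = dd[dd <= d1], start_age = start_age,
                    end_age = end_age, gamma_U2 = gamma_U2, gamma_D = gamma_D)
    },
    t1_t4_daily_90d = dose_schedule("U2",
      u2_intervals = matrix(c(d1 - 90, d1), ncol = 2),
      start_age = max(start_age, 50), end_age = end_age,
      gamma_U2 = gamma_U2, gamma_D = gamma_D),
    stop("unknown pattern: ", pattern_name)
  )
}

#' Combine a UC-II and a fisetin schedule into a combination arm
#'
#' @param u2_schedule,d_schedule schedules produced by [make_schedule()] (or
#'   `NULL` for a missing component).
#' @return A `dose_schedule` with `drug = "both"` (or the single drug).
#' @export
combine_schedules <- function(u2_schedule = NULL, d_schedule = NULL) {
  if (is.null(u2_schedule) && is.null(d_schedule)) return(no_treatment())
  if (is.null(d_schedule)) return(u2_schedule)
  if (is.null(u2_schedule)) return(d_schedule)
  dose_schedule("both",
    u2_intervals = u2_schedule$u2_intervals,
    d_dose_days = d_schedule$d_dose_days,
    start_age = min(u2_schedule$start_age, d_schedule$start_age),
    end_age = max(u2_schedule$end_age, d_schedule$end_age),
    gamma_U2 = u2_schedule$gamma_U2, gamma_D = d_schedule$gamma_D)
}
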