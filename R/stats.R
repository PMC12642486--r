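# Organismal-assay statistics: negative-geotaxis climbing index, Welch
# two-sample tests, Kaplan-Meier survival, log-rank comparisons, group
# summary tables, and a seeded cohort simulator so every statistic can be
# exercised without real assay data.

#' Climbing index (negative geotaxis)
#'
#' Per-vial percentage of flies that crossed the 2.5 cm line within 10 s of
#' being tapped down, summarized per group (mean, SD, SEM over vials).
#'
#' @param trials data.frame with columns `n_flies` (> 0) and `n_crossed`
#'   (`0 <= n_crossed <= n_flies`); an optional `group` column splits the
#'   summary, otherwise all vials form one group.
#' @return A list: `per_vial` (the input with a `pct` column) and `summary`
#'   (data.frame `group`, `n_vials`, `mean_pct`, `sd_pct`, `sem_pct`).
#' @export
#' @examples
#' climbing_index(data.frame(n_flies = 20, n_crossed = 15))$summary
climbing_index <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) stopf("empty trial set")
  need <- c("n_flies", "n_crossed")
  if (!all(need %in% names(trials)))
    stopf("trials need columns %s", paste(need, collapse = ", "))
  if (any(trials$n_flies <= 0) ||
      any(trials$n_crossed < 0 | trials$n_crossed > trials$n_flies))
    stopf("need 0 <= n_crossed <= n_flies and n_flies > 0")
  trials$pct <- 100 * trials$n_crossed / trials$n_flies
  grp <- if ("group" %in% names(trials)) trials$group else rep("all", nrow(trials))
  agg <- lapply(split(trials$pct, grp), function(p)
    data.frame(n_vials = length(p), mean_pct = mean(p),
               sd_pct = if (length(p) > 1L) sd(p) else 0,
               sem_pct = if (length(p) > 1L) sd(p) / sqrt(length(p)) else 0))
  summary <- cbind(data.frame(group = names(agg)),
                   do.call(rbind, unname(agg)))
  list(per_vial = trials, summary = summary)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite degrees of
#' freedom), two-sided, with a 95% confidence interval on the mean
#' difference. Computed by [stats::t.test()]; this wrapper adds the input
#' validation and the uniform result container used across the package.
#'
#' @param a,b numeric samples, each with n >= 2 and nonzero variance.
#' @param conf_level confidence level for the interval.
#' @return An object of class `stat_result`: `statistic`, `df`, `p_value`,
#'   `estimate` (mean difference a - b), `conf_int`, `method`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
welch_t_test <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each sample needs n >= 2")
  if (var(a) == 0 && var(b) == 0 && mean(a) != mean(b))
    stopf("degenerate samples: both variances zero")
  tt <- t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  stat_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value,
              estimate = unname(diff(rev(tt$estimate))),
              conf_int = as.numeric(tt$conf.int),
              method = "Welch two-sample t-test")
}

#' Uniform statistical-result container
#'
#' @param statistic test statistic value.
#' @param df degrees of freedom (or `NULL`).
#' @param p_value p-value in `[0, 1]`.
#' @param estimate,conf_int optional effect estimate and its confidence
#'   interval.
#' @param method label.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic, df = NULL, p_value, estimate = NULL,
                        conf_int = NULL, method = "") {
  if (!is_num1(p_value) || p_value < 0 || p_value > 1)
    stopf("p_value must lie in [0, 1]")
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 estimate = estimate, conf_int = conf_int, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n  statistic %.4g", x$method, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df %.4g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$estimate))
    cat(sprintf("  estimate %.4g [%.4g, %.4g]\n", x$estimate,
                x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

# normalize survival records: accepts event as 1/0, TRUE/FALSE, or
# "died"/"censored"
as_survival <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stopf("empty survival record set")
  need <- c("time_days", "event")
  if (!all(need %in% names(records)))
    stopf("records need columns %s", paste(need, collapse = ", "))
  if (any(records$time_days <= 0)) stopf("time_days must be > 0")
  ev <- records$event
  if (is.character(ev) || is.factor(ev)) ev <- as.character(ev) == "died"
  records$event <- as.integer(as.logical(ev))
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring,
#' via [survival::survfit()]. The curve is a right-continuous step function
#' with `S(0) = 1`.
#'
#' @param records data.frame with `time_days` (> 0) and `event` (1/`TRUE`/
#'   `"died"` for deaths, 0/`FALSE`/`"censored"` for censoring).
#' @return An object of class `km_curve`: data.frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
#' @examples
#' km <- kaplan_meier(data.frame(time_days = 1:4, event = 1))
#' km_survival_at(km, 2)  # 0.5
kaplan_meier <- function(records) {
  records <- as_survival(records)
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @rdname kaplan_meier
#' @param curve a `km_curve`.
#' @param t time(s) at which to evaluate the step function.
#' @return `km_survival_at()`: the estimated survival probability S(t).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- which(curve$time <= ti)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test between two survival groups
#'
#' Standard (rho = 0) log-rank chi-square with hypergeometric variance over
#' the pooled event times, via [survival::survdiff()]; two-sided p-value
#' from the chi-square(1) reference.
#'
#' @param a,b survival record sets as in [kaplan_meier()], both non-empty
#'   with at least one event overall.
#' @return A `stat_result` with the chi-square statistic, df = 1, and
#'   p-value.
#' @export
logrank_test <- function(a, b) {
  a <- as_survival(a); b <- as_survival(b)
  if (sum(a$event) + sum(b$event) == 0L)
    stopf("no events in either group: log-rank undefined")
  df <- rbind(data.frame(time_days = a$time_days, event = a$event, g = "a"),
              data.frame(time_days = b$time_days, event = b$event, g = "b"))
  sd0 <- survival::survdiff(
    survival::Surv(time_days, event) ~ g, data = df, rho = 0)
  stat_result(statistic = sd0$chisq, df = 1,
              p_value = pchisq(sd0$chisq, 1, lower.tail = FALSE),
              method = "log-rank test")
}

#' Significance stars
#'
#' `*`, `**`, `***`, `****` for p < 0.05, 0.01, 0.001, 0.0001; `"ns"`
#' otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of star labels.
#' @export
signif_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Cohort configuration for the assay simulator
#'
#' @param groups named list; each element is a list that may override the
#'   per-group defaults: `n` (flies for survival), `lifespan_shape`,
#'   `lifespan_rate` (Gompertz per-day parameters), `lifespan_scale`
#'   (multiplier on drawn lifespans; a disease effect), `censor_prob`
#'   (accidental-loss censoring), `n_vials`, `flies_per_vial`,
#'   `climbing_p` (per-fly crossing probability), `eda_um2`, `esa_um2`,
#'   `area_cv` (between-fly CV of areas), `rate_hz`, `rate_cv`, `ai`.
#' @param seed integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups, seed = 1L) {
  defaults <- list(n = 100L, lifespan_shape = 0.1, lifespan_rate = 1.72e-4,
                   lifespan_scale = 1, censor_prob = 0,
                   n_vials = 5L, flies_per_vial = 20L, climbing_p = 0.75,
                   eda_um2 = 7.7e3, esa_um2 = 2.9e3, area_cv = 0.25,
                   rate_hz = 2, rate_cv = 0.1, ai = 0.05)
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  groups <- lapply(groups, function(g) {
    bad <- setdiff(names(g), names(defaults))
    if (length(bad)) stopf("unknown cohort parameter(s): %s",
                           paste(bad, collapse = ", "))
    utils::modifyList(defaults, g)
  })
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate an assay cohort
#'
#' Draws, per group: per-fly lifespans from a Gompertz model (the standard
#' adult-fly mortality law; [flexsurv::rgompertz()]) scaled by
#' `lifespan_scale` and rounded up to whole days, with optional uniform
#' accidental-loss censoring; per-vial climbing counts as binomial draws;
#' and per-fly cardiac parameters (EDA/ESA log-normal around the group
#' means with CV `area_cv`, rates normal, AI jittered). The same seed
#' reproduces the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @return A list of data.frames: `survival`
#'   (`fly_id,group,time_days,event`), `climbing`
#'   (`vial_id,group,n_flies,n_crossed`), `cardiac`
#'   (`fly_id,group,eda_um2,esa_um2,fs_percent,hr_hz,ai`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  surv <- list(); climb <- list(); card <- list()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    t_death <- flexsurv::rgompertz(g$n, shape = g$lifespan_shape,
                                   rate = g$lifespan_rate) * g$lifespan_scale
    t_death <- pmax(1, ceiling(t_death))
    cens <- runif(g$n) < g$censor_prob
    t_obs <- ifelse(cens, pmax(1, ceiling(t_death * runif(g$n))), t_death)
    surv[[gname]] <- data.frame(
      fly_id = paste0(gname, "_", seq_len(g$n)), group = gname,
      time_days = t_obs, event = as.integer(!cens))
    climb[[gname]] <- data.frame(
      vial_id = paste0(gname, "_v", seq_len(g$n_vials)), group = gname,
      n_flies = g$flies_per_vial,
      n_crossed = rbinom(g$n_vials, g$flies_per_vial, g$climbing_p))
    sdlog <- sqrt(log(1 + g$area_cv^2))
    eda_i <- g$eda_um2 * exp(rnorm(g$n, -sdlog^2 / 2, sdlog))
    esa_i <- pmin(g$esa_um2 * exp(rnorm(g$n, -sdlog^2 / 2, sdlog)),
                  0.95 * eda_i)
    hr_i <- pmax(0.2, rnorm(g$n, g$rate_hz, g$rate_cv * g$rate_hz))
    ai_i <- pmax(0, rnorm(g$n, g$ai, g$ai / 4))
    card[[gname]] <- data.frame(
      fly_id = paste0(gname, "_", seq_len(g$n)), group = gname,
      eda_um2 = eda_i, esa_um2 = esa_i,
      fs_percent = 100 * (eda_i - esa_i) / eda_i,
      hr_hz = hr_i, ai = ai_i)
  }
  list(survival = do.call(rbind, c(surv, make.row.names = FALSE)),
       climbing = do.call(rbind, c(climb, make.row.names = FALSE)),
       cardiac = do.call(rbind, c(card, make.row.names = FALSE)))
}

#' Group summary table with pairwise Welch tests
#'
#' Per-group n, mean, SD and SEM for each requested parameter, plus all
#' pairwise Welch comparisons with significance stars at the conventional
#' thresholds (see [signif_stars()]); no multiplicity correction is applied.
#'
#' @param reports data.frame of per-recording (or per-fly) parameters with
#'   a grouping column.
#' @param params character vector of numeric columns to summarize.
#' @param group_col name of the grouping column.
#' @return A list of data.frames: `summary` (`group`, `parameter`, `n`,
#'   `mean`, `sd`, `sem`) and `tests` (`parameter`, `group_a`, `group_b`,
#'   `t`, `df`, `p_value`, `stars`).
#' @export
group_summary <- function(reports,
                          params = intersect(c("eda_um2", "esa_um2",
                                               "fs_percent", "hr_hz", "ai"),
                                             names(reports)),
                          group_col = "group") {
  stopifnot(is.data.frame(reports), group_col %in% names(reports),
            length(params) >= 1L, all(params %in% names(reports)))
  groups <- split(reports, reports[[group_col]])
  if (any(vapply(groups, nrow, integer(1)) == 0L)) stopf("empty group")
  summ <- do.call(rbind, lapply(names(groups), function(gn) {
    do.call(rbind, lapply(params, function(p) {
      v <- groups[[gn]][[p]]; v <- v[is.finite(v)]
      data.frame(group = gn, parameter = p, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1L) sd(v) else 0,
                 sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0)
    }))
  }))
  tests <- NULL
  gn <- names(groups)
  if (length(gn) >= 2L) {
    pairs <- utils::combn(gn, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(params, function(p) {
        va <- groups[[pr[1]]][[p]]; vb <- groups[[pr[2]]][[p]]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        # groups too small or degenerate for Welch yield NA, not an error
        tt <- tryCatch(welch_t_test(va, vb), error = function(e) NULL)
        if (is.null(tt))
          return(data.frame(parameter = p, group_a = pr[1], group_b = pr[2],
                            t = NA_real_, df = NA_real_, p_value = NA_real_,
                            stars = NA_character_))
        data.frame(parameter = p, group_a = pr[1], group_b = pr[2],
                   t = tt$statistic, df = tt$df, p_value = tt$p_value,
                   stars = signif_stars(tt$p_value))
      }))
    }))
  }
  list(summary = summ, tests = tests)
}

#' Read assay CSV files
#'
#' `read_survival_csv()` expects columns `fly_id,group,time_days,event`
#' (plus optional extras such as `sex`); `read_climbing_csv()` expects
#' `vial_id,group,n_flies,n_crossed`.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_survival_csv <- function(path) {
  df <- read.csv(path)
  need <- c("fly_id", "group", "time_days", "event")
  if (!all(need %in% names(df)))
    stopf("survival CSV must have columns %s", paste(need, collapse = ","))
  as_survival(df)
}

#' @rdname read_survival_csv
#' @export
read_climbing_csv <- function(path) {
  df <- read.csv(path)
  need <- c("vial_id", "group", "n_flies", "n_crossed")
  if (!all(need %in% names(df)))
    stopf("climbing CSV must have columns %s", paste(need, collapse = ","))
  df
}
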