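## Normalise survival input: data.frame with time/event, a cohort (cases
## only), or separate vectors. Applies the follow-up horizon: subjects with
## time > horizon are administratively censored at the horizon.
survival_records <- function(x, event = NULL, horizon = NULL) {
  if (inherits(x, "cohort")) {
    df <- x$subjects
    if (!"time" %in% names(df)) stop("cohort has no survival columns")
    keep <- df$status == "case" & !is.na(df$time)
    rec <- data.frame(time = df$time[keep], event = df$event[keep])
  } else if (is.data.frame(x)) {
    rec <- data.frame(time = x$time, event = as.logical(x$event))
  } else {
    rec <- data.frame(time = as.numeric(x), event = as.logical(event))
  }
  if (!nrow(rec)) stop("no survival records")
  if (any(is.na(rec$time)) || any(is.na(rec$event)))
    stop("missing values in survival records")
  if (any(rec$time < 0)) stop("survival times must be >= 0")
  if (!is.null(horizon)) {
    stopifnot(horizon > 0)
    over <- rec$time > horizon
    rec$event[over] <- FALSE
    rec$time[over] <- horizon
  }
  rec
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survivor function with Greenwood variance.
#' An optional follow-up horizon administratively censors subjects beyond
#' it (events after the horizon do not count). At tied times, deaths are
#' processed before censorings.
#'
#' @param x survival input: a data.frame with `time` (years) and `event`
#'   (logical, `TRUE` = death from the endpoint cause), a [cohort()] object
#'   (cases with follow-up are used), or a numeric time vector.
#' @param event logical event vector when `x` is a time vector.
#' @param horizon optional follow-up horizon in years (e.g. 5 or 10).
#' @return A `km_curve` object: data.frame-backed list with one row per
#'   distinct event time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `greenwood_var`, `se`; plus `n`, `n_events`, `horizon`.
#' @export
km_estimate <- function(x, event = NULL, horizon = NULL) {
  rec <- survival_records(x, event, horizon)
  ut <- sort(unique(rec$time[rec$event]))
  n <- nrow(rec)
  surv <- 1
  cum <- 0
  rows <- vector("list", length(ut))
  for (i in seq_along(ut)) {
    t <- ut[i]
    at_risk <- sum(rec$time >= t)       # deaths precede censorings at ties
    d <- sum(rec$time == t & rec$event)
    cns <- sum(rec$time == t & !rec$event)
    surv <- surv * (1 - d / at_risk)
    cum <- cum + if (at_risk > d) d / (at_risk * (at_risk - d)) else 0
    rows[[i]] <- data.frame(time = t, n_risk = at_risk, n_event = d,
                            n_censor = cns, surv = surv,
                            greenwood_var = surv^2 * cum)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               n_censor = integer(), surv = numeric(), greenwood_var = numeric())
  tab$se <- sqrt(tab$greenwood_var)
  structure(list(table = tab, n = n, n_events = sum(rec$event),
                 horizon = horizon), class = "km_curve")
}

#' Survivor-function value at given times
#'
#' @param object a [km_estimate()] result.
#' @param times numeric times at which to evaluate the step function.
#' @param ... unused.
#' @return Numeric vector of survival probabilities.
#' @export
predict.km_curve <- function(object, times, ...) {
  tab <- object$table
  vapply(times, function(t) {
    i <- sum(tab$time <= t)
    if (i == 0) 1 else tab$surv[i]
  }, 0)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d events%s\n", x$n,
              x$n_events,
              if (!is.null(x$horizon)) paste0(", horizon ", x$horizon, " yr")
              else ""))
  if (nrow(x$table)) print(format(x$table, digits = 4), row.names = FALSE)
  else cat("  (no events: S(t) = 1 throughout)\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Years", ylab = "Survival", ylim = c(0, 1),
                          ...) {
  tab <- x$table
  t <- c(0, rep(tab$time, each = 2))
  s <- c(1, 1, rep(tab$surv, each = 2)[seq_len(max(0, 2 * nrow(tab) - 1))])
  graphics::plot(t, s, type = "l", xlab = xlab, ylab = ylab, ylim = ylim, ...)
  invisible(x)
}

logrank_stats <- function(groups, horizon = NULL) {
  k <- length(groups)
  recs <- lapply(groups, survival_records, horizon = horizon)
  g <- rep(seq_len(k), vapply(recs, nrow, 0L))
  all <- do.call(rbind, recs)
  if (sum(all$event) == 0)
    stop("no events in any group: log-rank statistic undefined")
  ut <- sort(unique(all$time[all$event]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- all$time >= t
    n_t <- sum(at_risk)
    n_jt <- vapply(seq_len(k), function(j) sum(at_risk & g == j), 0)
    d_t <- sum(all$time == t & all$event)
    d_jt <- vapply(seq_len(k), function(j)
      sum(all$time == t & all$event & g == j), 0)
    O <- O + d_jt
    E <- E + d_t * n_jt / n_t
    if (n_t > 1) {
      ## hypergeometric covariance: V_jl = c_t * (n_jt * n_t * [j==l] - n_jt * n_lt)
      c_t <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      V <- V + c_t * (diag(n_jt * n_t, nrow = k) - outer(n_jt, n_jt))
    }
  }
  list(O = O, E = E, V = V, k = k, n_events = sum(all$event))
}

#' Two-group log-rank test
#'
#' Signed log-rank statistic `z = (O_a - E_a) / sqrt(V)` with hypergeometric
#' variance summed over distinct event times; `group_a` is by convention
#' the minor-allele homozygote group, so `z < 0` means fewer deaths than
#' expected in that group. Two-sided p from the standard normal.
#'
#' @param group_a,group_b survival inputs (see [km_estimate()]); both
#'   non-empty.
#' @param horizon optional follow-up horizon in years.
#' @return A `logrank_test` object with `z`, `chi2` (`= z^2`), `df = 1`,
#'   `p_value`, `observed`, `expected`, `n_events`.
#' @export
logrank_2group <- function(group_a, group_b, horizon = NULL) {
  st <- logrank_stats(list(group_a, group_b), horizon)
  v <- st$V[1, 1]
  if (v <= 0) stop("zero log-rank variance: statistic undefined")
  z <- (st$O[1] - st$E[1]) / sqrt(v)
  structure(list(z = z, chi2 = z^2, df = 1L,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 observed = st$O, expected = st$E, n_events = st$n_events),
            class = "logrank_test")
}

#' k-sample log-rank test
#'
#' The k-sample log-rank chi-square on `k - 1` degrees of freedom, used as
#' the across-genotype (additive-model) survival comparison. At `k = 2` it
#' reduces to the squared two-group statistic.
#'
#' @param groups list of `k >= 2` survival inputs (see [km_estimate()]).
#' @param horizon optional follow-up horizon in years.
#' @return A `logrank_test` object with `chi2`, `df = k - 1`, `p_value`,
#'   `observed`, `expected`, `n_events` (`z` is `NA` for `k > 2`).
#' @export
logrank_ksample <- function(groups, horizon = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  st <- logrank_stats(groups, horizon)
  k <- st$k
  idx <- seq_len(k - 1)
  Vsub <- st$V[idx, idx, drop = FALSE]
  u <- (st$O - st$E)[idx]
  qr_v <- qr(Vsub)
  if (qr_v$rank < k - 1) {
    chi2 <- drop(t(u) %*% MASS_ginv(Vsub) %*% u)
  } else {
    chi2 <- drop(t(u) %*% solve(Vsub, u))
  }
  z <- if (k == 2) (st$O[1] - st$E[1]) / sqrt(st$V[1, 1]) else NA_real_
  structure(list(z = z, chi2 = chi2, df = k - 1L,
                 p_value = stats::pchisq(chi2, k - 1, lower.tail = FALSE),
                 observed = st$O, expected = st$E, n_events = st$n_events),
            class = "logrank_test")
}

## Moore-Penrose pseudo-inverse (degenerate variance matrices only)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  if (x$df == 1 && !is.na(x$z))
    cat(sprintf("Log-rank test: z = %.3f, chi2 = %.3f (df = 1), p = %.3g\n",
                x$z, x$chi2, x$p_value))
  else
    cat(sprintf("k-sample log-rank: chi2 = %.3f (df = %d), p = %.3g\n",
                x$chi2, x$df, x$p_value))
  m <- rbind(observed = x$observed, expected = round(x$expected, 2))
  colnames(m) <- paste0("group", seq_along(x$observed))
  print(m)
  invisible(x)
}

#' Approximate power of the two-group log-rank test
#'
#' Schoenfeld's approximation: `power = Phi(sqrt(d * p1 * p2) * |log HR| -
#' z_{alpha/2})` with `d` expected total events and allocation proportions
#' `p1`, `p2`.
#'
#' @param hr hazard ratio under the alternative.
#' @param d expected total number of events.
#' @param p1 allocation proportion of group 1 (default 0.5).
#' @param alpha two-sided level (default 0.05).
#' @return Power as a proportion in `[0, 1]`.
#' @export
logrank_power_schoenfeld <- function(hr, d, p1 = 0.5, alpha = 0.05) {
  stats::pnorm(sqrt(d * p1 * (1 - p1)) * abs(log(hr)) -
               stats::qnorm(1 - alpha / 2))
}
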