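# Product-limit survival estimation and the two-group Mantel-Haenszel
# (log-rank) test, implemented from the defining formulas. The survival
# package is used only as an independent oracle in the test suite.

check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "time", "event") %in% names(cohort)))
  if (any(cohort$time <= 0)) stop("survival times must be positive")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(cohort)
}

#' Kaplan-Meier product-limit survival curve
#'
#' Computes S(t) = prod over event times t_i <= t of (1 - d_i / n_i),
#' where d_i deaths occur among n_i at risk. Individuals censored at a
#' death time are still counted at risk at that time (deaths precede
#' censorings at ties, the standard convention). The Greenwood standard
#' error S(t) * sqrt(sum d_i / (n_i (n_i - d_i))) is attached per step.
#'
#' @param cohort `data.frame` with columns `group`, `time` (days > 0) and
#'   `event` (1 = death, 0 = right-censored).
#' @param group which group to estimate; `NULL` pools all records.
#' @return object of class `survival_curve`: `data.frame` with columns
#'   `time` (distinct death times), `n_risk`, `n_event`, `surv`, `se`.
#' @export
kaplan_meier <- function(cohort, group = NULL) {
  check_cohort(cohort)
  if (!is.null(group)) {
    cohort <- cohort[cohort$group == group, , drop = FALSE]
    if (!nrow(cohort)) stop("no records for group '", group, "'")
  }
  dt <- sort(unique(cohort$time[cohort$event == 1]))
  if (!length(dt)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0), se = numeric(0))
    class(out) <- c("survival_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(dt, function(t) sum(cohort$time >= t), integer(1))
  n_event <- vapply(dt, function(t) sum(cohort$time == t & cohort$event == 1),
                    integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), NA_real_))
  out <- data.frame(time = dt, n_risk = n_risk, n_event = n_event,
                    surv = surv, se = surv * sqrt(gw))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Two-group Mantel-Haenszel (log-rank) test
#'
#' At each distinct death time with n at risk (n1 in group 1) and d total
#' deaths, the expected group-1 deaths are d * n1 / n with hypergeometric
#' variance d (n1/n) (n2/n) (n - d) / (n - 1) (zero when n = 1). The
#' statistic is (O1 - E1)^2 / sum(V), referred to the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param cohort two-group cohort `data.frame` (`group`, `time`, `event`).
#' @return object of class `log_rank_result`: list with `chi2`, `df`, `p`,
#'   and per-group `observed` / `expected` event totals.
#' @export
log_rank_test <- function(cohort) {
  check_cohort(cohort)
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) stop("log-rank test requires exactly two groups")
  if (sum(cohort$event) < 1) stop("log-rank test requires at least one death")
  dt <- sort(unique(cohort$time[cohort$event == 1]))
  g1 <- cohort$group == groups[1]
  O1 <- 0; E1 <- 0; V <- 0; D <- 0
  for (t in dt) {
    at <- cohort$time >= t
    n <- sum(at); n1 <- sum(at & g1)
    dd <- sum(cohort$time == t & cohort$event == 1)
    d1 <- sum(cohort$time == t & cohort$event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * ((n - n1) / n) * (n - dd) / (n - 1)
    D <- D + dd
  }
  if (V <= 0) stop("degenerate data: zero log-rank variance")
  chi2 <- (O1 - E1)^2 / V
  p <- max(stats::pchisq(chi2, df = 1, lower.tail = FALSE),
           .Machine$double.xmin)
  structure(
    list(chi2 = chi2, df = 1L, p = p,
         observed = stats::setNames(c(O1, D - O1), groups),
         expected = stats::setNames(c(E1, D - E1), groups)),
    class = "log_rank_result"
  )
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel log-rank test: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  cat("  observed:", paste(sprintf("%s=%g", names(x$observed), x$observed),
                           collapse = ", "), "\n")
  cat("  expected:", paste(sprintf("%s=%.3f", names(x$expected), x$expected),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Median survival time from a product-limit curve
#'
#' @param curve a `survival_curve`.
#' @return the smallest death time at which S(t) <= 0.5, or `NA` when the
#'   curve never reaches 0.5.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  hit <- which(curve$surv <= 0.5)
  if (!length(hit)) NA_real_ else curve$time[hit[1]]
}

#' Read a survival cohort CSV (`id,group,time,event`)
#' @param path CSV file.
#' @return cohort `data.frame`.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival CSV must have header id,group,time,event")
  }
  check_cohort(df[need])
}

#' Write a survival cohort CSV
#' @param cohort cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(cohort, path) {
  utils::write.csv(cohort[c("id", "group", "time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
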