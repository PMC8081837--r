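# Synthetic two-arm survival cohorts on a field visit schedule, and
# multi-sample OTU count tables with controllable evenness per group.

#' Simulate an interval-censored two-arm survival cohort
#'
#' Each individual draws a latent death time from a constant-hazard
#' (exponential) model — or Weibull when `shape != 1` — at its group's
#' rate. Deaths are only detected at field visits: the recorded event time
#' is the first visit at or after the true death time (event = 1);
#' individuals alive at the last visit are right-censored there
#' (event = 0). The default schedule is the field survey's visit grid
#' (days 15, 30, 60, 90, 180, 342, 410, 733; the day-0 visit records no
#' events) and the default arm size is 50.
#'
#' @param hazards named numeric vector of per-day hazard rates, one per
#'   group (default two arms at rates 0.003 and 0.009 per day, a 3:1
#'   hazard ratio with the control arm reaching 50% mortality in roughly
#'   2.5 months and the treated arm in roughly 8).
#' @param n_per_group individuals per arm.
#' @param schedule strictly increasing positive visit days.
#' @param shape Weibull shape; 1 (default) is the exponential model.
#' @param seed integer seed.
#' @return `data.frame` with columns `id`, `group`, `time`, `event`.
#' @export
simulate_survival_cohort <- function(hazards = c(Eplus = 0.003, Eminus = 0.009),
                                     n_per_group = 50,
                                     schedule = c(15, 30, 60, 90, 180, 342, 410, 733),
                                     shape = 1, seed = 1) {
  stopifnot(length(hazards) >= 1, !is.null(names(hazards)), all(hazards >= 0),
            all(diff(schedule) > 0), all(schedule > 0), n_per_group >= 1,
            shape > 0)
  set.seed(seed)
  last <- schedule[length(schedule)]
  out <- lapply(names(hazards), function(g) {
    lambda <- hazards[[g]]
    death <- if (lambda == 0) {
      rep(Inf, n_per_group)
    } else if (shape == 1) {
      stats::rexp(n_per_group, rate = lambda)
    } else {
      # survival exp(-(lambda*t)^shape)
      stats::rweibull(n_per_group, shape = shape, scale = 1 / lambda)
    }
    detected <- death <= last
    time <- ifelse(detected,
                   schedule[findInterval(death, schedule, left.open = TRUE) + 1],
                   last)
    data.frame(id = paste0(g, "_", seq_len(n_per_group)), group = g,
               time = time, event = as.integer(detected),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a taxa-by-sample OTU count table
#'
#' Per group, taxon base abundances are drawn log-normal(0, sigma) and
#' normalised into a group relative-abundance profile; each sample then
#' draws `depth` reads multinomially from its group's profile. A larger
#' sigma gives a less even community (stronger dominance), so group-wise
#' evenness differences can be dialed in directly.
#'
#' @param taxa_n number of taxa (>= 2).
#' @param sigma named numeric vector: log-normal sigma of the taxon base
#'   abundances for each group (names are the group labels). The default
#'   emulates the three-condition rhizosphere design (inoculated,
#'   non-inoculated, unmanipulated control) with a slightly less even
#'   community in the non-inoculated group.
#' @param samples_per_group samples per group (default 5).
#' @param depth reads per sample (>= `taxa_n` recommended).
#' @param seed integer seed.
#' @return object of class `count_table`: list with `counts`
#'   (taxa x samples integer matrix) and `groups` (named character vector,
#'   one group label per sample).
#' @export
simulate_count_table <- function(taxa_n = 200,
                                 sigma = c(Eplus = 1, Eminus = 1.5, Control = 1),
                                 samples_per_group = 5, depth = 20000,
                                 seed = 1) {
  stopifnot(taxa_n >= 2, depth >= taxa_n, !is.null(names(sigma)),
            all(sigma >= 0), samples_per_group >= 1)
  set.seed(seed)
  taxa <- sprintf("otu%03d", seq_len(taxa_n))
  cols <- list(); grp <- character(0)
  for (g in names(sigma)) {
    base <- exp(stats::rnorm(taxa_n, 0, sigma[[g]]))
    p <- base / sum(base)
    m <- stats::rmultinom(samples_per_group, size = depth, prob = p)
    colnames(m) <- paste0(g, "_", seq_len(samples_per_group))
    cols[[g]] <- m
    grp <- c(grp, stats::setNames(rep(g, samples_per_group), colnames(m)))
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- taxa
  count_table(counts, grp)
}
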