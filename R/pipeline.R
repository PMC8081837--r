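# End-to-end orchestration: flat key-value config, per-stage seeding,
# consolidated JSON report, and a seeded fixture writer that materialises a
# complete synthetic demo dataset.

# Stage seed offsets: stages are independently re-runnable.
STAGE_OFFSET <- c(fixtures = 11L, sdm = 101L, survival = 211L, diversity = 307L)

stage_seed <- function(global_seed, stage) {
  as.integer((as.numeric(global_seed) + STAGE_OFFSET[[stage]]) %% 2147483647)
}

#' Read a flat key-value run configuration
#'
#' Plain-text lines `section.key = value` (comments with `#`). Recognised
#' sections: `paths.*` (stack_dir, points_csv, survival_csv, counts_tsv,
#' metadata_tsv, out_dir), `sdm.*` (iterations, train_fraction, threshold,
#' trees), `scenario.*` (layers as comma-separated names, fraction, mode),
#' `flags.*` (flat_area, rarefy) and a top-level `seed`.
#'
#' @param path config file.
#' @return a nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[trimws(lines) != ""])
  cfg <- list(seed = 1, paths = list(), sdm = list(), scenario = list(),
              flags = list())
  known <- c("seed", "paths.stack_dir", "paths.points_csv",
             "paths.survival_csv", "paths.counts_tsv", "paths.metadata_tsv",
             "paths.out_dir", "sdm.iterations", "sdm.train_fraction",
             "sdm.threshold", "sdm.trees", "scenario.layers",
             "scenario.fraction", "scenario.mode", "flags.flat_area",
             "flags.rarefy")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num) && key != "scenario.layers") num else val
    if (key == "seed") {
      cfg$seed <- parsed
    } else {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      cfg[[parts[1]]][[parts[2]]] <- parsed
    }
  }
  # relative paths are taken relative to the config file's directory, so a
  # fixture directory can be relocated wholesale
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p) {
    if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  })
  structure(cfg, class = "run_config")
}

null_or <- function(x, default) if (is.null(x)) default else x

#' Run every configured pipeline stage
#'
#' Stages run in order (distribution-model scenario pair, survival,
#' diversity) with per-stage seeds derived from the global seed by fixed
#' offsets. A stage whose inputs are not configured is marked `skipped`; a
#' stage that fails is marked `failed` with its error message, without
#' aborting the others. The consolidated report is returned and, when
#' `paths.out_dir` is set, written to `report.json` there.
#'
#' @param config a `run_config` (or path to one).
#' @return a list of class `run_report`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  flat_area <- null_or(config$flags$flat_area, NULL)
  report <- list(schema = "nicheshift-report/1",
                 version = as.character(utils::packageVersion("nicheshift")),
                 seed = config$seed,
                 config = unclass(config),
                 stages = list())

  run_stage <- function(name, have_inputs, fn) {
    if (!have_inputs) {
      return(list(status = "skipped",
                  reason = "inputs not configured"))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      c(list(status = "ok"), fn(stage_seed(config$seed, name))),
      error = function(e) list(status = "failed",
                               error = conditionMessage(e))
    )
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  report$stages$sdm <- run_stage(
    "sdm",
    !is.null(config$paths$stack_dir) && !is.null(config$paths$points_csv),
    function(seed) {
      stack <- read_stack(config$paths$stack_dir)
      points <- read_occurrences(config$paths$points_csv)
      sc <- scenario_spec(
        layers = strsplit(null_or(config$scenario$layers, "BIO12,BIO19"),
                          ",")[[1]],
        fraction = null_or(config$scenario$fraction, 0.147)
      )
      cfg <- sdm_config(
        n_iterations = null_or(config$sdm$iterations, 100),
        train_fraction = null_or(config$sdm$train_fraction, 0.70),
        threshold = null_or(config$sdm$threshold, 0.95),
        n_trees = null_or(config$sdm$trees, 500),
        seed = seed
      )
      pair <- run_scenario_pair(
        points, stack, sc, cfg,
        scenario_mode = null_or(config$scenario$mode, "reduced-presences"),
        flat_area = flat_area
      )
      list(
        baseline_area = unclass(pair$baseline$area)[c("mean_ha", "sd_ha",
                                                      "ensemble_map_area_ha")],
        modified_area = unclass(pair$modified$area)[c("mean_ha", "sd_ha",
                                                      "ensemble_map_area_ha")],
        expansion_ratio = pair$expansion_ratio,
        ratio_defined = pair$ratio_defined,
        mean_auc = list(
          baseline = mean(pair$baseline$ensemble$records$auc, na.rm = TRUE),
          modified = mean(pair$modified$ensemble$records$auc, na.rm = TRUE)
        )
      )
    })

  report$stages$survival <- run_stage(
    "survival", !is.null(config$paths$survival_csv),
    function(seed) {
      cohort <- read_survival_csv(config$paths$survival_csv)
      groups <- sort(unique(cohort$group))
      curves <- lapply(groups, function(g) {
        cv <- kaplan_meier(cohort, g)
        list(group = g, time = cv$time, surv = cv$surv, se = cv$se,
             median_days = median_survival(cv))
      })
      lr <- log_rank_test(cohort)
      list(curves = curves,
           log_rank = list(chi2 = lr$chi2, df = lr$df, p = lr$p,
                           observed = as.list(lr$observed),
                           expected = as.list(lr$expected)))
    })

  report$stages$diversity <- run_stage(
    "diversity",
    !is.null(config$paths$counts_tsv) && !is.null(config$paths$metadata_tsv),
    function(seed) {
      tab <- read_count_table(config$paths$counts_tsv,
                              config$paths$metadata_tsv)
      rarefy <- null_or(config$flags$rarefy, NULL)
      if (!is.null(rarefy)) tab <- rarefy_table(tab, rarefy, seed = seed)
      prof <- alpha_profile(tab)
      tests <- lapply(c(H = "H", S = "S", D = "D", E = "E",
                        chao1 = "chao1", ace = "ace"), function(ix) {
        gt <- compare_groups(prof[[ix]], prof$group, method = "kw_mwu")
        list(statistic = gt$statistic, df = gt$df, p = gt$p)
      })
      ord <- bray_curtis_pcoa(tab)
      list(profile = prof, group_tests = tests,
           pcoa = list(
             eigenvalues = ord$ordination$eigenvalues,
             proportion = ord$ordination$proportion,
             coordinates = as.data.frame(ord$ordination$coordinates)
           ))
    })

  class(report) <- "run_report"
  if (!is.null(config$paths$out_dir)) {
    dir.create(config$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(strip_timing(report),
                         file.path(config$paths$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# Timing fields vary run to run; everything else in a report is
# deterministic under a fixed seed.
strip_timing <- function(report) {
  report$stages <- lapply(report$stages, function(s) {
    s$elapsed_s <- NULL
    s
  })
  report
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement to `depth` (samples
#' already at or below `depth` are kept as is), with a stated seed.
#'
#' @param table a `count_table`.
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return the rarefied `count_table`.
#' @export
rarefy_table <- function(table, depth, seed = 1) {
  stopifnot(inherits(table, "count_table"), depth >= 1)
  set.seed(seed)
  counts <- apply(table$counts, 2, function(x) {
    N <- sum(x)
    if (N <= depth) return(x)
    picked <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picked, nbins = length(x))
  })
  rownames(counts) <- rownames(table$counts)
  keep <- colSums(counts) > 0
  count_table(counts[, keep, drop = FALSE], table$groups[keep])
}

#' Write a complete seeded synthetic demo dataset
#'
#' Materialises everything the pipeline reads: the eight-layer virtual
#' landscape as ESRI ASCII grids, a presence/background occurrence CSV for
#' the packaged wet-margin species, a two-arm survival CSV at a 3:1 hazard
#' ratio on the field visit schedule, a three-group count TSV with its
#' metadata TSV, a ready-to-run `config.txt`, and a manifest CSV with MD5
#' checksums of every written file.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; identical seeds give identical checksums.
#' @param n_rows,n_cols landscape dimensions. The default 200 x 200 grid
#'   carries 100 background points at about 0.25% of cells — the same
#'   background sparsity as 100 points on a 2-degree 30-arc-second
#'   climate grid.
#' @param presence_n presence points for the wet-margin species.
#' @param sdm_iterations ensemble iterations written into the demo config.
#' @return `data.frame` manifest (`file`, `md5`), invisibly; also written
#'   as `manifest.csv`.
#' @export
make_fixtures <- function(out_dir, seed = 1, n_rows = 200, n_cols = 200,
                          presence_n = 50, sdm_iterations = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)

  stack <- make_virtual_landscape(n_rows, n_cols,
                                  seed = stage_seed(seed, "fixtures"))
  write_stack(stack, file.path(out_dir, "stack"))
  species <- wet_margin_species(presence_n = presence_n)
  suit <- true_suitability(stack, species)
  pts <- sample_points(suit, stack, presence_n = species$presence_n,
                       background_n = 100,
                       seed = stage_seed(seed, "fixtures"),
                       mode = species$mode)
  write_occurrences(pts, file.path(out_dir, "points.csv"))
  write_raster(suit, file.path(out_dir, "true_suitability.asc"))

  cohort <- simulate_survival_cohort(hazards = c(Eplus = 0.003, Eminus = 0.009),
                                     n_per_group = 50,
                                     seed = stage_seed(seed, "survival"))
  write_survival_csv(cohort, file.path(out_dir, "survival.csv"))

  tab <- simulate_count_table(taxa_n = 200,
                              sigma = c(Eplus = 1, Eminus = 1.5, Control = 1),
                              samples_per_group = 5, depth = 20000,
                              seed = stage_seed(seed, "diversity"))
  write_count_table(tab, file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "metadata.tsv"))

  writeLines(c(
    sprintf("seed = %d", as.integer(seed)),
    "paths.stack_dir = stack",
    "paths.points_csv = points.csv",
    "paths.survival_csv = survival.csv",
    "paths.counts_tsv = counts.tsv",
    "paths.metadata_tsv = metadata.tsv",
    "paths.out_dir = out",
    sprintf("sdm.iterations = %d", as.integer(sdm_iterations)),
    "sdm.threshold = 0.95",
    "scenario.layers = BIO12,BIO19",
    "scenario.fraction = 0.147"
  ), file.path(out_dir, "config.txt"))

  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.csv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
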