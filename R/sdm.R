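# Ensemble presence/background distribution modelling and the
# physiological scenario transform. Each of B iterations re-splits the
# labeled points 70/30, fits a random forest (bagged classification trees),
# records the test AUC and the thresholded suitable area, and contributes
# its per-cell vote-fraction map to the ensemble mean.

#' Ensemble model configuration
#'
#' Defaults follow the standard protocol for a small presence/background
#' design: 100 iterations, 70/30 train/test splits, 500 trees per forest,
#' floor(sqrt(p)) candidate features per split, and an occurrence
#' probability threshold of 0.95 for calling a cell suitable.
#'
#' @param n_iterations number of ensemble iterations B.
#' @param train_fraction fraction of points used for training per iteration.
#' @param threshold vote-fraction threshold p* for the suitable-area rule
#'   (inclusive).
#' @param n_trees trees per random forest.
#' @param mtry candidate features per split; `NULL` = floor(sqrt(p)).
#' @param seed integer seed governing every split and forest.
#' @return object of class `sdm_config`.
#' @export
sdm_config <- function(n_iterations = 100, train_fraction = 0.70,
                       threshold = 0.95, n_trees = 500, mtry = NULL,
                       seed = 1) {
  stopifnot(n_iterations >= 1, train_fraction > 0, train_fraction < 1,
            threshold > 0, threshold <= 1, n_trees >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, threshold = threshold,
                 n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "sdm_config")
}

# Deterministic per-iteration seed derived from the config seed; kept
# below 2^31 - 1.
iteration_seed <- function(seed, b) {
  as.integer((as.numeric(seed) + 1664525 * as.numeric(b)) %% 2147483647)
}

#' Area under the ROC curve by the rank-sum formulation
#'
#' AUC = (sum of positive-score ranks - n1(n1+1)/2) / (n1 n0), with tied
#' scores sharing average ranks — the Mann-Whitney U statistic scaled to
#' \[0, 1\].
#'
#' @param scores numeric classifier scores.
#' @param labels logical or 0/1; `TRUE`/1 marks the positive class.
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Feature data.frame for every cell of the stack; keeps the validity mask.
stack_grid_features <- function(stack) {
  g1 <- stack$layers[[1]]
  n <- grid_nrow(g1) * grid_ncol(g1)
  m <- matrix(NA_real_, n, length(stack$layers),
              dimnames = list(NULL, names(stack$layers)))
  for (j in seq_along(stack$layers)) m[, j] <- as.vector(stack$layers[[j]]$values)
  valid <- !apply(m, 1, anyNA)
  list(features = as.data.frame(m[valid, , drop = FALSE]), valid = valid,
       dim = dim(g1$values), grid = g1)
}

#' Fit the iterated presence/background ensemble
#'
#' For each of B iterations: (1) randomly split all labeled points into
#' train/test at `train_fraction` (redrawing, with a count, if either class
#' is missing from the training split); (2) fit a random forest on the
#' training points; (3) record the test-set AUC; (4) predict the per-cell
#' presence vote fraction over the whole (projection) grid; (5) record the
#' area of cells at or above the threshold. The ensemble mean probability
#' map is the arithmetic mean of the per-iteration maps.
#'
#' @param points occurrence `data.frame` (`lon`, `lat`, `label`).
#' @param stack the `raster_stack` supplying background features and (by
#'   default) presence features and the projection grid.
#' @param config an `sdm_config`.
#' @param presence_stack optional stack from which presence feature vectors
#'   are extracted instead (the physiological-scenario mechanism); geometry
#'   must match `stack`.
#' @param project_stack optional stack to project onto (defaults to
#'   `stack`).
#' @param flat_area optional constant per-cell area (ha) instead of
#'   geodesic areas.
#' @param keep_maps keep every iteration's probability map (memory-hungry;
#'   off by default).
#' @return object of class `sdm_ensemble`: list with `records` (iteration,
#'   seed, auc, area_ha, redraws), `mean_prob` (a `raster_grid`), `config`,
#'   counts of points used, and optionally `maps`.
#' @export
fit_ensemble <- function(points, stack, config = sdm_config(),
                         presence_stack = NULL, project_stack = NULL,
                         flat_area = NULL, keep_maps = FALSE) {
  stopifnot(inherits(config, "sdm_config"))
  if (is.null(presence_stack)) presence_stack <- stack
  if (is.null(project_stack)) project_stack <- stack
  pres_pts <- points[points$label == "presence", , drop = FALSE]
  bg_pts <- points[points$label == "background", , drop = FALSE]
  if (nrow(pres_pts) < 2 || nrow(bg_pts) < 2) {
    stop("need at least 2 presence and 2 background points")
  }
  cm_p <- extract_values(presence_stack, pres_pts)
  cm_b <- extract_values(stack, bg_pts)
  if (nrow(cm_p$values) < 2 || nrow(cm_b$values) < 2) {
    stop("fewer than 2 points per class survived extraction")
  }
  x <- rbind(cm_p$values, cm_b$values)
  if (any(!is.finite(x))) stop("non-finite feature values after extraction")
  y <- factor(c(rep("presence", nrow(cm_p$values)),
                rep("background", nrow(cm_b$values))),
              levels = c("background", "presence"))
  if (nrow(cm_p$values) / nrow(cm_b$values) < 0.2) {
    message("presence:background ratio below 1:5; vote fractions rarely ",
            "reach high thresholds unless classes separate strongly")
  }
  gf <- stack_grid_features(project_stack)
  areas <- cell_area_matrix(gf$grid, flat_area = flat_area)
  x_df <- as.data.frame(x)
  n <- nrow(x_df)
  n_train <- max(2, round(config$train_fraction * n))
  if (n_train >= n) n_train <- n - 1
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else config$mtry
  B <- config$n_iterations
  prob_sum <- rep(0, sum(gf$valid))
  rec <- data.frame(iteration = seq_len(B), seed = NA_integer_,
                    auc = NA_real_, area_ha = NA_real_, redraws = 0L)
  maps <- if (keep_maps) vector("list", B) else NULL
  for (b in seq_len(B)) {
    it_seed <- iteration_seed(config$seed, b)
    set.seed(it_seed)
    redraws <- 0L
    repeat {
      tr <- sample.int(n, n_train)
      if (length(unique(y[tr])) == 2) break
      redraws <- redraws + 1L
      if (redraws > 1000L) stop("could not draw a two-class training split")
    }
    rf <- randomForest::randomForest(x = x_df[tr, , drop = FALSE], y = y[tr],
                                     ntree = config$n_trees, mtry = mtry)
    te <- setdiff(seq_len(n), tr)
    auc <- if (length(unique(y[te])) == 2) {
      sc <- predict(rf, x_df[te, , drop = FALSE], type = "prob")[, "presence"]
      auc_rank(sc, y[te] == "presence")
    } else NA_real_
    pv <- predict(rf, gf$features, type = "prob")[, "presence"]
    pm <- rep(NA_real_, length(gf$valid))
    pm[gf$valid] <- pv
    pm <- matrix(pm, gf$dim[1], gf$dim[2])
    rec$seed[b] <- it_seed
    rec$auc[b] <- auc
    rec$area_ha[b] <- sum(areas[!is.na(pm) & pm >= config$threshold])
    rec$redraws[b] <- redraws
    prob_sum <- prob_sum + pv
    if (keep_maps) maps[[b]] <- pm
  }
  mean_map <- rep(NA_real_, length(gf$valid))
  mean_map[gf$valid] <- prob_sum / B
  g <- gf$grid
  structure(
    list(records = rec,
         mean_prob = raster_grid(matrix(mean_map, gf$dim[1], gf$dim[2]),
                                 west = g$west, north = g$north,
                                 cell_size = g$cell_size, nodata = g$nodata),
         config = config, flat_area = flat_area,
         n_presence = nrow(cm_p$values), n_background = nrow(cm_b$values),
         dropped = cm_p$dropped_count + cm_b$dropped_count,
         maps = maps),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: B = %d iterations, %d presence / %d background\n",
              nrow(x$records), x$n_presence, x$n_background))
  cat(sprintf("  mean test AUC %.3f; mean thresholded area %.1f ha (p* = %.2f)\n",
              mean(x$records$auc, na.rm = TRUE), mean(x$records$area_ha),
              x$config$threshold))
  invisible(x)
}

#' Suitable-area estimate from a fitted ensemble
#'
#' The per-iteration thresholded areas give the mean and sample SD
#' (denominator B - 1; SD reported as `NA` when B = 1); the thresholded
#' ensemble-mean map gives a single map-level area computed by the same
#' inclusive >= rule.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param threshold threshold for the ensemble-map area (defaults to the
#'   config threshold; per-iteration areas always use the config
#'   threshold they were fitted with).
#' @return object of class `area_estimate`: list with `mean_ha`, `sd_ha`,
#'   `ensemble_map_area_ha`, `per_iteration_ha`, `threshold`.
#' @export
projected_area <- function(ensemble, threshold = NULL) {
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  if (is.null(threshold)) threshold <- ensemble$config$threshold
  per <- ensemble$records$area_ha
  structure(
    list(mean_ha = mean(per),
         sd_ha = if (length(per) > 1) stats::sd(per) else NA_real_,
         ensemble_map_area_ha = true_area_ha(ensemble$mean_prob, threshold,
                                             flat_area = ensemble$flat_area),
         per_iteration_ha = per, threshold = threshold),
    class = "area_estimate"
  )
}

#' Define a physiological scenario
#'
#' Translates a measured relative water-use-efficiency gain into the
#' climate space: the named precipitation layers are reduced by the
#' fraction `f`, mimicking a proportionally lower water requirement.
#'
#' @param layers layer names to rescale (default BIO12 and BIO19, annual
#'   and coldest-quarter precipitation).
#' @param fraction reduction fraction f in \[0, 1); the default 0.147 is
#'   the measured 14.7% WUE gain of endophyte-inoculated seedlings.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(layers = c("BIO12", "BIO19"), fraction = 0.147) {
  stopifnot(fraction >= 0, fraction < 1, length(layers) >= 1)
  structure(list(layers = layers, fraction = fraction), class = "scenario_spec")
}

#' Apply a scenario to a stack
#'
#' Multiplies every non-nodata value of each named layer by (1 - f);
#' geometry, nodata cells and all other layers are untouched.
#'
#' @param stack a `raster_stack`.
#' @param scenario a `scenario_spec`.
#' @return the rescaled `raster_stack`.
#' @export
apply_scenario <- function(stack, scenario) {
  stopifnot(inherits(stack, "raster_stack"), inherits(scenario, "scenario_spec"))
  miss <- setdiff(scenario$layers, names(stack$layers))
  if (length(miss)) stop("unknown scenario layer(s): ", paste(miss, collapse = ", "))
  out <- stack$layers
  for (nm in scenario$layers) {
    l <- out[[nm]]
    out[[nm]] <- raster_grid(l$values * (1 - scenario$fraction),
                             west = l$west, north = l$north,
                             cell_size = l$cell_size, nodata = l$nodata)
  }
  raster_stack(out)
}

#' Run the baseline / scenario ensemble pair
#'
#' Baseline: presences and background extracted from, and projected onto,
#' the original stack. Scenario run (default mode `"reduced-presences"`):
#' presence feature vectors come from the scenario-rescaled stack while
#' background vectors and the projection grid stay original — the model
#' learns a climate envelope shifted toward drier values and is then asked
#' where on the real landscape that envelope holds. The alternative mode
#' `"project-on-reduced"` projects the shifted model onto the rescaled
#' stack instead, for sensitivity analysis. Both ensembles share the same
#' seed, so a zero-fraction scenario reproduces the baseline exactly.
#'
#' @param points occurrence `data.frame`.
#' @param stack original `raster_stack`.
#' @param scenario a `scenario_spec`.
#' @param config an `sdm_config`.
#' @param scenario_mode `"reduced-presences"` or `"project-on-reduced"`.
#' @param flat_area optional constant per-cell area (ha).
#' @return list with `baseline` and `modified` (each `list(ensemble,
#'   area)`), `expansion_ratio` (modified mean area / baseline mean area;
#'   `NA` with `ratio_defined = FALSE` when the baseline area is zero) and
#'   `scenario`.
#' @export
run_scenario_pair <- function(points, stack, scenario = scenario_spec(),
                              config = sdm_config(),
                              scenario_mode = c("reduced-presences",
                                                "project-on-reduced"),
                              flat_area = NULL) {
  scenario_mode <- match.arg(scenario_mode)
  base_ens <- fit_ensemble(points, stack, config, flat_area = flat_area)
  reduced <- apply_scenario(stack, scenario)
  mod_ens <- if (scenario_mode == "reduced-presences") {
    fit_ensemble(points, stack, config, presence_stack = reduced,
                 flat_area = flat_area)
  } else {
    fit_ensemble(points, stack, config, presence_stack = reduced,
                 project_stack = reduced, flat_area = flat_area)
  }
  base_area <- projected_area(base_ens)
  mod_area <- projected_area(mod_ens)
  defined <- base_area$mean_ha > 0
  list(baseline = list(ensemble = base_ens, area = base_area),
       modified = list(ensemble = mod_ens, area = mod_area),
       expansion_ratio = if (defined) mod_area$mean_ha / base_area$mean_ha
                         else NA_real_,
       ratio_defined = defined,
       scenario = scenario, scenario_mode = scenario_mode)
}
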