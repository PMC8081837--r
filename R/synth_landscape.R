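# Virtual-species landscapes: eight correlated bioclim-role layers over a
# lon/lat grid, an analytic suitability surface, and seeded point sampling.
# These supply the ground truth against which the distribution-model stage
# is validated.

# Smoothed standard-normal random field: white noise passed twice through a
# separable moving-average kernel (reflected edges), then re-standardised.
# Dependency-free and gives adequate spatial autocorrelation.
smooth_field <- function(n_rows, n_cols, kernel_width = 7) {
  stopifnot(kernel_width >= 1)
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (kernel_width > 1) {
    k <- rep(1 / kernel_width, kernel_width)
    pad <- kernel_width %/% 2
    smooth_vec <- function(v) {
      vp <- c(rev(v[seq_len(pad)]), v, rev(v[seq(length(v) - pad + 1, length(v))]))
      out <- stats::filter(vp, k, sides = 2)
      as.numeric(out[seq(pad + 1, pad + length(v))])
    }
    z <- apply(z, 2, smooth_vec)
    z <- t(apply(z, 1, smooth_vec))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate a virtual eight-layer bioclim landscape
#'
#' Builds a seeded `raster_stack` with the canonical bioclim role names
#' (BIO2, BIO4, BIO5, BIO6, BIO12, BIO15, BIO18, BIO19). Every layer is a
#' deterministic latitudinal gradient plus a smoothed random field:
#' temperature roles increase northward and precipitation roles increase
#' southward, mimicking a central-Chile coastal gradient. The annual
#' precipitation profile (BIO12) follows a power-law curve in latitude so
#' that dry cells greatly outnumber wet ones — the right-skewed
#' precipitation distribution typical of a Mediterranean range edge, where
#' the wet extreme is geographically rare. BIO19 (winter precipitation)
#' tracks BIO12 tightly; BIO18 (the scarce summer precipitation) and the
#' seasonality layer BIO15 are only weakly coupled to it; and across a
#' 2-degree coastal strip the temperature layers vary little relative to
#' their local (topographic) noise, so precipitation amount is the dominant
#' climatic axis, as it is for a drought-limited Mediterranean tree.
#'
#' @param n_rows,n_cols grid dimensions (each at least 8).
#' @param bbox numeric `c(west, east, south, north)` in degrees; default
#'   covers 73-71 W, 36.5-34.5 S.
#' @param seed integer seed; identical inputs give bit-identical stacks.
#' @param kernel_width moving-average kernel width for the precipitation
#'   random fields (synoptic scale).
#' @param ancillary_kernel kernel width for the temperature/seasonality
#'   fields, which vary at finer (topographic) scales.
#' @return a `raster_stack` of eight layers.
#' @export
make_virtual_landscape <- function(n_rows = 100, n_cols = 100,
                                   bbox = c(-73, -71, -36.5, -34.5),
                                   seed = 1, kernel_width = 7,
                                   ancillary_kernel = 3) {
  stopifnot(n_rows >= 8, n_cols >= 8)
  set.seed(seed)
  west <- bbox[1]; east <- bbox[2]; south <- bbox[3]; north <- bbox[4]
  cs <- (north - south) / n_rows
  if (abs((east - west) / n_cols - cs) > 1e-9) {
    # keep cells square: derive n_cols span from cell size
    east <- west + n_cols * cs
  }
  lat_c <- north - (seq_len(n_rows) - 0.5) * cs
  # southness in (0, 1): 0 at the northern edge, 1 at the southern edge
  s <- (north - lat_c) / (north - south)
  smat <- matrix(s, n_rows, n_cols)

  # annual precipitation: power-law profile, 300 mm (north) to 1100 mm
  # (south); P(BIO12 >= x) ~ x^-4, so wet cells are geographically rare
  lo <- 300; hi <- 1100; gam <- 4
  bio12_det <- (lo^-gam - smat * (lo^-gam - hi^-gam))^(-1 / gam)
  f1 <- smooth_field(n_rows, n_cols, kernel_width)
  f2 <- smooth_field(n_rows, n_cols, kernel_width)
  r <- replicate(6, smooth_field(n_rows, n_cols, ancillary_kernel),
                 simplify = FALSE)
  bio12 <- bio12_det + 25 * f1
  bio19 <- 0.45 * bio12 + 20 * f2            # winter precipitation, tracks BIO12
  bio18 <- 15 + 0.02 * bio12 + 4 * r[[1]]    # summer precipitation: scarce,
                                             # weakly coupled to annual totals
  bio15 <- 70 + 6 * smat + 5 * r[[2]]        # precipitation seasonality (CV)
  t <- 1 - smat                              # northness
  bio5 <- 26 + 1.2 * t + 1.2 * r[[3]]        # max temperature of warmest month
  bio6 <- 4 + 1.0 * t + 1.0 * r[[4]]         # min temperature of coldest month
  bio2 <- 11 + 0.8 * t + 0.8 * r[[5]]        # mean diurnal range
  bio4 <- 400 + 60 * t + 60 * r[[6]]         # temperature seasonality (sd*100)

  mk <- function(m) raster_grid(m, west = west, north = north, cell_size = cs)
  raster_stack(list(
    BIO2 = mk(bio2), BIO4 = mk(bio4), BIO5 = mk(bio5), BIO6 = mk(bio6),
    BIO12 = mk(pmax(bio12, 1)), BIO15 = mk(pmax(bio15, 1)),
    BIO18 = mk(pmax(bio18, 0)), BIO19 = mk(pmax(bio19, 1))
  ))
}

#' Define a virtual species
#'
#' A virtual species is a set of per-layer response functions whose product
#' is the true occurrence suitability. Temperature-role layers take
#' `gaussian(optimum, width)` responses (value 1 at the optimum);
#' precipitation-role layers take `logistic(midpoint, slope)` responses
#' (value 0.5 at the midpoint; a positive slope means the species needs
#' wetter cells).
#'
#' @param responses named list; each element is
#'   `list(type = "gaussian", optimum =, width =)` or
#'   `list(type = "logistic", midpoint =, slope =)`, named by layer.
#' @param presence_n number of presence points to sample (>= 2).
#' @param mode presence sampling mode: `"weighted"` draws cells without
#'   replacement with probability proportional to suitability;
#'   `"bernoulli"` draws cells independently (with replacement) in
#'   proportion to suitability, so repeat presences at one cell can occur.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(responses, presence_n = 15,
                            mode = c("weighted", "bernoulli")) {
  mode <- match.arg(mode)
  stopifnot(is.list(responses), length(responses) >= 1, presence_n >= 2)
  for (r in responses) {
    if (identical(r$type, "gaussian")) {
      if (!(r$width > 0)) stop("gaussian response width must be > 0")
    } else if (identical(r$type, "logistic")) {
      if (r$slope == 0) stop("logistic response slope must be nonzero")
    } else stop("response type must be 'gaussian' or 'logistic'")
  }
  structure(list(responses = responses, presence_n = presence_n, mode = mode),
            class = "virtual_species")
}

# The packaged wet-margin demo species: precipitation-limited at the dry
# edge (needs BIO12 above ~800 mm) with a broad thermal optimum.
#' Packaged wet-margin demo species
#'
#' The default virtual species used by the fixtures and the validation
#' studies: a steep logistic precipitation requirement on BIO12 (midpoint
#' 950 mm, so only the wet southern fraction of a percent of the default
#' landscape is suitable — a range-restricted wet-margin endemic clinging
#' to the regional precipitation maximum) and a broad Gaussian thermal
#' response on BIO5 that barely constrains it.
#'
#' @param presence_n presences to sample.
#' @return a `virtual_species`.
#' @export
wet_margin_species <- function(presence_n = 15) {
  virtual_species(
    responses = list(
      BIO12 = list(type = "logistic", midpoint = 950, slope = 0.08),
      BIO5 = list(type = "gaussian", optimum = 26.5, width = 5)
    ),
    presence_n = presence_n, mode = "weighted"
  )
}

#' Packaged broad-niche species for recovery studies
#'
#' A virtual species whose suitability varies over a substantial share of
#' the default landscape (logistic precipitation response with midpoint
#' 550 mm, moderate slope, broad thermal response). Used to validate that
#' the ensemble recovers the generating suitability surface; the
#' range-restricted [wet_margin_species()] is the harder scenario-study
#' fixture.
#'
#' @param presence_n presences to sample.
#' @return a `virtual_species`.
#' @export
broad_niche_species <- function(presence_n = 50) {
  virtual_species(
    responses = list(
      BIO12 = list(type = "logistic", midpoint = 550, slope = 0.02),
      BIO5 = list(type = "gaussian", optimum = 26.5, width = 4)
    ),
    presence_n = presence_n, mode = "weighted"
  )
}

#' Analytic true suitability of a virtual species
#'
#' Evaluates the product of the species' per-layer response functions on
#' every cell; the result is the exact occurrence suitability in \[0, 1\]
#' that the distribution model is later asked to recover.
#'
#' @param stack a `raster_stack` containing every layer named in `species`.
#' @param species a `virtual_species`.
#' @return a `raster_grid` of suitabilities in \[0, 1\] (NA where any input
#'   layer is nodata).
#' @export
true_suitability <- function(stack, species) {
  stopifnot(inherits(stack, "raster_stack"), inherits(species, "virtual_species"))
  miss <- setdiff(names(species$responses), names(stack$layers))
  if (length(miss)) stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  g1 <- stack$layers[[1]]
  suit <- matrix(1, grid_nrow(g1), grid_ncol(g1))
  for (nm in names(species$responses)) {
    r <- species$responses[[nm]]
    x <- stack$layers[[nm]]$values
    fac <- if (r$type == "gaussian") {
      exp(-(x - r$optimum)^2 / (2 * r$width^2))
    } else {
      1 / (1 + exp(-r$slope * (x - r$midpoint)))
    }
    suit <- suit * fac
  }
  raster_grid(suit, west = g1$west, north = g1$north, cell_size = g1$cell_size,
              nodata = g1$nodata)
}

#' Sample presence and background points from a suitability surface
#'
#' Presences are drawn from cells in proportion to true suitability (per the
#' species' sampling mode) and placed at cell centers; background points are
#' drawn uniformly over cells that are valid (non-nodata) in every layer of
#' the stack — the same validity mask a background sampler working from the
#' raster layers would see.
#'
#' @param suitability a `raster_grid` of true suitabilities.
#' @param stack the `raster_stack` providing the validity mask.
#' @param presence_n presence points to draw.
#' @param background_n background points to draw.
#' @param seed integer seed.
#' @param mode `"weighted"` (without replacement) or `"bernoulli"`
#'   (independent, with replacement).
#' @return occurrence `data.frame` (`lon`, `lat`, `label`).
#' @export
sample_points <- function(suitability, stack, presence_n, background_n,
                          seed = 1, mode = c("weighted", "bernoulli")) {
  mode <- match.arg(mode)
  set.seed(seed)
  valid <- !is.na(suitability$values)
  for (l in stack$layers) valid <- valid & !is.na(l$values)
  s <- suitability$values
  s[!valid] <- 0
  pos <- which(s > 0)
  if (length(pos) < 1 || (mode == "weighted" && length(pos) < presence_n)) {
    stop("not enough cells with positive suitability for presence_n = ",
         presence_n)
  }
  pres_idx <- pos[sample.int(length(pos), presence_n,
                             replace = mode == "bernoulli", prob = s[pos])]
  vidx <- which(valid)
  bg_idx <- vidx[sample.int(length(vidx), background_n,
                            replace = background_n > length(vidx))]
  ctr <- cell_centers(suitability)
  idx2pt <- function(idx, label) {
    rc <- arrayInd(idx, dim(s))
    data.frame(lon = ctr$lon[rc[, 2]], lat = ctr$lat[rc[, 1]],
               label = rep(label, nrow(rc)), stringsAsFactors = FALSE)
  }
  rbind(idx2pt(pres_idx, "presence"), idx2pt(bg_idx, "background"))
}

#' Ground-truth suitable area above a threshold
#'
#' Brute-force oracle: sums the geodesic cell area over every cell whose
#' suitability (or predicted probability) is at or above the threshold.
#'
#' @param suitability a `raster_grid`.
#' @param threshold inclusion threshold in (0, 1].
#' @param flat_area optional constant per-cell area in hectares.
#' @return area in hectares.
#' @export
true_area_ha <- function(suitability, threshold, flat_area = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  areas <- cell_area_matrix(suitability, flat_area = flat_area)
  sel <- !is.na(suitability$values) & suitability$values >= threshold
  sum(areas[sel])
}
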