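# Synthetic generators: landscapes, suitability, point sampling, survival
# cohorts, count tables.

test_that("virtual landscapes are seeded, correlated and gradiented", {
  a <- make_virtual_landscape(30, 30, seed = 5)
  b <- make_virtual_landscape(30, 30, seed = 5)
  expect_identical(a, b)
  c <- make_virtual_landscape(30, 30, seed = 6)
  expect_false(identical(a$layers$BIO12$values, c$layers$BIO12$values))
  expect_setequal(names(a), c("BIO2", "BIO4", "BIO5", "BIO6",
                              "BIO12", "BIO15", "BIO18", "BIO19"))
  st <- make_virtual_landscape(60, 60, seed = 9)
  expect_gt(cor(as.vector(st$layers$BIO12$values),
                as.vector(st$layers$BIO19$values)), 0.5)
  expect_gt(cor(as.vector(st$layers$BIO12$values),
                as.vector(st$layers$BIO18$values)), 0)
  b12 <- st$layers$BIO12$values
  expect_gt(mean(b12[nrow(b12), ]), mean(b12[1, ]))     # wetter southward
  b5 <- st$layers$BIO5$values
  expect_gt(mean(b5[1, ]), mean(b5[nrow(b5), ]))        # warmer northward
})

test_that("true suitability is the product of the response functions", {
  g <- function(v) raster_grid(matrix(v, 1, 1), 0, 1, 1)
  st <- raster_stack(list(BIO12 = g(600), BIO5 = g(25)))
  # gaussian at its optimum contributes a factor of exactly 1
  sp <- virtual_species(list(BIO5 = list(type = "gaussian", optimum = 25,
                                         width = 3)), presence_n = 2)
  expect_equal(true_suitability(st, sp)$values[1, 1], 1)
  # logistic at its midpoint contributes exactly 0.5
  sp2 <- virtual_species(list(BIO12 = list(type = "logistic", midpoint = 600,
                                           slope = 0.05)), presence_n = 2)
  expect_equal(true_suitability(st, sp2)$values[1, 1], 0.5)
  # product rule: 0.5 * 1 at these values, and 0.4 for factors 0.8 x 0.5
  sp3 <- virtual_species(list(
    BIO12 = list(type = "logistic", midpoint = 600, slope = 0.05),
    BIO5 = list(type = "gaussian", optimum = 25, width = 3)
  ), presence_n = 2)
  expect_equal(true_suitability(st, sp3)$values[1, 1], 0.5)
  st2 <- raster_stack(list(BIO12 = g(600),
                           BIO5 = g(25 + 3 * sqrt(2 * log(1 / 0.8)))))
  expect_equal(true_suitability(st2, sp3)$values[1, 1], 0.4, tolerance = 1e-12)
  expect_error(true_suitability(raster_stack(list(BIO12 = g(1))), sp3),
               "missing layer")
  # suitability lives in [0, 1] on a full landscape
  stl <- make_virtual_landscape(20, 20, seed = 2)
  su <- true_suitability(stl, wet_margin_species())
  expect_true(all(su$values >= 0 & su$values <= 1))
})

test_that("sample_points honors counts, labels and degenerate support", {
  st <- make_virtual_landscape(20, 20, seed = 3)
  su <- true_suitability(st, broad_niche_species())
  pts <- sample_points(su, st, presence_n = 12, background_n = 100, seed = 1)
  expect_equal(sum(pts$label == "presence"), 12)
  expect_equal(sum(pts$label == "background"), 100)
  expect_identical(pts, sample_points(su, st, 12, 100, seed = 1))
  # degenerate support: single positive cell under bernoulli sampling
  m <- matrix(0, 20, 20); m[4, 7] <- 1
  su1 <- raster_grid(m, st$layers$BIO12$west, st$layers$BIO12$north,
                     st$layers$BIO12$cell_size)
  p3 <- sample_points(su1, st, 3, 5, seed = 2, mode = "bernoulli")
  pres <- p3[p3$label == "presence", ]
  ctr <- cell_centers(su1)
  expect_true(all(pres$lon == ctr$lon[7] & pres$lat == ctr$lat[4]))
  expect_error(sample_points(su1, st, 3, 5, seed = 2, mode = "weighted"),
               "not enough cells")
})

test_that("presence frequency tracks suitability across seeded draws", {
  st <- make_virtual_landscape(12, 12, seed = 8)
  su <- true_suitability(st, broad_niche_species())
  counts <- numeric(length(su$values))
  for (s in 1:1000) {
    pts <- sample_points(su, st, presence_n = 8, background_n = 0, seed = s,
                         mode = "bernoulli")
    rc <- nicheshift:::point_cell(su, pts$lon, pts$lat)
    idx <- (rc$col - 1) * nrow(su$values) + rc$row
    for (i in idx) counts[i] <- counts[i] + 1
  }
  expect_gt(cor(counts, as.vector(su$values), method = "spearman"), 0.9)
})

test_that("true_area_ha matches a brute-force loop and is monotone", {
  set.seed(42)
  for (rep in 1:10) {
    m <- matrix(runif(400), 20, 20)
    su <- raster_grid(m, west = -72, north = -35, cell_size = 0.02)
    thr <- runif(1, 0.2, 0.9)
    brute <- 0
    for (i in 1:20) for (j in 1:20) {
      if (m[i, j] >= thr) brute <- brute + cell_area_ha(su, i)
    }
    expect_equal(true_area_ha(su, thr), brute, tolerance = 1e-9)
    t2 <- min(thr + 0.05, 1)
    expect_lte(true_area_ha(su, t2), true_area_ha(su, thr))
  }
  m <- matrix(0.1, 5, 5); m[1, 1:3] <- 0.99
  su <- raster_grid(m, 0, 1, 0.1)
  expect_equal(true_area_ha(su, 0.95, flat_area = 100), 300)
  expect_equal(true_area_ha(raster_grid(matrix(0.2, 3, 3), 0, 1, 0.1), 0.5), 0)
})

test_that("lowering a wet-margin species' midpoint enlarges its true range", {
  st <- make_virtual_landscape(100, 100, seed = 12)
  base <- wet_margin_species()
  lower <- base
  lower$responses$BIO12$midpoint <- base$responses$BIO12$midpoint * (1 - 0.147)
  for (thr in c(0.3, 0.5, 0.8)) {
    expect_gt(true_area_ha(true_suitability(st, lower), thr),
              true_area_ha(true_suitability(st, base), thr))
  }
})

test_that("survival cohorts follow the visit-grid recording convention", {
  # zero hazard: everyone right-censored at the last visit
  c0 <- simulate_survival_cohort(hazards = c(A = 0, B = 0), n_per_group = 10,
                                 seed = 1)
  expect_true(all(c0$event == 0))
  expect_true(all(c0$time == 733))
  # enormous hazard: every death recorded at the first visit
  c1 <- simulate_survival_cohort(hazards = c(A = 10, B = 10), n_per_group = 10,
                                 seed = 1)
  expect_true(all(c1$event == 1))
  expect_true(all(c1$time == 15))
  # determinism and shape
  c2 <- simulate_survival_cohort(seed = 7)
  expect_identical(c2, simulate_survival_cohort(seed = 7))
  expect_equal(nrow(c2), 100)
  expect_equal(unname(table(c2$group)["Eplus"]), 50)
  expect_true(all(c2$time %in% c(15, 30, 60, 90, 180, 342, 410, 733)))
})

test_that("death times map to the first visit at or after the true time", {
  # a death at day 100 under the default schedule is recorded at day 180
  sched <- c(15, 30, 60, 90, 180, 342, 410, 733)
  expect_equal(sched[findInterval(100, sched, left.open = TRUE) + 1], 180)
  # verify through the generator: exponential quantiles pinned by seed
  set.seed(99)
  true_times <- rexp(1000, rate = 0.005)
  set.seed(99)
  coh <- simulate_survival_cohort(hazards = c(G = 0.005), n_per_group = 1000,
                                  seed = 99)
  # recompute the expected recording visit for each drawn death time
  expected <- ifelse(true_times <= 733,
                     sched[findInterval(true_times, sched, left.open = TRUE) + 1],
                     733)
  expect_equal(coh$time, expected)
  expect_equal(coh$event, as.integer(true_times <= 733))
})

test_that("count tables respect depth, determinism and evenness control", {
  tab <- simulate_count_table(taxa_n = 40, depth = 5000, seed = 3)
  expect_true(all(colSums(tab$counts) == 5000))
  expect_identical(tab$counts,
                   simulate_count_table(taxa_n = 40, depth = 5000, seed = 3)$counts)
  expect_equal(ncol(tab$counts), 15)
  expect_setequal(unique(unname(tab$groups)), c("Eplus", "Eminus", "Control"))
  # sigma -> 0: expected Shannon approaches ln(taxa_n)
  H <- numeric(100)
  for (s in 1:100) {
    t0 <- simulate_count_table(taxa_n = 50, sigma = c(G = 1e-8),
                               samples_per_group = 1, depth = 1e5, seed = s)
    H[s] <- alpha_profile(t0)$H
  }
  expect_lt(abs(mean(H) - log(50)) / log(50), 0.02)
})

test_that("a less even base community yields lower expected evenness", {
  e_lo <- e_hi <- numeric(100)
  for (s in 1:100) {
    t1 <- simulate_count_table(taxa_n = 60, sigma = c(G = 0.5),
                               samples_per_group = 1, depth = 2e4, seed = s)
    t2 <- simulate_count_table(taxa_n = 60, sigma = c(G = 2),
                               samples_per_group = 1, depth = 2e4, seed = s)
    e_lo[s] <- alpha_profile(t1)$E
    e_hi[s] <- alpha_profile(t2)$E
  }
  expect_gt(mean(e_lo), mean(e_hi))
})
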