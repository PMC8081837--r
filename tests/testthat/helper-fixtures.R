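# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing binary is stored.

# A tiny 2x2 grid with values 1..4 row-major from the NW corner.
tiny_grid <- function(cell_size = 0.5, west = 10, north = 20) {
  raster_grid(matrix(1:4, 2, 2, byrow = TRUE), west = west, north = north,
              cell_size = cell_size)
}

# A small stack of named constant/gradient layers sharing geometry.
small_stack <- function(n = 10, cell_size = 0.1, west = -71, north = -35) {
  vals <- matrix(seq_len(n * n), n, n, byrow = TRUE)
  raster_stack(list(
    A = raster_grid(vals, west, north, cell_size),
    B = raster_grid(vals * 2, west, north, cell_size)
  ))
}

# The worked 4-subject cohort: deaths at days 15 and 30, two censored at
# the end of follow-up.
four_subject_cohort <- function() {
  data.frame(id = paste0("s", 1:4), group = "E",
             time = c(15, 30, 733, 733), event = c(1, 1, 0, 0))
}

# Hand-built two-group cohort: group A deaths at days 1 and 2, group B
# deaths at days 3 and 4, no censoring.
ab_cohort <- function() {
  data.frame(id = paste0("s", 1:4), group = rep(c("A", "B"), each = 2),
             time = c(1, 2, 3, 4), event = 1L)
}

# Random cohort generator for oracle-comparison loops.
random_cohort <- function(n_per_group = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    id = seq_len(2 * n_per_group),
    group = rep(c("A", "B"), each = n_per_group),
    time = sample(c(15, 30, 60, 90, 180, 342, 410, 733), 2 * n_per_group,
                  replace = TRUE),
    event = rbinom(2 * n_per_group, 1, 0.7)
  )
}

# Random small count table (plain matrix with names).
random_counts <- function(taxa = 12, samples = 6, seed = 1, lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(taxa * samples, lambda), taxa, samples,
              dimnames = list(sprintf("t%02d", seq_len(taxa)),
                              sprintf("s%02d", seq_len(samples))))
  m[, colSums(m) == 0] <- 1
  m
}
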