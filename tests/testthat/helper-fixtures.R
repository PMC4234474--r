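# small fixture builders used across test files

rg <- function(m, px = 30) raster_grid(m, pixel_size_m = px)

block_mask <- function(nr, nc, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

disc_mask <- function(nr, nc, radius, center = c((nr + 1) / 2, (nc + 1) / 2)) {
  d <- sqrt(outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2,
                  "+"))
  d <= radius
}

random_mask <- function(nr, nc, density, seed) {
  set.seed(seed)
  matrix(runif(nr * nc) < density, nr, nc)
}

# tiny three-service table with planted monotone structure
toy_services <- function(n = 20, seed = 42) {
  set.seed(seed)
  base <- runif(n, 1, 30)
  data.frame(city_id = sprintf("c%02d", seq_len(n)),
             recreation_m2_per_capita = base,
             carbon_t_per_ha = base * 3 + rnorm(n, sd = 4),
             habitat_potential_pct = runif(n, 5, 95))
}
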