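## Shared in-code fixtures: small grids and template sets used across test
## files. Everything is generated at test time from fixed seeds.

tiny_grid <- function(n = 10, mm = 2) volume_grid(c(n, n, n), mm)

tiny_templates <- function(K = 2, n = 10, overlap = 0.2, seed = 11) {
  make_templates(K, tiny_grid(n), smoothness_mm = 6, overlap = overlap,
                 seed = seed)
}

# A deterministic blob template (no RNG): Gaussian bump centred in the grid.
bump_template <- function(n = 10, mm = 2, name = "DAT") {
  g <- tiny_grid(n, mm)
  cx <- (n - 1) / 2
  co <- grid_voxel_coords(g)
  d <- exp(-rowSums((co - cx)^2) / (2 * (n / 4)^2))
  molecular_template(name, array(d, dim = g$shape), g)
}
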