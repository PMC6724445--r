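# independent oracle: shortest chamfer-path distances on the 8-neighbor
# pixel graph via Dijkstra (igraph), capped at d_max
dijkstra_chamfer <- function(mask, d_max) {
  nr <- nrow(mask); nc <- ncol(mask)
  id <- function(i, j) (j - 1L) * nr + i
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    if (!(dj > 0 || (dj == 0 && di > 0))) next  # each undirected edge once
    ii <- seq_len(nr); jj <- seq_len(nc)
    ok_i <- ii[ii + di >= 1 & ii + di <= nr]
    ok_j <- jj[jj + dj >= 1 & jj + dj <= nc]
    grid <- expand.grid(i = ok_i, j = ok_j)
    from <- c(from, id(grid$i, grid$j))
    to <- c(to, id(grid$i + di, grid$j + dj))
    w <- c(w, rep(if (di != 0 && dj != 0) sqrt(2) else 1, nrow(grid)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  src <- which(mask != 0)
  d <- igraph::distances(g, v = src, to = igraph::V(g))
  pmin(matrix(apply(d, 2, min), nr, nc), d_max)
}

random_centerline_mask <- function(seed, size = 32, n_chains = 2) {
  set.seed(seed)
  chains <- replicate(n_chains, cbind(runif(4, 0, size - 1),
                                      runif(4, 0, size - 1)),
                      simplify = FALSE)
  rasterize_polyline(chains, c(size, size))
}

# geometry in which camera and patient axes coincide in-plane and the
# detector-plane scale is 2 px/mm at the isocenter (sid 1000, sod 500),
# with a hand-built capped map holding known values on row y = 5
aadd_fixture <- function() {
  g <- carm_geometry(0, 0, 1000, 500, pixel_spacing = 1,
                     image_size = c(11L, 11L), principal_point = c(5, 5))
  grid <- matrix(20, 11, 11)
  grid[6, c(2, 4, 8)] <- c(2, 4, 10)   # pixels x = 1, 3, 7 at y = 5
  map <- structure(list(grid = grid, d_max = 20, unit = "px",
                        source_mask = matrix(0L, 11, 11)),
                   class = "local_distance_map")
  pts <- t(vapply(c(1, 3, 7), function(x) {
    patient_from_camera(c((x - 5) / 2, 0, 500), g)
  }, numeric(3)))
  list(geom = g, map = map, pts = pts)
}
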