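# small hand-built trees used across tests

# single straight branch along +x, given length and number of points
straight_tree <- function(length_mm = 10, n = 2, side = "RCA", label = "RCA") {
  pts <- tibble::tibble(x = seq(0, length_mm, length.out = n), y = 0, z = 0,
                        branch = label)
  br <- tibble::tibble(id = label, parent = NA_character_, attach = NA_integer_,
                       class = "main", main_label = label)
  vessel_tree(pts, br, side)
}

# main branch along +x with sub-branches attached at given point indices,
# each sub going off in +y, sub_len mm with n_sub_pts points
forked_tree <- function(main_len = 90, n_main = 10, attach_at = c(4, 7),
                        sub_len = 10, n_sub_pts = 3, side = "RCA") {
  pts <- tibble::tibble(x = seq(0, main_len, length.out = n_main), y = 0, z = 0,
                        branch = "RCA")
  br <- tibble::tibble(id = "RCA", parent = NA_character_,
                       attach = NA_integer_, class = "main",
                       main_label = "RCA")
  for (k in seq_along(attach_at)) {
    a <- attach_at[k]
    x0 <- pts$x[a]
    sub <- tibble::tibble(x = x0, y = seq(0, sub_len, length.out = n_sub_pts),
                          z = 0, branch = sprintf("S%d", k))
    pts <- dplyr::bind_rows(pts, sub)
    br <- dplyr::bind_rows(br, tibble::tibble(
      id = sprintf("S%d", k), parent = "RCA", attach = as.integer(a),
      class = "sub", main_label = NA_character_))
  }
  vessel_tree(pts, br, side)
}

# geometry with simple round numbers (PA view)
simple_geometry <- function(sid = 1000, sod = 700, spacing = 0.25,
                            image_size = c(512L, 512L),
                            principal_point = c(256, 256)) {
  carm_geometry(primary_angle = 0, secondary_angle = 0, sid = sid, sod = sod,
                pixel_spacing = spacing, image_size = image_size,
                principal_point = principal_point)
}

# patient coordinates of a desired camera-frame point for a geometry
patient_from_camera <- function(cam, geom) {
  ext <- extrinsic_from_angles(geom)
  as.numeric(t(ext$R) %*% (cam - ext$t))
}
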