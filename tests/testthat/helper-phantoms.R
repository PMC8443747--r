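# Shared phantom builders used across the suite.

# 5 coated nuclei + 8 micronuclei (4 with an envelope shell), disjoint,
# on a 14 x 100 x 150 stack at 0.4 x 0.4 x 1 um
make_disjoint_phantom <- function(noise_sigma = 0, seed = 1L) {
  sp <- c(0.4, 0.4, 1)
  nuc_y <- c(8, 8, 8, 28, 28)
  nuc_x <- c(10, 28, 46, 14, 38)
  objs <- list()
  for (i in 1:5)
    objs[[i]] <- list(center_um = c(6.5, nuc_y[i], nuc_x[i]),
                      semi_axes_um = c(5.5, 6, 6) * 0.9,
                      pattern = "cell_marker_coat")
  mn_y <- c(16, 16, 16, 16, 20, 20, 20, 20)
  mn_x <- c(6, 18, 30, 42, 52, 44, 25, 8)
  mn_r <- c(0.9, 1.2, 1.5, 1.8, 1.0, 1.3, 1.6, 1.1)
  for (j in 1:8)
    objs[[5 + j]] <- list(center_um = c(6.5, mn_y[j], mn_x[j]),
                          semi_axes_um = rep(mn_r[j], 3),
                          pattern = if (j <= 4) "chromatin+envelope"
                                    else "chromatin")
  make_phantom(phantom_spec(shape = c(14L, 100L, 150L), spacing = sp,
                            objects = objs, noise_sigma = noise_sigma,
                            seed = seed))
}

# digitized sphere of radius r_um, centred on a voxel, as a label map with
# a single label (1)
sphere_labels <- function(r_um, spacing_um) {
  n <- as.integer(ceiling(r_um / spacing_um)) + 2L
  g <- seq(-n, n) * spacing_um
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  array(as.integer(d2 <= r_um^2), dim = rep(2L * n + 1L, 3))
}

# binary circle / ellipse rasterisers for 2D fitting tests
circle_mask <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

ellipse_mask <- function(ny, nx, cy, cx, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
  v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}
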