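# Shared fixture builders. Everything is generated in code; grids are kept
# small so the default suite stays fast.

# compact two-lumen geometry for FLEF / perturbation tests
small_geometry <- function(n_frames_grid = c(40, 32, 32)) {
  phantom_geometry(grid_shape = n_frames_grid,
                   voxel_size = c(1.5, 1.5, 2.5),
                   lumen_radius_tl = 6, lumen_radius_fl = 8,
                   septum_thickness = 3, tear_diameter = 8)
}

# steady Poiseuille tube; h_in = in-plane spacing (mm), R/L in mm
small_tube <- function(h_in = 3, hz = 5, R = 10, L = 100, flow_ml_s = 83.3,
                       odd = FALSE) {
  nz <- round(L / hz)
  nxy <- ceiling(2 * (R + 3 * h_in) / h_in)
  if (odd && nxy %% 2 == 0) nxy <- nxy + 1L
  geom <- phantom_geometry(grid_shape = c(nxy, nxy, nz),
                           voxel_size = c(h_in, h_in, hz),
                           lumen_radius_tl = R, tear_diameter = 5)
  make_poiseuille_field(geom, flow_ml_s)
}

tube_planes <- function(ph) {
  d <- dim(ph$mask$labels)
  zmax <- (d[3] - 1) * ph$mask$voxel_size[3]
  list(inlet = analysis_plane(c(0, 0, 0), c(0, 0, 1),
                              roi_radius_mm = 10, id = "inlet"),
       outlet = analysis_plane(c(0, 0, zmax), c(0, 0, 1),
                               roi_radius_mm = 10, id = "outlet"))
}

# smooth sinusoidal-systole field: v_z = V (1 + sin(2 pi t / P)) on a block
# subsection; true MSDR = 2 pi V / T_sys^2 with T_sys = P / 2
msdr_field <- function(V = 60, P = 0.94, n = 20, gs = c(12, 12, 12)) {
  dt <- P / n
  tt <- (seq_len(n) - 1) * dt
  data <- array(0, c(gs, 3, n))
  for (i in seq_len(n)) data[, , , 3, i] <- V * (1 + sin(2 * pi * tt[i] / P))
  sub <- array(FALSE, gs)
  sub[3:(gs[1] - 2), 3:(gs[2] - 2), 3:(gs[3] - 2)] <- TRUE
  list(field = velocity_field(data, c(1.5, 1.5, 2.5), dt * 1000, 200),
       sub = sub,
       phases = cardiac_phases(1:(n / 2 + 1), n),
       t_sys = P / 2, V = V, n = n)
}

# uniform-velocity field (single frame unless nt > 1)
uniform_field <- function(v = c(0, 0, 10), gs = c(24, 24, 24),
                          vox = c(1.5, 1.5, 1.5), nt = 1) {
  data <- array(0, c(gs, 3, nt))
  for (c_i in 1:3) data[, , , c_i, ] <- v[c_i]
  velocity_field(data, vox, 47, 200)
}
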