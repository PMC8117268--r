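# Virtual work-energy relative pressure (vWERP). A divergence-free,
# no-slip, unit-net-flow "virtual" field w is computed over the analyzed
# lumen by a staggered-grid (MAC) Stokes solve; dotting the Navier-Stokes
# equations with w and integrating turns the unknown pressure gradient into
# a boundary term, giving the inlet-to-outlet relative pressure
#
#   dP(t) = (1/Q_v) [ dKe/dt + A(t) + V(t) ],   dP = p_inlet - p_outlet,
#
# with Ke = rho \int v.w dV, A = rho \int (v.grad v).w dV,
# V = mu \int grad v : grad w dV. SI internally; reported in mmHg (/m).
#
# Discretization: velocities on voxel faces, pressure-like multiplier on
# voxel centers; no-slip walls via reflected ghosts; unit flow imposed as a
# Dirichlet inlet profile (the fully developed profile of the inlet
# cross-section from a 2-D Poisson solve) with natural outflow. The saddle
# problem is solved Uzawa-style: conjugate gradients on the pressure Schur
# complement, with the velocity Laplacian factored once (sparse Cholesky).

# permutation mapping the dominant normal axis to the third array axis
flow_axis_perm <- function(normal) {
  ax <- which.max(abs(normal))
  switch(ax, c(2, 3, 1), c(3, 1, 2), c(1, 2, 3))
}

#' Divergence-free unit-flow virtual field over a lumen
#'
#' Solves the Stokes problem `-mu_v lap(w) + grad(lambda) = 0`,
#' `div(w) = 0` on the lumen voxels between the inlet and outlet stations,
#' with no-slip walls, a fully developed Dirichlet inlet profile scaled to
#' unit net flow (1 m^3/s in SI scaling) and natural outflow.
#'
#' @param mask a [lumen_mask].
#' @param lumen `"TL"` or `"FL"`.
#' @param inlet_plane,outlet_plane [analysis_plane]s; their origins select
#'   the axial stations and the dominant component of the inlet normal
#'   selects the flow axis (the analyzed segment must run along a grid
#'   axis).
#' @param tolerance divergence tolerance: maximum per-cell volumetric
#'   imbalance of `w` relative to the unit through-flow (dimensionless).
#'   Default 1e-8.
#' @param mu_v virtual viscosity of the Stokes solve; `w` is invariant to
#'   this scale (only the multiplier rescales). Exposed so the invariance is
#'   testable.
#' @param max_iter CG iteration cap (a structured error reports the
#'   residual on non-convergence).
#' @return object of class `virtual_field`: cell-centered `w` (list of three
#'   arrays, m/s at unit flux), `q_v = 1`, `divergence` (normalized max
#'   per-cell imbalance), `station_flux` (flux through five cross-sections),
#'   solver diagnostics, and domain bookkeeping used by the energy
#'   quadrature.
#' @export
compute_virtual_field <- function(mask, lumen, inlet_plane, outlet_plane,
                                  tolerance = 1e-8, mu_v = 1,
                                  max_iter = 2000L) {
  lab <- if (lumen == "TL") LABEL_TL else LABEL_FL
  perm <- flow_axis_perm(inlet_plane$normal)
  if (!identical(flow_axis_perm(outlet_plane$normal), perm))
    stop("inlet and outlet normals must share the same dominant axis")
  ax <- perm[3]                        # flow axis in original order
  labels <- aperm(mask$labels, perm)
  h_mm <- mask$voxel_size[perm]
  k_in <- round(inlet_plane$origin_mm[ax] / mask$voxel_size[ax]) + 1L
  k_out <- round(outlet_plane$origin_mm[ax] / mask$voxel_size[ax]) + 1L
  d0 <- dim(labels)
  # solve in a frame where flow runs towards increasing k; flip back after
  reversed <- k_in > k_out
  if (reversed) {
    labels <- labels[, , d0[3]:1, drop = FALSE]
    k_in <- d0[3] + 1L - k_in
    k_out <- d0[3] + 1L - k_out
  }
  k1 <- k_in; k2 <- k_out
  if (k1 >= k2) stop("inlet and outlet stations coincide")
  if (k1 < 1 || k2 > d0[3]) stop("analysis stations outside the grid")
  fluid0 <- labels == lab
  if (k1 > 1) fluid0[, , 1:(k1 - 1)] <- FALSE
  if (k2 < d0[3]) fluid0[, , (k2 + 1):d0[3]] <- FALSE
  if (!any(fluid0)) stop("no ", lumen, " voxels between the stations")
  if (!is_connected6(fluid0))
    stop("lumen ", lumen, " is disconnected between inlet and outlet")
  # pad one background layer so every face of a fluid cell is on the lattice
  d <- d0 + 2L
  fluid <- array(FALSE, d)
  fluid[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)] <- fluid0
  kin <- k1 + 1L; kout <- k2 + 1L
  h <- h_mm / 1000                     # m
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  sol <- stokes_solve(fluid, h, area, kin, kout, mu_v, tolerance, max_iter)
  ks <- unique(round(seq(kin, kout - 1, length.out = 5)))
  st_flux <- vapply(ks, function(k) sum(sol$Uz[, , k]) * area[3], 0.0)
  w_pad <- face_to_center(sol, fluid)
  crop <- function(a) a[2:(d0[1] + 1), 2:(d0[2] + 1), 2:(d0[3] + 1)]
  w_perm <- lapply(w_pad, crop)
  # cells whose missing flow-axis neighbor is an open end (inlet/outlet),
  # needed for one-sided (copy) ghosts in the energy quadrature
  open_lo_p <- array(FALSE, d0); open_hi_p <- array(FALSE, d0)
  open_lo_p[, , k1] <- fluid0[, , k1]
  open_hi_p[, , k2] <- fluid0[, , k2]
  if (reversed) {
    flipz <- function(a) a[, , d0[3]:1, drop = FALSE]
    w_perm <- lapply(w_perm, flipz)
    w_perm[[3]] <- -w_perm[[3]]
    fluid0 <- flipz(fluid0)
    tmp <- flipz(open_lo_p); open_lo_p <- flipz(open_hi_p); open_hi_p <- tmp
    ks12 <- c(d0[3] + 1L - k2, d0[3] + 1L - k1)
    k1 <- ks12[1]; k2 <- ks12[2]
  }
  inv <- order(perm)
  w_cells <- lapply(1:3, function(c0) aperm(w_perm[[inv[c0]]], inv))
  fl_orig <- aperm(fluid0, inv)
  structure(list(
    w = w_cells, q_v = 1,
    fluid = fl_orig, flow_axis = ax,
    open_lo = aperm(open_lo_p, inv), open_hi = aperm(open_hi_p, inv),
    divergence = sol$div_residual,
    station_flux = st_flux,
    inlet_flux = sol$inlet_flux,
    solver = list(iterations = sol$iterations, residual = sol$residual,
                  mu_v = mu_v, converged = sol$converged),
    slabs = c(k1, k2),
    length_m = (k2 - k1 + 1) * h[3]),
    class = "virtual_field")
}

#' @export
print.virtual_field <- function(x, ...) {
  cat(sprintf(
    "<virtual_field> %d cells, div residual %.2e, CG iters %d\n  station flux: %s\n",
    sum(x$fluid), x$divergence, x$solver$iterations,
    paste(sprintf("%.4f", x$station_flux), collapse = " ")))
  invisible(x)
}

# core MAC Stokes solve on a padded logical fluid array; flow along axis 3
stokes_solve <- function(fluid, h, area, kin, kout, mu_v, tolerance,
                         max_iter) {
  d <- dim(fluid)
  ncell <- sum(fluid)
  cell_id <- array(0L, d)
  cell_id[fluid] <- seq_len(ncell)
  ex <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  # face status per axis: face index p <-> face between cells p and p + e_a
  # codes: 1 unknown; -1 inlet (Dirichlet); -2 wall (zero); 0 outside
  fstat <- vector("list", 3)
  for (a in 1:3) {
    L <- fluid
    R <- shift_logical(fluid, -ex[[a]])   # R[p] = fluid[p + e_a]
    st <- array(0L, d)
    st[L & R] <- 1L
    st[xor(L, R)] <- -2L
    fstat[[a]] <- st
  }
  Rk <- shift_logical(fluid, -ex[[3]])
  inlet <- (!fluid) & Rk
  inlet[, , setdiff(seq_len(d[3]), kin - 1L)] <- FALSE
  outlet <- fluid & !Rk
  outlet[, , setdiff(seq_len(d[3]), kout)] <- FALSE
  fstat[[3]][inlet] <- -1L
  fstat[[3]][outlet] <- 1L               # unknown: natural outflow
  fid <- vector("list", 3)
  nf <- 0L
  for (a in 1:3) {
    idx <- which(fstat[[a]] == 1L)
    ida <- array(0L, d)
    ida[idx] <- nf + seq_along(idx)
    nf <- nf + length(idx)
    fid[[a]] <- ida
  }
  # inlet Dirichlet profile scaled to unit flux
  psi <- poisson2d_profile(fluid[, , kin], h[1:2])
  uin2d <- psi / (sum(psi) * area[3])
  uin <- array(0, d)
  uin[, , kin - 1L] <- uin2d
  # ---- assembly ----
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  gi <- list(); gj <- list(); gx <- list()
  b_mom <- numeric(nf)
  for (a in 1:3) {
    fpos <- which(fid[[a]] > 0L)
    if (length(fpos) == 0L) next
    ids <- fid[[a]][fpos]
    coords <- arrayInd(fpos, d)
    diag_acc <- numeric(length(fpos))
    for (e in 1:3) {
      c_e <- mu_v / h[e]^2
      for (sgn in c(-1L, 1L)) {
        o <- ex[[e]] * sgn
        nb1 <- coords[, 1] + o[1]; nb2 <- coords[, 2] + o[2]
        nb3 <- coords[, 3] + o[3]
        okb <- nb1 >= 1L & nb1 <= d[1] & nb2 >= 1L & nb2 <= d[2] &
          nb3 >= 1L & nb3 <= d[3]
        lin <- nb1 + (nb2 - 1L) * d[1] + (nb3 - 1L) * d[1] * d[2]
        stat <- integer(length(fpos))
        stat[okb] <- fstat[[a]][lin[okb]]
        idnb <- integer(length(fpos))
        idnb[okb] <- fid[[a]][lin[okb]]
        is_unk <- idnb > 0L
        diag_acc <- diag_acc + c_e * is_unk
        if (any(is_unk)) {
          trip_i[[length(trip_i) + 1L]] <- ids[is_unk]
          trip_j[[length(trip_j) + 1L]] <- idnb[is_unk]
          trip_x[[length(trip_x) + 1L]] <- rep(-c_e, sum(is_unk))
        }
        is_in <- stat == -1L
        if (any(is_in)) {
          diag_acc <- diag_acc + c_e * is_in
          b_mom[ids[is_in]] <- b_mom[ids[is_in]] + c_e * uin[lin[is_in]]
        }
        is_wall <- stat == -2L
        diag_acc <- diag_acc + c_e * is_wall
        is_out <- stat == 0L
        if (e == a) {
          # longitudinal missing neighbor: beyond the outlet (or a solid
          # run): zero-gradient, no contribution
        } else {
          # transverse missing neighbor: reflected no-slip ghost (u -> -u)
          diag_acc <- diag_acc + 2 * c_e * is_out
        }
      }
    }
    trip_i[[length(trip_i) + 1L]] <- ids
    trip_j[[length(trip_j) + 1L]] <- ids
    trip_x[[length(trip_x) + 1L]] <- diag_acc
    # gradient rows: (G lambda)_f = (lambda_R - lambda_L) / h_a
    cl <- cell_id[fpos]
    okl <- cl > 0L
    if (any(okl)) {
      gi[[length(gi) + 1L]] <- ids[okl]
      gj[[length(gj) + 1L]] <- cl[okl]
      gx[[length(gx) + 1L]] <- rep(-1 / h[a], sum(okl))
    }
    linR <- fpos + switch(a, 1L, d[1], d[1] * d[2])
    cr <- cell_id[linR]
    okr <- cr > 0L
    if (any(okr)) {
      gi[[length(gi) + 1L]] <- ids[okr]
      gj[[length(gj) + 1L]] <- cr[okr]
      gx[[length(gx) + 1L]] <- rep(1 / h[a], sum(okr))
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(nf, nf))
  A <- Matrix::forceSymmetric(A, uplo = "U")
  G <- Matrix::sparseMatrix(i = unlist(gi), j = unlist(gj),
                            x = unlist(gx), dims = c(nf, ncell))
  b_div <- numeric(ncell)
  in_pos <- which(inlet)
  if (length(in_pos)) {
    cell_above <- in_pos + d[1] * d[2]
    b_div[cell_id[cell_above]] <- uin[in_pos] / h[3]
  }
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  solveA <- function(b) as.numeric(Matrix::solve(ch, b, system = "A"))
  u0 <- solveA(b_mom)
  rhs <- as.numeric(Matrix::crossprod(G, u0)) + b_div
  applyS <- function(lam)
    as.numeric(Matrix::crossprod(G, solveA(as.numeric(G %*% lam))))
  vol <- prod(h)
  lam <- numeric(ncell)
  r <- rhs
  p <- r
  rs <- sum(r * r)
  it <- 0L
  while (max(abs(r)) * vol > 0.01 * tolerance && it < max_iter) {
    it <- it + 1L
    Sp <- applyS(p)
    alpha <- rs / sum(p * Sp)
    lam <- lam + alpha * p
    r <- r - alpha * Sp
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  u <- solveA(b_mom - as.numeric(G %*% lam))
  div_defect <- as.numeric(Matrix::crossprod(G, u)) + b_div
  div_residual <- max(abs(div_defect)) * vol    # per-cell imbalance / Q_v
  converged <- div_residual <= tolerance
  if (!converged)
    stop(sprintf(paste0(
      "Stokes solve did not converge: divergence residual %.3e > %g ",
      "after %d CG iterations"), div_residual, tolerance, it))
  U <- lapply(1:3, function(a) {
    ua <- array(0, d)
    sel <- fid[[a]] > 0L
    ua[sel] <- u[fid[[a]][sel]]
    ua
  })
  U[[3]][inlet] <- uin[inlet]
  list(Ux = U[[1]], Uy = U[[2]], Uz = U[[3]],
       iterations = it, residual = sqrt(rs),
       div_residual = div_residual, converged = converged,
       inlet_flux = sum(uin[inlet]) * area[3])
}

# fully developed profile of a 2-D cross-section: -lap psi = 1 with
# reflected no-slip ghosts (zero at the half-voxel wall)
poisson2d_profile <- function(slab, h2) {
  d <- dim(slab)
  n <- sum(slab)
  if (n == 0L) stop("empty inlet cross-section")
  id <- array(0L, d)
  id[slab] <- seq_len(n)
  coords <- arrayInd(which(slab), d)
  ti <- list(); tj <- list(); tx <- list()
  diag_acc <- numeric(n)
  offs <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (r in 1:4) {
    o <- offs[r, ]
    e <- if (o[1] != 0L) 1L else 2L
    c_e <- 1 / h2[e]^2
    nb1 <- coords[, 1] + o[1]; nb2 <- coords[, 2] + o[2]
    okb <- nb1 >= 1L & nb1 <= d[1] & nb2 >= 1L & nb2 <= d[2]
    lin <- nb1 + (nb2 - 1L) * d[1]
    idnb <- integer(n)
    idnb[okb] <- id[lin[okb]]
    is_fluid <- idnb > 0L
    diag_acc <- diag_acc + ifelse(is_fluid, c_e, 2 * c_e)
    if (any(is_fluid)) {
      ti[[length(ti) + 1L]] <- which(is_fluid)
      tj[[length(tj) + 1L]] <- idnb[is_fluid]
      tx[[length(tx) + 1L]] <- rep(-c_e, sum(is_fluid))
    }
  }
  L <- Matrix::sparseMatrix(i = c(unlist(ti), seq_len(n)),
                            j = c(unlist(tj), seq_len(n)),
                            x = c(unlist(tx), diag_acc), dims = c(n, n))
  psi_v <- as.numeric(Matrix::solve(L, rep(1, n)))
  psi <- array(0, d)
  psi[slab] <- psi_v
  psi
}

# average staggered face velocities to cell centers (padded grid)
face_to_center <- function(sol, fluid) {
  d <- dim(fluid)
  U <- list(sol$Ux, sol$Uy, sol$Uz)
  out <- vector("list", 3)
  for (a in 1:3) {
    plus <- U[[a]]
    minus <- array(0, d)
    if (a == 1) minus[2:d[1], , ] <- plus[1:(d[1] - 1), , ]
    if (a == 2) minus[, 2:d[2], ] <- plus[, 1:(d[2] - 1), ]
    if (a == 3) minus[, , 2:d[3]] <- plus[, , 1:(d[3] - 1)]
    w <- (plus + minus) / 2
    w[!fluid] <- 0
    out[[a]] <- w
  }
  out
}

#' Mean inscribed lumen radius check (TL-narrowing exclusion rule)
#'
#' Severely narrowed lumens lose velocity data; pressure traces from lumens
#' whose mean inscribed radius along the medial axis is below 2 image
#' voxels are excluded from analysis.
#'
#' @param mask a [lumen_mask].
#' @param lumen `"TL"` or `"FL"`.
#' @return list `(pass, mean_radius_voxels)`; `pass` is `FALSE` iff the
#'   mean radius < 2 voxels.
#' @export
lumen_radius_check <- function(mask, lumen = "TL") {
  lab <- if (lumen == "TL") LABEL_TL else LABEL_FL
  sel <- mask$labels == lab
  if (!any(sel)) stop("empty lumen ", lumen)
  dt <- distance_transform(sel, mask$voxel_size / mask$voxel_size[1])
  d <- dim(sel)
  radii <- numeric(0)
  for (k in seq_len(d[3])) {
    sl <- sel[, , k]
    if (!any(sl)) next
    radii <- c(radii, max(dt[, , k][sl]) - 0.5)
  }
  mean_r <- mean(radii)
  list(pass = mean_r >= 2, mean_radius_voxels = mean_r)
}

# cell-centered gradient with reflected no-slip ghosts at walls; open ends
# along the flow axis use one-sided (copy) ghosts instead
grad_axis <- function(v, fluid, e, h_e, open_lo = NULL, open_hi = NULL,
                      flow_axis = 0L) {
  o <- c(0L, 0L, 0L); o[e] <- 1L
  vp <- shift_array_num(v, -o)
  fp <- shift_logical(fluid, -o)
  ghost_p <- -v
  if (e == flow_axis && !is.null(open_hi)) ghost_p[open_hi] <- v[open_hi]
  vp <- ifelse(fp, vp, ghost_p)
  vm <- shift_array_num(v, o)
  fm <- shift_logical(fluid, o)
  ghost_m <- -v
  if (e == flow_axis && !is.null(open_lo)) ghost_m[open_lo] <- v[open_lo]
  vm <- ifelse(fm, vm, ghost_m)
  g <- (vp - vm) / (2 * h_e)
  g[!fluid] <- 0
  g
}

shift_array_num <- function(a, o) {
  d <- dim(a)
  out <- array(0, d)
  src <- list(seq_len(d[1]) - o[1], seq_len(d[2]) - o[2],
              seq_len(d[3]) - o[3])
  ok <- lapply(1:3, function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

#' Work-energy terms of the Navier-Stokes balance
#'
#' Per-frame kinetic (`Ke = rho int v.w dV`), advective
#' (`A = rho int (v.grad v).w dV`) and viscous
#' (`V = mu int grad v : grad w dV`) terms by midpoint voxel quadrature over
#' the analyzed domain; spatial gradients by central differences with
#' reflected ghosts at walls and one-sided ghosts at the open inlet/outlet.
#'
#' @param field a [velocity_field] (cm/s; converted to SI internally).
#' @param virtual a `virtual_field` from [compute_virtual_field].
#' @param fluid a [fluid_properties].
#' @return list of class `energy_terms`: vectors `ke_j`, `adv_w`, `visc_w`
#'   (one entry per frame) plus the frame interval.
#' @export
compute_energy_terms <- function(field, virtual, fluid) {
  stopifnot(inherits(virtual, "virtual_field"),
            inherits(fluid, "fluid_properties"))
  if (!identical(dim(field$data)[1:3], dim(virtual$fluid)))
    stop("field grid does not match the virtual field domain")
  if (is.null(field$frame_interval_ms) || is.null(field$voxel_size))
    stop("field is missing unit metadata")
  fl <- virtual$fluid
  h <- field$voxel_size / 1000
  vol <- prod(h)
  w <- virtual$w
  flax <- virtual$flow_axis
  gw <- lapply(1:3, function(dc) lapply(1:3, function(e)
    grad_axis(w[[dc]], fl, e, h[e], virtual$open_lo, virtual$open_hi, flax)))
  nt <- field$n_frames
  ke <- adv <- visc <- numeric(nt)
  rho <- fluid$density_kg_m3
  mu <- fluid$viscosity_pa_s
  for (t_i in seq_len(nt)) {
    v <- lapply(1:3, function(c_i) {
      a <- field$data[, , , c_i, t_i] / 100
      a[!fl] <- 0
      a
    })
    gv <- lapply(1:3, function(dc) lapply(1:3, function(e)
      grad_axis(v[[dc]], fl, e, h[e], virtual$open_lo, virtual$open_hi,
                flax)))
    ke_t <- 0; adv_t <- 0; visc_t <- 0
    for (dc in 1:3) {
      ke_t <- ke_t + sum(v[[dc]][fl] * w[[dc]][fl])
      conv <- gv[[dc]][[1]] * v[[1]] + gv[[dc]][[2]] * v[[2]] +
        gv[[dc]][[3]] * v[[3]]
      adv_t <- adv_t + sum(conv[fl] * w[[dc]][fl])
      for (e in 1:3)
        visc_t <- visc_t + sum(gv[[dc]][[e]][fl] * gw[[dc]][[e]][fl])
    }
    ke[t_i] <- rho * ke_t * vol
    adv[t_i] <- rho * adv_t * vol
    visc[t_i] <- mu * visc_t * vol
  }
  structure(list(ke_j = ke, adv_w = adv, visc_w = visc,
                 frame_interval_ms = field$frame_interval_ms),
            class = "energy_terms")
}

#' Relative pressure trace from the work-energy balance
#'
#' `dP(t) = (1/Q_v) [dKe/dt + A(t) + V(t)]` (Pa, reported in mmHg), with
#' `dP = p_inlet - p_outlet`: positive while flow accelerates down the
#' segment. The kinetic derivative uses cyclic central differences (gated
#' periodicity); single-frame (steady) fields use `dKe/dt = 0`.
#'
#' @param terms an `energy_terms`.
#' @param virtual the `virtual_field` the terms were computed with.
#' @return a [relative_pressure_trace] in mmHg (not yet length-normalized).
#' @export
compute_relative_pressure <- function(terms, virtual) {
  if (virtual$q_v <= 1e-12) stop("degenerate virtual flow Q_v")
  nt <- length(terms$ke_j)
  dt <- terms$frame_interval_ms / 1000
  dke <- if (nt >= 3) {
    ip <- c(2:nt, 1); im <- c(nt, 1:(nt - 1))
    (terms$ke_j[ip] - terms$ke_j[im]) / (2 * dt)
  } else rep(0, nt)
  dp_pa <- (dke + terms$adv_w + terms$visc_w) / virtual$q_v
  relative_pressure_trace((seq_len(nt) - 1) * dt, dp_pa * MMHG_PER_PA)
}

#' Length-normalize a relative pressure trace and extract its extrema
#'
#' Traces are normalized by aortic (segment) length to account for
#' inter-subject anatomy; extrema are then in mmHg/m.
#'
#' @param trace a [relative_pressure_trace] (mmHg).
#' @param length_m centerline length of the analyzed segment, m (> 0).
#' @return list `(dp_max, dp_min, trace)` with extrema in mmHg/m.
#' @export
normalize_and_extract <- function(trace, length_m) {
  if (!is.finite(length_m) || length_m <= 0)
    stop("normalization length must be positive")
  dpn <- trace$dp / length_m
  out <- relative_pressure_trace(trace$time_s, dpn,
                                 lumen = attr(trace, "lumen") %||% "TL",
                                 normalized = TRUE, length_m = length_m)
  list(dp_max = max(dpn), dp_min = min(dpn), trace = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transseptal pressure trace (TL minus FL)
#'
#' The per-frame difference between TL and FL relative pressure: the load
#' exerted on the dissection flap.
#'
#' @param tl,fl [relative_pressure_trace]s on the same time base and with
#'   the same normalization state.
#' @return a [relative_pressure_trace] tagged `"transseptal"`, with
#'   attributes `dp_max`/`dp_min`.
#' @export
transseptal_pressure <- function(tl, fl) {
  if (length(tl$time_s) != length(fl$time_s) ||
      max(abs(tl$time_s - fl$time_s)) > 1e-12)
    stop("TL and FL traces have mismatched time bases")
  if (!identical(attr(tl, "normalized"), attr(fl, "normalized")))
    stop("TL and FL traces have different normalization states")
  d <- tl$dp - fl$dp
  out <- relative_pressure_trace(tl$time_s, d, lumen = "transseptal",
                                 normalized = attr(tl, "normalized"),
                                 length_m = attr(tl, "length_m"))
  attr(out, "dp_max") <- max(d)
  attr(out, "dp_min") <- min(d)
  out
}

#' One-call vWERP analysis of a lumen
#'
#' Convenience wrapper: virtual field, energy terms, relative pressure and
#' length normalization in one step.
#'
#' @param field a [velocity_field].
#' @param mask a [lumen_mask].
#' @param lumen `"TL"` or `"FL"`.
#' @param inlet_plane,outlet_plane station planes.
#' @param fluid a [fluid_properties].
#' @param length_m normalization length, m; defaults to the axial extent of
#'   the analyzed segment (exact for straight phantoms), otherwise supply a
#'   [centerline_length].
#' @param ... passed to [compute_virtual_field].
#' @return list: `dp_max`, `dp_min` (mmHg/m), `trace_mmhg`, `trace_norm`,
#'   `virtual`, `length_m`, `radius_check`.
#' @export
vwerp <- function(field, mask, lumen, inlet_plane, outlet_plane,
                  fluid = fluid_properties(), length_m = NULL, ...) {
  check_congruent(mask, field)
  vf <- compute_virtual_field(mask, lumen, inlet_plane, outlet_plane, ...)
  terms <- compute_energy_terms(field, vf, fluid)
  trace <- compute_relative_pressure(terms, vf)
  attr(trace, "lumen") <- lumen
  if (is.null(length_m)) length_m <- vf$length_m
  ext <- normalize_and_extract(trace, length_m)
  list(dp_max = ext$dp_max, dp_min = ext$dp_min,
       trace_mmhg = trace, trace_norm = ext$trace,
       virtual = vf, length_m = length_m,
       radius_check = lumen_radius_check(mask, lumen))
}
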