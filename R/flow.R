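# Geometric and temporal primitives shared by all metrics: plane flow
# quantification, cardiac-phase detection, FL subsection extraction,
# speed/acceleration traces, centerline length, noise estimation, and the
# segmentation/plane perturbations used in the reproducibility analysis.

# trilinear interpolation of a 3-D volume at continuous 0-based voxel
# coordinates (n x 3 matrix); points outside the grid return `fill`
interp_trilinear <- function(vol, idx, fill = 0) {
  d <- dim(vol)
  n <- nrow(idx)
  out <- rep(fill, n)
  inside <- idx[, 1] > -0.5 & idx[, 1] < d[1] - 0.5 &
    idx[, 2] > -0.5 & idx[, 2] < d[2] - 0.5 &
    idx[, 3] > -0.5 & idx[, 3] < d[3] - 0.5
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  p0 <- floor(p)
  fr <- p - p0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wi <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    ii <- pmin(pmax(p0[, 1] + dx, 0), d[1] - 1)
    jj <- pmin(pmax(p0[, 2] + dy, 0), d[2] - 1)
    kk <- pmin(pmax(p0[, 3] + dz, 0), d[3] - 1)
    val <- val + wi * vol[cbind(ii + 1, jj + 1, kk + 1)]
  }
  out[inside] <- val
  out
}

# any unit vector orthogonal to n, plus its companion (right-handed basis)
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Flow-rate trace through an analysis plane
#'
#' Integrates `v . n` over the circular region of interest by trilinear
#' sampling of the velocity volume on an in-plane lattice with spacing half
#' the smallest voxel edge. Positive values follow the plane's
#' `antegrade_sign` convention.
#'
#' @param field a [velocity_field].
#' @param plane an [analysis_plane].
#' @return a [flow_trace] (ml/s per frame).
#' @export
compute_flow_trace <- function(field, plane) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(plane, "analysis_plane"))
  delta <- min(field$voxel_size) / 2
  r <- plane$roi_radius_mm
  g <- seq(-r + delta / 2, r - delta / 2, by = delta)
  if (length(g) == 0) g <- 0
  st <- expand.grid(s = g, t = g)
  st <- st[st$s^2 + st$t^2 <= r^2, , drop = FALSE]
  b <- plane_basis(plane$normal)
  pts <- cbind(plane$origin_mm[1] + st$s * b$e1[1] + st$t * b$e2[1],
               plane$origin_mm[2] + st$s * b$e1[2] + st$t * b$e2[2],
               plane$origin_mm[3] + st$s * b$e1[3] + st$t * b$e2[3])
  idx <- sweep(pts, 2, field$voxel_size, "/")        # 0-based voxel coords
  d <- dim(field$data)[1:3]
  in_grid <- idx[, 1] > -0.5 & idx[, 1] < d[1] - 0.5 &
    idx[, 2] > -0.5 & idx[, 2] < d[2] - 0.5 &
    idx[, 3] > -0.5 & idx[, 3] < d[3] - 0.5
  if (!any(in_grid))
    stop("plane region of interest does not intersect the volume")
  nt <- field$n_frames
  q <- numeric(nt)
  da_cm2 <- delta^2 / 100
  for (t_i in seq_len(nt)) {
    vn <- numeric(nrow(idx))
    for (c_i in 1:3) {
      if (abs(plane$normal[c_i]) < 1e-12) next
      vn <- vn + plane$normal[c_i] *
        interp_trilinear(field$data[, , , c_i, t_i], idx)
    }
    q[t_i] <- plane$antegrade_sign * sum(vn) * da_cm2
  }
  dt_s <- field$frame_interval_ms / 1000
  flow_trace((seq_len(nt) - 1) * dt_s, q, plane_id = plane$id,
             period_s = nt * dt_s)
}

#' Detect systole and diastole from a flow trace
#'
#' Systole starts at the last frame before the flow first exceeds 10\% of
#' its peak and ends at the frame before the first non-positive flow after
#' the peak (at the post-peak minimum when the flow never crosses zero);
#' diastole is the cyclic remainder.
#'
#' @param trace a [flow_trace] with a dominant positive lobe.
#' @return a [cardiac_phases].
#' @export
detect_cardiac_phases <- function(trace) {
  q <- trace$flow_ml_s
  n <- length(q)
  if (all(q == 0)) stop("all-zero flow trace: cannot detect phases")
  pk <- which.max(q)
  if (q[pk] <= 0) stop("flow trace has no positive lobe")
  thr <- 0.1 * q[pk]
  above <- which(q > thr)
  onset <- max(1L, above[1] - 1L)
  after <- if (pk < n) (pk + 1L):n else integer(0)
  nonpos <- after[q[after] <= 0]
  if (length(nonpos) > 0) {
    end <- nonpos[1] - 1L
  } else if (length(after) > 0) {
    end <- after[which.min(q[after])]
  } else {
    end <- n
  }
  cardiac_phases(onset:end, n)
}

#' Antegrade and retrograde-diastolic flow volumes
#'
#' Antegrade volume is the cyclic integral of `max(Q, 0)` over the full
#' cycle; retrograde diastolic volume integrates `max(-Q, 0)` over diastole.
#' For uniformly sampled gated data the cyclic trapezoidal rule reduces to
#' the rectangle sum `dt * sum(Q_i)`, which is what is used.
#'
#' @param trace a [flow_trace].
#' @param phases a [cardiac_phases] consistent with the trace.
#' @return list `(antegrade_ml, retrograde_diastolic_ml)`.
#' @export
antegrade_retrograde_volumes <- function(trace, phases) {
  q <- trace$flow_ml_s
  n <- length(q)
  if (phases$n_frames != n) stop("phases inconsistent with trace length")
  dt <- attr(trace, "period_s") / n
  list(antegrade_ml = sum(pmax(q, 0)) * dt,
       retrograde_diastolic_ml = sum(pmax(-q[phases$diastole], 0)) * dt)
}

#' Extract the proximal FL subsection used for MSDR
#'
#' FL voxels between the entry-tear station and a distal landmark (the
#' pulmonary bifurcation level) when a landmark is given; otherwise a 5 cm
#' window centered on the tear. Windows are truncated (with a warning) at
#' the domain edge.
#'
#' @param mask a [lumen_mask].
#' @param tear_axial_position_mm axial station of the entry tear, mm.
#' @param landmark_axial_position_mm optional second axial station, mm.
#' @return a [lumen_mask] containing only the FL subsection (attribute
#'   `subsection_id` records the axial span).
#' @export
extract_fl_subsection <- function(mask, tear_axial_position_mm,
                                  landmark_axial_position_mm = NULL) {
  stopifnot(inherits(mask, "lumen_mask"))
  if (!any(mask$labels == LABEL_FL)) stop("mask has no FL voxels")
  if (is.null(landmark_axial_position_mm)) {
    lo <- tear_axial_position_mm - 25
    hi <- tear_axial_position_mm + 25
  } else {
    lo <- min(tear_axial_position_mm, landmark_axial_position_mm)
    hi <- max(tear_axial_position_mm, landmark_axial_position_mm)
  }
  zmax <- (dim(mask$labels)[3] - 1) * mask$voxel_size[3]
  if (lo < 0 || hi > zmax) {
    warning(sprintf(
      "subsection [%.1f, %.1f] mm truncated to the axial extent [0, %.1f]",
      lo, hi, zmax))
    lo <- max(lo, 0); hi <- min(hi, zmax)
  }
  z <- (seq_len(dim(mask$labels)[3]) - 1) * mask$voxel_size[3]
  keep_z <- z >= lo & z <= hi
  labels <- mask$labels
  labels[labels == LABEL_TL] <- LABEL_BG
  labels[, , !keep_z] <- LABEL_BG
  if (!any(labels == LABEL_FL)) stop("empty FL subsection")
  out <- lumen_mask(labels, mask$voxel_size, mask$affine)
  attr(out, "subsection_id") <- sprintf("FL[%.1f-%.1f mm]", lo, hi)
  out
}

#' Mean-speed trace over a subsection
#'
#' Mean of the velocity magnitude over the subsection voxels, per frame.
#'
#' @param field a [velocity_field].
#' @param subsection a [lumen_mask] (any non-background voxel counts) or a
#'   logical array.
#' @return object of class `acceleration_trace` with `mean_speed_cm_s`
#'   filled and `acceleration_cm_s2` set to `NA` until
#'   [differentiate_trace] is applied.
#' @export
mean_speed_trace <- function(field, subsection) {
  sel <- if (inherits(subsection, "lumen_mask"))
    subsection$labels != LABEL_BG else subsection != 0
  if (!any(sel)) stop("empty subsection")
  if (!identical(dim(sel), dim(field$data)[1:3]))
    stop("subsection grid does not match the field")
  nt <- field$n_frames
  sp <- numeric(nt)
  for (t_i in seq_len(nt)) {
    s <- sqrt(field$data[, , , 1, t_i]^2 + field$data[, , , 2, t_i]^2 +
                field$data[, , , 3, t_i]^2)
    sp[t_i] <- mean(s[sel])
  }
  dt_s <- field$frame_interval_ms / 1000
  structure(list(time_s = (seq_len(nt) - 1) * dt_s,
                 mean_speed_cm_s = sp,
                 acceleration_cm_s2 = rep(NA_real_, nt),
                 subsection_id = attr(subsection, "subsection_id")),
            class = "acceleration_trace")
}

#' Differentiate a mean-speed trace in time
#'
#' Cyclic central differences (second order), exploiting the periodicity of
#' gated cine data for the first/last frames.
#'
#' @param trace an `acceleration_trace` from [mean_speed_trace].
#' @return the trace with `acceleration_cm_s2` filled (cm/s^2).
#' @export
differentiate_trace <- function(trace) {
  s <- trace$mean_speed_cm_s
  n <- length(s)
  if (n < 3) stop("need at least 3 frames for a cyclic derivative")
  dt <- trace$time_s[2] - trace$time_s[1]
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  trace$acceleration_cm_s2 <- (s[ip] - s[im]) / (2 * dt)
  trace
}

# 26-neighborhood offsets (half set; the graph is undirected)
NEIGH26 <- {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
      (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
}

#' Geodesic centerline length of a lumen between two planes
#'
#' Shortest path through the lumen voxel graph (26-connectivity, physical
#' edge lengths) between the medial lumen voxels nearest to the two plane
#' origins. For straight or piecewise-axis-aligned vessels this matches the
#' skeleton arc length; it is an approximation (documented in the methods
#' vignette) for strongly oblique curved vessels.
#'
#' @param mask a [lumen_mask].
#' @param lumen `"TL"` or `"FL"`.
#' @param start_plane,end_plane [analysis_plane]s whose origins mark the
#'   stations.
#' @return length in metres.
#' @export
centerline_length <- function(mask, lumen, start_plane, end_plane) {
  lab <- if (lumen == "TL") LABEL_TL else LABEL_FL
  sel <- which(mask$labels == lab)
  if (length(sel) == 0) stop("empty lumen ", lumen)
  d <- dim(mask$labels)
  h <- mask$voxel_size
  coord <- arrayInd(sel, d)                      # 1-based
  phys <- sweep(coord - 1, 2, h, "*")
  nearest <- function(p) {
    which.min(colSums((t(phys) - p)^2))
  }
  a <- nearest(start_plane$origin_mm)
  b <- nearest(end_plane$origin_mm)
  if (a == b) return(0)
  # voxel graph: map linear voxel index -> node id
  node_of <- integer(prod(d))
  node_of[sel] <- seq_along(sel)
  edges <- list(); wts <- list()
  for (r in seq_len(nrow(NEIGH26))) {
    o <- NEIGH26[r, ]
    ii <- coord[, 1] + o[1]; jj <- coord[, 2] + o[2]; kk <- coord[, 3] + o[3]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    lin <- ii[ok] + (jj[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
    nb <- node_of[lin]
    keep <- nb > 0
    if (!any(keep)) next
    edges[[length(edges) + 1]] <- rbind(which(ok)[keep], nb[keep])
    wts[[length(wts) + 1]] <- rep(sqrt(sum((o * h)^2)), sum(keep))
  }
  g <- igraph::graph_from_edgelist(t(do.call(cbind, edges)),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(sel))
    g <- igraph::add_vertices(g, length(sel) - igraph::vcount(g))
  len <- igraph::distances(g, v = a, to = b, weights = unlist(wts))[1, 1]
  if (!is.finite(len))
    stop("lumen ", lumen, " is disconnected between the planes")
  len / 1000
}

#' Velocity-to-noise ratio from a static-tissue region
#'
#' VNR = venc divided by the standard deviation of the velocity components
#' over a static region of interest (e.g. posterior back muscles) and all
#' frames.
#'
#' @param field a [velocity_field].
#' @param static_roi logical array (congruent grid), TRUE inside the static
#'   region; must not intersect a lumen.
#' @return the VNR (dimensionless); `Inf` with a warning for a noise-free
#'   field.
#' @export
estimate_vnr <- function(field, static_roi) {
  sel <- if (inherits(static_roi, "lumen_mask"))
    static_roi$labels != LABEL_BG else static_roi != 0
  if (!identical(dim(sel), dim(field$data)[1:3]))
    stop("static_roi grid does not match the field")
  if (!any(sel)) stop("empty static region of interest")
  nt <- field$n_frames
  vals <- unlist(lapply(seq_len(nt), function(t_i)
    lapply(1:3, function(c_i) field$data[, , , c_i, t_i][sel])))
  s <- stats::sd(vals)
  if (s == 0) {
    warning("noise-free static region: VNR is infinite")
    return(Inf)
  }
  field$venc / s
}

shift_logical <- function(a, o) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- list(seq_len(d[1]) - o[1], seq_len(d[2]) - o[2], seq_len(d[3]) - o[3])
  ok <- lapply(1:3, function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

OFF6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))

# 6-neighborhood erosion that treats out-of-grid as foreground, so open
# inlet/outlet faces are not eaten
erode6 <- function(a) {
  out <- a
  d <- dim(a)
  for (r in 1:6) {
    o <- OFF6[r, ]
    s <- shift_logical(a, o)
    # replicate padding: out-of-grid counts as foreground
    if (o[1] == 1) s[1, , ] <- a[1, , ]
    if (o[1] == -1) s[d[1], , ] <- a[d[1], , ]
    if (o[2] == 1) s[, 1, ] <- a[, 1, ]
    if (o[2] == -1) s[, d[2], ] <- a[, d[2], ]
    if (o[3] == 1) s[, , 1] <- a[, , 1]
    if (o[3] == -1) s[, , d[3]] <- a[, , d[3]]
    out <- out & s
  }
  out
}

dilate6 <- function(a) {
  out <- a
  for (r in 1:6) out <- out | shift_logical(a, OFF6[r, ])
  out
}

# connected test (6-connectivity) via flood fill with array dilation
is_connected6 <- function(a) {
  if (!any(a)) return(FALSE)
  seed <- array(FALSE, dim(a))
  seed[which(a)[1]] <- TRUE
  repeat {
    grown <- dilate6(seed) & a
    if (sum(grown) == sum(seed)) break
    seed <- grown
  }
  sum(seed) == sum(a)
}

#' Perturb a segmentation for reproducibility analysis
#'
#' Emulates the three segmentation-variation modes: systematically smaller
#' (morphological erosion), systematically larger (dilation constrained to
#' exclude the other lumen), and mixed (a seeded per-axial-slab choice of
#' erode/dilate, emulating manual variation along the vessel). Out-of-grid
#' voxels count as lumen during erosion so the open inlet/outlet faces are
#' preserved.
#'
#' @param mask a [lumen_mask].
#' @param mode `"smaller"`, `"larger"` or `"mixed"`.
#' @param magnitude structuring iterations (voxels), >= 1.
#' @param seed seed for `"mixed"` slab choices.
#' @return a perturbed [lumen_mask]; errors if a lumen would be emptied or
#'   disconnected.
#' @export
perturb_mask <- function(mask, mode = c("smaller", "larger", "mixed"),
                         magnitude = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (magnitude < 1) stop("magnitude must be >= 1")
  labels <- mask$labels
  d <- dim(labels)
  slab_choice <- NULL
  if (mode == "mixed")
    slab_choice <- with_seed(seed, sample(c("smaller", "larger"), d[3],
                                          replace = TRUE))
  for (it in seq_len(magnitude)) {
    new_labels <- array(LABEL_BG, d)
    for (lab in c(LABEL_TL, LABEL_FL)) {
      cur <- labels == lab
      if (!any(cur)) next
      other <- labels != lab & labels != LABEL_BG
      small <- erode6(cur)
      # growth is constrained: never claim the other lumen or touch it
      big <- cur | (dilate6(cur) & !other & !dilate6(other))
      out <- switch(mode, smaller = small, larger = big, mixed = {
        res <- cur
        for (k in seq_len(d[3]))
          res[, , k] <- if (slab_choice[k] == "smaller") small[, , k]
            else big[, , k]
        res
      })
      if (!any(out))
        stop("perturbation emptied lumen ", lab)
      new_labels[out] <- lab
    }
    labels <- new_labels
  }
  for (lab in c(LABEL_TL, LABEL_FL)) {
    if (any(mask$labels == lab) && !is_connected6(labels == lab))
      stop("perturbation disconnected lumen ", lab)
  }
  lumen_mask(labels, mask$voxel_size, mask$affine)
}

#' Randomly re-place an analysis plane (second-rater emulation)
#'
#' Seeded random tilt (rotation of the normal about a random in-plane axis,
#' angle uniform in `[0, max_tilt_deg]`) and translation (uniform within a
#' ball of radius `max_shift_mm`).
#'
#' @param plane an [analysis_plane].
#' @param max_tilt_deg,max_shift_mm perturbation bounds (>= 0).
#' @param seed integer seed.
#' @return a perturbed [analysis_plane].
#' @export
perturb_plane <- function(plane, max_tilt_deg = 5, max_shift_mm = 2,
                          seed = 1L) {
  if (max_tilt_deg < 0 || max_shift_mm < 0) stop("bounds must be >= 0")
  with_seed(seed, {
    n <- plane$normal
    b <- plane_basis(n)
    phi <- stats::runif(1, 0, 2 * pi)
    axis <- cos(phi) * b$e1 + sin(phi) * b$e2
    ang <- stats::runif(1, 0, max_tilt_deg) * pi / 180
    # Rodrigues rotation of n about axis
    n2 <- n * cos(ang) + c(axis[2] * n[3] - axis[3] * n[2],
                           axis[3] * n[1] - axis[1] * n[3],
                           axis[1] * n[2] - axis[2] * n[1]) * sin(ang) +
      axis * sum(axis * n) * (1 - cos(ang))
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2)) * stats::runif(1, 0, max_shift_mm)
    analysis_plane(plane$origin_mm + u, n2, plane$roi_radius_mm,
                   plane$antegrade_sign, plane$id)
  })
}
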