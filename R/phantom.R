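#' Phantom parameters
#'
#' Parameter bundle for [generate_phantom()]. The phantom emulates a fresh
#' wheat grain scanned in a paraffin-filled gelatin capsule: a bright grain
#' whose transverse section is an ellipse (semi-axes
#' `lobe_radius + lobe_separation/2` along X and `lobe_radius` along Y,
#' tapered elliptically along Z over `half_length`) notched by a ventral
#' triangular crease of per-slice depth `d(z)`; an outer tissue shell of
#' `shell_thickness` separated from the inner core by a gap of `gap_width`
#' partly occupied by dark voids (random smoothed arcs covering
#' `void_fraction` of the gap, the rest bridging shell to core); a
#' mid-intensity paraffin cylinder bounded by a thin bright capsule wall; and
#' optional additive Gaussian noise.
#'
#' @param dims volume dimensions in voxels.
#' @param voxel_size mm per voxel.
#' @param half_length grain half length along Z (voxels).
#' @param lobe_radius transverse semi-minor axis (voxels); the crease splits
#'   the section into the grain's two lobes.
#' @param lobe_separation widens the section along X by this much (voxels).
#' @param crease_depth_fn list of parabolic bumps `c(center, half_width,
#'   peak)` over normalized position `u` in `[0, 1]` (bottom to top); depths
#'   add and are capped at 85% of the local section height.
#' @param crease_width notch half-width at the equator (voxels).
#' @param shell_thickness outer tissue thickness (voxels, >= 1).
#' @param gap_width shell-core gap (voxels).
#' @param void_fraction fraction of the gap filled by voids, in `[0, 1]`.
#' @param crease_bridge,bridge_extent touching-lobe regime: over the lower
#'   `bridge_extent` fraction of the grain a tissue roof of `crease_bridge`
#'   voxels closes the crease mouth, turning the channel beneath it into an
#'   enclosed cavity (the documented late-development failure mode of
#'   per-slice crease detection).
#' @param end_cap longitudinal margin (voxels) by which the core and gap stop
#'   short of the grain tips, leaving solid outer tissue caps; `NULL` uses
#'   `max(4, 2 * shell_thickness)`.
#' @param intensities named vector (background, paraffin, capsule, grain) on
#'   the 16-bit scale; voids are as dark as the background.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param pose list with `theta_z`, `theta_y` (degrees) and `translation`
#'   (voxels) applied to the grain (scanner frame keeps the capsule upright).
#' @param capsule_radius,capsule_thickness capsule wall geometry (voxels);
#'   `NULL` places the wall 4 voxels inside the smaller transverse field edge.
#' @param seed integer seed for void placement and noise.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(dims = c(192L, 192L, 192L), voxel_size = 0.01,
                           half_length = 80, lobe_radius = 50,
                           lobe_separation = 24,
                           crease_depth_fn = list(c(0.5, 0.5, 20)),
                           crease_width = 14,
                           shell_thickness = 6, gap_width = 4,
                           void_fraction = 0.85,
                           crease_bridge = 0, bridge_extent = 0,
                           end_cap = NULL,
                           intensities = c(background = 4000, paraffin = 18000,
                                           capsule = 46000, grain = 50000),
                           noise_sigma = 0,
                           pose = list(theta_z = 0, theta_y = 0,
                                       translation = c(0, 0, 0)),
                           capsule_radius = NULL, capsule_thickness = 1,
                           seed = 1L) {
  gt_assert(length(dims) == 3 && all(dims >= 8), "argument",
            "dims must be three values >= 8")
  gt_assert(shell_thickness >= 1, "argument", "shell_thickness must be >= 1")
  gt_assert(void_fraction >= 0 && void_fraction <= 1, "argument",
            "void_fraction must lie in [0, 1]")
  req <- c("background", "paraffin", "capsule", "grain")
  gt_assert(all(req %in% names(intensities)), "argument",
            "intensities must name background, paraffin, capsule, grain")
  gt_assert(intensities["background"] < intensities["paraffin"] &&
              intensities["paraffin"] < intensities["grain"],
            "argument", "need background < paraffin < grain intensities")
  peak_depth <- max(phantom_depth_raw(crease_depth_fn, seq(0, 1, by = 0.01)))
  gt_assert(lobe_radius > peak_depth * 0.999, "argument",
            "lobe_radius must exceed the maximum crease depth")
  if (is.null(capsule_radius)) capsule_radius <- floor(min(dims[1:2]) / 2) - 4
  if (is.null(end_cap)) end_cap <- max(4, 2 * shell_thickness)
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 half_length = half_length, lobe_radius = lobe_radius,
                 lobe_separation = lobe_separation,
                 crease_depth_fn = crease_depth_fn,
                 crease_width = crease_width,
                 shell_thickness = shell_thickness, gap_width = gap_width,
                 void_fraction = void_fraction,
                 crease_bridge = crease_bridge, bridge_extent = bridge_extent,
                 end_cap = end_cap, intensities = intensities,
                 noise_sigma = noise_sigma, pose = pose,
                 capsule_radius = capsule_radius,
                 capsule_thickness = capsule_thickness,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Raw (uncapped) crease depth at normalized position u in [0, 1].
phantom_depth_raw <- function(bumps, u) {
  d <- rep(0, length(u))
  for (bp in bumps) {
    d <- d + bp[3] * pmax(0, 1 - ((u - bp[1]) / bp[2])^2)
  }
  d
}

#' Ground-truth crease depth of a phantom
#'
#' Analytic depth applied at normalized position `u` (0 = grain bottom,
#' 1 = top): the summed parabolic bumps, capped at 85% of the local tapered
#' section height, exactly as the generator applies it.
#'
#' @param p a [phantom_params()] bundle.
#' @param u positions in `[0, 1]`.
#' @return Depths in voxels.
#' @export
phantom_depth_truth <- function(p, u) {
  s <- sqrt(pmax(0, 1 - (2 * u - 1)^2))
  pmin(phantom_depth_raw(p$crease_depth_fn, u), 0.85 * p$lobe_radius * s)
}

#' Analytic grain extents of a phantom
#'
#' Ground-truth length and mean central-window width/thickness implied by the
#' phantom geometry (continuous ellipse extents plus the half-voxel
#' rasterization allowance), for validating the morphometry operators.
#'
#' @param p a [phantom_params()] bundle.
#' @param n_slices central window used for width/thickness.
#' @return Named vector `c(length_vox, width_vox, thickness_vox)`.
#' @export
phantom_truth_extents <- function(p, n_slices = 200L) {
  L <- p$half_length
  zs <- seq(-floor(L) + 1, floor(L) - 1)
  win <- floor(min(n_slices, length(zs)) / 2)
  zc <- zs[abs(zs) <= win]
  s <- sqrt(pmax(0, 1 - (zc / L)^2))
  a <- (p$lobe_radius + p$lobe_separation / 2) * s
  b <- p$lobe_radius * s
  u <- (zc / L + 1) / 2
  d <- pmin(phantom_depth_raw(p$crease_depth_fn, u), 0.85 * b)
  w <- p$crease_width * s
  # the notch removes the ellipse apex at |x| <= w, so the +Y extreme drops
  # from b to the mouth-corner height b*sqrt(1 - (w/a)^2)
  ytop <- ifelse(d > 0.5 & w >= 1 & w < a,
                 b * sqrt(pmax(0, 1 - (w / pmax(a, 1e-6))^2)), b)
  c(length_vox = 2 * L,
    width_vox = mean(b + ytop + 1),
    thickness_vox = mean(2 * a + 1))
}

# Smoothed random indicator over (angle bin, z bin) cells marking void arcs.
void_cell_field <- function(n_theta, n_zeta, void_fraction) {
  if (void_fraction <= 0) return(matrix(FALSE, n_theta, n_zeta))
  if (void_fraction >= 1) return(matrix(TRUE, n_theta, n_zeta))
  U <- matrix(runif(n_theta * n_zeta), n_theta, n_zeta)
  for (pass in 1:2) {
    V <- U
    for (dt in -1:1) for (dz in -1:1) {
      rows <- ((seq_len(n_theta) - 1 + dt) %% n_theta) + 1
      cols <- pmin(pmax(seq_len(n_zeta) + dz, 1), n_zeta)
      V <- V + U[rows, cols]
    }
    U <- V / 10
  }
  U <= stats::quantile(U, void_fraction)
}

#' Generate a synthetic grain phantom with ground truth
#'
#' Deterministic given `seed`. Returns the 16-bit intensity volume and a
#' voxel-exact truth: the label grid (0 background, 1 paraffin, 2 capsule
#' wall, 3 outer tissue, 4 inner tissue, 5 void), label counts, the applied
#' pose and a parameter echo. Before noise, the volume is a pure function of
#' the labels, so thresholding the noiseless volume at midpoints between the
#' intensity levels reproduces the intensity classes exactly.
#'
#' @param p a [phantom_params()] bundle.
#' @return List with `volume` (a [vol_image]) and `truth`.
#' @export
generate_phantom <- function(p) {
  gt_assert(inherits(p, "phantom_params"), "argument",
            "p must come from phantom_params()")
  d <- p$dims
  ctr <- (d + 1) / 2
  tvec <- p$pose$translation
  L <- p$half_length
  a0 <- p$lobe_radius + p$lobe_separation / 2
  b0 <- p$lobe_radius
  t <- p$shell_thickness
  g <- p$gap_width

  # conservative fit check: rotated bounding-box corners must stay in-grid
  Mfwd <- rot_z(p$pose$theta_z) %*% rot_y(p$pose$theta_y)
  corners <- as.matrix(expand.grid(x = c(-a0, a0), y = c(-b0, b0), z = c(-L, L)))
  moved <- corners %*% t(Mfwd)
  lims <- sweep(moved, 2, ctr + tvec, "+")
  gt_assert(all(lims >= 1) && all(sweep(lims, 2, d, "-") <= 0),
            "argument", "grain geometry exceeds dims under the requested pose")

  set.seed(p$seed)
  n_theta <- 36L; n_zeta <- 48L
  vfield <- void_cell_field(n_theta, n_zeta, p$void_fraction)

  Minv <- rot_y(-p$pose$theta_y) %*% rot_z(-p$pose$theta_z)

  labels <- array(0L, dim = d)
  xg <- rep(seq_len(d[1]), times = d[2]) - ctr[1]
  yg <- rep(seq_len(d[2]), each = d[1]) - ctr[2]
  r2xy <- xg^2 + yg^2
  cap_out2 <- p$capsule_radius^2
  cap_in2 <- (p$capsule_radius - p$capsule_thickness)^2
  cap_sl <- r2xy <= cap_out2 & r2xy > cap_in2
  par_sl <- r2xy <= cap_in2

  # ellipse and notch-cut membership for the tapered section shrunk inward
  # by `shrink`; `bridged` closes the crease mouth with a tissue roof of
  # p$crease_bridge voxels (touching lobes)
  shape_parts <- function(X, Y, s, dv, shrink, bridged) {
    av <- a0 * s - shrink
    bv <- b0 * s - shrink
    ok <- av > 0.5 & bv > 0.5
    ell <- ok & ((X / pmax(av, 1e-6))^2 + (Y / pmax(bv, 1e-6))^2 <= 1)
    wv <- p$crease_width * s
    notch_on <- wv >= 1 & dv > 0.5
    frac <- pmin(pmax(wv / pmax(av, 1e-6), 0), 1)
    ym <- bv * sqrt(pmax(0, 1 - frac^2))
    cut <- notch_on & abs(X) <= wv & Y > ym - dv * (1 - abs(X) / pmax(wv, 1e-6))
    cut <- cut & !(bridged & Y > ym - p$crease_bridge)
    list(ell = ell, cut = ell & cut)
  }

  for (z in seq_len(d[3])) {
    xr <- xg - tvec[1]; yr <- yg - tvec[2]; zr <- z - ctr[3] - tvec[3]
    Xc <- Minv[1, 1] * xr + Minv[1, 2] * yr + Minv[1, 3] * zr
    Yc <- Minv[2, 1] * xr + Minv[2, 2] * yr + Minv[2, 3] * zr
    Zc <- Minv[3, 1] * xr + Minv[3, 2] * yr + Minv[3, 3] * zr
    zeta <- Zc / L
    s <- sqrt(pmax(0, 1 - zeta^2))
    u <- (zeta + 1) / 2
    dv <- pmin(phantom_depth_raw(p$crease_depth_fn, u), 0.85 * b0 * s)
    inz <- s > 0

    bridged <- p$crease_bridge > 0 & u < p$bridge_extent
    core_ok <- abs(Zc) <= L - p$end_cap
    pO <- shape_parts(Xc, Yc, s, dv, 0, bridged)
    pA <- shape_parts(Xc, Yc, s, dv, t, bridged)
    pC <- shape_parts(Xc, Yc, s, dv, t + g, bridged)
    O <- inz & pO$ell & !pO$cut
    A <- inz & core_ok & pA$ell & !pA$cut
    C <- inz & core_ok & pC$ell & !pC$cut
    channel <- inz & bridged & pO$cut   # sealed crease channel = enclosed cavity

    lab <- integer(length(xg))
    lab[par_sl] <- 1L
    lab[cap_sl] <- 2L
    gap <- A & !C
    if (any(gap)) {
      th_bin <- pmin(n_theta, 1L + floor((atan2(Yc[gap], Xc[gap]) + pi) /
                                           (2 * pi) * n_theta))
      z_bin <- pmin(n_zeta, pmax(1L, 1L + floor(u[gap] * n_zeta)))
      isvoid <- vfield[cbind(th_bin, z_bin)]
    } else isvoid <- logical(0)
    lab[O & !A] <- 3L                      # shell
    gi <- which(gap)
    lab[gi[!isvoid]] <- 3L                 # bridges count as outer tissue
    lab[C] <- 4L                           # core
    lab[gi[isvoid]] <- 5L                  # voids
    lab[channel] <- 5L                     # sealed crease channel
    labels[, , z] <- lab
  }

  ints <- p$intensities
  lut <- c(ints["background"], ints["paraffin"], ints["capsule"],
           ints["grain"], ints["grain"], ints["background"])
  vol <- array(lut[labels + 1L], dim = d)
  if (p$noise_sigma > 0) {
    vol <- vol + rnorm(length(vol), sd = p$noise_sigma)
    vol <- round(pmin(pmax(vol, 0), 65535))
  }

  counts <- setNames(tabulate(labels + 1L, nbins = 6L),
                     c("background", "paraffin", "capsule", "outer", "inner",
                       "void"))
  list(volume = vol_image(vol, p$voxel_size, id = sprintf("phantom-%d", p$seed)),
       truth = list(labels = labels, counts = counts,
                    pose = p$pose, params = p, seed = p$seed))
}

#' Grain mask implied by a phantom truth
#'
#' Foreground of the grain (outer plus inner tissue labels).
#' @param phantom result of [generate_phantom()].
#' @return A [binary_mask].
#' @export
phantom_grain_mask <- function(phantom) {
  lab <- phantom$truth$labels
  binary_mask(array(lab == 3L | lab == 4L, dim = dim(lab)),
              phantom$truth$params$voxel_size)
}

#' Preset phantom parameter bundles
#'
#' Three qualitative developmental regimes:
#' `"early"` -- small grain with a thick shell and a thin core (the regime
#' where opening-based tissue separation is expected to fail);
#' `"mid"` -- well-developed shell/gap/core with abundant voids, the regime
#' every stage handles well; `"late"` -- near-ellipsoidal grain with a thin
#' shell, few voids and a deep narrow crease whose lobes can touch (the
#' regime where per-slice crease detection becomes unstable).
#'
#' @param name one of `"early"`, `"mid"`, `"late"`.
#' @param seed seed stored in the bundle.
#' @return A [phantom_params()] bundle.
#' @export
phantom_preset <- function(name = c("mid", "early", "late"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    mid = phantom_params(dims = c(160L, 160L, 176L), half_length = 72,
                         lobe_radius = 40, lobe_separation = 20,
                         crease_depth_fn = list(c(0.5, 0.5, 16)),
                         crease_width = 12, shell_thickness = 5, gap_width = 4,
                         void_fraction = 0.8, noise_sigma = 800, seed = seed),
    early = phantom_params(dims = c(96L, 96L, 112L), half_length = 48,
                           lobe_radius = 16, lobe_separation = 8,
                           crease_depth_fn = list(c(0.5, 0.5, 8)),
                           crease_width = 8, shell_thickness = 8, gap_width = 2,
                           void_fraction = 0.15, end_cap = 6,
                           noise_sigma = 500, seed = seed),
    late = phantom_params(dims = c(160L, 160L, 192L), half_length = 80,
                          lobe_radius = 36, lobe_separation = 16,
                          crease_depth_fn = list(c(0.5, 0.55, 31)),
                          crease_width = 4, shell_thickness = 3, gap_width = 3,
                          void_fraction = 0.35, crease_bridge = 2,
                          bridge_extent = 0.45, noise_sigma = 500,
                          seed = seed))
}
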