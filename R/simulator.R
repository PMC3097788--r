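#' Acquisition setup
#'
#' Everything one exposure needs: geometry, optional phantom and blocker,
#' tube spectrum and output settings, and the Monte Carlo budget.  The
#' defaults mirror the study conditions: 3 s exposures, 100 mA (water
#' phantom) or 200 mA (polypropylene), 10^6 photons.
#'
#' @param geometry a [scanner_geometry()]
#' @param phantom a [ct_phantom()] or NULL
#' @param blocker a [blocker_array()] or NULL
#' @param spectrum an [xray_spectrum()]
#' @param tube_current tube current, mA
#' @param exposure_s exposure time, s
#' @param n_photons Monte Carlo photon budget
#' @param seed RNG seed for the Monte Carlo and the noise model
#' @param noise `"off"` or `"poisson"`
#' @export
acquisition_setup <- function(geometry, phantom = NULL, blocker = NULL,
                              spectrum, tube_current = 100, exposure_s = 3,
                              n_photons = 1e6, seed = 1,
                              noise = c("off", "poisson")) {
  stopifnot(inherits(geometry, "scanner_geometry"),
            inherits(spectrum, "xray_spectrum"))
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "ct_phantom"))
    validate_phantom(phantom, geometry)
  }
  if (!is.null(blocker)) stopifnot(inherits(blocker, "blocker_array"))
  if (tube_current <= 0 || exposure_s <= 0)
    stop("tube_current and exposure_s must be positive")
  if (n_photons < 0) stop("n_photons must be nonnegative")
  structure(list(geometry = geometry, phantom = phantom, blocker = blocker,
                 spectrum = spectrum, tube_current = tube_current,
                 exposure_s = exposure_s, n_photons = n_photons,
                 seed = as.integer(seed), noise = match.arg(noise)),
            class = "acquisition_setup")
}

#' @export
print.acquisition_setup <- function(x, ...) {
  cat(sprintf("<acquisition_setup> %g kVp, %g mA, %g s; phantom: %s; blocker: %s; %g photons, seed %d, noise %s\n",
              x$spectrum$kvp, x$tube_current, x$exposure_s,
              if (is.null(x$phantom)) "none" else
                paste0(x$phantom$fill_diameter, " mm ", x$phantom$fill_material),
              if (is.null(x$blocker)) "none" else
                paste0(x$blocker$n_bars, " bars"),
              x$n_photons, x$seed, x$noise))
  invisible(x)
}

# total emitted photon weight for an exposure (arbitrary detector units):
# output ~ k * mA * s * kVp^2
tube_output <- function(setup) {
  .const$tube_output_k * setup$tube_current * setup$exposure_s *
    setup$spectrum$kvp^2
}

# per-channel blocker factor: open fraction + covered fraction times the
# 3 mm lead bar transmission (single-valued mu = 37.52 cm^-1)
blocker_channel_factor <- function(geom, blocker) {
  if (is.null(blocker)) return(rep(1, geom$n_channels_total))
  cov <- blocker_coverage(geom, blocker)$coverage
  t_bar <- exp(-lead_blocker_attenuation() * blocker$bar_thickness / 10)
  1 - cov + cov * t_bar
}

#' Simulate the primary (unscattered) signal
#'
#' Beer-Lambert ray integral per channel: the tube output share of each
#' channel ray times the fluence-and-energy-weighted transmission through
#' the phantom materials, times the blocker shadow factor (bar
#' transmission for fully covered channels, a linear edge fraction for
#' partially covered boundary channels).  Deterministic; all rows carry
#' the same profile since the phantom is z-invariant over the small cone
#' angle.
#'
#' @param setup an [acquisition_setup()]
#' @return `n_rows x n_channels` matrix of detector readings
#' @export
simulate_primary <- function(setup) {
  stopifnot(inherits(setup, "acquisition_setup"))
  g <- setup$geometry
  sp <- setup$spectrum
  nch <- g$n_channels_total
  B <- blocker_channel_factor(g, setup$blocker)
  if (is.null(setup$phantom)) {
    att_sum <- rep(sum(sp$fluence * sp$energy), nch)
  } else {
    ph <- setup$phantom
    gamma <- channel_fan_angle(g, 0:(nch - 1)) * pi / 180
    yc <- g$source_to_iso + ph$axial_offset
    d <- abs(yc * sin(gamma))
    chord <- function(R) ifelse(d < R, 2 * sqrt(pmax(R^2 - d^2, 0)), 0) / 10
    l_fill <- chord(ph$fill_diameter / 2)
    l_wall <- chord(phantom_outer_radius(ph)) - l_fill
    mu_f <- linear_attenuation(ph$fill_material, sp$energy)
    mu_w <- if (ph$wall_thickness > 0)
      linear_attenuation(ph$wall_material, sp$energy) else rep(0, length(sp$energy))
    # outer(E, channel): exp(-mu_f l_f - mu_w l_w), weighted by fluence*E
    att_sum <- as.vector(crossprod(sp$fluence * sp$energy,
                                   exp(-outer(mu_f, l_fill) - outer(mu_w, l_wall))))
  }
  row_profile <- tube_output(setup) / nch * att_sum * B
  matrix(rep(row_profile, each = g$n_rows), g$n_rows, nch)
}

# fine uniform energy grid for attenuation lookups at scattered energies
.fine_mu <- function(material, emin = 10, emax = 150, step = 0.25) {
  e <- seq(emin, emax, by = step)
  list(emin = emin, step = step,
       mu = if (is.null(material)) rep(0, length(e))
            else linear_attenuation(material, e))
}

.fine_lookup <- function(fm, energy) {
  e <- pmin(pmax(energy, fm$emin), fm$emin + (length(fm$mu) - 1) * fm$step)
  i <- pmin(floor((e - fm$emin) / fm$step) + 1, length(fm$mu) - 1)
  w <- (e - (fm$emin + (i - 1) * fm$step)) / fm$step
  fm$mu[i] * (1 - w) + fm$mu[i + 1] * w
}

#' Single-scatter Compton Monte Carlo
#'
#' Transports `n_photons` source photons through one fan plane: energy
#' sampled from the spectrum (stratified within each channel block), fan
#' direction stratified uniformly over the channels whose rays cross the
#' phantom, the Compton interaction point sampled along the ray inside
#' the phantom fill with density proportional to the local attenuation
#' (split over equal-probability depth strata, with an antithetic copy
#' for the in-plane azimuth sign), scattering angle sampled from the
#' Klein-Nishina distribution, and the scattered-energy-weighted
#' contribution deposited at the detector channel the exit ray crosses,
#' attenuated by the exit path through fill and wall.  The
#' stratification and splitting are pure variance reduction; every
#' sub-path is an unbiased sample of the same single-scatter estimand.
#'
#' Two aspects of the z (row) dimension are handled analytically rather
#' than sampled.  First, the out-of-plane azimuthal component, which
#' only sets the exit ray's z intercept, is integrated exactly: each
#' photon's contribution is spread over z-offset bins with the arcsine
#' weight of the uniform azimuth (an expected-value tally; over the
#' +-4 degree exit band the in-plane direction and path lengths are
#' treated as constant).  Second, the cone illuminates all 64 row fans,
#' and the phantom is z-invariant, so every fan plane produces the same
#' single-plane deposit pattern shifted by its own row: the per-row
#' scatter is the convolution of the single-plane z-offset pattern with
#' the 64 illuminated planes.  Offsets falling outside the detector band
#' for every plane are lost (out-of-cone exits are discarded); the small
#' z divergence of the cone (+-2 degrees) is neglected.  The blocker
#' attenuates the incident ray; it sits upstream of the phantom, so exit
#' rays toward the detector cannot recross it.  Bit-reproducible for a
#' fixed seed.
#'
#' @param setup an [acquisition_setup()]; a phantom must be present
#' @return list with `scatter` and `se` matrices (`n_rows x n_channels`,
#'   `se` the per-element Monte Carlo standard error), plus
#'   `channel_total` and `channel_se`, the per-channel sums over rows
#'   with their standard errors (the row-summed SE cannot be assembled
#'   from the per-element SEs because one photon's deposits across rows
#'   are correlated)
#' @export
simulate_scatter_mc <- function(setup) {
  stopifnot(inherits(setup, "acquisition_setup"))
  if (is.null(setup$phantom))
    stop("scatter simulation requires a phantom in the setup")
  g <- setup$geometry; ph <- setup$phantom; sp <- setup$spectrum
  nch <- g$n_channels_total; nr <- g$n_rows
  zero <- matrix(0, nr, nch)
  zero_res <- list(scatter = zero, se = zero,
                   channel_total = numeric(nch), channel_se = numeric(nch))
  if (setup$n_photons == 0) return(zero_res)

  pitch <- channel_pitch(g) * pi / 180
  rd <- g$source_to_detector
  row_pitch_det <- g$row_pitch_at_iso * rd / g$source_to_iso
  yc <- g$source_to_iso + ph$axial_offset
  r_fill <- ph$fill_diameter / 2
  r_out <- phantom_outer_radius(ph)
  has_wall <- ph$wall_thickness > 0

  # per-spectrum-bin physics tables
  ebins <- sp$energy
  mu_f_bin <- linear_attenuation(ph$fill_material, ebins)
  mu_w_bin <- if (has_wall) linear_attenuation(ph$wall_material, ebins)
              else rep(0, length(ebins))
  muc_bin <- compton_linear_attenuation(ph$fill_material, ebins)
  th_grid <- .kn_theta_grid()
  # per-bin inverse CDF of the scattering angle, tabulated on a fixed
  # quantile grid for O(1) vectorised sampling
  n_q <- 8192L
  qgrid <- (0:n_q) / n_q
  qtab <- vapply(ebins, function(E)
    approx(.kn_theta_cdf(E), th_grid, xout = qgrid, ties = "ordered")$y,
    numeric(n_q + 1L))
  fm_fill <- .fine_mu(ph$fill_material)
  fm_wall <- .fine_mu(if (has_wall) ph$wall_material else NULL)
  Bch <- blocker_channel_factor(g, setup$blocker)

  n <- setup$n_photons

  with_local_seed(setup$seed, {
    # only channels whose rays cross the fill can contribute; the photon
    # budget is stratified equally over those channels (the others'
    # contribution is identically zero)
    gamma_all <- ((0:(nch - 1)) - (nch - 1) / 2) * pitch
    hit_ch <- which(r_fill^2 - (yc * sin(gamma_all))^2 > 0) - 1L
    if (length(hit_ch) == 0) return(zero_res)
    m_ch <- length(hit_ch)
    n_per <- rep(n %/% m_ch, m_ch)
    rem <- n - sum(n_per)
    if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
    ch <- rep.int(hit_ch, n_per)
    blk <- sequence(n_per)                  # position within channel block
    w0 <- tube_output(setup) / (nch * rep.int(n_per, n_per))
    gamma <- gamma_all[ch + 1]
    dx <- sin(gamma); dy <- cos(gamma)
    # energy: stratified inverse-CDF draw within each channel block
    u_e <- (blk - runif(length(ch))) / rep.int(n_per, n_per)
    ebin <- findInterval(u_e, c(0, cumsum(sp$fluence)),
                         rightmost.closed = TRUE)
    ebin <- pmin(pmax(ebin, 1L), length(ebins))

    dperp <- yc * dx                       # signed perpendicular distance
    disc <- r_fill^2 - dperp^2
    m0 <- yc * dy
    t0 <- m0 - sqrt(disc); t1 <- m0 + sqrt(disc)
    wall_in <- if (has_wall) t0 - (m0 - sqrt(r_out^2 - dperp^2)) else 0

    e0 <- ebins[ebin]
    mu_f <- mu_f_bin[ebin]; mu_w <- mu_w_bin[ebin]; muc <- muc_bin[ebin]
    L_cm <- (t1 - t0) / 10
    surv <- 1 - exp(-mu_f * L_cm)
    w_ph <- w0 * Bch[ch + 1] * exp(-mu_w * wall_in / 10) * surv *
      (muc / mu_f)

    # each photon splits into a full factorial of K equal-probability
    # depth strata of the truncated exponential x T scattering-angle
    # strata x both in-plane azimuth signs (variance reduction by
    # stratified splitting; every sub-path is an unbiased sample).
    # Photons are processed in fixed-size chunks to bound memory.
    K <- 4L                                # depth strata
    Tt <- 8L                               # angle strata
    n_sub <- 2L * K * Tt
    s <- matrix(0, nr, nch); s2 <- matrix(0, nr, nch)
    s_tot <- numeric(nch); s2_tot <- numeric(nch)
    nph_all <- length(ch)
    ph_chunk <- 12500L
    # sub-path layout within a photon: sign alternates fastest, then
    # depth stratum, then angle stratum
    sub_sgn <- rep_len(c(-1, 1), n_sub)
    sub_dep <- rep(rep(seq_len(K), each = 2), Tt)
    sub_ang <- rep(seq_len(Tt), each = 2L * K)
    for (p0 in seq(1, nph_all, by = ph_chunk)) {
      p1 <- min(p0 + ph_chunk - 1L, nph_all)
      ii <- p0:p1
      nph <- length(ii)
      rep_k <- function(x) rep(x[ii], each = n_sub)
      u_dep <- (rep(sub_dep, nph) - runif(n_sub * nph)) / K
      chc <- rep_k(ch); ebc <- rep_k(ebin); e0c <- rep_k(e0)
      dxc <- rep_k(dx); dyc <- rep_k(dy)
      mufc <- rep_k(mu_f); t0c <- rep_k(t0)
      wc <- rep_k(w_ph) / n_sub
      sgn <- rep_len(sub_sgn, n_sub * nph)
      s_cm <- -log1p(-u_dep * rep_k(surv)) / mufc

      # scattering angle: stratified quantile within each photon, then
      # interpolated from the tabulated inverse CDF
      v <- (rep(sub_ang, nph) - runif(length(chc))) / Tt
      vq <- v * n_q
      iq <- pmin(floor(vq), n_q - 1L)
      fq <- vq - iq
      theta <- qtab[cbind(iq + 1L, ebc)] * (1 - fq) +
        qtab[cbind(iq + 2L, ebc)] * fq
      ct <- cos(theta); st <- sin(theta)
      e1 <- e0c / (1 + (e0c / .const$electron_rest_keV) * (1 - ct))

      # interaction point (mm, z = 0 plane)
      px <- dxc * (t0c + 10 * s_cm); py <- dyc * (t0c + 10 * s_cm)

      # in-plane exit direction; the out-of-plane azimuth component is
      # integrated analytically below
      ux <- ct * dxc + st * sgn * dyc
      uy <- ct * dyc - st * sgn * dxc

      # exit path lengths through fill and wall along the in-plane ray
      rx <- px; ry <- py - yc               # relative to phantom centre
      bq <- ux * rx + uy * ry
      c0 <- rx^2 + ry^2 - r_fill^2
      l_fill_ip <- -bq + sqrt(pmax(bq^2 - c0, 0))
      l_wall_ip <- if (has_wall) {
        c0o <- rx^2 + ry^2 - r_out^2
        (-bq + sqrt(pmax(bq^2 - c0o, 0))) - l_fill_ip
      } else 0
      att_out <- exp(-(.fine_lookup(fm_fill, e1) * l_fill_ip +
                       .fine_lookup(fm_wall, e1) * l_wall_ip) / 10)

      # crossing of the detector arc (radius-R circle about the source)
      bq2 <- px * ux + py * uy
      c2 <- px^2 + py^2 - rd^2
      tcross <- -bq2 + sqrt(pmax(bq2^2 - c2, 0))
      gx <- px + tcross * ux; gy <- py + tcross * uy
      gdet <- atan2(gx, gy)
      chan <- floor(gdet / pitch + nch / 2)
      ok <- chan >= 0 & chan < nch
      if (!any(ok)) next
      val <- (wc * att_out * e1)[ok]
      chan <- chan[ok]
      # z intercept per unit cos(phi): z = tcross sin(theta) cos(phi);
      # the uniform azimuth puts arcsine-distributed mass over z-offset
      # bins, and summing the 64 illuminated planes turns the offset
      # pattern into per-row deposits (convolution with a 64-wide box)
      zspread <- pmax((tcross * st)[ok], 1e-9)
      tl <- mc_tally_cpp(val, as.integer(chan), zspread, row_pitch_det,
                         as.integer(nr), as.integer(nch))
      s <- s + tl$s; s2 <- s2 + tl$s2
      s_tot <- s_tot + tl$s_tot; s2_tot <- s2_tot + tl$s2_tot
    }
    list(scatter = s, se = sqrt(s2),
         channel_total = s_tot, channel_se = sqrt(s2_tot))
  })
}

#' Deterministic single-scatter quadrature
#'
#' Quadrature oracle for [simulate_scatter_mc()]: discretises the
#' incident fan into rays (partitioned at the bar edges) and each ray's
#' chord through the phantom fill into steps of `grid_resolution`,
#' groups the spectrum into energy groups, and for every (interaction
#' point, detector channel) pair integrates source-to-point attenuation
#' x the Klein-Nishina angular density over the channel bin as seen
#' from the point x exit attenuation x scattered energy; each
#' contribution is spread over the 64 detector rows with the same
#' arcsine row-window function the Monte Carlo tally uses (uniform
#' out-of-plane azimuth summed over the illuminated fan planes).  Same
#' estimand and normalisation as the Monte Carlo; converges to it as
#' the resolutions increase.
#'
#' @param setup an [acquisition_setup()]; a phantom must be present
#' @param grid_resolution step along each chord, mm (must be positive)
#' @param channel_stride incident-fan resolution: about one quadrature
#'   ray per `channel_stride` channels, with the fan partitioned at the
#'   bar edges so the blocker structure is exact at any stride
#' @param n_energy_groups number of spectrum energy groups
#' @return `n_rows x n_channels` scatter matrix
#' @export
simulate_scatter_deterministic <- function(setup, grid_resolution = 2,
                                           channel_stride = 2,
                                           n_energy_groups = 40) {
  stopifnot(inherits(setup, "acquisition_setup"))
  if (is.null(setup$phantom))
    stop("scatter simulation requires a phantom in the setup")
  if (grid_resolution <= 0) stop("grid_resolution must be positive")
  g <- setup$geometry; ph <- setup$phantom; sp <- setup$spectrum
  nch <- g$n_channels_total; nr <- g$n_rows
  pitch <- channel_pitch(g) * pi / 180
  fan_rad <- g$fan_angle * pi / 180
  rd <- g$source_to_detector
  row_pitch_det <- g$row_pitch_at_iso * rd / g$source_to_iso
  yc <- g$source_to_iso + ph$axial_offset
  r_fill <- ph$fill_diameter / 2
  r_out <- phantom_outer_radius(ph)
  has_wall <- ph$wall_thickness > 0

  # incident-fan quadrature partitioned at the bar edges, so the sharp
  # blocker structure of the incident fluence (and hence the forward-
  # scatter dips it imprints on the scatter profile) is resolved exactly:
  # within each segment the blocker factor is constant
  seg_edges <- c(-fan_rad / 2, fan_rad / 2)
  t_bar <- 1
  if (!is.null(setup$blocker)) {
    ba <- blocker_coverage(g, setup$blocker)$bar_angles
    t_bar <- exp(-lead_blocker_attenuation() * setup$blocker$bar_thickness / 10)
    seg_edges <- sort(unique(c(seg_edges, ba[, "lo"], ba[, "hi"])))
  }
  gamma_r <- numeric(0); w_r <- numeric(0); B_r <- numeric(0)
  stride_angle <- channel_stride * pitch
  for (s in seq_len(length(seg_edges) - 1)) {
    a <- seg_edges[s]; b <- seg_edges[s + 1]
    covered <- !is.null(setup$blocker) &&
      any(a >= ba[, "lo"] - 1e-12 & b <= ba[, "hi"] + 1e-12)
    nn <- if (covered) 1L else max(1L, as.integer(ceiling((b - a) /
                                                            stride_angle)))
    gamma_r <- c(gamma_r, a + (seq_len(nn) - 0.5) / nn * (b - a))
    w_r <- c(w_r, rep((b - a) / nn / pitch, nn))   # weight in channel units
    B_r <- c(B_r, rep(if (covered) t_bar else 1, nn))
  }
  n_rays <- length(gamma_r)
  dperp <- yc * sin(gamma_r)
  disc <- r_fill^2 - dperp^2
  hit <- disc > 0
  m0 <- yc * cos(gamma_r)
  t0 <- m0 - sqrt(pmax(disc, 0)); t1 <- m0 + sqrt(pmax(disc, 0))
  wall_in <- if (has_wall)
    (t0 - (m0 - sqrt(pmax(r_out^2 - dperp^2, 0)))) / 10 else rep(0, n_rays)

  # energy groups: contiguous blocks, fluence-weighted representative energy
  nb <- length(sp$energy)
  ng <- min(n_energy_groups, nb)
  grp <- as.integer(cut(seq_len(nb), ng, labels = FALSE))
  Eg <- vapply(seq_len(ng), function(k)
    sum(sp$energy[grp == k] * sp$fluence[grp == k]) /
      max(sum(sp$fluence[grp == k]), 1e-300), numeric(1))
  fg <- vapply(seq_len(ng), function(k) sum(sp$fluence[grp == k]), numeric(1))
  ok_g <- fg > 0
  Eg <- Eg[ok_g]; fg <- fg[ok_g]
  muf_g <- linear_attenuation(ph$fill_material, Eg)
  muw_g <- if (has_wall) linear_attenuation(ph$wall_material, Eg)
           else rep(0, length(Eg))
  muc_g <- compton_linear_attenuation(ph$fill_material, Eg)
  sig_g <- kn_total_cross_section(Eg)
  fm_fill <- .fine_mu(ph$fill_material)
  fm_wall <- .fine_mu(if (has_wall) ph$wall_material else NULL)

  scatter_quadrature_cpp(
    gamma_r[hit], B_r[hit], w_r[hit], t0[hit], t1[hit], wall_in[hit],
    Eg, fg, muf_g, muw_g, muc_g, sig_g,
    fm_fill$mu, fm_wall$mu, fm_fill$emin, fm_fill$step,
    as.integer(nr), as.integer(nch), pitch, rd, row_pitch_det,
    yc, r_fill, if (has_wall) r_out else 0,
    grid_resolution, tube_output(setup) / nch)
}

#' Compare Monte Carlo scatter against the quadrature oracle
#'
#' Runs both scatter estimators on the same setup and reports, per
#' detector channel (summed over rows), the z-score of the Monte Carlo
#' estimate against the deterministic quadrature.  The per-channel
#' standard error is locally pooled over `2 * pool_halfwidth + 1`
#' neighbouring channels: the true sampling variance varies smoothly
#' with channel, and pooling stabilises the variance estimate where the
#' per-channel deposit weights are heavy-tailed.
#'
#' @param setup an [acquisition_setup()] with a phantom
#' @param pool_halfwidth half-width of the variance-pooling window
#' @param ... passed to [simulate_scatter_deterministic()]
#' @return list with per-channel `z`, the `fraction_within_3se`, and the
#'   two per-channel profiles (`mc`, `oracle`)
#' @export
mc_oracle_agreement <- function(setup, pool_halfwidth = 8, ...) {
  mc <- simulate_scatter_mc(setup)
  det <- simulate_scatter_deterministic(setup, ...)
  mm <- mc$channel_total
  dm <- colSums(det)
  se2 <- mc$channel_se^2
  n <- length(se2)
  pooled <- vapply(seq_len(n), function(i)
    mean(se2[max(1, i - pool_halfwidth):min(n, i + pool_halfwidth)]),
    numeric(1))
  z <- (mm - dm) / sqrt(pooled)
  list(z = z, fraction_within_3se = mean(abs(z) <= 3), mc = mm, oracle = dm)
}

.poissonize <- function(readings, mean_e, seed) {
  with_local_seed(seed, {
    counts <- readings / mean_e
    matrix(rpois(length(counts), counts), nrow(readings)) * mean_e
  })
}

#' Render a two-exposure acquisition pair
#'
#' Writes the method's two raw frames - (1) blocker only, (2) blocker
#' plus phantom - each equal to primary plus scatter (plus optional
#' Poisson noise) passed through the calibration, together with a
#' plain-text ground-truth sidecar holding the uncalibrated pre-noise
#' primary and scatter matrices of the with-phantom exposure and the
#' setup echoed in the header.
#'
#' @param setup an [acquisition_setup()] with both blocker and phantom
#' @param calibration a [calibration_table()], or NULL for identity (the
#'   frames are then written uncalibrated)
#' @param out_dir output directory (created if missing)
#' @param basename file-name stem; writes `<stem>_with.ctraw`,
#'   `<stem>_without.ctraw`, `<stem>_truth.txt`
#' @param scatter_model `"mc"` (Monte Carlo, the default) or
#'   `"deterministic"` (quadrature; noise-free scatter)
#' @param ... passed to [simulate_scatter_deterministic()] when
#'   `scatter_model = "deterministic"`
#' @return named list of the three file paths, invisibly
#' @export
render_acquisition_pair <- function(setup, calibration = NULL, out_dir,
                                    basename = "acq",
                                    scatter_model = c("mc", "deterministic"),
                                    ...) {
  stopifnot(inherits(setup, "acquisition_setup"))
  scatter_model <- match.arg(scatter_model)
  if (is.null(setup$blocker))
    stop("both exposures of a pair require the blocker")
  if (is.null(setup$phantom))
    stop("the with-phantom exposure requires a phantom")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- setup$geometry

  setup_wo <- setup; setup_wo$phantom <- NULL
  prim_wo <- simulate_primary(setup_wo)
  scat_wo <- matrix(0, g$n_rows, g$n_channels_total)

  prim_w <- simulate_primary(setup)
  if (scatter_model == "mc") {
    mc <- simulate_scatter_mc(setup)
    scat_w <- mc$scatter; se_w <- mc$se
  } else {
    scat_w <- simulate_scatter_deterministic(setup, ...)
    se_w <- matrix(0, g$n_rows, g$n_channels_total)
  }

  total_wo <- prim_wo + scat_wo
  total_w <- prim_w + scat_w
  if (setup$noise == "poisson") {
    me <- mean_energy(setup$spectrum)
    total_wo <- .poissonize(total_wo, me, setup$seed + 1L)
    total_w <- .poissonize(total_w, me, setup$seed + 2L)
  }

  mkframe <- function(readings, phantom_present) {
    f <- detector_frame(readings, kvp = setup$spectrum$kvp,
                        tube_current = setup$tube_current,
                        exposure_s = setup$exposure_s,
                        phantom_present = phantom_present,
                        blocker_present = TRUE, seed = setup$seed)
    if (!is.null(calibration)) f <- calibrate(f, calibration)
    f
  }
  compression <- if (is.null(calibration)) "none" else calibration$compression
  p_with <- file.path(out_dir, paste0(basename, "_with.ctraw"))
  p_without <- file.path(out_dir, paste0(basename, "_without.ctraw"))
  p_truth <- file.path(out_dir, paste0(basename, "_truth.txt"))
  write_frame(mkframe(total_w, TRUE), p_with, compression)
  write_frame(mkframe(total_wo, FALSE), p_without, compression)
  write_ground_truth(p_truth, setup, prim_w, scat_w, se_w, scatter_model)
  invisible(list(with_phantom = p_with, without_phantom = p_without,
                 truth = p_truth))
}

# ground-truth sidecar: '#' header echoing the setup, then named blocks
# of row-major numbers, one detector row per line
write_ground_truth <- function(path, setup, primary, scatter, scatter_se,
                               scatter_model) {
  ph <- setup$phantom
  hdr <- c(
    "# ctscatter ground-truth sidecar",
    sprintf("# n_rows: %d", nrow(primary)),
    sprintf("# n_channels: %d", ncol(primary)),
    sprintf("# kvp: %g", setup$spectrum$kvp),
    sprintf("# tube_current_ma: %g", setup$tube_current),
    sprintf("# exposure_s: %g", setup$exposure_s),
    sprintf("# n_photons: %g", setup$n_photons),
    sprintf("# seed: %d", setup$seed),
    sprintf("# noise: %s", setup$noise),
    sprintf("# scatter_model: %s", scatter_model),
    sprintf("# phantom: %s %g mm wall %g mm %s offset %g mm",
            ph$fill_material, ph$fill_diameter, ph$wall_thickness,
            if (is.null(ph$wall_material)) "none" else ph$wall_material,
            ph$axial_offset),
    sprintf("# blocker_bars: %d", setup$blocker$n_bars))
  block <- function(m) apply(m, 1, function(r) paste(sprintf("%.10g", r),
                                                     collapse = " "))
  writeLines(c(hdr, "primary", block(primary), "scatter", block(scatter),
               "scatter_se", block(scatter_se)), path)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path file written by [render_acquisition_pair()]
#' @return list with `primary`, `scatter`, `scatter_se` matrices and the
#'   header `meta` lines
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1]))
  }
  nr <- get("n_rows"); nc <- get("n_channels")
  body <- lines[!grepl("^#", lines)]
  read_block <- function(name) {
    i <- which(body == name)
    if (length(i) != 1) stop("missing block '", name, "' in ", path)
    rows <- body[(i + 1):(i + nr)]
    do.call(rbind, lapply(strsplit(rows, " +"), as.numeric))
  }
  list(primary = read_block("primary"), scatter = read_block("scatter"),
       scatter_se = read_block("scatter_se"), meta = meta)
}

#' Generate the full study's fixtures
#'
#' Enumerates the study conditions - {80, 100, 120, 140} kVp for the
#' 215 mm water phantom at 100 mA and the 300 mm polypropylene phantom at
#' 200 mA, plus an axial off-centring sweep {-100, -50, 0, +50, +100} mm
#' at 120 kVp / 100 mA - renders each two-exposure pair, and writes a
#' manifest listing every acquisition with its settings (26 frames in 13
#' pairs for the defaults).
#'
#' @param out_dir output directory
#' @param seed seed shared by every acquisition of the study: the arms
#'   of the kVp / phantom / off-centring comparisons use common random
#'   numbers, so between-arm differences are estimated with far less
#'   Monte Carlo variance than independent streams would give
#'   (a paired design; each arm remains an unbiased simulation)
#' @param n_photons Monte Carlo budget per acquisition
#' @param kvps tube voltages for the kVp sweeps
#' @param offsets signed axial offsets, mm, for the off-centring sweep
#' @param exposure_s exposure time, s
#' @param noise `"off"` or `"poisson"`
#' @param calibration optional [calibration_table()]
#' @param scatter_model `"mc"` or `"deterministic"`
#' @return the manifest data frame, invisibly; also written to
#'   `manifest.tsv` in `out_dir`
#' @export
make_study_fixtures <- function(out_dir, seed = 1, n_photons = 1e6,
                                kvps = c(80, 100, 120, 140),
                                offsets = c(-100, -50, 0, 50, 100),
                                exposure_s = 3, noise = "off",
                                calibration = NULL,
                                scatter_model = "mc") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- scanner_geometry()
  blocker <- default_blocker_array(geom)
  runs <- rbind(
    data.frame(phantom = "water215", kvp = kvps, ma = 100, offset = 0),
    data.frame(phantom = "poly300", kvp = kvps, ma = 200, offset = 0),
    data.frame(phantom = "water215", kvp = 120, ma = 100, offset = offsets))
  manifest <- NULL
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    id <- sprintf("%s_%03dkvp_off%+04d", r$phantom, r$kvp, r$offset)
    setup <- acquisition_setup(
      geom, standard_phantom(r$phantom, axial_offset = r$offset), blocker,
      xray_spectrum(r$kvp), tube_current = r$ma, exposure_s = exposure_s,
      n_photons = n_photons, seed = seed, noise = noise)
    paths <- render_acquisition_pair(setup, calibration, out_dir, id,
                                     scatter_model = scatter_model)
    manifest <- rbind(manifest, data.frame(
      id = id, phantom = r$phantom, kvp = r$kvp, ma = r$ma,
      exposure_s = exposure_s, offset_mm = r$offset,
      n_photons = n_photons, seed = seed,
      with_file = basename(paths$with_phantom),
      without_file = basename(paths$without_phantom),
      truth_file = basename(paths$truth)))
  }
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
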