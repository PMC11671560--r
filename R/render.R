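# Synthetic CLE frame rendering.
#
# Image formation: a noiseless expected-intensity field is assembled from the
# filter-dependent background, an optional diffuse low-spatial-frequency
# component with negative-contrast silhouettes, and additively stamped
# objects; detector noise (gain-scaled Poisson + Gaussian read noise) is then
# sampled in one pass and the frame quantized to 16-bit.
#
# Conventions: 0-based, row-major, pixel-center coordinates; positions are
# stored in micrometers and converted through pixel_size_um, so the pixel at
# matrix index [r, c] has centre ((r-1)*psz, (c-1)*psz) um as (y, x).
#
# RNG: one root seed; per-class substreams (see stream_seed) so that adding
# one object class leaves every other class's draws untouched, and the
# BP/LP noise streams are independent while geometry is shared.

um_to_px <- function(um, psz) um / psz + 1    # 1-based fractional index
px_to_um <- function(px, psz) (px - 1) * psz

# Add `patch` onto S centred at fractional (r0, c0); clips at borders.
stamp_add <- function(S, patch, r0, c0) {
  pr <- nrow(patch); pc <- ncol(patch)
  r1 <- round(r0) - (pr - 1L) %/% 2L
  c1 <- round(c0) - (pc - 1L) %/% 2L
  rr <- max(1L, r1):min(nrow(S), r1 + pr - 1L)
  cc <- max(1L, c1):min(ncol(S), c1 + pc - 1L)
  if (!length(rr) || !length(cc)) return(S)
  S[rr, cc] <- S[rr, cc] + patch[rr - r1 + 1L, cc - c1 + 1L]
  S
}

# Radial distance grid (px) of an odd-sized patch around fractional centre.
patch_radius_grid <- function(half, r_frac, c_frac) {
  idx <- -half:half
  dr <- idx - r_frac
  dc <- idx - c_frac
  sqrt(outer(dr^2, dc^2, `+`))
}

soft_disk <- function(rad, R, edge = 1) 1 / (1 + exp((rad - R) / edge))

gaussian_spot_patch <- function(amp, sigma, r_frac, c_frac) {
  half <- ceiling(3.5 * sigma) + 1L
  rad <- patch_radius_grid(half, r_frac, c_frac)
  amp * exp(-rad^2 / (2 * sigma^2))
}

# Separable small-kernel blur used for cytoplasm texture inside a patch.
patch_blur <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2)); k <- k / sum(k)
  n1 <- nrow(x); n2 <- ncol(x)
  K1 <- matrix(0, n1, n1); K2 <- matrix(0, n2, n2)
  for (o in -half:half) {
    i <- seq_len(n1); j <- pmin(pmax(i + o, 1L), n1)
    K1[cbind(i, j)] <- K1[cbind(i, j)] + k[o + half + 1]
    i2 <- seq_len(n2); j2 <- pmin(pmax(i2 + o, 1L), n2)
    K2[cbind(i2, j2)] <- K2[cbind(i2, j2)] + k[o + half + 1]
  }
  K1 %*% x %*% t(K2)
}

# Cell with fluorescent cytoplasm: soft-edged disk (half-amplitude crossing
# exactly at the annotated radius), darker nucleus, granular multiplicative
# texture confined to the cytoplasm.
cell_patch <- function(amp, R, r_frac, c_frac, granularity = 0.35,
                       nucleus_depth = 0.65, texture_sigma_px = 3) {
  half <- ceiling(R + 6)
  rad <- patch_radius_grid(half, r_frac, c_frac)
  body <- soft_disk(rad, R, edge = 0.8)
  nucleus <- soft_disk(rad, 0.42 * R, edge = 0.8)
  base <- body * (1 - nucleus_depth * nucleus)
  tex <- patch_blur(matrix(rnorm((2 * half + 1)^2), 2 * half + 1), texture_sigma_px)
  tex <- tex / max(sd(tex), 1e-9)
  tex <- pmin(pmax(tex, -2), 2)
  inner <- soft_disk(rad, R - 2, edge = 0.6)   # keep granules off the rim
  amp * base * (1 + granularity * tex * inner)
}

round_patch <- function(amp, R, r_frac, c_frac) {
  half <- ceiling(R + 6)
  rad <- patch_radius_grid(half, r_frac, c_frac)
  amp * soft_disk(rad, R, edge = 1.2)
}

# Smoothed random-walk polyline of a given arc length; returns n x 2 matrix
# of (row, col) px positions at ~1 px spacing.
fiber_path <- function(length_px, curvature_sd = 0.035) {
  n <- max(2L, ceiling(length_px))
  th <- runif(1, 0, 2 * pi) + cumsum(c(0, rnorm(n - 1, 0, curvature_sd)))
  cbind(cumsum(c(0, sin(th[-1]))), cumsum(c(0, cos(th[-1]))))
}

# Render a curvilinear structure with Gaussian cross-section of FWHM
# width_px along `path` into a bounding-box canvas. Returns a patch plus its
# centre so it can be applied like any other stamp. Amplitude = ridge height.
curve_patch <- function(path, amp, width_px) {
  sw <- width_px / 2.3548
  half <- ceiling(3 * sw) + 1L
  idx <- -half:half
  stamp <- exp(-outer(idx^2, idx^2, `+`) / (2 * sw^2)) * amp / (sqrt(2 * pi) * sw)
  pr <- 2L * half + 1L
  r_min <- floor(min(path[, 1])) - half - 1L
  c_min <- floor(min(path[, 2])) - half - 1L
  canvas <- matrix(0, ceiling(max(path[, 1])) - r_min + half + 2L,
                   ceiling(max(path[, 2])) - c_min + half + 2L)
  for (i in seq_len(nrow(path))) {
    r1 <- round(path[i, 1]) - r_min - half
    c1 <- round(path[i, 2]) - c_min - half
    canvas[r1:(r1 + pr - 1L), c1:(c1 + pr - 1L)] <-
      canvas[r1:(r1 + pr - 1L), c1:(c1 + pr - 1L)] + stamp
  }
  list(patch = canvas,
       r0 = r_min + (nrow(canvas) - 1) / 2,
       c0 = c_min + (ncol(canvas) - 1) / 2)
}

new_truth_row <- function(class, y_um, x_um, diameter_um = NA_real_,
                          length_um = NA_real_, width_um = NA_real_,
                          peak = NA_real_) {
  data.frame(class = class, x_um = x_um, y_um = y_um,
             equivalent_diameter_um = diameter_um,
             length_um = length_um, width_um = width_um, peak = peak,
             stringsAsFactors = FALSE)
}

empty_truth_objects <- function() {
  new_truth_row(character(0), numeric(0), numeric(0), numeric(0),
                numeric(0), numeric(0), numeric(0))[0, ]
}

# Rejection-sample a centre at least `margin` px from the border and
# respecting minimum distances to previously placed objects.
sample_center <- function(margin, placed, min_dist, max_retry = 1000L) {
  geom <- cle_geometry()
  for (i in seq_len(max_retry)) {
    r <- runif(1, 1 + margin, geom$nrow - margin)
    c <- runif(1, 1 + margin, geom$ncol - margin)
    ok <- TRUE
    if (nrow(placed)) {
      d <- sqrt((placed$r - r)^2 + (placed$c - c)^2)
      ok <- all(d >= pmax(min_dist, placed$keepout))
    }
    if (ok) return(c(r, c))
  }
  stop("packing error: could not place object after ", max_retry, " retries")
}

# Build the noiseless signal field and ground truth for one scene.
# Runs inside the geometry RNG stream.
place_objects <- function(spec, seed = spec$seed) {
  geom <- cle_geometry()
  psz <- geom$pixel_size_um
  sigma_bp <- background_sigma(spec, "BP")
  amp <- spec$object_contrast * sigma_bp
  truth <- empty_truth_objects()
  patches <- list()   # applied to S in one owned pass at the end
  add_patch <- function(patch, r0, c0) {
    patches[[length(patches) + 1L]] <<- list(p = patch, r0 = r0, c0 = c0)
  }
  # placed: centres + keepout radii (px) that later objects must respect
  placed <- data.frame(r = numeric(0), c = numeric(0), keepout = numeric(0))
  add_placed <- function(r, c, keepout) {
    placed[nrow(placed) + 1L, ] <<- c(r, c, keepout)
  }

  draw_disklike <- function(n, d_range, class, stamp_fun, amplitude, stream) {
    with_stream(seed, stream, {
      for (i in seq_len(n)) {
        d_um <- runif(1, d_range[1], d_range[2])
        R <- d_um / psz / 2
        ctr <- sample_center(R + 3, placed, min_dist = R + 3)
        add_patch(stamp_fun(amplitude, R, ctr[1] - round(ctr[1]), ctr[2] - round(ctr[2])),
                  ctr[1], ctr[2])
        add_placed(ctr[1], ctr[2], R + 3)
        truth[nrow(truth) + 1L, ] <<- new_truth_row(
          class, px_to_um(ctr[1], psz), px_to_um(ctr[2], psz),
          diameter_um = d_um, peak = amplitude)
      }
    })
    invisible(NULL)
  }

  # big structures first so later small objects sample around them
  draw_disklike(spec$n_round, spec$round_diameter_um, "round", round_patch,
                spec$round_contrast_frac * amp, "round")
  draw_disklike(spec$n_large_cells, spec$large_cell_diameter_um, "large_cell",
                cell_patch, amp, "large_cells")
  draw_disklike(spec$n_small_cells, spec$small_cell_diameter_um, "small_cell",
                cell_patch, amp, "small_cells")

  round_idx <- truth$class == "round"
  round_r <- um_to_px(truth$y_um[round_idx], psz)
  round_c <- um_to_px(truth$x_um[round_idx], psz)
  round_rad <- truth$equivalent_diameter_um[round_idx] / psz / 2

  with_stream(seed, "fibers", {
    for (i in seq_len(spec$n_fibers)) {
      L_um <- runif(1, spec$fiber_length_um[1], spec$fiber_length_um[2])
      w_um <- runif(1, spec$fiber_width_um[1], spec$fiber_width_um[2])
      L_px <- L_um / psz; w_px <- w_um / psz
      ok <- FALSE
      for (try in seq_len(1000L)) {
        path <- fiber_path(L_px)
        # place the path bounding box fully inside the frame
        rng_r <- range(path[, 1]); rng_c <- range(path[, 2])
        if (diff(rng_r) > geom$nrow - 20 || diff(rng_c) > geom$ncol - 20) next
        off_r <- runif(1, 10 - rng_r[1], geom$nrow - 10 - rng_r[2])
        off_c <- runif(1, 10 - rng_c[1], geom$ncol - 10 - rng_c[2])
        path_abs <- cbind(path[, 1] + off_r, path[, 2] + off_c)
        # fibers must not cross round structures
        clash <- FALSE
        if (length(round_r)) {
          sub <- path_abs[seq(1, nrow(path_abs), by = 4), , drop = FALSE]
          for (k in seq_along(round_r)) {
            dmin <- min(sqrt((sub[, 1] - round_r[k])^2 + (sub[, 2] - round_c[k])^2))
            if (dmin < round_rad[k] + w_px) { clash <- TRUE; break }
          }
        }
        if (clash) next
        cp <- curve_patch(path_abs, amp, w_px)
        add_patch(cp$patch, cp$r0, cp$c0)
        ctr <- colMeans(path_abs)
        truth[nrow(truth) + 1L, ] <- new_truth_row(
          "fiber", px_to_um(ctr[1], psz), px_to_um(ctr[2], psz),
          length_um = L_um, width_um = w_um, peak = amp)
        ok <- TRUE
        break
      }
      if (!ok) stop("packing error: could not place fiber after 1000 retries")
    }
  })

  with_stream(seed, "spots", {
    for (i in seq_len(spec$n_spots)) {
      d_um <- runif(1, spec$spot_diameter_um[1], spec$spot_diameter_um[2])
      sigma <- d_um / psz / 2.3548
      R <- d_um / psz / 2
      ctr <- sample_center(R + 2, placed, min_dist = 4 * R)
      add_patch(gaussian_spot_patch(amp, sigma, ctr[1] - round(ctr[1]), ctr[2] - round(ctr[2])),
                ctr[1], ctr[2])
      add_placed(ctr[1], ctr[2], 4 * R)
      truth[nrow(truth) + 1L, ] <- new_truth_row(
        "spot", px_to_um(ctr[1], psz), px_to_um(ctr[2], psz),
        diameter_um = d_um, peak = amp)
    }
  })

  with_stream(seed, "vessels", {
    for (i in seq_len(spec$n_vessels)) {
      L_px <- runif(1, 200, 500)
      w_px <- runif(1, 8, 20) / psz   # 8-20 um wide
      path <- fiber_path(L_px, curvature_sd = 0.01)
      rng_r <- range(path[, 1]); rng_c <- range(path[, 2])
      off_r <- runif(1, 10 - rng_r[1], geom$nrow - 10 - rng_r[2])
      off_c <- runif(1, 10 - rng_c[1], geom$ncol - 10 - rng_c[2])
      path_abs <- cbind(path[, 1] + off_r, path[, 2] + off_c)
      cp <- curve_patch(path_abs, -0.4 * amp, w_px)
      add_patch(cp$patch, cp$r0, cp$c0)
      ctr <- colMeans(path_abs)
      truth[nrow(truth) + 1L, ] <- new_truth_row(
        "vessel", px_to_um(ctr[1], psz), px_to_um(ctr[2], psz),
        length_um = L_px * psz, width_um = w_px * psz, peak = -0.4 * amp)
    }
  })

  # single owned pass: no copy-on-write of the 2-Mpx frame per object
  S <- matrix(0, geom$nrow, geom$ncol)
  for (pt in patches) {
    pr <- nrow(pt$p); pc <- ncol(pt$p)
    r1 <- round(pt$r0) - (pr - 1L) %/% 2L
    c1 <- round(pt$c0) - (pc - 1L) %/% 2L
    rr <- max(1L, r1):min(geom$nrow, r1 + pr - 1L)
    cc <- max(1L, c1):min(geom$ncol, c1 + pc - 1L)
    if (!length(rr) || !length(cc)) next
    S[rr, cc] <- S[rr, cc] + pt$p[rr - r1 + 1L, cc - c1 + 1L]
  }

  D <- NULL
  if (spec$diffuse_level > 0) {
    D <- with_stream(seed, "diffuse", diffuse_field(spec$diffuse_level, geom))
  }

  list(objects = truth, signal = S, diffuse = D,
       diffuse_flag = spec$diffuse_level > 0)
}

# Diffuse autofluorescence: a gently modulated plateau with a few
# negative-contrast round silhouettes, built on a coarse grid and
# bilinearly upsampled.
diffuse_field <- function(level, geom, mod_amp = 0.15, n_disks = 4,
                          disk_depth = 0.35) {
  cg_r <- 68L; cg_c <- 120L
  F <- patch_blur(matrix(rnorm(cg_r * cg_c), cg_r, cg_c), 5)
  F <- F / max(sd(F), 1e-9)
  F <- pmin(pmax(F, -2), 2)
  up <- function(n_to, n_from) {
    # interpolation matrix mapping coarse grid -> frame rows/cols
    pos <- seq(1, n_from, length.out = n_to)
    lo <- pmin(floor(pos), n_from - 1L)
    w <- pos - lo
    M <- matrix(0, n_to, n_from)
    M[cbind(seq_len(n_to), lo)] <- 1 - w
    M[cbind(seq_len(n_to), lo + 1L)] <- w
    M
  }
  D <- level * (1 + mod_amp * (up(geom$nrow, cg_r) %*% F %*% t(up(geom$ncol, cg_c))))
  for (i in seq_len(n_disks)) {
    R <- runif(1, 10, 25) / cle_geometry()$pixel_size_um / 2
    r0 <- runif(1, R, geom$nrow - R); c0 <- runif(1, R, geom$ncol - R)
    half <- ceiling(R + 6)
    rad <- patch_radius_grid(half, r0 - round(r0), c0 - round(c0))
    D <- stamp_add(D, -disk_depth * level * soft_disk(rad, R, 1.5), r0, c0)
  }
  pmax(D, 0)
}

#' Render one synthetic CLE frame with ground truth
#'
#' @param spec a [scene_spec()].
#' @param filter `"BP"` or `"LP"`; LP adds `lp_background_offset` to the
#'   background before noise.
#' @param seed root seed; geometry derives from it independently of `filter`,
#'   noise from (seed, filter), so the same seed with different filters gives
#'   identical object placement with independent noise.
#' @param noiseless render the expected-intensity field only (no shot or
#'   read noise); used for geometry checks and profile oracles.
#' @param case_id,image_id,acquisition,acq_index frame metadata; `image_id`
#'   defaults to `scene<seed>_<filter>`.
#' @return A list with elements `image` (a `cle_field_image`) and `truth`
#'   (list: `objects` data frame with per-object class, centroid (um),
#'   equivalent diameter or length/width, peak amplitude; `diffuse` flag;
#'   `artifact`; `seed`).
#' @export
render_scene <- function(spec, filter = c("BP", "LP"), seed = spec$seed,
                         noiseless = FALSE, case_id = "case1",
                         image_id = NULL,
                         acquisition = c("ex_vivo", "in_situ"),
                         acq_index = 1L) {
  filter <- match.arg(filter)
  acquisition <- match.arg(acquisition)
  validate_scene_spec(spec)
  geom <- cle_geometry()
  scene <- place_objects(spec, seed)
  bg <- spec$bp_background +
    if (filter == "LP") spec$lp_background_offset else 0
  px <- with_stream(seed, paste0("noise_", filter),
    .render_frame_cpp(scene$signal, scene$diffuse, bg,
                      spec$noise$poisson_scale, spec$noise$read_sigma,
                      noiseless))
  if (!is.na(spec$autobrightness_target)) {
    m <- mean(px)
    if (m > 0) {
      px <- matrix(.quantize_u16_cpp(as.numeric(px) *
                                       (spec$autobrightness_target / m)),
                   geom$nrow, geom$ncol)
    }
  }
  if (is.null(image_id)) image_id <- sprintf("scene%d_%s", seed, filter)
  img <- field_image(px, filter = filter, case_id = case_id,
                     image_id = image_id, acquisition = acquisition,
                     acq_index = acq_index,
                     meta = list(bg_level = bg,
                                 poisson_scale = spec$noise$poisson_scale,
                                 read_sigma = spec$noise$read_sigma,
                                 noiseless = noiseless,
                                 sigma_bg = background_sigma(spec, filter)))
  truth <- list(objects = scene$objects, diffuse = scene$diffuse_flag,
                artifact = "none", seed = as.integer(seed))
  list(image = img, truth = truth)
}

#' Render a matched BP/LP pair of the same field of view
#'
#' Both frames share identical object placement and diffuse field; only the
#' background level (LP adds `lp_background_offset`) and the independent
#' noise realizations differ. Object amplitudes are identical in both frames
#' (referenced to the BP background noise).
#'
#' @inheritParams render_scene
#' @return A list with elements `bp`, `lp` (each as from [render_scene()]).
#' @export
render_pair <- function(spec, seed = spec$seed, case_id = "case1",
                        acquisition = c("ex_vivo", "in_situ")) {
  acquisition <- match.arg(acquisition)
  list(bp = render_scene(spec, "BP", seed, case_id = case_id,
                         acquisition = acquisition, acq_index = 1L),
       lp = render_scene(spec, "LP", seed, case_id = case_id,
                         acquisition = acquisition, acq_index = 2L))
}

#' Inject an acquisition artifact into a rendered frame
#'
#' Artifact classes mirror those that lead to exclusion during in situ CLE:
#' `"motion"` (directional smear from probe movement: line-kernel
#' convolution plus fresh read noise), `"blank"` (no discernible signal:
#' background plus noise only), and `"duplicate"` (a re-acquisition of the
#' same field of view: small shift with fresh noise).
#'
#' @param scene a list with `image` and `truth` as returned by
#'   [render_scene()] (the truth is updated so artifact labels stay aligned).
#' @param kind `"motion"`, `"blank"` or `"duplicate"`.
#' @param strength motion: smear length in px (> 0); duplicate: maximum
#'   shift in px; ignored for blank.
#' @param seed seed for the artifact's randomness (smear direction, shift,
#'   fresh noise).
#' @param image_id id for the artifact frame (default `<id>_<kind>`).
#' @return A list with `image` and `truth` like [render_scene()].
#' @export
inject_artifact <- function(scene, kind = c("motion", "blank", "duplicate"),
                            strength = 50, seed = 1L, image_id = NULL) {
  if (!kind[1] %in% c("motion", "blank", "duplicate"))
    stop("unknown artifact kind: ", kind[1])
  kind <- match.arg(kind)
  img <- scene$image
  stopifnot(inherits(img, "cle_field_image"))
  meta <- img$meta
  read_sigma <- meta$read_sigma %||% robust_stats(img$pixels)$sigma / 2
  ps <- meta$poisson_scale %||% 0
  bg <- meta$bg_level %||% robust_stats(img$pixels)$median
  d1 <- nrow(img$pixels); d2 <- ncol(img$pixels)
  if (is.null(image_id)) image_id <- paste0(img$image_id, "_", kind)
  truth <- scene$truth

  if (kind == "blank") {
    vals <- with_stream(seed, "blank_noise",
      .add_noise_cpp(rep(as.numeric(bg), d1 * d2), ps, read_sigma))
    px <- matrix(.quantize_u16_cpp(vals), d1, d2)
    truth$objects <- empty_truth_objects()
    truth$diffuse <- FALSE
    truth$artifact <- "blank"
  } else if (kind == "motion") {
    if (strength <= 0) stop("motion strength (smear length, px) must be > 0")
    res <- with_stream(seed, "motion", {
      theta <- sample(seq(0, 165, by = 15), 1) * pi / 180
      sm <- fft_filter(matrix(as.numeric(img$pixels), d1, d2),
                       otf_line(d1, d2, strength, theta))
      sm + rnorm(d1 * d2, 0, read_sigma)
    })
    px <- matrix(.quantize_u16_cpp(as.numeric(res)), d1, d2)
    truth$artifact <- "motion"
  } else { # duplicate
    res <- with_stream(seed, "duplicate", {
      ang <- runif(1, 0, 2 * pi)
      mag <- runif(1, 0.3, 1) * strength
      dr <- mag * sin(ang); dc <- mag * cos(ang)
      bilinear_shift(matrix(as.numeric(img$pixels), d1, d2), dr, dc) +
        rnorm(d1 * d2, 0, read_sigma)
    })
    px <- matrix(.quantize_u16_cpp(as.numeric(res)), d1, d2)
    truth$artifact <- paste0("duplicate_of:", img$image_id)
  }
  img$pixels <- px
  img$image_id <- image_id
  list(image = img, truth = truth)
}

# OTF of a normalized line kernel (motion smear) of given length/angle.
otf_line <- function(d1, d2, length_px, theta) {
  key <- sprintf("line_%d_%d_%g_%.4f", d1, d2, length_px, theta)
  if (!is.null(.otf_cache[[key]])) return(.otf_cache[[key]])
  n <- max(2L, ceiling(length_px))
  t <- seq(-(length_px - 1) / 2, (length_px - 1) / 2, length.out = n)
  rr <- round(t * sin(theta)); cc <- round(t * cos(theta))
  K <- matrix(0, d1, d2)
  ri <- ((rr %% d1) + d1) %% d1 + 1L
  ci <- ((cc %% d2) + d2) %% d2 + 1L
  for (i in seq_len(n)) K[ri[i], ci[i]] <- K[ri[i], ci[i]] + 1
  K <- K / sum(K)
  otf_cache_put(key, stats::fft(K))
}

# Sub-pixel translation by (dr, dc) with edge replication.
bilinear_shift <- function(x, dr, dc) {
  ir <- floor(dr); fr <- dr - ir
  ic <- floor(dc); fc <- dc - ic
  (1 - fr) * (1 - fc) * shift_matrix(x, ir, ic) +
    (1 - fr) * fc * shift_matrix(x, ir, ic + 1) +
    fr * (1 - fc) * shift_matrix(x, ir + 1, ic) +
    fr * fc * shift_matrix(x, ir + 1, ic + 1)
}
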