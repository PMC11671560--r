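# The nine-feature classification layer and the per-frame orchestrator.
#
# The nine autofluorescence features and their count thresholds:
#   (1) sparse punctuate  — 1-3 um signals, 1-49 per field of view
#   (2) dense punctuate   — 1-3 um signals, >= 50 per field of view
#   (3) sparse small cells — fluorescent cytoplasm, < 25 um, 1-4 per FOV
#   (4) dense small cells  — >= 5 per FOV, < 25 um
#   (5) sparse large cells — >= 25 um, 1-4 per FOV
#   (6) dense large cells  — >= 25 um, >= 5 per FOV
#   (7) diffuse autofluorescence
#   (8) fibers
#   (9) round homogeneous structures
# Several features may be present in the same frame. A sparse flag requires
# at least one detection: an empty frame shows the feature as absent, not
# sparse.

#' Names of the nine autofluorescence feature flags
#' @return Character vector of the nine flag names in canonical order.
#' @export
feature_names <- function() {
  c("sparse_punctuate", "dense_punctuate",
    "sparse_small_cells", "dense_small_cells",
    "sparse_large_cells", "dense_large_cells",
    "diffuse", "fibers", "round_structures")
}

#' Classify detections into the nine-feature vector
#'
#' Pure function of the per-class counts and the diffuse result: spots
#' 1-49 sparse / >= 50 dense; small and large cells 1-4 sparse / >= 5
#' dense; fibers and round structures flag on at least one detection;
#' diffuse passes through.
#'
#' @param detections detections data frame (any subset of classes), or a
#'   named list/vector of counts (`n_spots`, `n_small_cells`,
#'   `n_large_cells`, `n_fibers`, `n_round`).
#' @param diffuse_result list from [detect_diffuse()], a logical scalar, or
#'   `NULL` (treated as absent).
#' @return A `cle_feature_vector`: list with `counts` (named integer
#'   vector), `diffuse_coverage`, and `flags` (named logical vector over
#'   [feature_names()]).
#' @export
classify_features <- function(detections, diffuse_result = NULL) {
  if (is.data.frame(detections)) {
    cnt <- function(cl) sum(detections$class == cl)
    counts <- c(n_spots = cnt("spot"), n_small_cells = cnt("small_cell"),
                n_large_cells = cnt("large_cell"), n_fibers = cnt("fiber"),
                n_round = cnt("round"))
  } else {
    counts <- c(n_spots = 0L, n_small_cells = 0L, n_large_cells = 0L,
                n_fibers = 0L, n_round = 0L)
    counts[names(detections)] <- unlist(detections)
  }
  counts <- vapply(counts, as.integer, integer(1))
  if (is.null(diffuse_result)) diffuse_result <- list(flag = FALSE, coverage = 0)
  if (is.logical(diffuse_result)) {
    diffuse_result <- list(flag = diffuse_result, coverage = NA_real_)
  }
  sparse_dense <- function(n, dense_at) {
    c(sparse = n >= 1 && n < dense_at, dense = n >= dense_at)
  }
  sp <- sparse_dense(counts[["n_spots"]], 50)
  sc <- sparse_dense(counts[["n_small_cells"]], 5)
  lc <- sparse_dense(counts[["n_large_cells"]], 5)
  flags <- c(sparse_punctuate = sp[["sparse"]], dense_punctuate = sp[["dense"]],
             sparse_small_cells = sc[["sparse"]], dense_small_cells = sc[["dense"]],
             sparse_large_cells = lc[["sparse"]], dense_large_cells = lc[["dense"]],
             diffuse = isTRUE(diffuse_result$flag),
             fibers = counts[["n_fibers"]] >= 1,
             round_structures = counts[["n_round"]] >= 1)
  structure(list(counts = counts,
                 diffuse_coverage = diffuse_result$coverage,
                 flags = flags[feature_names()]),
            class = "cle_feature_vector")
}

#' @export
print.cle_feature_vector <- function(x, ...) {
  cat("<cle_feature_vector> counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  on <- names(x$flags)[x$flags]
  cat("  flags:", if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# Disk mask accumulator used for the diffuse residual: marks pixels within
# radius_px of each centre.
accumulate_disks <- function(mask, r_px, c_px, radius_px) {
  d1 <- nrow(mask); d2 <- ncol(mask)
  for (i in seq_along(r_px)) {
    rad <- radius_px[i]
    rlo <- max(1, floor(r_px[i] - rad)); rhi <- min(d1, ceiling(r_px[i] + rad))
    clo <- max(1, floor(c_px[i] - rad)); chi <- min(d2, ceiling(c_px[i] + rad))
    if (rlo > rhi || clo > chi) next
    rr <- rlo:rhi; cc <- clo:chi
    sub <- outer((rr - r_px[i])^2, (cc - c_px[i])^2, `+`) <= rad^2
    mask[rr, cc] <- mask[rr, cc] | sub
  }
  mask
}

#' Detect and classify all nine features in one frame
#'
#' Runs the four object detectors, resolves cross-class conflicts so no
#' detection is counted twice (punctuate detections on fiber skeletons,
#' inside cells or inside round structures are suppressed; tiny cell
#' components that are actually merged spot pairs are dropped), builds the
#' object mask, evaluates the diffuse criterion on the masked residual, and
#' applies the classification thresholds.
#'
#' @param image a `cle_field_image` (should have passed QC).
#' @param params a [detect_config()].
#' @return List with `detections` (combined data frame), `feature_vector`
#'   (a `cle_feature_vector`) and `diffuse` (the [detect_diffuse()] result).
#' @export
detect_features <- function(image, params = detect_config()) {
  psz <- image$pixel_size_um
  rs <- robust_stats(image$pixels)
  ctx <- list(rs = rs,
              x = matrix(as.numeric(image$pixels) - rs$median,
                         nrow(image$pixels), ncol(image$pixels)))
  spots <- detect_spots(image, params, .ctx = ctx)
  cells <- detect_cells(image, params, .ctx = ctx)
  fibers <- detect_fibers(image, params, .ctx = ctx)
  rounds <- detect_round(image, params, .ctx = ctx)
  skels <- attr(fibers, "skeletons")

  # small blob candidates riding on a fiber ridge are not round structures
  if (nrow(rounds) && length(skels)) {
    drop <- logical(nrow(rounds))
    for (i in seq_len(nrow(rounds))) {
      if (rounds$equivalent_diameter_um[i] > 15) next
      for (sk in skels) {
        d2 <- (sk[, 1] - rounds$y_um[i])^2 + (sk[, 2] - rounds$x_um[i])^2
        if (min(d2) <= (rounds$equivalent_diameter_um[i] / 2 + 1)^2) {
          drop[i] <- TRUE; break
        }
      }
    }
    rounds <- rounds[!drop, , drop = FALSE]
  }
  # homogeneous-looking patches inside or against a larger cell are not
  # round structures (a genuine round structure can sit near a cell)
  if (nrow(rounds) && nrow(cells)) {
    drop <- logical(nrow(rounds))
    for (i in seq_len(nrow(rounds))) {
      bigger <- cells$equivalent_diameter_um >= rounds$equivalent_diameter_um[i]
      if (!any(bigger)) next
      d2 <- (cells$y_um[bigger] - rounds$y_um[i])^2 +
        (cells$x_um[bigger] - rounds$x_um[i])^2
      lim <- 0.8 * (cells$equivalent_diameter_um[bigger] +
                      rounds$equivalent_diameter_um[i]) / 2
      if (any(d2 <= lim^2)) drop[i] <- TRUE
    }
    rounds <- rounds[!drop, , drop = FALSE]
  }
  # granule chains threading through cells are not fibers
  if (nrow(fibers) && nrow(cells)) {
    drop <- logical(nrow(fibers))
    for (k in seq_along(skels)) {
      sk <- skels[[k]]
      inside <- rep(FALSE, nrow(sk))
      for (j in seq_len(nrow(cells))) {
        R <- cells$equivalent_diameter_um[j] / 2
        inside <- inside | ((sk[, 1] - cells$y_um[j])^2 +
                              (sk[, 2] - cells$x_um[j])^2 <= (1.1 * R)^2)
      }
      if (mean(inside) >= 0.5) drop[k] <- TRUE
    }
    fibers <- fibers[!drop, , drop = FALSE]
    skels <- skels[!drop]
  }
  # ridge arcs along the rim of a round structure are not fibers
  if (nrow(fibers) && nrow(rounds)) {
    drop <- logical(nrow(fibers))
    for (k in seq_along(skels)) {
      sk <- skels[[k]]
      for (j in seq_len(nrow(rounds))) {
        R <- rounds$equivalent_diameter_um[j] / 2
        d <- sqrt((sk[, 1] - rounds$y_um[j])^2 + (sk[, 2] - rounds$x_um[j])^2)
        if (mean(d <= 1.25 * R) >= 0.5) { drop[k] <- TRUE; break }
      }
    }
    fibers <- fibers[!drop, , drop = FALSE]
    skels <- skels[!drop]
  }

  # merged punctuate pairs masquerading as tiny cells
  if (nrow(cells) && nrow(spots)) {
    drop <- logical(nrow(cells))
    small <- which(cells$equivalent_diameter_um <= 6)
    for (i in small) {
      d2 <- (spots$y_um - cells$y_um[i])^2 + (spots$x_um - cells$x_um[i])^2
      if (any(d2 <= (cells$equivalent_diameter_um[i] / 2 + 1)^2)) drop[i] <- TRUE
    }
    cells <- cells[!drop, , drop = FALSE]
  }

  # suppress spots that sit on other structures
  if (nrow(spots)) {
    keep <- rep(TRUE, nrow(spots))
    suppress_near <- function(y, x, rad) {
      for (i in which(keep)) {
        d2 <- (y - spots$y_um[i])^2 + (x - spots$x_um[i])^2
        if (any(d2 <= rad^2)) keep[i] <<- FALSE
      }
    }
    if (nrow(cells)) {
      for (j in seq_len(nrow(cells))) {
        suppress_near(cells$y_um[j], cells$x_um[j],
                      0.65 * cells$equivalent_diameter_um[j] + 2.5)
      }
    }
    if (nrow(rounds)) {
      for (j in seq_len(nrow(rounds))) {
        suppress_near(rounds$y_um[j], rounds$x_um[j],
                      rounds$equivalent_diameter_um[j] / 2 + 1.5)
      }
    }
    if (length(skels)) {
      for (k in seq_along(skels)) {
        sk <- skels[[k]]
        rad <- fibers$width_um[k] / 2 + 2
        for (i in which(keep)) {
          d2 <- (sk[, 1] - spots$y_um[i])^2 + (sk[, 2] - spots$x_um[i])^2
          if (min(d2) <= rad^2) keep[i] <- FALSE
        }
      }
    }
    spots <- spots[keep, , drop = FALSE]
  }

  detections <- rbind(spots, cells, fibers[, names(empty_detections())],
                      rounds)

  # object mask for the diffuse residual (generous dilation)
  geom_mask <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
  dil <- params$diffuse$mask_dilate_um
  disk_like <- detections[detections$class != "fiber", , drop = FALSE]
  if (nrow(disk_like)) {
    rad_um <- disk_like$equivalent_diameter_um
    rad_um <- ifelse(disk_like$class == "spot", 2 * rad_um, 0.7 * rad_um) + dil
    geom_mask <- accumulate_disks(geom_mask,
                                  um_to_px(disk_like$y_um, psz),
                                  um_to_px(disk_like$x_um, psz),
                                  rad_um / psz)
  }
  if (length(skels)) {
    for (k in seq_along(skels)) {
      sk <- skels[[k]]
      geom_mask <- accumulate_disks(geom_mask,
                                    um_to_px(sk[, 1], psz),
                                    um_to_px(sk[, 2], psz),
                                    rep((fibers$width_um[k] + dil) / psz,
                                        nrow(sk)))
    }
  }
  diffuse <- detect_diffuse(image, params, object_mask = geom_mask, .ctx = ctx)
  fv <- classify_features(detections, diffuse)
  list(detections = detections, feature_vector = fv, diffuse = diffuse)
}

#' Feature vector implied by generator ground truth
#'
#' Applies the same classification thresholds to the planted object counts
#' of a synthetic scene, giving the reference against which detector
#' output is scored.
#'
#' @param truth the `truth` element returned by [render_scene()].
#' @return A `cle_feature_vector`.
#' @export
truth_feature_vector <- function(truth) {
  obj <- truth$objects
  counts <- list(n_spots = sum(obj$class == "spot"),
                 n_small_cells = sum(obj$class == "small_cell"),
                 n_large_cells = sum(obj$class == "large_cell"),
                 n_fibers = sum(obj$class == "fiber"),
                 n_round = sum(obj$class == "round"))
  classify_features(counts, isTRUE(truth$diffuse))
}
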