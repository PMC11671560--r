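# Fiber detection: multiscale curvilinear-structure enhancement (Hessian
# ridge filter at widths matched to 1-4 um) on a downsampled copy,
# thresholding, morphological thinning to a skeleton, and graph analysis of
# the skeleton (longest geodesic path per component; spurs below the prune
# length are ignored by construction). Closed rims (cell cytoplasm rings)
# have no endpoints and are rejected; width and aspect gates separate
# fibers from wide structures.

# Zhang-Suen thinning on a logical matrix (vectorized over the whole
# matrix; operates on the cropped bounding box of the mask).
zhang_suen_thin <- function(mask) {
  if (!any(mask)) return(mask)
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(mask), max(idx[, 1]) + 2L)
  c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(mask), max(idx[, 2]) + 2L)
  m <- mask[r0:r1, c0:c1] * 1L
  pad <- function(x, dr, dc) {
    y <- matrix(0L, nrow(x), ncol(x))
    rs <- seq_len(nrow(x)) + dr; cs <- seq_len(ncol(x)) + dc
    ok_r <- rs >= 1 & rs <= nrow(x); ok_c <- cs >= 1 & cs <= ncol(x)
    y[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    y
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 15L) break
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- pad(m, 1, 0);  p3 <- pad(m, 1, -1); p4 <- pad(m, 0, -1)
      p5 <- pad(m, -1, -1); p6 <- pad(m, -1, 0); p7 <- pad(m, -1, 1)
      p8 <- pad(m, 0, 1);  p9 <- pad(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[r0:r1, c0:c1] <- m == 1L
  out
}

# Skeleton graph analysis: per 8-connected component, the longest geodesic
# path (double sweep; exact on trees) with sqrt(2) diagonal weights, the
# number of endpoints, and the path's pixel indices.
skeleton_paths <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(list())
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[pts] <- seq_len(n)
  edges <- NULL; wts <- NULL
  for (sh in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))) {
    rr <- pts[, 1] + sh[1]; cc <- pts[, 2] + sh[2]
    ok <- rr >= 1 & rr <= nrow(skel) & cc >= 1 & cc <= ncol(skel)
    nb <- integer(n); nb[ok] <- id[cbind(rr[ok], cc[ok])]
    sel <- which(nb > 0)
    if (length(sel)) {
      edges <- rbind(edges, cbind(sel, nb[sel]))
      wts <- c(wts, rep(sh[3], length(sel)))
    }
  }
  if (is.null(edges)) {
    return(lapply(seq_len(n), function(i) {
      list(length_px = 0, endpoints = 1L, pts = pts[i, , drop = FALSE])
    }))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) < 2) {
      out[[length(out) + 1]] <- list(length_px = 0, endpoints = 1L,
                                     pts = pts[vs, , drop = FALSE])
      next
    }
    d1 <- igraph::distances(g, v = vs[1], to = vs)[1, ]
    u <- vs[which.max(d1)]
    d2 <- igraph::distances(g, v = u, to = vs)[1, ]
    out[[length(out) + 1]] <- list(length_px = max(d2[is.finite(d2)]),
                                   endpoints = sum(deg[vs] <= 1),
                                   pts = pts[vs, , drop = FALSE])
  }
  out
}

#' Detect autofluorescent fibers
#'
#' Hessian-based multiscale ridge enhancement (bright curvilinear
#' structures with widths around 1-4 um), thresholding in robust
#' response-noise units, skeletonization and per-component longest-path
#' measurement. A component is reported as one fiber when its skeleton is
#' an open curve (at least one endpoint — closed cell rims are loops), at
#' least `min_length_um` long, no wider than `max_width_um`, and with
#' length/width at least `min_aspect`.
#'
#' @param image a `cle_field_image` (should have passed QC).
#' @param params a [detect_config()].
#' @return Detections data frame (class `"fiber"`): centroid (um),
#'   `length_um` (skeleton geodesic length), `width_um` (mean of twice the
#'   distance transform along the mask). Attribute `"skeletons"` holds per
#'   fiber the skeleton pixel coordinates in um (used for cross-detector
#'   suppression).
#' @export
detect_fibers <- function(image, params = detect_config(), .ctx = NULL) {
  stopifnot(inherits(image, "cle_field_image"))
  p <- params$fiber
  psz <- image$pixel_size_um
  px <- image$pixels
  rs <- if (is.null(.ctx)) robust_stats(px) else .ctx$rs
  x <- if (is.null(.ctx)) {
    matrix(as.numeric(px) - rs$median, nrow(px), ncol(px))
  } else .ctx$x
  f <- p$downsample
  xd <- downsample(x, f)
  psz_d <- psz * f
  d1 <- nrow(xd); d2 <- ncol(xd)
  resp <- NULL
  for (s in p$sigmas_px) {
    H <- fft_filter(xd, list(otf_gauss_deriv2(d1, d2, s, "11"),
                             otf_gauss_deriv2(d1, d2, s, "22"),
                             otf_gauss_deriv2(d1, d2, s, "12")))
    tr2 <- (H[[1]] + H[[2]]) / 2
    dsc <- sqrt(((H[[1]] - H[[2]]) / 2)^2 + H[[3]]^2)
    l_min <- tr2 - dsc   # most negative eigenvalue on bright ridges
    l_max <- tr2 + dsc
    ridge <- s^2 * pmax(-l_min, 0)
    # suppress blobs: both eigenvalues strongly negative is not a ridge
    ridge[abs(l_max) > 0.5 * abs(l_min)] <- 0
    # noise scale from the unrectified eigenvalue map (the rectified map is
    # half zeros, which collapses a MAD estimate)
    sigma_r <- s^2 * robust_stats(l_min)$sigma
    rz <- ridge / max(sigma_r, p$min_response / p$z_threshold)
    resp <- if (is.null(resp)) rz else pmax(resp, rz)
  }
  band <- ceiling(3 * max(p$sigmas_px)) + 2L
  resp[c(seq_len(band), seq(nrow(resp) - band + 1, nrow(resp))), ] <- 0
  resp[, c(seq_len(band), seq(ncol(resp) - band + 1, ncol(resp)))] <- 0
  mask <- resp > p$z_threshold
  if (!any(mask)) return(empty_detections())
  mask <- EBImage::closing(mask, EBImage::makeBrush(3, "disc"))
  # drop components too small to hold a min-length skeleton before the
  # (more expensive) thinning
  lab <- EBImage::bwlabel(mask)
  min_area <- p$min_length_um / psz_d
  keep_lab <- which(tabulate(lab[lab > 0]) >= min_area)
  if (!length(keep_lab)) return(empty_detections())
  mask <- matrix(lab %in% keep_lab, nrow(mask), ncol(mask))
  dist <- EBImage::distmap(mask)
  skel <- zhang_suen_thin(mask)
  comps <- skeleton_paths(skel)
  out <- empty_detections()
  skels <- list()
  for (cp in comps) {
    len_um <- cp$length_px * psz_d
    if (len_um < p$min_length_um) next
    if (cp$endpoints < 1) next                     # closed rim, not a fiber
    if (nrow(cp$pts) > 2 * cp$length_px + 10) next # dense blobby cluster
    w_um <- 2 * mean(dist[cp$pts]) * psz_d
    if (w_um > p$max_width_um) next
    if (len_um / max(w_um, 1e-6) < p$min_aspect) next
    ctr <- colMeans(cp$pts)
    out <- rbind(out, detection_row("fiber",
                                    y_um = px_to_um((ctr[1] - 0.5) * f + 0.5, psz),
                                    x_um = px_to_um((ctr[2] - 0.5) * f + 0.5, psz),
                                    length_um = len_um, width_um = w_um))
    skels[[length(skels) + 1]] <- cbind(
      y_um = px_to_um((cp$pts[, 1] - 0.5) * f + 0.5, psz),
      x_um = px_to_um((cp$pts[, 2] - 0.5) * f + 0.5, psz))
  }
  attr(out, "skeletons") <- skels
  out
}
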