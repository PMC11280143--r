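## Signal isolation -------------------------------------------------------
##
## Axon-pixel binarization: (image x probability map), edge-enhanced by
## subtracting its Gaussian-blurred version, thresholded at a multiple of
## the standard deviation of the whole processed stack (default 6 x SD).
## Cell detection: Laplacian-of-Gaussian blob detection at the scale of the
## stated cell diameter (10 um), thresholded at 2 x SD of the
## background-subtracted stack, one detection per cell with a minimum
## separation of one diameter. Background removal is a rolling-ball
## (grayscale opening with a ball structuring element, radius 50 px).

.as_stack <- function(x) if (is.matrix(x)) list(x) else x

## separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  tmp <- matrix(0, n, m)
  for (j in seq_along(k)) {                 # vertical pass
    idx <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
    tmp <- tmp + k[j] * img[idx, , drop = FALSE]
  }
  out <- matrix(0, n, m)
  for (j in seq_along(k)) {                 # horizontal pass
    idx <- pmin(pmax(seq_len(m) + (j - r - 1L), 1L), m)
    out <- out + k[j] * tmp[, idx, drop = FALSE]
  }
  out
}

.ball_se <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- expand.grid(dx = -r:r, dy = -r:r)
  d <- d[d$dx^2 + d$dy^2 <= r^2, ]
  list(dx = as.integer(d$dx), dy = as.integer(d$dy),
       h = sqrt(radius_px^2 - d$dx^2 - d$dy^2))
}

#' Rolling-ball background subtraction
#'
#' Grayscale opening with a ball (hemisphere) structuring element of the
#' stated radius estimates the background; the result is image minus
#' background, never negative. Smooth ramps of spatial scale much larger
#' than the radius are removed exactly in the interior.
#'
#' @param image matrix or list of matrices (a stack).
#' @param rolling_radius_px ball radius in pixels (>= 1; default 50).
#' @return same shape as `image`.
#' @export
subtract_background <- function(image, rolling_radius_px = 50) {
  if (rolling_radius_px < 1) stopf("radius must be >= 1")
  stack <- .as_stack(image)
  se <- .ball_se(rolling_radius_px)
  out <- lapply(stack, function(im) {
    er <- cpp_gray_morph(im, se$dx, se$dy, se$h, TRUE)
    bg <- cpp_gray_morph(er, se$dx, se$dy, se$h, FALSE)
    pmax(im - bg, 0)
  })
  if (is.matrix(image)) out[[1]] else out
}

#' Binarize axon-label signal
#'
#' Multiplies the image by a pixel-probability map (an injectable stand-in
#' for an external pixel classifier; default is the min-max normalized
#' intensity of the stack), enhances edges by subtracting a Gaussian-blurred
#' version, and thresholds at `sd_multiplier` times the standard deviation
#' of the processed stack. A constant (zero-variance) processed stack yields
#' an all-FALSE mask with a warning.
#'
#' @param image matrix or list of matrices.
#' @param probability_map values in \[0, 1\], same shape as `image`;
#'   NULL for the intensity stand-in.
#' @param gaussian_sigma_px blur scale of the edge enhancement.
#' @param sd_multiplier threshold in stack-SD units (default 6).
#' @return logical mask(s), class `binary_mask`, with attributes
#'   `threshold` and `sd`.
#' @export
binarize_axon_signal <- function(image, probability_map = NULL,
                                 gaussian_sigma_px = 5, sd_multiplier = 6) {
  stack <- .as_stack(image)
  if (is.null(probability_map)) {
    rng <- range(unlist(lapply(stack, range)))
    probability_map <- lapply(stack, function(im)
      if (rng[2] > rng[1]) (im - rng[1]) / (rng[2] - rng[1])
      else im * 0)
  } else {
    probability_map <- .as_stack(probability_map)
    if (length(probability_map) != length(stack))
      stopf("probability map and image stacks differ in length")
    for (i in seq_along(stack))
      if (!all(dim(probability_map[[i]]) == dim(stack[[i]])))
        stopf("probability map and image differ in shape")
    pm <- unlist(probability_map)
    if (min(pm) < 0 || max(pm) > 1) stopf("probability map must be in [0, 1]")
  }
  edge <- lapply(seq_along(stack), function(i) {
    f <- stack[[i]] * probability_map[[i]]
    f - gaussian_blur(f, gaussian_sigma_px)
  })
  s <- sd(unlist(edge))
  if (!is.finite(s) || s == 0) {
    warnf("processed stack has zero variance; returning empty mask")
    masks <- lapply(stack, function(im) matrix(FALSE, nrow(im), ncol(im)))
  } else {
    masks <- lapply(edge, function(e) e > sd_multiplier * s)
  }
  out <- if (is.matrix(image)) masks[[1]] else masks
  structure(out, class = c("binary_mask", class(out)),
            threshold = sd_multiplier * s, sd = s)
}

.log_response <- function(img, sigma_px) {
  sm <- gaussian_blur(img, sigma_px)
  n <- nrow(sm); m <- ncol(sm)
  up <- sm[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
  dn <- sm[pmin(seq_len(n) + 1L, n), , drop = FALSE]
  lf <- sm[, pmax(seq_len(m) - 1L, 1L), drop = FALSE]
  rt <- sm[, pmin(seq_len(m) + 1L, m), drop = FALSE]
  -sigma_px^2 * (up + dn + lf + rt - 4 * sm)   # positive at bright blobs
}

#' Detect cell-sized spots
#'
#' Scale-matched Laplacian-of-Gaussian blob detection
#' (`sigma = diameter / (2 sqrt(2))`). Local maxima of the response are kept
#' if the response exceeds `sd_multiplier` times the SD of the (background
#' subtracted) input stack; surviving peaks are pruned greedily so that
#' centers within one slice are at least one spot diameter apart (ties in
#' response broken by lowest row, then column). Centers are refined to
#' sub-pixel precision by the center of mass of the positive response in a
#' diameter-sized window.
#'
#' @param image background-subtracted matrix or stack.
#' @param spot_diameter_um physical cell diameter (default 10 um).
#' @param sd_multiplier detection threshold in stack-SD units (default 2).
#' @param pixel_um pixel size; must be <= spot_diameter/3.
#' @return a `spot_list`: data.frame (slice, x_um, y_um, response) with
#'   attributes `threshold`, `pixel_um`, `min_separation_um`.
#' @export
detect_spots <- function(image, spot_diameter_um = 10, sd_multiplier = 2,
                         pixel_um) {
  if (pixel_um > spot_diameter_um / 3)
    stopf("pixel_um must be <= spot_diameter/3")
  stack <- .as_stack(image)
  s <- sd(unlist(stack))
  empty <- data.frame(slice = integer(0), x_um = numeric(0),
                      y_um = numeric(0), response = numeric(0))
  if (!is.finite(s) || s == 0) {
    warnf("image stack has zero variance; no spots detected")
    return(structure(empty, class = c("spot_list", "data.frame"),
                     threshold = NA_real_, pixel_um = pixel_um,
                     min_separation_um = spot_diameter_um))
  }
  thr <- sd_multiplier * s
  sigma_px <- spot_diameter_um / (2 * sqrt(2)) / pixel_um
  win <- max(1L, round(spot_diameter_um / 2 / pixel_um))
  out <- list()
  for (sl in seq_along(stack)) {
    resp <- .log_response(stack[[sl]], sigma_px)
    n <- nrow(resp); m <- ncol(resp)
    ## strict 8-neighbor local maxima above threshold
    sh <- function(di, dj) {
      ri <- pmin(pmax(seq_len(n) + di, 1L), n)
      cj <- pmin(pmax(seq_len(m) + dj, 1L), m)
      resp[ri, cj, drop = FALSE]
    }
    is_max <- resp > thr
    for (d in list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1),
                   c(0,1), c(1,-1), c(1,0), c(1,1)))
      is_max <- is_max & (resp >= sh(d[1], d[2]))
    idx <- which(is_max, arr.ind = TRUE)
    if (!nrow(idx)) next
    v <- resp[idx]
    ord <- order(-v, idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]; v <- v[ord]
    ## sub-pixel center of mass of the positive response around each peak
    centers <- t(vapply(seq_len(nrow(idx)), function(i) {
      r0 <- max(1L, idx[i, 1] - win); r1 <- min(n, idx[i, 1] + win)
      c0 <- max(1L, idx[i, 2] - win); c1 <- min(m, idx[i, 2] + win)
      wts <- pmax(resp[r0:r1, c0:c1, drop = FALSE], 0)
      tot <- sum(wts)
      if (tot == 0) return(c(idx[i, 1], idx[i, 2]))
      c(sum(wts * (r0:r1)) / tot, sum(t(wts) * (c0:c1)) / tot)
    }, numeric(2)))
    ## greedy suppression on refined centers keeps the min-separation contract
    kept <- matrix(numeric(0), 0, 2)
    keep <- logical(nrow(idx))
    min_sep_px <- spot_diameter_um / pixel_um
    for (i in seq_len(nrow(idx))) {
      if (!nrow(kept) ||
          min(sqrt((kept[, 1] - centers[i, 1])^2 +
                   (kept[, 2] - centers[i, 2])^2)) >= min_sep_px) {
        kept <- rbind(kept, centers[i, ])
        keep[i] <- TRUE
      }
    }
    centers <- centers[keep, , drop = FALSE]; v <- v[keep]
    out[[length(out) + 1]] <- data.frame(
      slice = sl,
      x_um = (centers[, 2] - 0.5) * pixel_um,
      y_um = (centers[, 1] - 0.5) * pixel_um,
      response = v
    )
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  structure(res, class = c("spot_list", "data.frame"),
            threshold = thr, pixel_um = pixel_um,
            min_separation_um = spot_diameter_um)
}
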