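## Rendered section images ------------------------------------------------
##
## Fixtures for the segmentation stage: Gaussian cell bodies ("spots") of a
## stated physical diameter, thin high-intensity axon ridges, a smooth
## additive background drift, and Gaussian pixel noise. Truth (exact spot
## centers in um, ridge pixel mask) is returned alongside the image.

#' Render one synthetic section image
#'
#' Pixel (r, c) covers \[(c-1), c) x \[(r-1), r) pixels; physical coordinates
#' are `x_um = (col - 0.5) * pixel_um`, `y_um = (row - 0.5) * pixel_um`.
#'
#' @param dims_px c(rows, cols) image size.
#' @param spots data.frame with `x_um`, `y_um` (and optional `amplitude`), or
#'   an integer count to place that many non-overlapping random spots.
#' @param ridges list of segments `list(x0, y0, x1, y1)` in um, or an integer
#'   count of random segments.
#' @param pixel_um pixel size; must be <= spot_diameter/3.
#' @param spot_diameter_um rendered cell diameter (default 10 um).
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param snr peak amplitude of spots/ridges in units of `noise_sd`.
#' @param ridge_halfwidth_um half thickness of ridge truth mask.
#' @param background constant background level; a smooth linear drift of
#'   comparable magnitude is added on top.
#' @param seed integer seed.
#' @return list: `image` (matrix), `spots` (data.frame of true centers),
#'   `ridge_mask` (logical matrix), `pixel_um`, `noise_sd`.
#' @export
render_section_image <- function(dims_px = c(128, 128), spots = 0, ridges = 0,
                                 pixel_um = 2, spot_diameter_um = 10,
                                 noise_sd = 1, snr = 10,
                                 ridge_halfwidth_um = 2,
                                 background = 20, seed = 1) {
  if (pixel_um > spot_diameter_um / 3)
    stopf("pixel_um must be <= spot_diameter/3 (got %g vs %g)",
          pixel_um, spot_diameter_um / 3)
  h <- dims_px[1]; w <- dims_px[2]
  xs <- (seq_len(w) - 0.5) * pixel_um
  ys <- (seq_len(h) - 0.5) * pixel_um
  amp <- snr * noise_sd

  with_seed(seed, {
    ## background: constant + gentle linear drift
    drift <- outer(ys, xs, function(y, x)
      background * 0.25 * (x / max(xs) - y / max(ys)))
    img <- background + drift

    if (is.numeric(spots) && length(spots) == 1) {
      n <- as.integer(spots)
      centers <- data.frame(x_um = numeric(0), y_um = numeric(0))
      margin <- spot_diameter_um
      tries <- 0
      while (nrow(centers) < n && tries < 20000) {
        tries <- tries + 1
        cx <- runif(1, margin, max(xs) - margin)
        cy <- runif(1, margin, max(ys) - margin)
        if (!nrow(centers) ||
            min(sqrt((centers$x_um - cx)^2 + (centers$y_um - cy)^2)) >
              2.5 * spot_diameter_um)
          centers <- rbind(centers, data.frame(x_um = cx, y_um = cy))
      }
      if (nrow(centers) < n)
        stopf("could not place %d non-overlapping spots in %dx%d px", n, h, w)
      spots <- centers
    }
    if (nrow(spots)) {
      if (is.null(spots$amplitude)) spots$amplitude <- amp
      sigma <- spot_diameter_um / (2 * sqrt(2))
      for (i in seq_len(nrow(spots))) {
        dx2 <- (xs - spots$x_um[i])^2
        dy2 <- (ys - spots$y_um[i])^2
        img <- img + spots$amplitude[i] *
          exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
      }
    }

    if (is.numeric(ridges) && length(ridges) == 1) {
      n <- as.integer(ridges)
      ridges <- replicate(n, {
        list(x0 = runif(1, 0, max(xs)), y0 = runif(1, 0, max(ys)),
             x1 = runif(1, 0, max(xs)), y1 = runif(1, 0, max(ys)))
      }, simplify = FALSE)
    }
    ridge_mask <- matrix(FALSE, h, w)
    if (length(ridges)) {
      sr <- ridge_halfwidth_um
      for (seg in ridges) {
        vx <- seg$x1 - seg$x0; vy <- seg$y1 - seg$y0
        len2 <- vx^2 + vy^2
        ## distance from every pixel center to the segment
        d <- outer(ys, xs, function(y, x) {
          t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x - seg$x0) * vx + (y - seg$y0) * vy) / len2))
          sqrt((x - (seg$x0 + t * vx))^2 + (y - (seg$y0 + t * vy))^2)
        })
        ## flat core at the stated amplitude across the truth width, Gaussian
        ## falloff outside (the label is saturated on the axon itself)
        img <- img + amp * exp(-pmax(d - sr, 0)^2 / (2 * (sr / 2)^2))
        ridge_mask <- ridge_mask | (d <= sr)
      }
    }

    img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    list(image = img, spots = if (is.data.frame(spots)) spots else
           data.frame(x_um = numeric(0), y_um = numeric(0)),
         ridge_mask = ridge_mask, pixel_um = pixel_um, noise_sd = noise_sd)
  })
}
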