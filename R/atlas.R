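## Toy region atlas ------------------------------------------------------
##
## A configurable stand-in for a reference atlas: mirrored left/right
## hemispheres, rectangular region masks tiled without overlap on every
## coronal slice, region-specific anterior-posterior (AP) extents, and
## volumes that are exactly voxel count x voxel volume. Geometry is
## deliberately simple; the quantification code never assumes it.

#' Build a synthetic mirrored region atlas
#'
#' Creates `2 * n_regions_per_hemisphere` rectangular regions (ids `1..n` on
#' the contralateral side, `n+1..2n` mirrored on the ipsilateral side),
#' writes the labeled mask stack as a multi-page uint16 TIFF (one page per
#' coronal slice, 0 = background) and returns the catalog.
#'
#' @param n_regions_per_hemisphere number of regions per hemisphere (>= 4).
#' @param ap_span_um anterior-posterior extent covered by the stack, in
#'   micrometers; must cover at least ten 100-um bins.
#' @param seed integer seed controlling the random AP extents.
#' @param dir directory for the mask TIFF.
#' @param pixel_um in-plane pixel size (um/px).
#' @param ap_step_um slice spacing (default 60 um/section).
#' @param hemisphere_width_px,height_px slice geometry in pixels.
#' @return an object of class `region_atlas`: list with `regions`
#'   (data.frame: region_id, acronym, hemisphere, area, ap_start_um,
#'   ap_end_um, volume_mm3), `mask_ref`, `ap_step_um`, `pixel_um`, `dims`,
#'   `n_slices`.
#' @export
make_atlas <- function(n_regions_per_hemisphere, ap_span_um, seed,
                       dir = tempdir(), pixel_um = 25, ap_step_um = 60,
                       hemisphere_width_px = 64, height_px = 96) {
  n <- as.integer(n_regions_per_hemisphere)
  if (n < 4) stopf("need at least 4 regions per hemisphere, got %d", n)
  if (ap_span_um < 10 * 100) stopf("ap_span_um must cover >= 10 bins of 100 um")
  n_slices <- as.integer(floor(ap_span_um / ap_step_um))

  ## grid tiling of one hemisphere: nr x nc rectangles with nr*nc == n
  nr <- as.integer(floor(sqrt(n)))
  while (n %% nr != 0L) nr <- nr - 1L
  nc <- n %/% nr
  if (hemisphere_width_px %/% nc < 2L || height_px %/% nr < 2L)
    stopf("%d regions cannot tile a %dx%d hemisphere without degenerate tiles",
          n, height_px, hemisphere_width_px)
  xb <- round(seq(0L, hemisphere_width_px, length.out = nc + 1L))
  yb <- round(seq(0L, height_px, length.out = nr + 1L))

  areas <- c("isocortex", "OLF", "CTXsp", "CNU", "TH", "HY", "MB", "HB")
  regions <- with_seed(seed, {
    ## each base region occupies a contiguous random slice range (>= 60%)
    len <- pmax(2L, round(runif(n, 0.6, 1.0) * n_slices))
    s0 <- vapply(len, function(l) sample.int(n_slices - l + 1L, 1L), 1L)
    data.frame(base = seq_len(n), slice0 = s0, slice1 = s0 + len - 1L)
  })

  W <- 2L * hemisphere_width_px
  masks <- vector("list", n_slices)
  tile <- matrix(0L, height_px, hemisphere_width_px)
  cell <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    cell <- cell + 1L
    tile[(yb[r] + 1L):yb[r + 1L], (xb[cc] + 1L):xb[cc + 1L]] <- cell
  }
  for (s in seq_len(n_slices)) {
    present <- regions$base[regions$slice0 <= s & regions$slice1 >= s]
    left <- tile
    left[!(left %in% present)] <- 0L
    right <- left[, rev(seq_len(hemisphere_width_px))]   # mirrored
    right[right > 0L] <- right[right > 0L] + n
    masks[[s]] <- cbind(left, right)
  }

  mask_ref <- file.path(dir, sprintf("atlas_mask_n%d_seed%d.tif", n, seed))
  write_tiff(masks, mask_ref, type = "uint16")

  vox_mm3 <- (pixel_um / 1000)^2 * (ap_step_um / 1000)
  px_per_slice <- as.vector(table(factor(tile[tile > 0L], levels = seq_len(n))))
  cat_one <- function(hemi, offset) {
    data.frame(
      region_id = regions$base + offset,
      acronym = sprintf("R%02d", regions$base),
      hemisphere = hemi,
      area = areas[(regions$base - 1L) %% length(areas) + 1L],
      ap_start_um = (regions$slice0 - 1L) * ap_step_um,
      ap_end_um = regions$slice1 * ap_step_um,
      volume_mm3 = px_per_slice * (regions$slice1 - regions$slice0 + 1L) * vox_mm3,
      stringsAsFactors = FALSE
    )
  }
  catalog <- rbind(cat_one("contra", 0L), cat_one("ipsi", n))

  structure(list(regions = catalog, mask_ref = mask_ref,
                 ap_step_um = ap_step_um, pixel_um = pixel_um,
                 dims = c(height_px, W), n_slices = n_slices),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d regions (%d per hemisphere), %d slices of %g um\n",
              nrow(x$regions), nrow(x$regions) %/% 2L, x$n_slices, x$ap_step_um))
  cat(sprintf("  slice geometry %d x %d px at %g um/px; masks: %s\n",
              x$dims[1], x$dims[2], x$pixel_um, x$mask_ref))
  invisible(x)
}

#' Read the label mask stack of an atlas
#' @param atlas a `region_atlas`.
#' @return list of integer label matrices, one per slice.
#' @export
atlas_masks <- function(atlas) read_tiff(atlas$mask_ref)

#' Write / read the atlas catalog as JSON
#'
#' The mask stack stays in its TIFF; only the catalog and geometry travel in
#' the JSON file.
#' @param atlas a `region_atlas`.
#' @param path JSON file path.
#' @return `path` / a `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  jsonlite::write_json(unclass(atlas), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$regions <- as.data.frame(x$regions, stringsAsFactors = FALSE)
  structure(x, class = "region_atlas")
}
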