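# First-order and morphological features of 3D lesion regions of interest.
# All outputs are in physical units (mm) so anisotropic voxel spacing is
# handled once, at construction.

#' Construct a lesion region of interest
#'
#' @param intensities 3D numeric array of attenuation values (HU).
#' @param mask 3D array (logical or 0/1) of the same shape marking lesion
#'   voxels; must be nonempty.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm, all positive.
#' @return Object of class `"lesion_roi"`.
#' @export
lesion_roi <- function(intensities, mask, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3L) stop("intensities must be a 3D array")
  if (!identical(dim(intensities), dim(mask)))
    stop("mask and intensities must have identical shape")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask is empty")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  structure(list(intensities = intensities, mask = mask,
                 spacing = as.numeric(spacing)),
            class = "lesion_roi")
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("lesion_roi: %s grid, %d mask voxels, spacing %s mm\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Read a lesion ROI from NIfTI image and mask files
#'
#' @param image_path Path to the intensity volume (NIfTI).
#' @param mask_path Path to the binary mask volume (NIfTI), same grid.
#' @return A [lesion_roi()] with spacing taken from the image header.
#' @export
read_lesion_nifti <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(img)[1:3]
  lesion_roi(array(as.numeric(img), dim(img)),
             array(as.numeric(msk) > 0.5, dim(msk)), sp)
}

#' Lesion volume in mm^3
#'
#' Voxel count inside the mask times the voxel volume.
#'
#' @param lesion A [lesion_roi()].
#' @return Volume in mm^3.
#' @export
roi_volume <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_roi"))
  sum(lesion$mask) * prod(lesion$spacing)
}

#' First-order histogram features of a lesion
#'
#' Over the in-mask attenuation values: `density` is the mean HU; `entropy`
#' is the Shannon entropy (bits) of the intensity histogram at a fixed bin
#' width; `skewness_pos` and `kurtosis_pos` are the third and fourth
#' standardized moments of the strictly positive (HU > 0) values (kurtosis
#' in the non-excess convention, normal = 3, switchable).
#'
#' @param lesion A [lesion_roi()].
#' @param bin_width Histogram bin width in HU (default 10).
#' @param bin_anchor Left edge the bin grid is anchored at (default -1000 HU).
#' @param excess_kurtosis If `TRUE`, report kurtosis minus 3.
#' @return Named list: `density`, `entropy`, `skewness_pos`, `kurtosis_pos`.
#'   The moment features are `NA` (with a warning) when fewer than 3 voxels
#'   have positive attenuation.
#' @export
roi_histogram_features <- function(lesion, bin_width = 10,
                                   bin_anchor = -1000,
                                   excess_kurtosis = FALSE) {
  stopifnot(inherits(lesion, "lesion_roi"))
  x <- lesion$intensities[lesion$mask]
  pos <- x[x > 0]
  if (length(pos) < 3L) {
    warning("fewer than 3 positive-HU voxels; skewness/kurtosis are NA")
    sk <- NA_real_; ku <- NA_real_
  } else {
    m <- mean(pos); s2 <- mean((pos - m)^2)
    if (s2 == 0) {
      sk <- NA_real_; ku <- NA_real_
      warning("positive-HU values are constant; skewness/kurtosis are NA")
    } else {
      sk <- mean((pos - m)^3) / s2^1.5
      ku <- mean((pos - m)^4) / s2^2
      if (excess_kurtosis) ku <- ku - 3
    }
  }
  list(density = mean(x),
       entropy = shannon_entropy(x, bin_width, bin_anchor),
       skewness_pos = sk, kurtosis_pos = ku)
}

# Shannon entropy (bits) of a fixed-width binning of x
shannon_entropy <- function(x, bin_width = 10, bin_anchor = -1000) {
  bins <- floor((x - bin_anchor) / bin_width)
  p <- tabulate(match(bins, unique(bins)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Entropy of the lesion core
#'
#' Shannon entropy (bits) of the attenuation histogram restricted to the
#' eroded mask: voxels whose physical distance to the mask boundary is at
#' least `margin_mm`. The erosion uses an ellipsoidal structuring element in
#' physical units, so anisotropic spacing is respected. If erosion empties
#' the mask the entropy of the full mask is returned with attribute
#' `fallback = TRUE`.
#'
#' @param lesion A [lesion_roi()].
#' @param margin_mm Erosion margin in mm, nonnegative (default 2).
#' @inheritParams roi_histogram_features
#' @return Entropy in bits, with attribute `fallback`.
#' @export
roi_entropy_inner <- function(lesion, margin_mm = 2, bin_width = 10,
                              bin_anchor = -1000) {
  stopifnot(inherits(lesion, "lesion_roi"))
  if (margin_mm < 0) stop("margin_mm must be nonnegative")
  core <- erode_mask(lesion$mask, lesion$spacing, margin_mm)
  fallback <- !any(core)
  if (fallback) core <- lesion$mask
  e <- shannon_entropy(lesion$intensities[core], bin_width, bin_anchor)
  attr(e, "fallback") <- fallback
  e
}

# binary erosion by an ellipsoidal structuring element of physical radius
# margin_mm; a voxel survives iff every voxel within that radius is in-mask
# (voxels outside the array count as background)
erode_mask <- function(mask, spacing, margin_mm) {
  if (margin_mm == 0) return(mask)
  r <- floor(margin_mm / spacing)
  off <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  dd <- sqrt((off$i * spacing[1])^2 + (off$j * spacing[2])^2 +
               (off$k * spacing[3])^2)
  off <- off[dd <= margin_mm, , drop = FALSE]
  d <- dim(mask)
  out <- array(TRUE, d)
  for (n in seq_len(nrow(off))) {
    sh <- shift_array(mask, c(off$i[n], off$j[n], off$k[n]))
    out <- out & sh
  }
  out & mask
}

# shift a 3D logical array by (di,dj,dk), filling with FALSE
shift_array <- function(a, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- by[ax]
    dst[[ax]] <- seq_len(d[ax])[seq_len(d[ax]) - s >= 1 &
                                  seq_len(d[ax]) - s <= d[ax]]
    src[[ax]] <- dst[[ax]] - s
  }
  if (any(vapply(dst, length, 1L) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' All named features of one lesion
#'
#' @param lesion A [lesion_roi()].
#' @param margin_mm Core-erosion margin for [roi_entropy_inner()].
#' @param extra Optional named list of additional feature functions, each
#'   taking the `lesion_roi` and returning a single number; results are
#'   appended under their names.
#' @inheritParams roi_histogram_features
#' @return Named numeric vector with `volume`, `surface_area`, `density`,
#'   `skewness_pos`, `kurtosis_pos`, `entropy`, `entropy_inner`, plus any
#'   `extra` features.
#' @export
roi_features <- function(lesion, margin_mm = 2, bin_width = 10,
                         bin_anchor = -1000, excess_kurtosis = FALSE,
                         extra = list()) {
  h <- roi_histogram_features(lesion, bin_width, bin_anchor, excess_kurtosis)
  out <- c(volume = roi_volume(lesion),
           surface_area = roi_surface_area(lesion),
           density = h$density,
           skewness_pos = h$skewness_pos,
           kurtosis_pos = h$kurtosis_pos,
           entropy = h$entropy,
           entropy_inner = as.numeric(
             roi_entropy_inner(lesion, margin_mm, bin_width, bin_anchor)))
  for (nm in names(extra)) out[nm] <- extra[[nm]](lesion)
  out
}

#' Volume-weighted aggregation of multiple target lesions
#'
#' Per RECIST, up to 5 target lesions contribute per patient and time point:
#' the aggregate volume is the sum of lesion volumes and every other feature
#' is the volume-weighted average across lesions.
#'
#' @param feature_list List of 1-5 named numeric vectors, each containing a
#'   `volume` element plus the other features.
#' @return Single named numeric vector of aggregated features.
#' @export
aggregate_lesions <- function(feature_list) {
  n <- length(feature_list)
  if (n == 0L) stop("empty lesion list")
  if (n > 5L) stop("at most 5 target lesions are allowed")
  vols <- vapply(feature_list, function(f) f[["volume"]], numeric(1))
  w <- vols / sum(vols)
  nms <- names(feature_list[[1L]])
  out <- stats::setNames(numeric(length(nms)), nms)
  for (nm in nms) {
    vals <- vapply(feature_list, function(f) f[[nm]], numeric(1))
    out[nm] <- if (nm == "volume") sum(vals) else sum(w * vals)
  }
  out
}

#' Generate a voxel phantom with known analytic ground truth
#'
#' Builds spherical or ellipsoidal masks with configurable intensity texture,
#' for validating feature extraction. Textures: `"constant"` (value 100),
#' `"gaussian"` (N(100, 20) HU everywhere), or `"core_rim"` (homogeneous
#' core at 100 HU with an independent-noise rim of width `rim_mm`).
#' Deterministic given the R random seed. Analytic truth (continuum volume
#' and surface area, target moments) is attached as the `truth` attribute.
#'
#' @param radius_mm Sphere radius, or 3 semi-axes for an ellipsoid, in mm.
#' @param spacing Voxel spacing in mm.
#' @param texture One of `"constant"`, `"gaussian"`, `"core_rim"`.
#' @param rim_mm Rim width for `"core_rim"` (default 3).
#' @param pad Voxels of background padding around the shape.
#' @return A [lesion_roi()] with attribute `truth` (list: `volume_mm3`,
#'   `surface_mm2`, and for `"gaussian"` the target `skewness` 0 and
#'   `kurtosis` 3).
#' @export
make_phantom <- function(radius_mm = 10, spacing = c(1, 1, 1),
                         texture = c("constant", "gaussian", "core_rim"),
                         rim_mm = 3, pad = 4L) {
  texture <- match.arg(texture)
  ax <- rep_len(radius_mm, 3)
  n <- 2L * ceiling(ax / spacing) + 2L * pad + 1L
  ctr <- (n + 1) / 2
  gx <- (seq_len(n[1]) - ctr[1]) * spacing[1]
  gy <- (seq_len(n[2]) - ctr[2]) * spacing[2]
  gz <- (seq_len(n[3]) - ctr[3]) * spacing[3]
  mask <- array(FALSE, n)
  dist2 <- array(0, n)
  for (k in seq_len(n[3])) {
    sl <- outer((gx / ax[1])^2, (gy / ax[2])^2, "+") + (gz[k] / ax[3])^2
    mask[, , k] <- sl <= 1
    dist2[, , k] <- sl
  }
  inten <- array(0, n)
  nv <- prod(n)
  if (texture == "constant") {
    inten[mask] <- 100
  } else if (texture == "gaussian") {
    inten <- array(stats::rnorm(nv, 100, 20), n)
  } else {
    inten[mask] <- 100
    rim <- mask & dist2 > (1 - rim_mm / max(ax))^2
    inten[rim] <- stats::runif(sum(rim), -50, 250)
  }
  truth <- list(volume_mm3 = 4 / 3 * pi * prod(ax))
  if (length(unique(ax)) == 1L) truth$surface_mm2 <- 4 * pi * ax[1]^2
  if (texture == "gaussian") truth <- c(truth, skewness = 0, kurtosis = 3)
  out <- lesion_roi(inten, mask, spacing)
  attr(out, "truth") <- truth
  out
}
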