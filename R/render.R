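#' Radial profile of a blurred bead
#'
#' Closed-form convolution of a uniform unit-amplitude ball of radius
#' `radius` with an isotropic 3D Gaussian of SD `sigma`, as a function of
#' distance `r` from the bead center. This is the noiseless image model for
#' a tantalum bead seen through the scanner point-spread function. With
#' `sigma = 0` it degenerates to the ball indicator.
#'
#' @param r Distances from the bead center (mm); vectorised.
#' @param radius Ball radius (mm).
#' @param sigma Gaussian SD (mm).
#' @return Profile values in `[0, 1]`.
#' @export
bead_profile <- function(r, radius, sigma) {
  r <- abs(as.numeric(r))
  if (sigma <= 0) return(as.numeric(r <= radius))
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  out <- 0.5 * (erf((radius - r) / (sigma * sqrt(2))) +
                  erf((radius + r) / (sigma * sqrt(2))))
  nz <- r > 1e-12
  out[nz] <- out[nz] + (sigma / (r[nz] * sqrt(2 * pi))) *
    (exp(-(radius + r[nz])^2 / (2 * sigma^2)) -
       exp(-(radius - r[nz])^2 / (2 * sigma^2)))
  # r -> 0 limit of the second term
  out[!nz] <- erf(radius / (sigma * sqrt(2))) -
    sqrt(2 / pi) * (radius / sigma) * exp(-radius^2 / (2 * sigma^2))
  pmin(pmax(out, 0), 1)
}

#' Render a CT volume of the posed phantom
#'
#' Renders pelvis and cup bead markers into a synthetic CT volume on the
#' configured acquisition grid. Each bead is a sphere of pre-blur contrast
#' `bead_intensity` convolved with the Gaussian PSF (`blur_sigma`), added on
#' a uniform `background_intensity`; partial volume at bead boundaries is
#' captured by supersampling each voxel `supersample^3` times. Seeded
#' Gaussian noise of SD `noise_sd` is added voxelwise. The field of view is
#' `config$fov`, centered by default on the posed marker centroid (the
#' acetabular region), with an axis-aligned grid.
#'
#' @param pelvis,cup [marker_set()]s in phantom coordinates.
#' @param phantom_pose [rigid_transform()] applied to the whole phantom
#'   (patient repositioning); identity by default.
#' @param config A [phantom_config()].
#' @param center Optional FOV center (world mm); default the posed marker
#'   centroid.
#' @param seed Noise seed; defaults to `config$seed`.
#' @return A [voxel_volume()].
#' @export
render_ct <- function(pelvis, cup, phantom_pose = rigid_transform(),
                      config = phantom_config(), center = NULL,
                      seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  pts <- rbind(marker_coords(pelvis), marker_coords(cup))
  labels <- c(paste0("pelvis/", pelvis$marker_id),
              paste0("cup/", cup$marker_id))
  pts <- apply_transform(phantom_pose, pts)
  if (is.null(center)) center <- colMeans(pts)

  sp <- config$spacing
  dims <- pmax(2L, as.integer(ceiling(config$fov / sp - 1e-9)))
  origin <- center - (dims - 1) / 2 * sp

  radius <- config$bead_diameter / 2
  sigma <- config$blur_sigma
  r_max <- radius + 4.5 * sigma # tail cutoff; beyond this the profile ~ 0
  idx <- sweep(sweep(pts, 2L, origin), 2L, sp, "/") # axis-aligned grid
  margin <- r_max / sp
  bad <- which(apply(idx, 1L, function(v)
    any(v < margin) || any(v > dims - 1 - margin)))
  if (length(bad))
    stop(sprintf("marker(s) outside the rendered field of view: %s",
                 paste(labels[bad], collapse = ", ")), call. = FALSE)

  # background (+ noise) in a single pass, then bead patches in place
  data <- if (config$noise_sd > 0) {
    with_seed(seed, rnorm(prod(dims), mean = config$background_intensity,
                          sd = config$noise_sd))
  } else rep(config$background_intensity, prod(dims))
  dim(data) <- dims

  ss <- config$supersample
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss # subvoxel offsets, voxel units
  for (b in seq_len(nrow(pts))) {
    lo <- floor(idx[b, ] - r_max / sp)
    hi <- ceiling(idx[b, ] + r_max / sp)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    patch <- array(0, c(length(ix), length(iy), length(iz)))
    for (ox in sub) for (oy in sub) for (oz in sub) {
      gx <- ((ix + ox) * sp[1] + origin[1] - pts[b, 1])^2
      gy <- ((iy + oy) * sp[2] + origin[2] - pts[b, 2])^2
      gz <- ((iz + oz) * sp[3] + origin[3] - pts[b, 3])^2
      r <- sqrt(outer(outer(gx, gy, "+"), gz, "+"))
      patch <- patch + bead_profile(r, radius, sigma)
    }
    data[ix + 1, iy + 1, iz + 1] <- data[ix + 1, iy + 1, iz + 1] +
      config$bead_intensity * patch / ss^3
  }
  voxel_volume(data, spacing = sp, origin = origin)
}
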