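# Synthetic serial-MRI phantoms with analytically known volume change.
#
# Geometry: a spherical "brain" with a cortical grey-matter shell and
# white-matter core, a central CSF-filled "ventricle" sphere, and two
# ellipsoidal grey-matter "hippocampi" embedded in the white matter. Atrophy
# is realised on the voxel grid directly: to remove (or add) m voxels we
# threshold the sorted voxel distances of the structure, so the realised
# mask-volume change equals the requested change to within one voxel volume
# exactly, and the realised value is recorded as ground truth.

#' Specify a serial phantom pair
#'
#' @param grid_shape Integer vector of 3 voxel counts per axis.
#' @param voxel_size Numeric vector of 3 voxel edge lengths in mm.
#' @param tissue_means Named or ordered numeric vector of CSF, GM, WM
#'   intensities (arbitrary units, strictly increasing).
#' @param brain_radius Outer brain radius in mm.
#' @param gm_thickness Cortical grey-matter shell thickness in mm.
#' @param ventricle_radius Radius of the central CSF sphere in mm.
#' @param hippocampus_semiaxes Numeric vector of 3 ellipsoid semiaxes in mm
#'   (both hippocampi share them; they sit at +/- `hippocampus_offset` mm
#'   along the first axis).
#' @param hippocampus_offset Distance of each hippocampus centre from the grid
#'   centre along the first axis, mm.
#' @param atrophy_ml True brain-boundary volume loss between timepoints, ml.
#' @param ventricle_growth_ml True ventricular expansion, ml.
#' @param hippo_atrophy_ml True summed hippocampal loss (split equally), ml.
#' @param seed Integer seed recorded with the spec (the noiseless phantom is
#'   deterministic; the seed seeds downstream noise).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = c(1, 1, 1),
                         tissue_means = c(csf = 20, gm = 45, wm = 65),
                         brain_radius = 25,
                         gm_thickness = 3,
                         ventricle_radius = 8,
                         hippocampus_semiaxes = c(5, 3.5, 3),
                         hippocampus_offset = 15,
                         atrophy_ml = 2,
                         ventricle_growth_ml = 1,
                         hippo_atrophy_ml = 0.05,
                         seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
    tissue_means = as.numeric(tissue_means), brain_radius = brain_radius,
    gm_thickness = gm_thickness, ventricle_radius = ventricle_radius,
    hippocampus_semiaxes = as.numeric(hippocampus_semiaxes),
    hippocampus_offset = hippocampus_offset,
    atrophy_ml = atrophy_ml, ventricle_growth_ml = ventricle_growth_ml,
    hippo_atrophy_ml = hippo_atrophy_ml, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (length(s$grid_shape) != 3 || any(s$grid_shape < 8)) {
    stop("grid_shape must be 3 integers >= 8")
  }
  if (length(s$voxel_size) != 3 || any(s$voxel_size <= 0)) {
    stop("voxel_size must be 3 positive lengths (mm)")
  }
  if (length(s$tissue_means) != 3 || any(diff(s$tissue_means) <= 0)) {
    stop("tissue_means must be strictly increasing (CSF < GM < WM)")
  }
  if (s$brain_radius <= 0 || s$ventricle_radius <= 0 ||
      any(s$hippocampus_semiaxes <= 0) || s$gm_thickness <= 0) {
    stop("all radii and thicknesses must be positive")
  }
  half_extent <- s$grid_shape * s$voxel_size / 2
  if (any(s$brain_radius + 2 > half_extent)) {
    stop("structure overflow of grid: brain does not fit (with a 2 mm margin)")
  }
  if (s$ventricle_radius >= s$brain_radius - s$gm_thickness) {
    stop("structure overflow of grid: ventricle does not fit inside white matter")
  }
  hip_outer <- s$hippocampus_offset + s$hippocampus_semiaxes[1]
  if (hip_outer >= s$brain_radius - s$gm_thickness) {
    stop("structure overflow of grid: hippocampus extends beyond white matter")
  }
  if (s$hippocampus_offset - s$hippocampus_semiaxes[1] <= s$ventricle_radius + 1.2) {
    stop("structure overflow of grid: hippocampus overlaps ventricle")
  }
  vol_ml <- function(v_mm3) v_mm3 / 1000
  brain_ml <- vol_ml(4 / 3 * pi * s$brain_radius^3)
  vent_ml <- vol_ml(4 / 3 * pi * s$ventricle_radius^3)
  hippo_ml <- 2 * vol_ml(4 / 3 * pi * prod(s$hippocampus_semiaxes))
  wm_ml <- vol_ml(4 / 3 * pi * (s$brain_radius - s$gm_thickness)^3)
  if (s$atrophy_ml < 0 || s$ventricle_growth_ml < 0 || s$hippo_atrophy_ml < 0) {
    stop("atrophy volumes must be >= 0")
  }
  if (s$atrophy_ml >= brain_ml) stop("atrophy exceeds structure volume: brain")
  if (s$hippo_atrophy_ml >= hippo_ml) {
    stop("atrophy exceeds structure volume: hippocampus")
  }
  if (vent_ml + s$ventricle_growth_ml >= wm_ml) {
    stop("atrophy exceeds structure volume: ventricle growth exceeds white matter")
  }
  invisible(spec)
}

# Shrink a structure by exactly `m` voxels by raising the threshold on its
# quadratic field (q <= q0 defines the baseline mask). Returns the new mask.
shrink_mask_by_voxels <- function(q, q0, m) {
  base <- q <= q0
  if (m == 0) return(base)
  qin <- q[base]
  if (m >= length(qin)) stop("atrophy exceeds structure volume")
  # keep the (n - m) smallest q values
  thr <- sort(qin, partial = length(qin) - m)[length(qin) - m]
  q <= thr & base
}

grow_mask_by_voxels <- function(q, q0, m) {
  base <- q <= q0
  if (m == 0) return(base)
  qout <- q[!base]
  if (m > length(qout)) stop("growth exceeds available volume")
  thr <- sort(qout, partial = m)[m]
  base | (q <= thr)
}

#' Generate a co-registered serial phantom pair with known volume change
#'
#' Builds noiseless piecewise-constant baseline and follow-up volumes on a
#' common grid. The follow-up differs from baseline only by boundary shifts:
#' the outer brain surface recedes by `atrophy_ml`, the ventricle expands by
#' `ventricle_growth_ml` into white matter, and the hippocampal ellipsoids
#' shrink by `hippo_atrophy_ml` in total. Each change is realised as an exact
#' voxel count (`round(ml / voxel_volume)`), and the realised (voxel-quantised)
#' ml changes are returned as ground truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `baseline`, `followup` (3D arrays), `voxel_volume_ml`,
#'   `masks` (brain/ventricle/hippocampus masks at both timepoints), and
#'   `truth` (realised ml changes).
#' @export
make_phantom_pair <- function(spec) {
  validate_phantom_spec(spec)
  s <- spec
  voxvol_ml <- prod(s$voxel_size) / 1000
  coords <- voxel_coords_mm(s$grid_shape, s$voxel_size)
  r2 <- quad_field(coords)

  brain0 <- r2 <= s$brain_radius^2
  wm <- r2 <= (s$brain_radius - s$gm_thickness)^2  # static inner boundary
  vent0 <- r2 <= s$ventricle_radius^2

  qh1 <- quad_field(coords, centre = c(s$hippocampus_offset, 0, 0),
                    scale = s$hippocampus_semiaxes)
  qh2 <- quad_field(coords, centre = c(-s$hippocampus_offset, 0, 0),
                    scale = s$hippocampus_semiaxes)
  hip1_0 <- qh1 <= 1
  hip2_0 <- qh2 <= 1

  m_brain <- round(s$atrophy_ml / voxvol_ml)
  m_vent <- round(s$ventricle_growth_ml / voxvol_ml)
  m_hip_each <- round(s$hippo_atrophy_ml / 2 / voxvol_ml)

  brain1 <- shrink_mask_by_voxels(r2, s$brain_radius^2, m_brain)
  vent1 <- grow_mask_by_voxels(r2, s$ventricle_radius^2, m_vent)
  hip1_1 <- shrink_mask_by_voxels(qh1, 1, m_hip_each)
  hip2_1 <- shrink_mask_by_voxels(qh2, 1, m_hip_each)

  tm <- s$tissue_means
  paint <- function(brain, vent, h1, h2) {
    img <- array(tm[1], dim = s$grid_shape)   # background + CSF
    img[brain] <- tm[2]                        # cortical GM
    img[brain & wm] <- tm[3]                   # WM core
    img[h1 | h2] <- tm[2]                      # hippocampal GM
    img[vent] <- tm[1]                         # ventricular CSF (wins)
    img
  }

  baseline <- paint(brain0, vent0, hip1_0, hip2_0)
  followup <- paint(brain1, vent1, hip1_1, hip2_1)

  truth <- list(
    brain_loss_ml = (sum(brain0) - sum(brain1)) * voxvol_ml,
    ventricle_growth_ml = (sum(vent1) - sum(vent0)) * voxvol_ml,
    hippo_loss_ml = ((sum(hip1_0) + sum(hip2_0)) -
                       (sum(hip1_1) + sum(hip2_1))) * voxvol_ml
  )

  list(
    baseline = baseline,
    followup = followup,
    voxel_volume_ml = voxvol_ml,
    voxel_size = s$voxel_size,
    masks = list(
      brain_base = brain0, brain_follow = brain1,
      ventricle_base = vent0, ventricle_follow = vent1,
      hippo_base = hip1_0 | hip2_0, hippo_follow = hip1_1 | hip2_1
    ),
    truth = truth,
    spec = s
  )
}

#' Specify acquisition noise for a scan type
#'
#' The accelerated (parallel-imaging) protocol is modelled with its highest
#' SNR at the head periphery, near the receive coils, decaying toward the grid
#' centre; the non-accelerated protocol with a spatially uniform SNR. Local
#' noise SD is `local_signal / local_SNR`.
#'
#' @param scan_type `"accelerated"` or `"non_accelerated"`.
#' @param snr_center Signal-to-noise ratio at the grid centre; `Inf` disables
#'   noise.
#' @param snr_gradient Fractional SNR increase per mm moving outward from the
#'   grid centre (so SNR is non-increasing from periphery toward centre when
#'   `snr_gradient >= 0`).
#' @param noise_model `"rician"` (magnitude MRI default) or `"gaussian"`.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(scan_type = c("accelerated", "non_accelerated"),
                       snr_center = 25,
                       snr_gradient = if (match.arg(scan_type) == "accelerated") 0.02 else 0,
                       noise_model = c("rician", "gaussian"),
                       seed = 1L) {
  scan_type <- match.arg(scan_type)
  noise_model <- match.arg(noise_model)
  if (!is.infinite(snr_center) && snr_center <= 0) stop("snr_center must be > 0")
  if (scan_type == "accelerated" && snr_gradient < 0) {
    stop("accelerated scans require snr_gradient >= 0 (SNR non-increasing toward centre)")
  }
  structure(list(scan_type = scan_type, snr_center = snr_center,
                 snr_gradient = snr_gradient, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add spatially varying acquisition noise to a volume
#'
#' @param image 3D numeric array of finite intensities.
#' @param noise A [noise_spec()].
#' @param voxel_size Voxel edge lengths in mm (for the radial SNR profile).
#' @return A new 3D array; the input is not modified. Deterministic given
#'   `noise$seed`.
#' @export
add_acquisition_noise <- function(image, noise, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(noise, "noise_spec"))
  if (!all(is.finite(image))) stop("image intensities must be finite")
  if (is.infinite(noise$snr_center)) return(image)
  coords <- voxel_coords_mm(dim(image), voxel_size, centre_offset = c(0, 0, 0))
  d_mm <- sqrt(quad_field(coords))
  snr <- noise$snr_center * (1 + noise$snr_gradient * d_mm)
  if (any(snr <= 0)) stop("non-positive SNR on the grid; check snr_gradient")
  sd_local <- abs(image) / snr
  with_seed(noise$seed, {
    n <- length(image)
    if (noise$noise_model == "gaussian") {
      out <- image + array(stats::rnorm(n), dim = dim(image)) * sd_local
    } else {
      # Rician: magnitude of complex signal with iid Gaussian channel noise
      re <- image + array(stats::rnorm(n), dim = dim(image)) * sd_local
      im <- array(stats::rnorm(n), dim = dim(image)) * sd_local
      out <- sqrt(re^2 + im^2)
    }
    out
  })
}

#' Add a motion artifact (directional blurring with ghosting)
#'
#' Convolves the volume with a 1-D Gaussian kernel along one axis (chosen
#' pseudo-randomly from the seed, standing in for the phase-encode direction)
#' with kernel width proportional to `severity`, then adds a low-amplitude
#' ghost replica shifted by half the field of view. Convolution is circular
#' and the ghost mixing is normalised, so the total image sum is conserved.
#'
#' @param image 3D numeric array.
#' @param severity Number in \[0, 1\]; 0 returns the input unchanged.
#' @param seed Integer seed (axis choice).
#' @param ghost_amplitude Ghost replica amplitude at severity 1.
#' @return Blurred 3D array.
#' @export
add_motion_artifact <- function(image, severity, seed = 1L,
                                ghost_amplitude = 0.1) {
  if (!is.numeric(severity) || length(severity) != 1 ||
      severity < 0 || severity > 1) {
    stop("severity must be a single number in [0, 1]")
  }
  if (severity == 0) return(image)
  with_seed(seed, {
    axis <- sample.int(3, 1)
    sigma_vox <- 3 * severity
    k <- gaussian_kernel_1d(sigma_vox)
    half <- (length(k) - 1L) / 2L
    out <- array(0, dim = dim(image))
    for (i in seq_along(k)) {
      out <- out + k[i] * shift_circ(image, i - 1L - half, axis)
    }
    amp <- ghost_amplitude * severity
    if (amp > 0) {
      out <- (out + amp * shift_circ(out, dim(image)[axis] %/% 2, axis)) / (1 + amp)
    }
    out
  })
}
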