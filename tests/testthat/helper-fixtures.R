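# Shared fixtures and independent oracles, built in code at test time.

# One default phantom pair, built once per test run and reused.
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom_pair(phantom_spec())
    cache
  }
})

# Brute-force 6-connectivity morphology oracle: voxel-by-voxel neighbour
# scan, independent of the array-shift implementation under test.
brute_dilate <- function(m) {
  d <- dim(m)
  out <- m
  idx <- which(m, arr.ind = TRUE)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    out[nb[ok, , drop = FALSE]] <- TRUE
  }
  out
}

brute_erode <- function(m) {
  # voxel survives iff all 6 neighbours are inside the grid and set
  d <- dim(m)
  out <- array(FALSE, d)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  keep <- rep(TRUE, nrow(idx))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[o, ], "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
      nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
    val <- rep(FALSE, nrow(idx))
    val[inside] <- m[nb[inside, , drop = FALSE]]
    keep <- keep & val
  }
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

# Noisy image pair for a phantom with per-seed reproducible acquisition noise.
noisy_pair <- function(ph, snr = 25, seed = 1L, scan_type = "accelerated",
                       noise_model = "rician", snr_gradient = 0) {
  nb <- add_acquisition_noise(
    ph$baseline,
    noise_spec(scan_type, snr_center = snr, snr_gradient = snr_gradient,
               noise_model = noise_model, seed = seed * 2L),
    ph$voxel_size
  )
  nf <- add_acquisition_noise(
    ph$followup,
    noise_spec(scan_type, snr_center = snr, snr_gradient = snr_gradient,
               noise_model = noise_model, seed = seed * 2L + 1L),
    ph$voxel_size
  )
  image_pair(nb, nf, ph$voxel_volume_ml)
}
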