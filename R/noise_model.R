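#' Fluorescence camera noise model
#'
#' Standard camera model for widefield/confocal detectors: the noiseless
#' signal plus a uniform background is blurred by a Gaussian PSF, scaled by a
#' photon gain and Poisson-sampled (shot noise), then Gaussian read noise is
#' added and the result clipped at zero. `gain = 0` disables shot noise
#' (deterministic passthrough), `psf_sigma = 0` disables blur.
#'
#' @param background mean background level, intensity units (>= 0).
#' @param gain photon gain: photons per intensity unit for Poisson sampling
#'   (>= 0; 0 = no shot noise).
#' @param read_sd Gaussian read-noise standard deviation (>= 0).
#' @param psf_sigma lateral PSF sigma in micrometers (>= 0).
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(background = 10, gain = 1, read_sd = 2,
                        psf_sigma = 0.1) {
  vals <- c(background = background, gain = gain, read_sd = read_sd,
            psf_sigma = psf_sigma)
  if (any(vals < 0)) stopf("noise model parameters must be >= 0")
  structure(as.list(vals), class = "noise_model")
}

#' Noise-free, blur-free acquisition model
#' @return a `noise_model` with all components disabled.
#' @export
noise_none <- function() noise_model(0, 0, 0, 0)

## Apply PSF blur + camera noise to one channel (2D matrix or 3D [y,x,z]
## array; 3D stacks are blurred laterally slice by slice). Uses the current
## RNG stream; callers are responsible for seeding.
apply_noise <- function(signal, noise, pixel_size_xy) {
  stopifnot(inherits(noise, "noise_model"))
  x <- signal
  if (noise$psf_sigma > 0) {
    sg <- noise$psf_sigma / pixel_size_xy
    if (length(dim(x)) == 3L) {
      for (z in seq_len(dim(x)[3])) x[, , z] <- EBImage::gblur(x[, , z], sigma = sg)
    } else {
      x <- EBImage::gblur(x, sigma = sg)
    }
  }
  x <- x + noise$background
  if (noise$gain > 0)
    x <- array(stats::rpois(length(x), pmax(x, 0) * noise$gain) / noise$gain, dim(x))
  if (noise$read_sd > 0)
    x <- x + array(stats::rnorm(length(x), 0, noise$read_sd), dim(x))
  pmax(x, 0)
}
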