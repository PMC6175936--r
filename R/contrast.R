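#' Michelson contrast from Weber contrast
#'
#' Converts a Weber contrast `W = (L - Lb)/Lb` to the equivalent Michelson
#' contrast `(Lmax - Lmin)/(Lmax + Lmin)`.  With stimulus luminance
#' `L = Lb (1 + W)` against background `Lb`, the Michelson contrast reduces to
#' `W / (W + 2)` independently of `Lb`.
#'
#' @param weber Weber contrast (dimensionless).  Must be greater than -1
#'   (stimulus luminance must be positive).
#' @return Michelson contrast in `[-1, 1]`.
#' @examples
#' michelson_from_weber(13.4)  # ~0.87, a high-contrast cue
#' michelson_from_weber(0)     # equal luminance -> 0
#' @export
michelson_from_weber <- function(weber) {
  if (!is.numeric(weber) || anyNA(weber)) {
    stop("`weber` must be a numeric value", call. = FALSE)
  }
  if (any(weber <= -1)) {
    stop("Weber contrast must be > -1 (stimulus luminance must be positive)",
         call. = FALSE)
  }
  weber / (weber + 2)
}

#' Conditioned-stimulus specification
#'
#' Describes the visual conditioned stimulus: a small colored square presented
#' at fixed eccentricity above or below the fixation point, defined by its
#' luminance contrast against the background.  If `michelson_contrast` is not
#' supplied it is derived from the Weber contrast.  Supplying both triggers a
#' consistency check: `michelson` must equal `weber / (weber + 2)` within
#' `tol`.
#'
#' @param background_luminance Background luminance, cd/m^2 (> 0).
#' @param weber_contrast Weber contrast of the stimulus.
#' @param michelson_contrast Michelson contrast; derived from
#'   `weber_contrast` when `NULL`.
#' @param size_deg Stimulus size, degrees of visual angle.
#' @param eccentricity_deg Eccentricity of the stimulus center, degrees.
#' @param direction_deg Direction from the fixation point relative to the
#'   horizontal axis, degrees.
#' @param tol Tolerance for the Weber/Michelson consistency check.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(background_luminance = 1.0,
                          weber_contrast = 13.4,
                          michelson_contrast = NULL,
                          size_deg = 2.2,
                          eccentricity_deg = 10,
                          direction_deg = 45,
                          tol = 0.005) {
  if (background_luminance <= 0) {
    stop("`background_luminance` must be > 0", call. = FALSE)
  }
  implied <- michelson_from_weber(weber_contrast)
  if (is.null(michelson_contrast)) {
    michelson_contrast <- implied
  } else if (abs(michelson_contrast - implied) > tol) {
    stop(sprintf(
      "inconsistent contrast pair: weber = %g implies michelson = %.4f but %.4f given",
      weber_contrast, implied, michelson_contrast), call. = FALSE)
  }
  structure(list(
    background_luminance = background_luminance,
    weber_contrast = weber_contrast,
    michelson_contrast = michelson_contrast,
    size_deg = size_deg,
    eccentricity_deg = eccentricity_deg,
    direction_deg = direction_deg
  ), class = "stimulus_spec")
}
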