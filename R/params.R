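#' Elastic network model parameters
#'
#' Collects the tunable constants of the beta-Gaussian network model (bGM).
#' The model couples every pair of interaction centroids (C-alpha atoms plus
#' pseudo side-chain centroids) lying within `cutoff` of each other by a
#' quadratic penalty on the component of their relative displacement along
#' the inter-centroid axis; consecutive C-alpha atoms of a chain are always
#' coupled, with a `backbone_strengthening`-fold stronger constant.
#'
#' Energies are expressed in model units: the overall spring constant `k` and
#' the thermal factor `kBT` are both fixed at 1, so RMSF values are on a
#' common adimensional scale across structures.
#'
#' @param cutoff Interaction cutoff R_c in Angstrom. Default 7.5.
#' @param k Spring constant in model units. Default 1.
#' @param kBT Thermal energy in model units. Default 1.
#' @param zero_mode_tol Relative eigenvalue threshold below which a mode is
#'   counted as a zero (rigid-body) mode, as a fraction of the largest
#'   eigenvalue. Must lie in (0, 1e-6].
#' @param cbeta_offset Distance in Angstrom from the C-alpha at which the
#'   pseudo side-chain centroid is placed, along the local outward direction
#'   `2 r_i - r_{i-1} - r_{i+1}` (normalized). Default 3.0.
#' @param backbone_strengthening Multiplier applied to the spring constant of
#'   consecutive C-alpha pairs within a chain. Default 2.
#'
#' @return A list of class `enm_params`.
#' @export
#' @examples
#' p <- enm_params()
#' p$cutoff
enm_params <- function(cutoff = 7.5, k = 1, kBT = 1,
                       zero_mode_tol = 1e-9,
                       cbeta_offset = 3.0,
                       backbone_strengthening = 2) {
  stopifnot(cutoff > 0, k > 0, kBT > 0,
            zero_mode_tol > 0, zero_mode_tol <= 1e-6,
            cbeta_offset >= 0, backbone_strengthening > 0)
  structure(
    list(cutoff = cutoff, k = k, kBT = kBT,
         zero_mode_tol = zero_mode_tol,
         cbeta_offset = cbeta_offset,
         backbone_strengthening = backbone_strengthening),
    class = "enm_params"
  )
}

#' @export
print.enm_params <- function(x, ...) {
  cat("bGM parameters: R_c =", x$cutoff, "A, k =", x$k, ", kBT =", x$kBT,
      "\n  cbeta_offset =", x$cbeta_offset,
      "A, backbone_strengthening =", x$backbone_strengthening,
      ", zero_mode_tol =", x$zero_mode_tol, "\n")
  invisible(x)
}

as_enm_params <- function(x) {
  if (inherits(x, "enm_params")) return(x)
  if (is.null(x)) return(enm_params())
  do.call(enm_params, x)
}
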