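#' Normal mode spectrum of an elastic network
#'
#' Diagonalizes the stiffness matrix and reports the full eigensystem in
#' ascending eigenvalue order. Eigenvalues smaller than
#' `zero_mode_tol * max(eigenvalue)` are counted as numerically-zero modes;
#' a connected structure has exactly six (rigid rotations and translations),
#' disconnected or effectively-free parts contribute extra ones.
#'
#' @param network An `elastic_network`, or a symmetric matrix (then `params`
#'   supplies the zero-mode tolerance).
#' @param params [enm_params()], used only when `network` is a bare matrix.
#' @return An object of class `mode_spectrum`: list with `values` (ascending),
#'   `vectors` (orthonormal columns, matching order), `n_zero`, `n_residues`,
#'   and `nodes` (when available).
#' @export
mode_spectrum <- function(network, params = enm_params()) {
  if (inherits(network, "elastic_network")) {
    M <- network$stiffness
    tol <- network$params$zero_mode_tol
    nodes <- network$nodes
  } else {
    M <- as.matrix(network)
    tol <- as_enm_params(params)$zero_mode_tol
    nodes <- NULL
  }
  if (!isSymmetric(M, tol = 1e-8))
    stop("stiffness matrix is not symmetric", call. = FALSE)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  values <- es$values[ord]
  vectors <- es$vectors[, ord, drop = FALSE]
  lam_max <- max(values)
  if (lam_max <= 0)
    stop("rank-deficient reference structure: stiffness matrix has no ",
         "positive eigenvalue", call. = FALSE)
  n_zero <- sum(values < tol * lam_max)
  structure(
    list(values = values, vectors = vectors, n_zero = n_zero,
         n_residues = nrow(M) / 3L, nodes = nodes),
    class = "mode_spectrum"
  )
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("Mode spectrum:", length(x$values), "modes,",
      x$n_zero, "numerically-zero\n")
  cat("  lowest non-zero eigenvalues:",
      paste(signif(utils::head(x$values[-seq_len(x$n_zero)], 4), 4),
            collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mode_spectrum <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    zero_mode = seq_along(x$values) <= x$n_zero
  )
}

#' @exportS3Method generics::glance
glance.mode_spectrum <- function(x, ...) {
  nz <- x$n_zero
  tibble::tibble(
    n_modes = length(x$values),
    n_zero = nz,
    lambda_min_nonzero = if (nz < length(x$values)) x$values[nz + 1] else NA_real_,
    lambda_max = max(x$values)
  )
}

#' Per-residue root mean square fluctuations
#'
#' Computes `RMSF(i) = sqrt( sum_a |v_i^a|^2 / lambda_a )` over the non-zero
#' modes, in model units (`k = kBT = 1`). This equals the square root of the
#' trace of residue `i`'s 3x3 diagonal block of the Moore-Penrose
#' pseudo-inverse of the stiffness matrix. The function refuses structures
#' whose zero-mode count differs from the expected rigid-body dimension, the
#' same filter used to exclude unsuitable dimers from analysis.
#'
#' @param spectrum A `mode_spectrum`.
#' @param nodes Optional residue table (tibble with `chain`, `resno`,
#'   `resid`); defaults to the one carried by the spectrum.
#' @param frame Label recorded in the output: `"subunit"` or `"complex"`.
#' @param expected_zero_modes Rigid-body null-space dimension, 6 for a
#'   connected body.
#' @return A tibble (`mobility_profile`): `chain`, `resno`, `resid`, `rmsf`,
#'   `frame`.
#' @export
rmsf_profile <- function(spectrum, nodes = NULL,
                         frame = c("subunit", "complex"),
                         expected_zero_modes = 6L) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  frame <- match.arg(frame)
  if (spectrum$n_zero != expected_zero_modes)
    stop("extra zero modes - structure unsuitable (found ",
         spectrum$n_zero, ", expected ", expected_zero_modes, ")",
         call. = FALSE)
  if (is.null(nodes)) nodes <- spectrum$nodes
  n <- spectrum$n_residues
  keep <- seq.int(spectrum$n_zero + 1L, length(spectrum$values))
  V <- spectrum$vectors[, keep, drop = FALSE]
  lam <- spectrum$values[keep]
  W <- V^2 %*% (1 / lam)                       # 3N x 1
  per_res <- sqrt(rowSums(matrix(W, nrow = n, byrow = TRUE)))
  out <- if (!is.null(nodes)) {
    tibble::tibble(chain = nodes$chain, resno = nodes$resno,
                   resid = nodes$resid, rmsf = per_res, frame = frame)
  } else {
    tibble::tibble(chain = NA_character_, resno = seq_len(n),
                   resid = NA_character_, rmsf = per_res, frame = frame)
  }
  class(out) <- c("mobility_profile", class(out))
  out
}

#' Write a mobility profile as tab-separated text
#' @param profile A `mobility_profile` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
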