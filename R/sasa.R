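#' Atomic radii and reference accessibilities
#'
#' Van der Waals radii follow the NACCESS/Chothia convention (C 1.87, peptide
#' carbonyl C 1.76, N 1.65, O 1.40, S 1.85 A); per-residue-type reference
#' accessibilities are the extended Ala-X-Ala tripeptide totals used to turn
#' absolute ASA into relative ASA (RASA, percent).
#'
#' @name asa_references
NULL

.elety_radii <- c(C = 1.76, N = 1.65, O = 1.40, OXT = 1.40)
.element_radii <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80)
.default_radius <- 1.80

# extended Ala-X-Ala total reference ASA (A^2) per residue type
.rasa_reference <- c(
  ALA = 107.95, ARG = 238.76, ASN = 143.94, ASP = 140.39, CYS = 134.28,
  GLN = 178.50, GLU = 172.25, GLY = 80.10, HIS = 182.88, ILE = 175.12,
  LEU = 178.63, LYS = 200.81, MET = 194.15, PHE = 199.48, PRO = 136.13,
  SER = 116.50, THR = 139.27, TRP = 249.36, TYR = 212.76, VAL = 151.44
)

atom_radii <- function(atoms) {
  if ("radius" %in% names(atoms) && !all(is.na(atoms$radius)))
    return(atoms$radius)
  ele <- if ("elesy" %in% names(atoms)) atoms$elesy else NA_character_
  ele <- toupper(ifelse(is.na(ele) | ele == "",
                        substr(gsub("[0-9']", "", atoms$elety), 1, 1), ele))
  r <- unname(.elety_radii[atoms$elety])
  r[is.na(r)] <- unname(.element_radii[ele[is.na(r)]])
  if (anyNA(r)) {
    warning(sum(is.na(r)), " atom(s) with unknown element: using default ",
            "radius ", .default_radius, " A", call. = FALSE)
    r[is.na(r)] <- .default_radius
  }
  r
}

# deterministic spiral (Fibonacci) unit-sphere point set
sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  theta <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(theta), rho * sin(theta), z)
}

#' Solvent-accessible surface area of an atom set
#'
#' Numerical SASA by deterministic sphere-point sampling (Shrake-Rupley with
#' a fixed spiral point set, so results are exactly reproducible): each
#' atom's solvent sphere of radius `r_atom + probe_radius` is sampled at
#' `n_points` points and the accessible fraction is the share of points
#' outside every neighboring solvent sphere. Per-atom areas are summed per
#' residue; RASA is the percentage of the residue type's extended-state
#' reference area. Hydrogen/deuterium atoms are ignored.
#'
#' @param atoms Tibble of atoms: `chain`, `resno`, `resid`, `elety`, `x`,
#'   `y`, `z`; optional `elesy` (element symbol) and `radius` (A, overrides
#'   the radii table - used by the synthetic single-sphere-per-residue
#'   representation).
#' @param probe_radius Probe sphere radius in Angstrom (water, 1.4).
#' @param n_points Sample points per atom (default 960).
#' @return An `accessibility_record`: per-residue tibble `chain`, `resno`,
#'   `resid`, `asa` (A^2), `rasa` (percent, `NA` for residue types without a
#'   reference), with attributes `total_asa`, `probe_radius`, `n_points`.
#' @export
#' @examples
#' one <- tibble::tibble(chain = "A", resno = 1, resid = "GLY",
#'                       elety = "CA", elesy = "C", x = 0, y = 0, z = 0,
#'                       radius = 2)
#' attr(compute_asa(one), "total_asa") / (4 * pi * (2 + 1.4)^2)
compute_asa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  stopifnot(is.data.frame(atoms), probe_radius >= 0, n_points >= 12)
  keep <- !grepl("^\\s*[HD]", atoms$elety)
  if ("elesy" %in% names(atoms))
    keep <- keep & !(toupper(atoms$elesy) %in% c("H", "D"))
  atoms <- atoms[keep, , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0) stop("no non-hydrogen atoms", call. = FALSE)
  r <- atom_radii(atoms) + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- sphere_points(n_points)

  area <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) == 0) { area[i] <- 4 * pi * r[i]^2; next }
    P <- pts * r[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      # strict burial, with an index tie-break for points exactly on a
      # neighbor's surface (degenerate coincident-sphere configurations)
      buried <- dj2 < r[j]^2 - 1e-9 |
        (abs(dj2 - r[j]^2) <= 1e-9 & j < i)
      free <- free & !buried
      if (!any(free)) break
    }
    area[i] <- 4 * pi * r[i]^2 * mean(free)
  }

  per_res <- tibble::tibble(chain = atoms$chain, resno = atoms$resno,
                            resid = atoms$resid, atom_asa = area) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid) |>
    dplyr::summarise(asa = sum(.data$atom_asa), .groups = "drop") |>
    dplyr::arrange(match(.data$chain, unique(atoms$chain)), .data$resno)
  per_res$rasa <- 100 * per_res$asa /
    unname(.rasa_reference[per_res$resid])
  out <- per_res
  attr(out, "total_asa") <- sum(area)
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  class(out) <- c("accessibility_record", class(out))
  out
}

#' Interface area of a complex
#'
#' The buried area: sum of the total ASA of the two isolated components
#' minus the total ASA of the complex, in A^2. Non-negative up to sampling
#' noise; a clearly negative value flags inconsistent records (different
#' probe or radii) and raises an error.
#'
#' @param complex_rec `accessibility_record` of the whole complex.
#' @param monomer_recs List of the two monomers' records (same probe and
#'   radii).
#' @return Interface area in A^2.
#' @export
interface_area <- function(complex_rec, monomer_recs) {
  stopifnot(inherits(complex_rec, "accessibility_record"),
            length(monomer_recs) == 2)
  pr <- vapply(monomer_recs, attr, numeric(1), "probe_radius")
  if (any(abs(pr - attr(complex_rec, "probe_radius")) > 1e-12))
    stop("records computed with different probe radii", call. = FALSE)
  area <- sum(vapply(monomer_recs, attr, numeric(1), "total_asa")) -
    attr(complex_rec, "total_asa")
  if (area < -1)
    stop("negative interface area (", round(area, 2),
         " A^2): inconsistent accessibility records", call. = FALSE)
  max(area, 0)
}

#' Classify surface and interface residues
#'
#' Surface residues have unbound-form RASA above `rasa_threshold` (percent).
#' Semi-interface residues are those whose ASA decreases by more than
#' `delta_asa_min` going from the isolated (unbound) monomer to the complex;
#' the interface is the union of the two semi-interfaces and the interface
#' size is the number of residues in it. Both labels are carried per
#' residue, so sets such as "surface but not interface" are derivable.
#'
#' @param complex_rec `accessibility_record` of the complex.
#' @param monomer_recs List of two records, first chain then second, from
#'   the isolated monomers (same probe and radii).
#' @param rasa_threshold Surface threshold, percent RASA (default 5).
#' @param delta_asa_min Minimum ASA loss (A^2) to call a residue buried by
#'   the partner (default 0.1; suppresses sampling noise while approximating
#'   "any decrease").
#' @return An `interface_annotation` tibble: `chain`, `resno`, `resid`,
#'   `asa_bound`, `asa_unbound`, `rasa_unbound`, `delta_asa`, `is_surface`,
#'   `is_interface`; attributes `interface_area`, `interface_size`,
#'   `semi_interface_sizes`, `rasa_threshold`, `delta_asa_min`.
#' @export
classify_residues <- function(complex_rec, monomer_recs,
                              rasa_threshold = 5, delta_asa_min = 0.1) {
  stopifnot(inherits(complex_rec, "accessibility_record"),
            length(monomer_recs) == 2)
  unbound <- dplyr::bind_rows(
    tibble::as_tibble(monomer_recs[[1]]),
    tibble::as_tibble(monomer_recs[[2]])
  )
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(complex_rec), asa_bound = "asa"),
    dplyr::rename(unbound, asa_unbound = "asa", rasa_unbound = "rasa"),
    by = c("chain", "resno", "resid")
  )
  if (nrow(joined) != nrow(complex_rec) || nrow(joined) != nrow(unbound))
    stop("mismatched residue indexing between complex and monomer records",
         call. = FALSE)
  out <- joined |>
    dplyr::mutate(
      delta_asa = .data$asa_unbound - .data$asa_bound,
      is_surface = !is.na(.data$rasa_unbound) &
        .data$rasa_unbound > rasa_threshold,
      is_interface = .data$delta_asa > delta_asa_min
    ) |>
    dplyr::select("chain", "resno", "resid", "asa_bound", "asa_unbound",
                  "rasa_unbound", "delta_asa", "is_surface", "is_interface")
  chains <- unique(out$chain)
  semi <- vapply(chains, function(ch)
    sum(out$is_interface[out$chain == ch]), integer(1))
  attr(out, "interface_area") <- interface_area(complex_rec, monomer_recs)
  attr(out, "interface_size") <- sum(out$is_interface)
  attr(out, "semi_interface_sizes") <- semi
  attr(out, "rasa_threshold") <- rasa_threshold
  attr(out, "delta_asa_min") <- delta_asa_min
  class(out) <- c("interface_annotation", class(out))
  out
}

#' @exportS3Method generics::glance
glance.interface_annotation <- function(x, ...) {
  semi <- attr(x, "semi_interface_sizes")
  tibble::tibble(
    interface_area = attr(x, "interface_area"),
    interface_size = attr(x, "interface_size"),
    semi_interface_first = semi[1],
    semi_interface_second = semi[2],
    n_surface = sum(x$is_surface),
    rasa_threshold = attr(x, "rasa_threshold"),
    delta_asa_min = attr(x, "delta_asa_min")
  )
}

#' Accessibility analysis of a dimer in one call
#'
#' Runs [compute_asa()] on the complex and on each isolated chain of the
#' dimer's atom table, then [classify_residues()].
#'
#' @param dimer A `dimer_structure` with an `atoms` table.
#' @param probe_radius,n_points Passed to [compute_asa()].
#' @param rasa_threshold,delta_asa_min Passed to [classify_residues()].
#' @return An `interface_annotation`.
#' @export
dimer_accessibility <- function(dimer, probe_radius = 1.4, n_points = 960,
                                rasa_threshold = 5, delta_asa_min = 0.1) {
  stopifnot(inherits(dimer, "dimer_structure"))
  if (is.null(dimer$atoms))
    stop("dimer carries no atom records for accessibility analysis",
         call. = FALSE)
  ch1 <- attr(dimer$first, "chain_id")
  ch2 <- attr(dimer$second, "chain_id")
  cplx <- compute_asa(dimer$atoms, probe_radius, n_points)
  m1 <- compute_asa(dimer$atoms[dimer$atoms$chain == ch1, ],
                    probe_radius, n_points)
  m2 <- compute_asa(dimer$atoms[dimer$atoms$chain == ch2, ],
                    probe_radius, n_points)
  classify_residues(cplx, list(m1, m2), rasa_threshold, delta_asa_min)
}
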