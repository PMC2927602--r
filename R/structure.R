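#' Monomer and dimer structure containers
#'
#' A monomer is a tibble of ordered residues carrying the C-alpha trace of one
#' chain: columns `chain`, `resno` (1-based contiguous ordinal within the
#' chain), `resno_pdb` (author residue number, with any insertion code),
#' `resid` (3-letter residue name), `x`, `y`, `z` (Angstrom). A dimer bundles
#' two monomers (the *first* chain defines the subunit reference frame used
#' downstream) together with the full-atom records needed by the
#' accessibility stage and optional complex metadata.
#'
#' @name structures
NULL

new_monomer_structure <- function(residues, chain_id) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "resno", "resno_pdb", "resid", "x", "y", "z") %in%
                  names(residues)))
  out <- tibble::as_tibble(residues)
  attr(out, "chain_id") <- chain_id
  class(out) <- c("monomer_structure", class(out))
  out
}

#' @export
print.monomer_structure <- function(x, ...) {
  cat("Monomer structure: chain", attr(x, "chain_id"),
      "-", nrow(x), "residues with C-alpha\n")
  NextMethod()
}

new_dimer_structure <- function(first, second, atoms = NULL,
                                metadata = list()) {
  stopifnot(inherits(first, "monomer_structure"),
            inherits(second, "monomer_structure"))
  if (identical(attr(first, "chain_id"), attr(second, "chain_id")))
    stop("chain ids of the two monomers must be distinct", call. = FALSE)
  if (!is.null(metadata$interface_type) &&
      !metadata$interface_type %in% c("I", "II", "III"))
    stop("interface_type must be one of I, II, III", call. = FALSE)
  if (!is.null(metadata$obligate_class) &&
      !metadata$obligate_class %in% c("obligate", "non-obligate",
                                      "non-biological"))
    stop("obligate_class must be obligate, non-obligate or non-biological",
         call. = FALSE)
  structure(
    list(first = first, second = second, atoms = atoms, metadata = metadata),
    class = "dimer_structure"
  )
}

#' @export
print.dimer_structure <- function(x, ...) {
  md <- x$metadata
  cat("Dimer structure",
      if (!is.null(md$pdb_id)) paste0("[", md$pdb_id, "]") else "", "\n")
  cat("  first  chain ", attr(x$first, "chain_id"), ": ",
      nrow(x$first), " residues\n", sep = "")
  cat("  second chain ", attr(x$second, "chain_id"), ": ",
      nrow(x$second), " residues\n", sep = "")
  if (!is.null(md$interface_type))
    cat("  interface type", md$interface_type, "\n")
  if (!is.null(md$obligate_class)) cat(" ", md$obligate_class, "complex\n")
  invisible(x)
}

#' Read a two-chain complex from a PDB file
#'
#' Parses a standard PDB file (first model only), retains the two requested
#' protein chains and returns a [dimer structure][structures] whose monomers
#' hold the C-alpha traces and whose `atoms` table keeps the full-atom records
#' of the two chains for the accessibility stage. Heteroatoms and waters are
#' excluded; for alternate locations the highest-occupancy conformer is kept;
#' residues lacking a C-alpha atom are dropped with a warning and the residue
#' ordinals re-indexed to stay contiguous.
#'
#' @param path Path to a PDB file.
#' @param chain_ids Character vector of length 2: the first and second chain.
#'   The first chain defines the subunit reference frame.
#' @param metadata Optional list with `pdb_id`, `interface_type` (\"I\", \"II\"
#'   or \"III\") and `obligate_class` (\"obligate\", \"non-obligate\",
#'   \"non-biological\").
#'
#' @return A `dimer_structure`.
#' @export
#' @examples
#' d <- make_dimer(synthetic_dimer_spec(n_first = 12, n_second = 12,
#'                                      target_interchain_contacts = 6))
#' f <- tempfile(fileext = ".pdb")
#' write_dimer_pdb(d, f)
#' read_dimer(f, c("A", "B"))
read_dimer <- function(path, chain_ids, metadata = list()) {
  stopifnot(length(chain_ids) == 2)
  if (chain_ids[1] == chain_ids[2])
    stop("the two chain ids must be distinct", call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- tibble::as_tibble(pdb$atom)
  atoms <- dplyr::filter(atoms, .data$type == "ATOM",
                         .data$chain %in% chain_ids)
  present <- unique(atoms$chain)
  missing <- setdiff(chain_ids, present)
  if (length(missing) > 0)
    stop("chain(s) ", paste(missing, collapse = ", "),
         " not found in '", path, "'", call. = FALSE)
  # highest-occupancy alternate conformer per atom
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  atoms <- dplyr::arrange(atoms, match(.data$chain, chain_ids),
                          .data$resno)

  monomers <- lapply(chain_ids, function(ch) {
    ca <- dplyr::filter(atoms, .data$chain == ch, .data$elety == "CA")
    full_res <- dplyr::distinct(
      dplyr::filter(atoms, .data$chain == ch),
      .data$resno, .data$insert
    )
    if (nrow(ca) < nrow(full_res))
      warning(nrow(full_res) - nrow(ca), " residue(s) of chain ", ch,
              " lack a C-alpha atom and were dropped; ordinals re-indexed",
              call. = FALSE)
    if (nrow(ca) < 3)
      stop("chain ", ch, " has ", nrow(ca),
           " C-alpha residues: too short for ENM", call. = FALSE)
    lab <- ifelse(is.na(ca$insert) | ca$insert == "",
                  as.character(ca$resno),
                  paste0(ca$resno, ca$insert))
    new_monomer_structure(
      tibble::tibble(chain = ch, resno = seq_len(nrow(ca)),
                     resno_pdb = lab, resid = ca$resid,
                     x = ca$x, y = ca$y, z = ca$z),
      chain_id = ch
    )
  })

  atom_tbl <- tibble::tibble(
    chain = atoms$chain, resno = atoms$resno,
    resid = atoms$resid, elety = atoms$elety,
    elesy = atoms$elesy,
    x = atoms$x, y = atoms$y, z = atoms$z
  )
  new_dimer_structure(monomers[[1]], monomers[[2]], atoms = atom_tbl,
                      metadata = metadata)
}

#' Split a complex into its structurally-quenched monomers
#'
#' Returns the two monomers exactly as they sit in the complex: the in-silico
#' split keeps the bound-form coordinates without any relaxation or
#' re-centering, so each monomer is the structurally-quenched unbound form.
#'
#' @param dimer A `dimer_structure`.
#' @return A list with elements `first` and `second` (`monomer_structure`).
#' @export
split_complex <- function(dimer) {
  stopifnot(inherits(dimer, "dimer_structure"))
  list(first = dimer$first, second = dimer$second)
}

#' Validate a dimer for elastic-network analysis
#'
#' Counts the numerically-zero modes of the bGM stiffness matrix of the
#' complex and of each monomer taken alone. A compact connected body has
#' exactly six zero modes (rigid rotations and translations); extra zero or
#' near-zero modes signal effectively free parts (long exposed loops,
#' termini, or uncoupled chains) whose diffusive motion the harmonic network
#' cannot model, and such complexes are excluded from analysis.
#'
#' @param dimer A `dimer_structure`.
#' @param params [enm_params()].
#' @return A tibble with one row: `n_zero_modes_complex`,
#'   `n_zero_modes_first`, `n_zero_modes_second`, `enm_suitable` (`TRUE` iff
#'   all three counts equal 6).
#' @export
validate_for_enm <- function(dimer, params = enm_params()) {
  stopifnot(inherits(dimer, "dimer_structure"))
  params <- as_enm_params(params)
  nz <- function(s) mode_spectrum(build_network(s, params))$n_zero
  n_complex <- nz(dimer)
  n_first <- nz(dimer$first)
  n_second <- nz(dimer$second)
  tibble::tibble(
    n_zero_modes_complex = n_complex,
    n_zero_modes_first = n_first,
    n_zero_modes_second = n_second,
    enm_suitable = n_complex == 6L && n_first == 6L && n_second == 6L
  )
}

#' Coordinates of a monomer as a numeric matrix
#' @param monomer A `monomer_structure`.
#' @return An N x 3 matrix of C-alpha coordinates in Angstrom.
#' @export
ca_coords <- function(monomer) {
  as.matrix(monomer[, c("x", "y", "z")])
}
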