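#' Read a classic DSSP output file
#'
#' Parses the fixed-column residue section of classic DSSP text output and
#' returns the seven-state secondary-structure assignment (H alpha helix, B
#' isolated beta-bridge, E extended strand, G 3_10 helix, I pi helix, T
#' hydrogen-bonded turn, S bend, blank for unassigned). Chain-break records
#' (`!` in the amino-acid column) are skipped; alignment to the surrounding
#' residues is preserved. The three-state collapse is filled in by
#' [collapse_ss()] and returned alongside.
#'
#' @param path Path to a classic DSSP output file.
#' @return A tibble: `chain`, `resno_pdb`, `aa` (one-letter code), `ss7`,
#'   `ss3`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1)
    stop("malformed DSSP file: residue-section header not found in '",
         path, "'", call. = FALSE)
  body <- lines[seq.int(hdr + 1, length(lines))]
  body <- body[nzchar(trimws(body))]
  recs <- lapply(seq_along(body), function(k) {
    ln <- body[k]
    if (nchar(ln) < 17)
      stop("malformed DSSP record at line ", hdr + k, call. = FALSE)
    aa <- substr(ln, 14, 14)
    if (aa == "!") return(NULL)        # chain break
    resno <- trimws(substr(ln, 6, 11)) # author number + insertion code
    if (resno == "")
      stop("malformed DSSP record (empty residue number) at line ",
           hdr + k, call. = FALSE)
    tibble::tibble(
      chain = substr(ln, 12, 12),
      resno_pdb = resno,
      aa = aa,
      ss7 = substr(ln, 17, 17)
    )
  })
  out <- dplyr::bind_rows(recs)
  out$ss3 <- collapse_ss(out$ss7)
  out
}

#' Collapse seven-state secondary structure to three states
#'
#' Maps the DSSP alphabet onto helix (H, G, I), strand (B, E) and coil
#' (T, S, or blank). Any other symbol is an error.
#'
#' @param ss7 Character vector of single DSSP state codes (`" "` or `""`
#'   for unassigned).
#' @return Character vector over `{"helix", "strand", "coil"}`.
#' @export
#' @examples
#' collapse_ss(c("H", "G", "I", "B", "E", "T", "S", " "))
collapse_ss <- function(ss7) {
  map <- c(H = "helix", G = "helix", I = "helix",
           B = "strand", E = "strand",
           T = "coil", S = "coil", " " = "coil")
  key <- ifelse(ss7 == "", " ", ss7)
  bad <- !key %in% names(map)
  if (any(bad))
    stop("unknown secondary-structure code(s): ",
         paste(unique(ss7[bad]), collapse = ", "), call. = FALSE)
  unname(map[key])
}

#' Secondary-structure assignment for synthetic fixtures
#'
#' Synthetic traces have no hydrogen-bond pattern for DSSP to read, so ideal
#' helices are labeled `H` by construction (globule walks default to blank,
#' i.e. coil after collapse), keeping secondary-structure-grouped analyses
#' runnable offline.
#'
#' @param monomer A `monomer_structure`.
#' @param state7 Single DSSP state code applied to every residue.
#' @return A tibble: `chain`, `resno_pdb`, `aa`, `ss7`, `ss3`.
#' @export
synthetic_ss <- function(monomer, state7 = "H") {
  stopifnot(inherits(monomer, "monomer_structure"))
  tibble::tibble(
    chain = monomer$chain,
    resno_pdb = as.character(monomer$resno_pdb),
    aa = "A",
    ss7 = state7,
    ss3 = collapse_ss(rep(state7, nrow(monomer)))
  )
}

#' Merge secondary structure into a per-residue profile
#'
#' Joins three-state labels onto a profile table (e.g. the paired
#' bound/unbound profile) through the monomer's author residue numbering;
#' residues without an assignment get `"coil"`.
#'
#' @param profile A tibble with `chain` and `resno` columns (contiguous
#'   ordinals, as produced by the profile functions).
#' @param ss An assignment tibble from [read_dssp()] or [synthetic_ss()].
#' @param monomer The `monomer_structure` linking ordinals to author
#'   numbering.
#' @return `profile` with an `ss3` column appended.
#' @export
add_secondary_structure <- function(profile, ss, monomer) {
  stopifnot(inherits(monomer, "monomer_structure"))
  key <- tibble::tibble(chain = monomer$chain, resno = monomer$resno,
                        resno_pdb = as.character(monomer$resno_pdb))
  out <- profile |>
    dplyr::left_join(key, by = c("chain", "resno")) |>
    dplyr::left_join(dplyr::select(ss, "chain", "resno_pdb", "ss3"),
                     by = c("chain", "resno_pdb")) |>
    dplyr::mutate(ss3 = dplyr::coalesce(.data$ss3, "coil")) |>
    dplyr::select(-"resno_pdb")
  class(out) <- class(profile)
  out
}
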