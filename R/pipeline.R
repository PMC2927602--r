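#' The reference dimer manifest
#'
#' The 22 representative dimeric interfaces analyzed by the package's
#' reference study, shipped in `inst/extdata/table1_interfaces.tsv`: PDB id,
#' the two analysis chains (the first defines the subunit reference frame),
#' chain sizes, published interface area and (semi-)interface sizes, the
#' interface type (I: members of the cluster share the whole fold; II:
#' interface-only similarity; III: only one semi-interface shared) and the
#' obligate/non-obligate/non-biological classification. Two printed totals
#' (`n_both` of 1a15 and 1lfa) do not equal `n_first + n_second`; the table
#' is shipped exactly as published.
#'
#' @return A tibble with one row per complex.
#' @export
#' @examples
#' sum(reference_manifest()$n_first)
reference_manifest <- function() {
  path <- system.file("extdata", "table1_interfaces.tsv",
                      package = "dimerdyn", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Build a synthetic dataset manifest
#'
#' A seeded family of synthetic dimers with varied sizes and interface
#' densities, usable wherever a manifest of real structures would be. Dense
#' interfaces stand in for large type-I-like contact patches and sparse ones
#' for medium interfaces.
#'
#' @param n_entries Number of dimers.
#' @param seed Base seed; entry `i` uses `seed + i`.
#' @param n_first,n_second Chain lengths (recycled).
#' @param contacts Target inter-chain contact counts (recycled).
#' @param geometry Trace geometry (recycled).
#' @return A tibble manifest with columns `id`, `source`, `n_first`,
#'   `n_second`, `target_contacts`, `geometry`, `seed`, `interface_type`,
#'   `obligate_class`.
#' @export
synthetic_manifest <- function(n_entries = 6, seed = 1L,
                               n_first = c(24, 30, 36),
                               n_second = c(24, 30, 36),
                               contacts = c(18, 8, 12),
                               geometry = "compact_globule_pair") {
  i <- seq_len(n_entries)
  tibble::tibble(
    id = sprintf("synth%02d", i),
    source = "synthetic",
    n_first = rep_len(n_first, n_entries),
    n_second = rep_len(n_second, n_entries),
    target_contacts = rep_len(contacts, n_entries),
    geometry = rep_len(geometry, n_entries),
    seed = seed + i,
    interface_type = rep_len(c("I", "II", "III"), n_entries),
    obligate_class = rep_len(c("obligate", "non-obligate"), n_entries)
  )
}

resolve_manifest_entry <- function(entry) {
  if (identical(entry$source, "synthetic")) {
    make_dimer(synthetic_dimer_spec(
      n_first = entry$n_first, n_second = entry$n_second,
      target_interchain_contacts = entry$target_contacts,
      geometry = entry$geometry, seed = entry$seed
    ))
  } else {
    read_dimer(entry$source, c(entry$chain_first, entry$chain_second),
               metadata = list(pdb_id = entry$id,
                               interface_type = entry$interface_type,
                               obligate_class = entry$obligate_class))
  }
}

#' Run the interface-dynamics pipeline over a manifest
#'
#' For each manifest entry: resolve the dimer (synthetic generation or PDB
#' file), validate the zero-mode structure (entries with extra zero modes
#' are excluded with a recorded reason, mirroring the dataset filter),
#' compute bound/unbound RMSF profiles of the first chain in the subunit
#' frame, classify surface and interface residues from solvent
#' accessibility, and merge everything into a per-residue table. Dataset
#' level: RMSF distribution summaries for semi-interface vs
#' surface-not-interface residues (bound form, first chains), bound-vs-
#' unbound scatter with interpolating slopes per interface type and per
#' obligate class, and a mobility scenario label per complex. Deterministic
#' given manifest and configuration.
#'
#' @param manifest A tibble as from [synthetic_manifest()], or a manifest of
#'   PDB paths with columns `id`, `source` (file path), `chain_first`,
#'   `chain_second`, `interface_type`, `obligate_class`.
#' @param params [enm_params()].
#' @param probe_radius,n_points,rasa_threshold,delta_asa_min Accessibility
#'   settings, see [compute_asa()] and [classify_residues()].
#' @param mobility_threshold Threshold for distribution summaries and
#'   scenario labels (model units).
#' @return A `dimerdyn_run`: list with `residues` (per-residue table over
#'   all analyzed first chains: id, interface type, obligate class, RMSF
#'   bound/unbound, accessibility labels), `entries` (per-entry status,
#'   achieved contacts, interface area, semi-interface sizes, scenario
#'   label), `summaries` (distribution summaries), `slopes_by_type`,
#'   `slopes_by_class`, `config`.
#' @export
#' @examples
#' run <- run_pipeline(synthetic_manifest(2), n_points = 240)
#' glance(run)
run_pipeline <- function(manifest, params = enm_params(),
                         probe_radius = 1.4, n_points = 960,
                         rasa_threshold = 5, delta_asa_min = 0.1,
                         mobility_threshold = 1.0) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  params <- as_enm_params(params)
  config <- list(params = unclass(params), probe_radius = probe_radius,
                 n_points = n_points, rasa_threshold = rasa_threshold,
                 delta_asa_min = delta_asa_min,
                 mobility_threshold = mobility_threshold)

  entry_rows <- list(); res_rows <- list()
  for (k in seq_len(nrow(manifest))) {
    entry <- as.list(manifest[k, ])
    status <- tryCatch({
      dimer <- resolve_manifest_entry(entry)
      vr <- validate_for_enm(dimer, params)
      if (!vr$enm_suitable) {
        list(ok = FALSE, reason = paste0(
          "extra zero modes (complex ", vr$n_zero_modes_complex,
          ", first ", vr$n_zero_modes_first,
          ", second ", vr$n_zero_modes_second, ")"))
      } else {
        paired <- bound_unbound_profiles(dimer, params, validate = FALSE)
        ann <- dimer_accessibility(dimer, probe_radius, n_points,
                                   rasa_threshold, delta_asa_min)
        first_id <- attr(dimer$first, "chain_id")
        ann1 <- ann[ann$chain == first_id, ]
        merged <- dplyr::inner_join(
          paired,
          dplyr::select(ann1, "chain", "resno", "is_surface",
                        "is_interface", "delta_asa", "rasa_unbound"),
          by = c("chain", "resno")
        )
        merged$id <- entry$id
        merged$interface_type <- entry$interface_type %||% NA_character_
        merged$obligate_class <- entry$obligate_class %||% NA_character_
        scen <- classify_scenario(
          tibble::tibble(x = merged$rmsf_unbound[merged$is_interface],
                         y = merged$rmsf_bound[merged$is_interface]),
          mobility_threshold
        )
        list(ok = TRUE, merged = merged,
             interface_area = attr(ann, "interface_area"),
             semi = attr(ann, "semi_interface_sizes"),
             achieved = attr(dimer, "achieved_contacts"),
             scenario = if (sum(merged$is_interface) > 0) scen$label
                        else NA_character_)
      }
    }, error = function(e) list(ok = FALSE, reason = conditionMessage(e)))

    if (status$ok) {
      res_rows[[length(res_rows) + 1]] <- status$merged
      entry_rows[[length(entry_rows) + 1]] <- tibble::tibble(
        id = entry$id, analyzed = TRUE, reason = NA_character_,
        interface_area = status$interface_area,
        semi_interface_first = status$semi[1],
        semi_interface_second = status$semi[2],
        achieved_contacts = status$achieved %||% NA_integer_,
        scenario = status$scenario
      )
    } else {
      entry_rows[[length(entry_rows) + 1]] <- tibble::tibble(
        id = entry$id, analyzed = FALSE, reason = status$reason,
        interface_area = NA_real_, semi_interface_first = NA_integer_,
        semi_interface_second = NA_integer_,
        achieved_contacts = NA_integer_, scenario = NA_character_
      )
    }
  }

  residues <- dplyr::bind_rows(res_rows)
  entries <- dplyr::bind_rows(entry_rows)
  if (nrow(residues) == 0)
    stop("no manifest entry passed validation", call. = FALSE)

  semi_set <- residues[residues$is_interface, ]
  surf_set <- residues[residues$is_surface & !residues$is_interface, ]
  summaries <- list(
    semi_interface = if (nrow(semi_set) > 0)
      summarize_distribution(semi_set$rmsf_bound, mobility_threshold)
      else NULL,
    surface_not_interface = if (nrow(surf_set) > 0)
      summarize_distribution(surf_set$rmsf_bound, mobility_threshold)
      else NULL
  )
  slopes_by_type <- if (nrow(semi_set) > 0)
    scatter_and_fit(semi_set, group = "interface_type") else NULL
  slopes_by_class <- if (nrow(semi_set) > 0)
    scatter_and_fit(semi_set, group = "obligate_class") else NULL

  structure(
    list(residues = residues, entries = entries, summaries = summaries,
         slopes_by_type = slopes_by_type, slopes_by_class = slopes_by_class,
         config = config),
    class = "dimerdyn_run"
  )
}

#' @export
print.dimerdyn_run <- function(x, ...) {
  cat("dimerdyn run:", sum(x$entries$analyzed), "of", nrow(x$entries),
      "entries analyzed,", nrow(x$residues), "first-chain residues\n")
  if (!is.null(x$summaries$semi_interface)) {
    cat("  semi-interface bound RMSF:      ")
    print(x$summaries$semi_interface)
  }
  if (!is.null(x$summaries$surface_not_interface)) {
    cat("  surface-not-interface bound RMSF:")
    print(x$summaries$surface_not_interface)
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dimerdyn_run <- function(x, ...) {
  s1 <- x$summaries$semi_interface
  s2 <- x$summaries$surface_not_interface
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_analyzed = sum(x$entries$analyzed),
    n_residues = nrow(x$residues),
    n_semi_interface = sum(x$residues$is_interface),
    n_surface_not_interface =
      sum(x$residues$is_surface & !x$residues$is_interface),
    mean_rmsf_semi = if (!is.null(s1)) s1$mean else NA_real_,
    mean_rmsf_surface = if (!is.null(s2)) s2$mean else NA_real_,
    frac_below_semi = if (!is.null(s1)) s1$fraction_below else NA_real_,
    frac_below_surface = if (!is.null(s2)) s2$fraction_below else NA_real_
  )
}

#' @exportS3Method generics::tidy
tidy.dimerdyn_run <- function(x, ...) x$entries

#' Serialize a run summary to JSON
#'
#' Writes the per-entry table, distribution summaries, slopes and the full
#' configuration (every parameter echoed) as a JSON document; rerunning the
#' same manifest with the same configuration reproduces it byte for byte.
#'
#' @param run A `dimerdyn_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  stopifnot(inherits(run, "dimerdyn_run"))
  payload <- list(
    config = run$config,
    entries = run$entries,
    summaries = lapply(run$summaries, function(s)
      if (is.null(s)) NULL else glance(s)),
    slopes_by_type = if (!is.null(run$slopes_by_type))
      run$slopes_by_type$slopes else NULL,
    slopes_by_class = if (!is.null(run$slopes_by_class))
      run$slopes_by_class$slopes else NULL
  )
  jsonlite::write_json(payload, path, digits = 10, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
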