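# location of locally-provided full-atom structures for the 22 reference
# complexes (one <pdb_id>.pdb per entry); dataset-level tests require them
reference_structure_dir <- function() {
  cand <- c(getOption("dimerdyn.structure_dir", ""),
            Sys.getenv("DIMERDYN_STRUCTURE_DIR", ""),
            testthat::test_path("pdb_structures"),
            file.path("..", "..", "pdb_structures"))
  for (d in cand) if (nzchar(d) && dir.exists(d)) return(d)
  NA_character_
}

reference_file_manifest <- function(dir) {
  man <- reference_manifest()
  tibble::tibble(
    id = man$pdb_id,
    source = file.path(dir, paste0(man$pdb_id, ".pdb")),
    chain_first = man$chain_first,
    chain_second = man$chain_second,
    interface_type = man$interface_type,
    obligate_class = man$obligate_class
  )
}
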