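#' Load a packaged fixture
#'
#' Available fixtures:
#' * `"tdp43_lcd"`: TDP-43 low-complexity domain, residues 261-414 (154
#'   residues, 24 serines, all flagged as phosphosites), author numbering
#'   preserved.
#' * `"ck1d_truncated"`: CK1delta kinase domain sequence (residues 1-294)
#'   with the active site annotated at Asp149-Phe150-Gly151 and the whole
#'   domain as one rigid group.  Rigid-body coordinates are not bundled:
#'   pass `pdb_file` pointing to a local copy of PDB 6RU7 (or any
#'   coordinate file for residues 3-294); without it, an error explains
#'   what to fetch.
#' * `"ck1d_full_open"`, `"ck1d_full_closed"`: full-length CK1delta
#'   (1-415) requires user-supplied sequence and coordinates (UniProt
#'   P48730 / AlphaFold P48730 / PDB 6RU7); the loader errors with fetch
#'   instructions.
#' * `"toy_enzyme"`: the 4-bead rigid toy enzyme of
#'   [build_toy_validation_system()].
#' * `"hps_table"`, `"modified_hps_table"`: parameter sets via
#'   [load_parameter_set()].
#'
#' @param name fixture name.
#' @param pdb_file optional coordinate file for the kinase domain.
#' @return a `phos_sequence`, `phos_params`, or list as documented.
#' @export
load_fixture <- function(name, pdb_file = NULL) {
  extdata <- function(f) system.file("extdata", f, package = "phosdyn")
  switch(name,
    tdp43_lcd = read_sequence_fasta(extdata("tdp43_lcd.fasta")),
    ck1d_truncated = {
      sq <- read_sequence_fasta(extdata("ck1d_kinase.fasta"))
      sq$annotations$active_site <- c(149, 150, 151)
      sq$rigid_groups <- list(folded = sq$numbering)
      if (is.null(pdb_file))
        stop("fixture 'ck1d_truncated' needs rigid-body coordinates: ",
             "download PDB 6RU7 (https://www.rcsb.org/structure/6RU7) and ",
             "pass its path as pdb_file=, or use the sequence-only loader ",
             "load_fixture_sequence('ck1d_truncated')")
      if (!file.exists(pdb_file)) stop("coordinate file not found: ", pdb_file)
      list(sequence = sq, pdb_file = pdb_file)
    },
    ck1d_full_open = ,
    ck1d_full_closed = stop(
      "full-length CK1delta fixtures require user-supplied inputs: the ",
      "sequence from UniProt P48730 (residues 1-415) and coordinates from ",
      if (name == "ck1d_full_open") "PDB 6RU7 (open active site) "
      else "the AlphaFold entry P48730 (closed active site) ",
      "placed locally; they are not bundled"),
    toy_enzyme = build_toy_validation_system()$topology$chains[[2]],
    hps_table = load_parameter_set("hps"),
    modified_hps_table = load_parameter_set("modified_hps"),
    stop("unknown fixture '", name, "'")
  )
}

#' Sequence-only fixture loader
#'
#' Returns the bundled sequence for fixtures whose coordinates are
#' user-supplied, without demanding the coordinate file.
#'
#' @param name `"tdp43_lcd"` or `"ck1d_truncated"`.
#' @return `phos_sequence`.
#' @export
load_fixture_sequence <- function(name) {
  extdata <- function(f) system.file("extdata", f, package = "phosdyn")
  switch(name,
    tdp43_lcd = read_sequence_fasta(extdata("tdp43_lcd.fasta")),
    ck1d_truncated = {
      sq <- read_sequence_fasta(extdata("ck1d_kinase.fasta"))
      sq$annotations$active_site <- c(149, 150, 151)
      sq$rigid_groups <- list(folded = sq$numbering)
      sq
    },
    stop("unknown sequence fixture '", name, "'")
  )
}
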