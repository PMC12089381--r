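#' Construct a sequence model
#'
#' A chain of 1-letter residue codes with author (literature) numbering
#' preserved end-to-end, phosphosite annotations, rigid-group membership and
#' optional region annotations such as the kinase active site.
#'
#' @param codes character vector of 1-letter residue codes in chain order.
#' @param offset author number of the first residue (e.g. 261 for the TDP-43
#'   low-complexity domain).
#' @param phosphosites author numbers of phosphorylatable serines; defaults
#'   to every Ser in the chain.
#' @param rigid_groups named list of author-number vectors declaring rigid
#'   groups (must be disjoint).
#' @param annotations named list of author-number vectors (e.g.
#'   `active_site = c(149, 150, 151)`).
#' @param name chain label.
#' @return object of class `phos_sequence`.
#' @export
sequence_model <- function(codes, offset = 1L, phosphosites = NULL,
                           rigid_groups = list(), annotations = list(),
                           name = "chain") {
  stopifnot(length(codes) >= 1, all(nchar(codes) == 1))
  numbering <- seq.int(offset, length.out = length(codes))
  if (is.null(phosphosites)) phosphosites <- numbering[codes == "S"]
  if (!all(phosphosites %in% numbering[codes %in% c("S", "p")]))
    stop("phosphosites must be serine (or pSer) positions")
  if (length(rigid_groups) > 1 &&
      anyDuplicated(unlist(rigid_groups)) > 0)
    stop("rigid groups must be disjoint")
  structure(list(codes = codes, numbering = numbering, offset = offset,
                 phosphosites = sort(phosphosites),
                 rigid_groups = rigid_groups, annotations = annotations,
                 name = name),
            class = "phos_sequence")
}

#' @export
print.phos_sequence <- function(x, ...) {
  cat("<phos_sequence>", x$name, ":", length(x$codes), "residues, numbered",
      min(x$numbering), "-", max(x$numbering), "\n")
  cat("  phosphosites:", length(x$phosphosites),
      if (length(x$rigid_groups))
        paste0(" rigid groups: ", paste(names(x$rigid_groups), collapse = ", "))
      else "", "\n")
  invisible(x)
}

#' Read a FASTA file into a sequence model
#'
#' The header may carry `offset=N` to preserve author numbering.
#'
#' @param path FASTA file.
#' @param ... passed to [sequence_model()].
#' @return `phos_sequence`.
#' @export
read_sequence_fasta <- function(path, ...) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) != 1) stop("expected exactly one sequence in ", path)
  header <- names(aas)[1]
  offset <- 1L
  m <- regmatches(header, regexpr("offset=[0-9]+", header))
  if (length(m)) offset <- as.integer(sub("offset=", "", m))
  codes <- strsplit(as.character(aas[[1]]), "")[[1]]
  sequence_model(codes, offset = offset,
                 name = strsplit(header, " ")[[1]][1], ...)
}

#' Per-chain average bead parameters
#'
#' Arithmetic means of per-residue mass, sigma and hydropathy lambda over
#' the whole chain.  For the TDP-43 low-complexity domain (residues
#' 261-414) with the packaged HPS table this gives 98.957 amu, 0.54331 nm
#' and 0.64039.
#'
#' @param seq a `phos_sequence`.
#' @param params a `phos_params`.
#' @return named numeric vector `mass`, `sigma`, `lambda`.
#' @export
sequence_average_params <- function(seq, params) {
  if (length(seq$codes) == 0) stop("empty sequence")
  c(mass = mean(residue_param(params, seq$codes, "mass")),
    sigma = mean(residue_param(params, seq$codes, "sigma")),
    lambda = mean(residue_param(params, seq$codes, "lambda")))
}

#' Build an averaged-interaction sequence variant
#'
#' Replaces every non-Ser residue by a single averaged bead (code `"X"`)
#' whose mass, sigma and lambda are the whole-chain averages of the original
#' sequence and whose charge is zero.  Ser (and pSer) keep their own
#' parameters.  Two variants:
#'
#' * `"average_lambda"`: serines stay at their original positions;
#' * `"average_lambda_equi_ser"`: the same number of serines is spread at
#'   equal spacing over the chain (ties broken toward the N-terminus).
#'
#' @param seq a `phos_sequence`.
#' @param variant one of the two tags above.
#' @param params a `phos_params` used to compute the averages.
#' @return list with the new `sequence` (phos_sequence) and `params`
#'   (phos_params including the averaged bead row).
#' @export
build_sequence_variant <- function(seq, variant, params) {
  if (!variant %in% c("average_lambda", "average_lambda_equi_ser"))
    stop("variant must be 'average_lambda' or 'average_lambda_equi_ser'")
  n_ser <- sum(seq$codes == "S")
  if (n_ser == 0) stop("sequence has no Ser; nothing to phosphorylate")
  avg <- sequence_average_params(seq, params)
  n <- length(seq$codes)
  if (variant == "average_lambda") {
    ser_pos <- which(seq$codes == "S")
  } else {
    # equal spacing: k-th Ser at position round((k - 1/2) n / n_ser),
    # ties toward the N-terminus via floor of the midpoint rule
    ser_pos <- unique(pmax(1L, pmin(n, floor((seq_len(n_ser) - 0.5) * n / n_ser) + 1L)))
    stopifnot(length(ser_pos) == n_ser)
  }
  codes <- rep("X", n)
  codes[ser_pos] <- "S"
  new_params <- load_parameter_set(
    params$variant,
    overrides = list(table = data.frame(
      code = "X", mass = avg[["mass"]], sigma = avg[["sigma"]],
      lambda = avg[["lambda"]], charge = 0)))
  # the averaged variants carry no cation-pi enhancement (no aromatics left)
  new_seq <- sequence_model(codes, offset = seq$offset,
                            phosphosites = seq$numbering[ser_pos],
                            name = paste0(seq$name, "_", variant))
  list(sequence = new_seq, params = new_params)
}
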