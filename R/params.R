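#' Load a coarse-grained force-field parameter set
#'
#' Builds the residue-level parameter table (20 amino acids plus
#' phospho-serine, code `"p"`) and the global interaction constants of the
#' HPS model family.  Five variants are recognized:
#'
#' * `"hps"` - the plain hydropathy-scale model (no cation-pi enhancement);
#' * `"modified_hps"` - HPS with an additional cation-pi well of depth
#'   `cation_pi_epsilon` between \{R, K\} and \{F, W, Y\};
#' * `"no_charge"` - `modified_hps` with every charge zeroed except pSer;
#' * `"average_lambda"` and `"average_lambda_equi_ser"` - interaction
#'   constants as in `"hps"`; the sequence-side averaging is performed by
#'   [build_sequence_variant()].
#'
#' @param variant character tag, see above.
#' @param overrides named list of fields to override.  Scalar fields
#'   (`eps_ah`, `debye_length`, `dielectric`, `cation_pi_epsilon`,
#'   `folded_scale`, `cutoff_ah`, `cutoff_yukawa`, `bond_k`, `bond_r0`,
#'   `temperature`) replace the default; `table` may be a data frame with
#'   columns `code`, `mass`, `sigma`, `lambda`, `charge` replacing or
#'   extending rows of the default table.
#' @param table_file optional path to a user TSV table (columns `code`,
#'   `mass`, `sigma`, `lambda`, `charge`).
#' @return an object of class `phos_params`: a list with the residue `table`
#'   and the interaction constants.
#' @export
load_parameter_set <- function(variant = "hps", overrides = list(),
                               table_file = NULL) {
  variants <- c("hps", "modified_hps", "no_charge", "average_lambda",
                "average_lambda_equi_ser")
  if (!variant %in% variants)
    stop("unknown force-field variant '", variant, "'; expected one of: ",
         paste(variants, collapse = ", "))
  if (is.null(table_file))
    table_file <- system.file("extdata", "hps_table.tsv", package = "phosdyn")
  tab <- utils::read.delim(table_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("code", "mass", "sigma", "lambda", "charge")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  ps <- list(
    table = tab,
    eps_ah = 0.8368,            # kJ/mol (0.2 kcal/mol, HPS convention)
    debye_length = 1.0,         # nm, ~100 mM ionic strength
    dielectric = 80,
    cation_pi_epsilon = if (variant == "hps") 0 else 3.138, # kJ/mol
    folded_scale = 0.7,         # 30% reduction for folded-domain pairs
    cutoff_ah = 2.0,            # nm
    cutoff_yukawa = 3.5,        # nm
    bond_k = 8033,              # kJ/(mol nm^2), U = k/2 (r - r0)^2
    bond_r0 = 0.38,             # nm
    temperature = 300,          # K
    variant = variant
  )
  if (variant == "no_charge") {
    keep <- ps$table$code == "p"
    ps$table$charge[!keep] <- 0
  }
  for (nm in names(overrides)) {
    if (nm == "table") {
      ov <- overrides$table
      if (!all(need %in% names(ov)))
        stop("override table must have columns: ", paste(need, collapse = ", "))
      for (k in seq_len(nrow(ov))) {
        i <- match(ov$code[k], ps$table$code)
        if (is.na(i)) ps$table <- rbind(ps$table, ov[k, need])
        else ps$table[i, need] <- ov[k, need]
      }
    } else if (nm %in% names(ps)) {
      ps[[nm]] <- overrides[[nm]]
    } else {
      stop("override references unknown field '", nm, "'")
    }
  }
  validate_parameter_set(ps)
  class(ps) <- "phos_params"
  ps
}

validate_parameter_set <- function(ps) {
  tab <- ps$table
  if (anyDuplicated(tab$code)) stop("duplicate residue codes in table")
  if (any(tab$mass <= 0)) stop("residue masses must be positive")
  if (any(tab$sigma <= 0)) stop("residue sigma must be positive")
  if (any(tab$lambda < 0 | tab$lambda > 1))
    stop("hydropathy lambda must lie in [0, 1]")
  if (ps$folded_scale <= 0 || ps$folded_scale > 1)
    stop("folded_scale must lie in (0, 1]")
  if (ps$debye_length <= 0) stop("debye_length must be positive")
  if (ps$cutoff_ah <= 0 || ps$cutoff_yukawa <= 0)
    stop("cutoffs must be positive")
  invisible(ps)
}

#' @export
print.phos_params <- function(x, ...) {
  cat("<phos_params> variant:", x$variant, "\n")
  cat("  residues:", nrow(x$table),
      " eps_ah:", x$eps_ah, "kJ/mol",
      " cation-pi:", x$cation_pi_epsilon, "kJ/mol\n")
  cat("  debye:", x$debye_length, "nm  dielectric:", x$dielectric,
      "  folded scale:", x$folded_scale, "  T:", x$temperature, "K\n")
  invisible(x)
}

residue_param <- function(ps, code, field) {
  i <- match(code, ps$table$code)
  if (anyNA(i)) stop("missing residue entry: ",
                     paste(code[is.na(i)], collapse = ", "))
  ps$table[[field]][i]
}

#' Ashbaugh-Hatch pair energy
#'
#' Hydropathy-scaled truncated Lennard-Jones: below the Lennard-Jones
#' minimum `2^(1/6) sigma`,
#' `U = U_LJ(r) + (1 - lambda) epsilon`; for `2^(1/6) sigma < r <= cutoff`,
#' `U = lambda U_LJ(r)`; zero beyond the cutoff.  `U_LJ` is the 12-6
#' Lennard-Jones potential with well depth `epsilon`.  Continuous at the
#' minimum with value `-lambda epsilon`.  Vectorized over `r`.
#'
#' @param r distance, nm (> 0).
#' @param sigma pair vdW diameter, nm.
#' @param lambda pair hydropathy in \[0, 1\].
#' @param epsilon well depth, kJ/mol.
#' @param cutoff truncation distance, nm.
#' @return energy, kJ/mol.
#' @export
ashbaugh_hatch_energy <- function(r, sigma, lambda, epsilon, cutoff = 2.0) {
  if (any(r <= 0)) stop("r must be positive")
  s6 <- (sigma / r)^6
  ulj <- 4 * epsilon * (s6^2 - s6)
  rmin <- 2^(1 / 6) * sigma
  u <- ifelse(r <= rmin, ulj + (1 - lambda) * epsilon, lambda * ulj)
  ifelse(r > cutoff, 0, u)
}

#' Yukawa (screened Coulomb) pair energy
#'
#' `U = k_e qi qj exp(-r / debye_length) / (dielectric r)`, truncated at the
#' cutoff.  `k_e = 138.935458 kJ nm / (mol e^2)`.
#'
#' @param r distance, nm (> 0).
#' @param qi,qj charges, elementary units.
#' @param debye_length screening length, nm (> 0).
#' @param dielectric relative permittivity.
#' @param cutoff truncation distance, nm.
#' @return energy, kJ/mol.
#' @export
yukawa_energy <- function(r, qi, qj, debye_length = 1.0, dielectric = 80,
                          cutoff = 3.5) {
  if (any(r <= 0)) stop("r must be positive")
  if (debye_length <= 0) stop("debye_length must be positive")
  u <- 138.935458 * qi * qj * exp(-r / debye_length) / (dielectric * r)
  ifelse(r > cutoff, 0, u)
}

CATION <- c("R", "K")
AROMATIC <- c("F", "W", "Y")

#' Cation-pi pair energy
#'
#' Additional 12-6 well of depth `cation_pi_epsilon` between cation (R, K)
#' and aromatic (F, W, Y) residues, using the same arithmetic-mean sigma as
#' the Ashbaugh-Hatch term and the same cutoff.  Zero for all other pairs
#' and in the plain `hps` variant (where the well depth is 0).
#'
#' @param r distance, nm.
#' @param code_i,code_j 1-letter residue codes.
#' @param params a `phos_params` object.
#' @return energy, kJ/mol.
#' @export
cation_pi_energy <- function(r, code_i, code_j, params) {
  eps <- params$cation_pi_epsilon
  is_cpi <- (code_i %in% CATION & code_j %in% AROMATIC) |
            (code_j %in% CATION & code_i %in% AROMATIC)
  if (!any(is_cpi) || eps == 0) return(rep(0, length(r)))
  sigma <- 0.5 * (residue_param(params, code_i, "sigma") +
                  residue_param(params, code_j, "sigma"))
  s6 <- (sigma / r)^6
  u <- 4 * eps * (s6^2 - s6)
  ifelse(r > params$cutoff_ah | !is_cpi, 0, u)
}

#' Combined pair parameters for two beads
#'
#' Arithmetic-mean combination for sigma and lambda, plus the folded-domain
#' scale: 0.7 (by default) when at least one partner belongs to a rigid
#' folded group, else 1.  The scale multiplies the hydropathy-scaled
#' (attractive) part of the Ashbaugh-Hatch term and the cation-pi well;
#' electrostatics are unscaled.
#'
#' @param i,j bead indices (1-based).
#' @param topology a `phos_topology` object.
#' @param params a `phos_params` object.
#' @return list with `sigma_ij`, `lambda_ij`, `scale`.
#' @export
pair_params <- function(i, j, topology, params) {
  n <- nrow(topology$beads)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) stop("bead index out of range")
  ci <- topology$beads$code[i]; cj <- topology$beads$code[j]
  list(
    sigma_ij = 0.5 * (residue_param(params, ci, "sigma") +
                      residue_param(params, cj, "sigma")),
    lambda_ij = 0.5 * (residue_param(params, ci, "lambda") +
                       residue_param(params, cj, "lambda")),
    scale = if (topology$rigid[i] > 0 || topology$rigid[j] > 0)
      params$folded_scale else 1
  )
}

# Flatten a phos_params + topology into the list the C++ kernels expect.
# Types are indices into the parameter table (0-based on the C++ side).
engine_params <- function(topology, params) {
  tab <- params$table
  codes <- tab$code
  cpi <- matrix(0, nrow(tab), nrow(tab))
  if (params$cation_pi_epsilon != 0) {
    ic <- which(codes %in% CATION); ia <- which(codes %in% AROMATIC)
    cpi[ic, ia] <- params$cation_pi_epsilon
    cpi[ia, ic] <- params$cation_pi_epsilon
  }
  list(
    mass = tab$mass, sigma = tab$sigma, lambda = tab$lambda,
    charge = tab$charge, cpi = cpi,
    eps_ah = params$eps_ah, cut_ah = params$cutoff_ah,
    cut_yk = params$cutoff_yukawa, debye = params$debye_length,
    kcoul = 138.935458 / params$dielectric,
    folded_scale = params$folded_scale,
    bond_k = params$bond_k, bond_r0 = params$bond_r0
  )
}

type_index <- function(codes, params) {
  i <- match(codes, params$table$code)
  if (anyNA(i)) stop("missing residue entry: ",
                     paste(unique(codes[is.na(i)]), collapse = ", "))
  i - 1L
}
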