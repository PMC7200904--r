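#' In vitro dry matter disappearance
#'
#' DM digestibility of one in vitro step (pepsin-pancreatin hydrolysis or
#' microbial fermentation) from the dry weights before and after:
#' \deqn{IVDMD = 100 \cdot \frac{m_{before} - m_{residue}}{m_{before}}}
#'
#' @param mass_before Sample dry weight before the step, g DM (> 0).
#' @param residue_after Residue dry weight after the step, g DM
#'   (0 <= residue <= mass_before).
#' @return DM disappearance, %.
#' @export
#' @examples
#' ivdmd(2.000, 0.080)  # 96
ivdmd <- function(mass_before, residue_after) {
  if (any(mass_before <= 0)) stop("mass_before must be > 0", call. = FALSE)
  if (any(residue_after < 0) || any(residue_after > mass_before)) {
    stop("mass balance error: residue must lie in [0, mass_before]",
         call. = FALSE)
  }
  100 * (mass_before - residue_after) / mass_before
}

#' Combined total-tract in vitro DM digestibility
#'
#' Combines hydrolysis-step and fermentation-step DM disappearance: the
#' fermentation acts only on what hydrolysis left behind, so
#' \deqn{DMD = IVHDMD + (100 - IVHDMD) \cdot IVFDMD / 100}
#' (both arguments in percent). Bounded below by `max(ivhdmd, ivfdmd)`, above
#' by 100, and monotone in both arguments.
#'
#' @param ivhdmd Hydrolysis DM disappearance, % in \[0, 100\].
#' @param ivfdmd Fermentation DM disappearance (of the hydrolysis residue),
#'   % in \[0, 100\].
#' @return Total-tract DM digestibility, %.
#' @export
total_tract_dmd <- function(ivhdmd, ivfdmd) {
  if (any(ivhdmd < 0 | ivhdmd > 100) || any(ivfdmd < 0 | ivfdmd > 100)) {
    stop("digestibilities must lie in [0, 100]", call. = FALSE)
  }
  ivhdmd + (100 - ivhdmd) * ivfdmd / 100
}

# kcal released per mole of each fermentation acid
VFA_KCAL_PER_MOL <- c(acetate = 209, propionate = 365,
                      butyrate = 522, valerate = 678)

#' Energy released as volatile fatty acids
#'
#' Converts the fermentation VFA yield to an energy credit using molar
#' combustion energies of 0.209, 0.365, 0.522 and 0.678 Mcal/mol for acetate,
#' propionate, butyrate and valerate. Linear in each component.
#'
#' @param moles Named numeric vector of moles per kg of original sample DM;
#'   names among `acetate`, `propionate`, `butyrate`, `valerate` (missing
#'   acids contribute zero).
#' @return Energy release, kcal/kg sample DM.
#' @export
#' @examples
#' vfa_energy(c(acetate = 1))                     # 209
#' vfa_energy(c(acetate = 0.5, propionate = 0.5,
#'              butyrate = 0.5, valerate = 0.5))  # 887
vfa_energy <- function(moles) {
  if (length(moles) == 0) return(0)
  if (is.null(names(moles))) stop("'moles' must be named", call. = FALSE)
  unknown <- setdiff(names(moles), names(VFA_KCAL_PER_MOL))
  if (length(unknown)) {
    stop("unknown VFA: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(moles < 0)) stop("moles must be >= 0", call. = FALSE)
  sum(moles * VFA_KCAL_PER_MOL[names(moles)])
}

#' Convert VFA assay concentrations to moles per kg sample DM
#'
#' Bench sheets report VFA in mmol/L of fermentation supernatant; the energy
#' bookkeeping needs moles per kg of original sample DM. The conversion
#' volume (supernatant/buffer volume per fermentation bottle) and the sample
#' DM charged per bottle are explicit inputs.
#'
#' @param mmol_per_l Named numeric vector, mmol/L.
#' @param supernatant_l Supernatant volume per bottle, L (e.g. 0.030).
#' @param sample_g_dm Sample DM per bottle, g (e.g. 0.200).
#' @return Named numeric vector, mol/kg sample DM.
#' @export
vfa_moles_per_kg <- function(mmol_per_l, supernatant_l, sample_g_dm) {
  stopifnot(supernatant_l > 0, sample_g_dm > 0)
  mmol_per_l / 1000 * supernatant_l / (sample_g_dm / 1000)
}

#' In vitro total-tract digestible energy
#'
#' Energy that disappeared during hydrolysis plus the energy credited to
#' fermentation VFA, all per kg of original sample DM:
#' \deqn{DE_{ivt} = GE_{sample} - f_{res} \cdot GE_{residue} + E_{VFA}}
#' where `f_res` is the hydrolysis residue as a fraction of the original
#' sample DM, so the residue's energy density (per kg residue DM) is weighted
#' to the per-kg-of-sample scale before subtraction.
#'
#' @param ge_sample Sample gross energy, kcal/kg DM.
#' @param residue_fraction Hydrolysis residue mass / sample mass, in \[0, 1\].
#' @param ge_residue Residue gross energy, kcal/kg residue DM.
#' @param vfa_kcal VFA energy release, kcal/kg sample DM (see [vfa_energy]).
#' @return In vitro total-tract DE, kcal/kg sample DM.
#' @export
invitro_de <- function(ge_sample, residue_fraction, ge_residue, vfa_kcal = 0) {
  if (any(residue_fraction < 0 | residue_fraction > 1)) {
    stop("residue_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(ge_sample < 0) || any(ge_residue < 0) || any(vfa_kcal < 0)) {
    stop("energies must be >= 0", call. = FALSE)
  }
  de <- ge_sample - residue_fraction * ge_residue + vfa_kcal
  if (any(de > ge_sample + vfa_kcal + 1e-9)) {
    stop("mass balance error: DE exceeds GE + VFA energy", call. = FALSE)
  }
  de
}

#' Assemble a three-step in vitro result
#'
#' Bundles the hydrolysis and fermentation measurements of one sample into a
#' result row: step-wise and combined DM digestibility, VFA energy, and the
#' in vitro total-tract DE. The raw gas-production curve (hour, mL) is kept
#' as data only; no kinetic model is fitted.
#'
#' @param sample Sample name.
#' @param mass_pre_hydrolysis,residue_mass_hydrolysis g DM before/after
#'   hydrolysis.
#' @param ivfdmd Fermentation DM disappearance of the residue, %.
#' @param ge_sample,ge_residue kcal/kg DM of sample and hydrolysis residue.
#' @param vfa_moles Named vector of VFA mol/kg sample DM (see
#'   [vfa_moles_per_kg]).
#' @param om_digestibility Optional in vitro OM digestibility, g/kg DM (the
#'   input to the OMdv-based prediction equations; never derived here).
#' @param gas_curve Optional data frame with columns `hour`, `ml`.
#' @return A tibble row: sample, ivhdmd, ivfdmd, ivdmd_total, vfa_kcal,
#'   de_invitro, om_digestibility.
#' @export
invitro_result <- function(sample, mass_pre_hydrolysis,
                           residue_mass_hydrolysis, ivfdmd,
                           ge_sample, ge_residue, vfa_moles = numeric(),
                           om_digestibility = NA_real_, gas_curve = NULL) {
  ivh <- ivdmd(mass_pre_hydrolysis, residue_mass_hydrolysis)
  vfa <- vfa_energy(vfa_moles)
  tibble::tibble(
    sample = sample,
    ivhdmd = ivh,
    ivfdmd = ivfdmd,
    ivdmd_total = total_tract_dmd(ivh, ivfdmd),
    vfa_kcal = vfa,
    de_invitro = invitro_de(ge_sample,
                            residue_mass_hydrolysis / mass_pre_hydrolysis,
                            ge_residue, vfa),
    om_digestibility = om_digestibility,
    gas_curve = list(gas_curve)
  )
}
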