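#' Noninvasive cerebral perfusion pressure from transcranial Doppler
#'
#' The diastolic-velocity formula `nCPP = ABP * FVd / FVm + 14 mmHg`, where
#' FVd and FVm are the diastolic and mean middle-cerebral-artery blood
#' velocities (cm/s) and 14 mmHg is a preestablished calibration (zeroing)
#' constant. No clamping is applied. Vectorized.
#'
#' @param abp_mmHg Mean arterial pressure, mmHg (positive).
#' @param fvd_cm_s Diastolic MCA velocity, cm/s (nonnegative).
#' @param fvm_cm_s Mean MCA velocity, cm/s (positive).
#' @param calibration_mmHg Zeroing constant (default 14).
#' @return nCPP in mmHg.
#' @export
estimate_ncpp <- function(abp_mmHg, fvd_cm_s, fvm_cm_s,
                          calibration_mmHg = 14) {
  if (any(fvm_cm_s <= 0)) stop("division domain error: fvm must be positive")
  if (any(fvd_cm_s < 0)) stop("fvd must be nonnegative")
  if (any(abp_mmHg <= 0)) stop("abp must be positive")
  abp_mmHg * fvd_cm_s / fvm_cm_s + calibration_mmHg
}

#' TCD-based noninvasive ICP estimate
#'
#' `eICP_TCD = ABP - nCPP`; may be negative and is never clamped (the
#' published per-patient comparison table contains negative values). The
#' identity `eICP_TCD + nCPP = ABP` holds exactly.
#'
#' @inheritParams estimate_ncpp
#' @return eICP_TCD in mmHg.
#' @export
estimate_eicp_tcd <- function(abp_mmHg, fvd_cm_s, fvm_cm_s,
                              calibration_mmHg = 14) {
  abp_mmHg - estimate_ncpp(abp_mmHg, fvd_cm_s, fvm_cm_s, calibration_mmHg)
}
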