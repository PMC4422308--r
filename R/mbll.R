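# Modified Beer-Lambert law, two wavelengths x two chromophores.
#
# dOD(lambda) = eps_HbO2(lambda) * dC_HbO2 * L + eps_HbR(lambda) * dC_HbR * L
#
# The differential form cancels the scattering-loss term, and no division by
# a differential pathlength factor is applied: concentrations stay as
# concentration x pathlength products in mM*mm, the unit the channel
# statistics are reported in.

#' Extinction coefficient table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' measurement wavelengths, in 1/(mM*mm). Rows index wavelength, columns the
#' chromophores (HbO2, HbR).
#'
#' @param wavelengths Numeric pair of wavelengths in nm (default 760, 840).
#' @param eps 2x2 numeric matrix, rows = wavelengths, cols = (HbO2, HbR),
#'   units 1/(mM*mm). Default values come from a standard published
#'   hemoglobin extinction tabulation (Prahl's compilation, converted from
#'   1/(M*cm)); override to match a specific instrument calibration.
#' @return An object of class \code{extinction_table} with the condition
#'   number of \code{eps} attached.
#' @export
extinction_table <- function(wavelengths = c(760, 840),
                             eps = matrix(c(0.0586, 0.15485,
                                            0.1058, 0.07819),
                                          nrow = 2, byrow = TRUE,
                                          dimnames = list(c("760", "840"),
                                                          c("HbO2", "HbR")))) {
  stopifnot(length(wavelengths) == 2L, is.matrix(eps),
            all(dim(eps) == c(2L, 2L)))
  if (any(eps <= 0)) stop("extinction coefficients must be positive")
  kappa <- kappa(eps, exact = TRUE)
  structure(list(wavelengths = wavelengths, eps = eps, condition = kappa),
            class = "extinction_table")
}

#' Read extinction coefficients from CSV
#'
#' Expects columns \code{wavelength_nm}, \code{eps_hbo2}, \code{eps_hbr}
#' with exactly two rows.
#'
#' @param path CSV path.
#' @return An \code{extinction_table}.
#' @export
read_extinction_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(nrow(df) == 2L,
            all(c("wavelength_nm", "eps_hbo2", "eps_hbr") %in% names(df)))
  extinction_table(df$wavelength_nm,
                   matrix(c(df$eps_hbo2[1], df$eps_hbr[1],
                            df$eps_hbo2[2], df$eps_hbr[2]),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(as.character(df$wavelength_nm),
                                          c("HbO2", "HbR"))))
}

check_conditioning <- function(ext, limit = 1e8) {
  if (!is.finite(ext$condition) || ext$condition > limit)
    stop("ill-conditioned extinction matrix")
}

#' Forward modified Beer-Lambert map: concentrations to optical density
#'
#' Linear per-sample map from (delta-oxy, delta-deoxy) in mM*mm to the
#' optical-density change pair at the two wavelengths.
#'
#' @param conc 2 x n matrix (rows: oxy, deoxy; mM*mm) or length-2 vector.
#' @param ext An \code{extinction_table}.
#' @return 2 x n matrix of OD changes (rows: first, second wavelength).
#' @export
mbll_forward <- function(conc, ext = extinction_table()) {
  if (is.null(dim(conc))) conc <- matrix(conc, nrow = 2L)
  stopifnot(nrow(conc) == 2L)
  ext$eps %*% conc
}

#' Inverse modified Beer-Lambert map: optical density to concentrations
#'
#' Solves the 2x2 linear system per sample. Composition with
#' \code{\link{mbll_forward}} is the identity to machine precision.
#'
#' @param od 2 x n matrix of OD changes (rows: first, second wavelength) or
#'   length-2 vector.
#' @param ext An \code{extinction_table}; must be well-conditioned
#'   (condition number below 1e8).
#' @return 2 x n matrix of concentration-pathlength changes (rows: oxy,
#'   deoxy; mM*mm).
#' @export
mbll_inverse <- function(od, ext = extinction_table()) {
  check_conditioning(ext)
  if (is.null(dim(od))) od <- matrix(od, nrow = 2L)
  stopifnot(nrow(od) == 2L)
  if (any(!is.finite(od))) stop("non-finite optical-density input")
  solve(ext$eps, od)
}

#' Convert an optical-density recording to hemoglobin units
#'
#' Applies \code{\link{mbll_inverse}} channel-wise to a recording in
#' optical-density units; recordings already in hemoglobin units pass
#' through unchanged.
#'
#' @param r A \code{nirs_recording}.
#' @param ext An \code{extinction_table}.
#' @return A \code{nirs_recording} with unit \code{"hb_mM_mm"}.
#' @export
recording_to_hb <- function(r, ext = extinction_table()) {
  if (r$unit == HB_UNIT) return(r)
  check_conditioning(ext)
  inv <- solve(ext$eps)
  oxy <- inv[1, 1] * r$data$od760 + inv[1, 2] * r$data$od840
  deoxy <- inv[2, 1] * r$data$od760 + inv[2, 2] * r$data$od840
  nirs_recording(r$subject_id, list(oxy = oxy, deoxy = deoxy),
                 sampling_rate = r$sampling_rate, unit = HB_UNIT,
                 start_time = r$start_time)
}

#' Convert a hemoglobin recording to optical-density units
#'
#' Forward map used by the study simulator to emit wavelength-space
#' recordings.
#'
#' @param r A \code{nirs_recording} in hemoglobin units.
#' @param ext An \code{extinction_table}.
#' @return A \code{nirs_recording} with unit \code{"optical_density"}.
#' @export
recording_to_od <- function(r, ext = extinction_table()) {
  if (r$unit == OD_UNIT) return(r)
  e <- ext$eps
  od760 <- e[1, 1] * r$data$oxy + e[1, 2] * r$data$deoxy
  od840 <- e[2, 1] * r$data$oxy + e[2, 2] * r$data$deoxy
  nirs_recording(r$subject_id, list(od760 = od760, od840 = od840),
                 sampling_rate = r$sampling_rate, unit = OD_UNIT,
                 start_time = r$start_time)
}
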