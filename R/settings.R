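#' CT acquisition settings S1-S10
#'
#' The ten reconstruction/transmission variants studied: a reference
#' acquisition (S2: 1 mm slices, 1024x1024 matrix, B_SHARP_C kernel,
#' console export) perturbed one parameter at a time -- PACS transmission
#' (S1), slice thickness 3/5 mm (S3, S4), five alternative convolution
#' kernels (S5-S9) and a 512x512 matrix (S10).
#'
#' @return data.frame with columns `setting_id`, `slice_thickness_mm`,
#'   `matrix`, `kernel_id`, `transmission`; one row per setting S1..S10.
#' @export
#' @examples
#' acquisition_settings()
acquisition_settings <- function() {
  data.frame(
    setting_id = paste0("S", 1:10),
    slice_thickness_mm = c(1, 1, 3, 5, 1, 1, 1, 1, 1, 1),
    matrix = c(rep(1024L, 9), 512L),
    kernel_id = c("B_SHARP_C", "B_SHARP_C", "B_SHARP_C", "B_SHARP_C",
                  "B_SHARP_A", "B_VSHARP_D", "B_SOFT_C", "B_SOFT_F",
                  "B_VSOFT_A", "B_SHARP_C"),
    transmission = c("PACS", rep("console", 9)),
    stringsAsFactors = FALSE
  )
}

#' Reference setting identifier
#'
#' S2 is the reference acquisition against which all other settings are
#' compared; applying it to a volume generated at reference geometry is the
#' identity.
#' @return the string `"S2"`.
#' @export
reference_setting <- function() "S2"

#' Kernel smoothing/sharpening parameters
#'
#' The six proprietary convolution kernels are modelled as a one-parameter
#' blur/sharpen family preserving their ordinal soft-to-sharp structure:
#' soft kernels apply an in-plane Gaussian blur of the given sigma (mm),
#' sharp kernels unsharp masking of the given amount, and the reference
#' kernel (B_SHARP_C) is the identity. Values are a modelling choice, not a
#' claim of fidelity to any scanner's modulation transfer function; they can
#' be overridden via the `kernels` argument of [apply_setting()].
#'
#' @return data.frame with columns `kernel_id`, `op`
#'   (one of `"identity"`, `"blur"`, `"sharpen"`) and `param`
#'   (sigma in mm for blur, dimensionless amount for sharpen).
#' @export
kernel_params <- function() {
  data.frame(
    kernel_id = c("B_VSOFT_A", "B_SOFT_F", "B_SOFT_C",
                  "B_SHARP_A", "B_SHARP_C", "B_VSHARP_D"),
    op = c("blur", "blur", "blur", "sharpen", "identity", "sharpen"),
    param = c(0.7, 0.5, 0.3, 0.2, 0, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Setting groups for per-parameter stability analysis
#'
#' Maps each stability question to the settings that isolate it, always
#' including the reference S2: slice thickness {S2,S3,S4}, reconstruction
#' matrix {S2,S10}, convolution kernel {S2,S5..S9}, transmission {S1,S2}.
#'
#' @return named list of character vectors of setting ids.
#' @export
#' @examples
#' setting_group_plan()
setting_group_plan <- function() {
  plan <- list(
    slice_thickness = c("S2", "S3", "S4"),
    matrix = c("S2", "S10"),
    kernel = c("S2", "S5", "S6", "S7", "S8", "S9"),
    transmission = c("S1", "S2")
  )
  validate_group_plan(plan)
  plan
}

validate_group_plan <- function(plan) {
  ids <- acquisition_settings()$setting_id
  ref <- reference_setting()
  for (g in names(plan)) {
    if (!all(plan[[g]] %in% ids)) {
      stop("group '", g, "' contains unknown setting ids")
    }
    if (!ref %in% plan[[g]]) {
      stop("group '", g, "' must contain the reference setting ", ref)
    }
  }
  invisible(plan)
}
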