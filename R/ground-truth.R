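#' Ground-truth generative parameters for synthetic laminar datasets
#'
#' Encodes, per ROI family, the effects the simulator plants and the
#' downstream pipeline is expected to recover: a monotone superficial-bias
#' depth gain on stimulus-driven responses, crossmodal deactivation with a
#' planted (constant, linear) laminar shape, a spatially patchy crossmodal
#' modulation field correlated with the deactivation field, a multiplicative
#' pattern-preserving attentional gain weighted toward the surface, and
#' block-level noise with subject random effects.
#'
#' Defaults express the qualitative findings the simulator emulates: in
#' auditory ROIs the visual-induced deactivation is constant across depth
#' (C* = -1, L* = 0); in visual ROIs the auditory-induced deactivation grows
#' toward the surface (more negative superficially, L* = -0.2); attentional
#' gain scales the response pattern multiplicatively and increases toward the
#' surface; the crossmodal modulation field is patchy and correlates with the
#' deactivation field at `rho_deact_mod`.
#'
#' @param depth_gain 6-vector, multiplicative gain per depth (index 1 = white
#'   matter boundary, 6 = most superficial); strictly positive.
#' @param activation_mean mean stimulus-driven response amplitude (a.u.).
#' @param activation_patch_sd sd of the patchy vertex variation of the
#'   activation field.
#' @param deact_C,deact_L planted deactivation shape in auditory ROIs
#'   (constant, per-depth-step slope).
#' @param deact_C_visual,deact_L_visual planted deactivation shape in visual
#'   ROIs.
#' @param deact_patch_sd sd of the patchy vertex variation of the
#'   deactivation constant.
#' @param mod_C,mod_L planted crossmodal-modulation shape (applies to AV
#'   versus the ROI's preferred unisensory condition).
#' @param mod_patch_sd sd of the patchy sign-varying modulation field.
#' @param rho_deact_mod target correlation between the deactivation and
#'   modulation patchy fields, in [-1, 1].
#' @param attention_gain multiplicative attentional gain gamma (>= 0) applied
#'   when the ROI's preferred modality is attended.
#' @param attention_depth_weight 6-vector weighting the attentional gain
#'   across depth (increasing toward the surface by default).
#' @param noise_sd block-level Gaussian noise sd on every beta.
#' @param subject_sd_C,subject_sd_L sd of Gaussian subject random effects on
#'   the planted deactivation (C*, L*).
#' @param field_corr_length correlation length (grid units) of all patchy
#'   fields.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(depth_gain = seq(1, 2, length.out = 6),
                         activation_mean = 2,
                         activation_patch_sd = 0.4,
                         deact_C = -1, deact_L = 0,
                         deact_C_visual = -1, deact_L_visual = -0.2,
                         deact_patch_sd = 0.4,
                         mod_C = 0.3, mod_L = 0,
                         mod_patch_sd = 0.5,
                         rho_deact_mod = 0.5,
                         attention_gain = 0.2,
                         attention_depth_weight = seq(0.5, 1.5, length.out = 6),
                         noise_sd = 0.5,
                         subject_sd_C = 0.2, subject_sd_L = 0.05,
                         field_corr_length = 3) {
  stopifnot_positive(depth_gain = depth_gain)
  if (attention_gain < 0) stop("attention_gain must be >= 0", call. = FALSE)
  if (abs(rho_deact_mod) > 1) {
    stop("rho_deact_mod must lie in [-1, 1]", call. = FALSE)
  }
  if (length(depth_gain) != 6L || length(attention_depth_weight) != 6L) {
    stop("depth_gain and attention_depth_weight must have length 6",
         call. = FALSE)
  }
  vals <- mget(names(formals(ground_truth)))
  if (any(!is.finite(unlist(vals)))) {
    stop("all ground-truth parameters must be finite", call. = FALSE)
  }
  structure(vals, class = "ground_truth")
}

## ROI family conventions: auditory ROIs prefer A, deactivate to V, are
## modulated in AV vs A, and gain from auditory attention; visual ROIs mirror.
roi_family <- function(roi_name) {
  if (grepl("^V", roi_name)) "visual" else "auditory"
}
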