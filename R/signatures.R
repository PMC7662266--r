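#' Gait-class signatures
#'
#' A class signature is the small set of biomechanical parameters that the
#' synthetic cohort generator uses to tell the five gait classes apart:
#'
#' * `stance_fraction_left`, `stance_fraction_right` — fraction of the stride
#'   during which each foot is in ground contact (0-1). Normal walking spends
#'   about 60% of the cycle in stance; an unstable foot deviates from that and
#'   shortens its step.
#' * `heel_metatarsal_gap` — seconds between heel contact and metatarsal
#'   (medial forefoot) contact. Supination (toe-out gait) reduces this gap
#'   relative to normal; pronation (toe-in gait), as the opposite movement,
#'   lengthens it.
#' * `lateral_weight_share` — fraction of forefoot load carried by the lateral
#'   sensor as opposed to the medial one (0-1; 0.5 = even). Both toe-angle
#'   abnormalities shift load laterally in this model: strongly for
#'   supination, where the lateral border carries the body mass, and
#'   moderately for pronation (toe-in), where the inward-turned toes shift
#'   weight to the outside of the foot. The direction is a plain parameter and
#'   can be overridden for users who prefer the conventional medially-loaded
#'   description of pronation.
#' * `step_length_scale_left`, `step_length_scale_right` — multipliers on the
#'   step taken onto each foot; an unstable foot takes a shortened step
#'   (scale < 1), which also weakens that leg's swing.
#'
#' Defaults encode the qualitative directions of each abnormality as roughly
#' 15-30% deviations from normal; every value can be overridden.
#'
#' @param gait_class One of [gait_classes()].
#' @param overrides Named list of signature fields to override.
#' @return A list of class `"gait_signature"` with the fields above plus
#'   `gait_class`.
#' @examples
#' class_signature("normal")$stance_fraction_left
#' class_signature("supination", overrides = list(lateral_weight_share = 0.8))
#' @export
class_signature <- function(gait_class, overrides = list()) {
  classes <- gait_classes()
  if (length(gait_class) != 1L || !gait_class %in% classes) {
    stop("unknown gait class ", deparse(gait_class), "; valid classes are: ",
         paste(classes, collapse = ", "))
  }
  defaults <- list(
    normal = list(
      stance_fraction_left = 0.60, stance_fraction_right = 0.60,
      heel_metatarsal_gap = 0.12, lateral_weight_share = 0.50,
      step_length_scale_left = 1.00, step_length_scale_right = 1.00
    ),
    unstable_left = list(
      stance_fraction_left = 0.52, stance_fraction_right = 0.62,
      heel_metatarsal_gap = 0.12, lateral_weight_share = 0.50,
      step_length_scale_left = 0.75, step_length_scale_right = 1.00
    ),
    unstable_right = list(
      stance_fraction_left = 0.62, stance_fraction_right = 0.52,
      heel_metatarsal_gap = 0.12, lateral_weight_share = 0.50,
      step_length_scale_left = 1.00, step_length_scale_right = 0.75
    ),
    supination = list(
      stance_fraction_left = 0.60, stance_fraction_right = 0.60,
      heel_metatarsal_gap = 0.05, lateral_weight_share = 0.75,
      step_length_scale_left = 1.00, step_length_scale_right = 1.00
    ),
    pronation = list(
      stance_fraction_left = 0.60, stance_fraction_right = 0.60,
      heel_metatarsal_gap = 0.19, lateral_weight_share = 0.65,
      step_length_scale_left = 1.00, step_length_scale_right = 1.00
    )
  )
  sig <- defaults[[gait_class]]
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(sig))
    if (length(bad)) {
      stop("unknown signature field(s): ", paste(bad, collapse = ", "))
    }
    sig[names(overrides)] <- overrides
  }
  fracs <- c("stance_fraction_left", "stance_fraction_right",
             "lateral_weight_share")
  for (f in fracs) {
    v <- sig[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("signature field ", f, " must be a fraction in (0, 1), got ",
           format(v))
    }
  }
  for (f in c("heel_metatarsal_gap", "step_length_scale_left",
              "step_length_scale_right")) {
    v <- sig[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop("signature field ", f, " must be a non-negative number")
    }
  }
  sig$gait_class <- gait_class
  class(sig) <- "gait_signature"
  sig
}
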