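# The seven Maddox cue conditions. Codes follow the field convention:
# upper-case letters are stimulated cues (B blur, D disparity, P proximal),
# the suffix after "-" lists diminished cues. Binocular conditions collect
# 30 movements per session (15 far-to-near + 15 near-to-far, interleaved);
# monocular conditions repeat per eye for 60.

CUE_CODES <- c("BDP", "BD-p", "BP-d", "DP-b", "B-dp", "D-bp", "P-bd")
MONOCULAR_CUES <- c("B-dp", "P-bd", "BP-d")

#' The seven Maddox cue conditions of the step-response protocol
#'
#' @return A tibble with one row per cue condition: `code`, `presentation`
#'   (`"binocular"` or `"monocular"`), and `movements_per_session` (30 for
#'   binocular cues, 60 for monocular cues, far-to-near and near-to-far
#'   interleaved in equal numbers).
#' @examples
#' cue_conditions()
#' @export
cue_conditions <- function() {
  presentation <- ifelse(CUE_CODES %in% MONOCULAR_CUES, "monocular", "binocular")
  tibble::tibble(
    code = CUE_CODES,
    presentation = presentation,
    movements_per_session = ifelse(presentation == "monocular", 60L, 30L)
  )
}

cue_movement_count <- function(code) {
  code <- match.arg(code, CUE_CODES)
  if (code %in% MONOCULAR_CUES) 60L else 30L
}

#' Per-cue final-amplitude gain table
#'
#' Default expected response gains (final amplitude / stimulated demand) for
#' each cue condition, used by the synthetic-cohort generator: near-unity
#' for the all-cue and blur+disparity conditions, intermediate for the other
#' blur- or disparity-containing conditions, and low for the isolated
#' proximal cue.
#'
#' @return Named numeric vector of gains in `[0, 1.2]`, one per cue code.
#' @examples
#' default_gain_table()
#' @export
default_gain_table <- function() {
  c("BDP" = 0.97, "BD-p" = 0.97, "BP-d" = 0.80, "B-dp" = 0.71,
    "DP-b" = 0.60, "D-bp" = 0.55, "P-bd" = 0.33)
}
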