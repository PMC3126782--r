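#' Canonical sample labels
#'
#' The six-library study design: female/male bodies (FB, MB), antennae
#' (FA, MA) and maxillary palps (FP, MP).  `SAMPLE_LABELS` is the
#' simulation order; `PROFILE_ORDER` is the fixed heatmap/report order used
#' by [family_profile()].
#'
#' @format Character vectors of length 6.
#' @export
SAMPLE_LABELS <- c("FB", "FA", "FP", "MB", "MA", "MP")

#' @rdname SAMPLE_LABELS
#' @export
PROFILE_ORDER <- c("FP", "FB", "FA", "MA", "MB", "MP")

BODY_OF <- c(FA = "FB", FP = "FB", MA = "MB", MP = "MB")

#' Published cross-sex normalization constants
#'
#' Named constants used to place male appendage expression on a
#' female-equivalent scale, with the morphological or expression basis each
#' one derives from:
#'
#' * `trichoid_sensilla`: mean antennal trichoid sensilla counts from
#'   published morphological surveys of adult *Anopheles gambiae*
#'   (female 630, male 225; ratio 2.8). Odorant receptors (Or) are expressed
#'   in trichoid-sensilla neurons.
#' * `orco_rpkm`: antennal RPKM of the obligate odorant-receptor
#'   co-receptor Orco in the source six-library survey (female antennae 916,
#'   male antennae 186; ratio 4.9), an expression-based alternative to
#'   sensilla counts.
#' * `grooved_peg_factor`: female:male fold-difference in grooved-peg
#'   sensilla counts (4.2), the sensillar class housing ionotropic-receptor
#'   (Ir) neurons.
#' * `palp_factor`: female:male capitate-peg factor used for maxillary
#'   palps (4).
#'
#' The underlying counts for the last two factors are not re-derivable here;
#' they ship as fixed values (basis `"fixed"`).
#'
#' @seealso [normalization_factor()], [derive_orco_factor()],
#'   [normalize_profile()]
#' @format A named list.
#' @export
NORMALIZATION_CONSTANTS <- list(
  trichoid_sensilla = c(female = 630, male = 225),
  orco_rpkm = c(female_antennae = 916, male_antennae = 186),
  grooved_peg_factor = 4.2,
  palp_factor = 4
)
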