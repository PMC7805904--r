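# Body-segment inertial-parameter regression table (version 1).
#
# Sex-specific segment mass fractions, longitudinal COM positions and radii of
# gyration follow the adjusted Zatsiorsky-Seluyanov regressions published by
# de Leva (1996); segment lengths are expressed as fractions of stature using
# standard anthropometric landmark ratios. Mass fractions are renormalised so
# that the 16 body segments sum exactly to the total body mass.
#
# Columns:
#   segment    one of the 10 segment types (paired segments appear once)
#   mass_frac  segment mass / total body mass
#   com_frac   COM distance from the proximal end / segment length
#   r_sag, r_trn, r_lng  radii of gyration / segment length, about the
#              anteroposterior, mediolateral and longitudinal axes through
#              the segment COM
#   len_frac   segment length / stature
#   paired     TRUE for left/right segment pairs

bsp_table_version <- "deleva-adjusted-1"

.bsp_raw <- function(sex) {
  if (sex == "male") {
    df <- data.frame(
      segment   = c("head", "upper_trunk", "mid_trunk", "pelvis",
                    "upper_arm", "forearm", "hand", "thigh", "shank", "foot"),
      mass_frac = c(0.0694, 0.1596, 0.1633, 0.1117,
                    0.0271, 0.0162, 0.0061, 0.1416, 0.0433, 0.0137),
      com_frac  = c(0.5976, 0.2999, 0.4502, 0.6115,
                    0.5772, 0.4574, 0.7900, 0.4095, 0.4459, 0.4415),
      r_sag     = c(0.362, 0.716, 0.482, 0.615,
                    0.285, 0.276, 0.628, 0.329, 0.255, 0.257),
      r_trn     = c(0.376, 0.454, 0.383, 0.551,
                    0.269, 0.265, 0.513, 0.329, 0.249, 0.245),
      r_lng     = c(0.312, 0.659, 0.468, 0.587,
                    0.158, 0.121, 0.401, 0.149, 0.103, 0.124)
    )
  } else {
    df <- data.frame(
      segment   = c("head", "upper_trunk", "mid_trunk", "pelvis",
                    "upper_arm", "forearm", "hand", "thigh", "shank", "foot"),
      mass_frac = c(0.0668, 0.1545, 0.1465, 0.1247,
                    0.0255, 0.0138, 0.0056, 0.1478, 0.0481, 0.0129),
      com_frac  = c(0.5894, 0.2077, 0.4512, 0.4920,
                    0.5754, 0.4559, 0.7474, 0.3612, 0.4416, 0.4014),
      r_sag     = c(0.330, 0.746, 0.433, 0.433,
                    0.278, 0.261, 0.531, 0.369, 0.271, 0.299),
      r_trn     = c(0.359, 0.502, 0.354, 0.402,
                    0.260, 0.257, 0.454, 0.364, 0.267, 0.279),
      r_lng     = c(0.318, 0.718, 0.415, 0.444,
                    0.148, 0.094, 0.335, 0.162, 0.093, 0.139)
    )
  }
  # segment length as fraction of stature (landmark ratios, sex-shared)
  df$len_frac <- c(0.182, 0.100, 0.120, 0.068,
                   0.186, 0.146, 0.108, 0.245, 0.246, 0.152)
  df$paired <- c(FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  df
}

#' Body-segment parameter regression table
#'
#' Returns the versioned sex-specific table of segment mass fractions,
#' longitudinal COM positions, radii of gyration and segment-length stature
#' fractions used by [de_leva_parameters()]. Mass fractions are renormalised
#' so that a whole body (paired segments counted twice) sums exactly to 1.
#'
#' @param sex `"female"` or `"male"`.
#' @return A data frame with one row per segment type and attribute
#'   `"version"` identifying the table revision.
#' @export
bsp_table <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  df <- .bsp_raw(sex)
  total <- sum(df$mass_frac * ifelse(df$paired, 2, 1))
  df$mass_frac <- df$mass_frac / total
  attr(df, "version") <- bsp_table_version
  df
}

## the 16 canonical whole-body segments, with their table row and side
.segment_list <- function() {
  data.frame(
    name = c("pelvis", "mid_trunk", "upper_trunk", "head",
             "thigh_l", "shank_l", "foot_l", "thigh_r", "shank_r", "foot_r",
             "upper_arm_l", "forearm_l", "hand_l",
             "upper_arm_r", "forearm_r", "hand_r"),
    type = c("pelvis", "mid_trunk", "upper_trunk", "head",
             "thigh", "shank", "foot", "thigh", "shank", "foot",
             "upper_arm", "forearm", "hand",
             "upper_arm", "forearm", "hand"),
    side = c(NA, NA, NA, NA,
             "left", "left", "left", "right", "right", "right",
             "left", "left", "left", "right", "right", "right"),
    stringsAsFactors = FALSE
  )
}
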