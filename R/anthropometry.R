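# Subject anthropometry and segment inertial parameters.

#' Subject anthropometry
#'
#' Validated container of the subject measurements that drive the
#' segment-parameter regression: sex, total body mass, stature and the
#' hip-to-ankle leg length, plus an optional prosthesis specification.
#'
#' @param sex `"female"` or `"male"`.
#' @param total_mass body mass in kg (> 0).
#' @param total_height stature in m (> 0).
#' @param leg_length hip-to-ankle length in m; defaults to 0.491 * stature,
#'   the landmark ratio implied by the segment-length table.
#' @param prosthesis optional list `list(side =, mass_ratio =, ...)` where
#'   `side` is `"left"` or `"right"` and `mass_ratio` in (0, 1] is the mass of
#'   the prosthetic leg relative to the contralateral leg. Optional
#'   per-segment overrides (see [apply_prosthesis()]) may be included.
#' @return An object of class `subject_anthro`.
#' @export
subject_anthropometry <- function(sex, total_mass, total_height,
                                  leg_length = NULL, prosthesis = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(is.numeric(total_mass), length(total_mass) == 1, total_mass > 0,
            is.numeric(total_height), length(total_height) == 1,
            total_height > 0)
  if (is.null(leg_length)) leg_length <- 0.491 * total_height
  stopifnot(is.numeric(leg_length), leg_length > 0)
  if (leg_length >= total_height)
    stop("leg_length must be smaller than total_height")
  if (!is.null(prosthesis)) {
    if (is.null(prosthesis$side) ||
        !prosthesis$side %in% c("left", "right"))
      stop("prosthesis$side must be 'left' or 'right'")
    mr <- prosthesis$mass_ratio
    if (!is.numeric(mr) || length(mr) != 1 || mr <= 0 || mr > 1)
      stop("prosthesis$mass_ratio must be in (0, 1]")
  }
  structure(list(sex = sex, total_mass = total_mass,
                 total_height = total_height, leg_length = leg_length,
                 prosthesis = prosthesis),
            class = "subject_anthro")
}

#' @export
print.subject_anthro <- function(x, ...) {
  cat("Subject anthropometry\n")
  cat(sprintf("  sex: %s, mass: %.1f kg, height: %.2f m, leg length: %.3f m\n",
              x$sex, x$total_mass, x$total_height, x$leg_length))
  if (!is.null(x$prosthesis))
    cat(sprintf("  prosthesis: %s side, mass ratio %.2f\n",
                x$prosthesis$side, x$prosthesis$mass_ratio))
  invisible(x)
}

## local-frame conventions per segment type:
##  * legs, arms, trunk, head: origin at the proximal joint, longitudinal axis
##    along local z (distal end at -z for limbs hanging/standing, +z for trunk
##    segments and the head which extend upward from their proximal joint)
##  * foot: origin at the ankle, longitudinal axis along +x (anterior); the
##    heel lies at x = -0.25 * foot length, the sole at z = -ankle height
.seg_direction <- function(type) {
  if (type %in% c("pelvis", "mid_trunk", "upper_trunk", "head")) c(0, 0, 1)
  else if (type == "foot") c(1, 0, 0)
  else c(0, 0, -1)
}

.foot_heel_frac <- 0.25   # ankle sits above 25 % of foot length from the heel

#' Segment inertial parameters from anthropometric regression
#'
#' Computes mass, COM offset, inertia tensor (about the segment COM, in the
#' segment frame) and length for each of the 16 whole-body segments from the
#' sex-specific regression table returned by [bsp_table()]. Masses are
#' fractions of total body mass; lengths scale with stature; radii of gyration
#' scale with segment length so the inertia scales with mass * length^2.
#'
#' @param anthro a [subject_anthropometry()] object.
#' @param apply_prosthesis if `TRUE` (default) and `anthro$prosthesis` is set,
#'   the prosthesis mass scaling is applied via [apply_prosthesis()].
#' @return An object of class `segment_params`: a list of per-segment lists
#'   with elements `name`, `type`, `side`, `mass` (kg), `com_offset` (m,
#'   local frame), `inertia` (3x3, kg m^2, about the COM) and `length` (m).
#' @export
de_leva_parameters <- function(anthro, apply_prosthesis = TRUE) {
  stopifnot(inherits(anthro, "subject_anthro"))
  tab <- bsp_table(anthro$sex)
  segs <- .segment_list()
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    row <- tab[tab$segment == segs$type[i], ]
    if (nrow(row) != 1)
      stop("segment type not in regression table: ", segs$type[i])
    len <- row$len_frac * anthro$total_height
    mass <- row$mass_frac * anthro$total_mass
    dir <- .seg_direction(segs$type[i])
    if (segs$type[i] == "foot") {
      ankle_h <- 0.039 * anthro$total_height
      com <- c((row$com_frac - .foot_heel_frac) * len, 0, -0.5 * ankle_h)
      # foot longitudinal axis is x: (x, y, z) <- (r_lng, r_sag, r_trn)
      radii <- c(row$r_lng, row$r_sag, row$r_trn) * len
    } else {
      com <- dir * row$com_frac * len
      radii <- c(row$r_sag, row$r_trn, row$r_lng) * len
    }
    out[[i]] <- list(name = segs$name[i], type = segs$type[i],
                     side = segs$side[i], mass = mass,
                     com_offset = com, inertia = diag(mass * radii^2),
                     length = len)
  }
  names(out) <- segs$name
  attr(out, "anthro") <- anthro
  attr(out, "bsp_version") <- attr(tab, "version")
  class(out) <- "segment_params"
  if (apply_prosthesis && !is.null(anthro$prosthesis))
    out <- apply_prosthesis(out, anthro$prosthesis)
  out
}

#' @export
print.segment_params <- function(x, ...) {
  cat(sprintf("Segment parameters (%d segments, table %s)\n",
              length(x), attr(x, "bsp_version")))
  df <- as.data.frame(x)
  print(df[, c("name", "mass", "length")], row.names = FALSE, digits = 4)
  cat(sprintf("  total mass: %.4f kg\n", sum(df$mass)))
  invisible(x)
}

#' @export
as.data.frame.segment_params <- function(x, ...) {
  data.frame(name = vapply(x, `[[`, "", "name"),
             type = vapply(x, `[[`, "", "type"),
             side = vapply(x, function(s) s$side %||% NA_character_, ""),
             mass = vapply(x, `[[`, 0, "mass"),
             length = vapply(x, `[[`, 0, "length"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Apply a prosthesis mass model to one leg
#'
#' Scales the thigh, shank and foot of the prosthesis side so that their total
#' mass equals `mass_ratio` times the total mass of the contralateral leg.
#' Scaling is uniform across the three segments by default; inertia tensors
#' scale with the same factor (COM offsets unchanged). Measured per-segment
#' data can be injected through `overrides`, a named list
#' (`thigh`/`shank`/`foot`) of lists with any of `mass`, `com_offset`,
#' `inertia`; overridden segments are excluded from the uniform scaling and
#' the remaining segments absorb the residual so the leg mass ratio is exact.
#'
#' @param segments a `segment_params` object (16 segments).
#' @param prosthesis list with `side`, `mass_ratio` and optional `overrides`.
#' @return The modified `segment_params` object.
#' @export
apply_prosthesis <- function(segments, prosthesis) {
  stopifnot(inherits(segments, "segment_params"))
  side <- match.arg(prosthesis$side, c("left", "right"))
  ratio <- prosthesis$mass_ratio
  if (!is.numeric(ratio) || ratio <= 0)
    stop("prosthesis mass_ratio must be positive")
  sfx <- if (side == "left") "_l" else "_r"
  osfx <- if (side == "left") "_r" else "_l"
  leg <- paste0(c("thigh", "shank", "foot"), sfx)
  contra <- paste0(c("thigh", "shank", "foot"), osfx)
  if (!all(leg %in% names(segments)))
    stop("prosthesis-side leg segments missing from model")
  target <- ratio * sum(vapply(segments[contra], `[[`, 0, "mass"))
  overrides <- prosthesis$overrides %||% list()
  fixed <- 0; free <- character()
  for (s in c("thigh", "shank", "foot")) {
    nm <- paste0(s, sfx)
    ov <- overrides[[s]]
    if (!is.null(ov)) {
      if (!is.null(ov$mass)) segments[[nm]]$mass <- ov$mass
      if (!is.null(ov$com_offset)) segments[[nm]]$com_offset <- ov$com_offset
      if (!is.null(ov$inertia)) segments[[nm]]$inertia <- ov$inertia
      fixed <- fixed + segments[[nm]]$mass
    } else free <- c(free, nm)
  }
  if (length(free)) {
    base <- sum(vapply(segments[free], `[[`, 0, "mass"))
    k <- (target - fixed) / base
    if (k <= 0)
      stop("prosthesis overrides exceed the target leg mass")
    for (nm in free) {
      segments[[nm]]$mass <- k * segments[[nm]]$mass
      segments[[nm]]$inertia <- k * segments[[nm]]$inertia
    }
  }
  attr(segments, "prosthesis") <- prosthesis
  segments
}

#' Read a subject description from YAML or JSON
#'
#' Expected keys: `sex`, `mass_kg`, `height_m`, optional `leg_length_m` and
#' `prosthesis: {side, mass_ratio, overrides...}`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A [subject_anthropometry()] object.
#' @export
read_subject <- function(path) {
  if (!file.exists(path)) stop("subject file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  subject_anthropometry(sex = x$sex, total_mass = x$mass_kg,
                        total_height = x$height_m,
                        leg_length = x$leg_length_m %||% NULL,
                        prosthesis = x$prosthesis)
}
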