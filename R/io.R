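# File I/O: marker trajectories (TRC, CSV), marker-set and subject
# configuration (YAML), trajectory/metrics exports (CSV + JSON).
#
# Internal units are strictly SI (m, kg, s, rad); conversions happen only
# at these boundaries, driven by explicit unit metadata - never guessed.

#' Read marker trajectories
#'
#' @param path input file.
#' @param format `"trc"`, `"csv"` or `"c3d"` (guessed from the extension
#'   by default). C3D is a binary vendor format not supported by this
#'   build; TRC or CSV exports are expected instead.
#' @param units for CSV input, the length unit of the coordinates
#'   (`"m"` or `"mm"`); mandatory because bare CSV carries no unit
#'   metadata. TRC files carry their unit in the header.
#' @return marker data list (`times`, `markers` n x m x 3 array, `valid`)
#'   as consumed by [fit_trajectory()].
#' @export
read_markers <- function(path, format = NULL, units = NULL) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         trc = .read_trc(path),
         csv = .read_marker_csv(path, units),
         c3d = stop("C3D input is not supported by this build; export ",
                    "the trial as TRC or CSV"),
         stop("unknown marker format: ", format))
}

.unit_scale <- function(units) {
  switch(units,
         m = 1, mm = 1e-3,
         stop("unsupported length unit: '", units, "' (use m or mm)"))
}

.read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1]))
    stop("not a TRC file (missing PathFileType header): ", path)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  units <- hdr_vals[match("Units", hdr_names)]
  if (is.na(units)) stop("TRC header missing Units field: ", path)
  scale <- .unit_scale(units)
  mk_line <- strsplit(lines[4], "\t")[[1]]
  mnames <- mk_line[-(1:2)]
  mnames <- mnames[mnames != ""]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t",
                           header = FALSE, fill = TRUE)
  nm <- length(mnames)
  if (ncol(dat) < 2 + 3 * nm)
    stop("TRC data has fewer columns than the header announces: ", path)
  times <- as.numeric(dat[[2]])
  if (any(diff(times) <= 0))
    stop("non-monotone timestamps in ", path)
  n <- nrow(dat)
  arr <- array(NA_real_, c(n, nm, 3),
               dimnames = list(NULL, mnames, c("x", "y", "z")))
  for (k in seq_len(nm))
    for (d in 1:3)
      arr[, k, d] <- as.numeric(dat[[2 + (k - 1) * 3 + d]]) * scale
  list(times = times, markers = arr,
       valid = !apply(is.na(arr), c(1, 2), any))
}

#' Write marker trajectories as TRC
#'
#' @param mdata marker data (`times`, `markers`, optional `valid`).
#' @param path output file.
#' @param units `"m"` (default) or `"mm"`.
#' @export
write_trc <- function(mdata, path, units = "m") {
  scale <- 1 / .unit_scale(units)
  arr <- mdata$markers * scale
  mnames <- dimnames(arr)[[2]]
  n <- dim(arr)[1]; nm <- dim(arr)[2]
  rate <- if (n > 1) 1 / stats::median(diff(mdata$times)) else 100
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(num(rate), num(rate), n, nm, units, num(rate), 1, n, sep = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(mnames, "", ""))), collapse = "\t"),
    paste(c("", "", as.vector(vapply(seq_len(nm), function(k)
      paste0(c("X", "Y", "Z"), k), character(3)))), collapse = "\t")
  ), con)
  for (i in seq_len(n)) {
    row <- as.vector(t(arr[i, , ]))
    writeLines(paste(c(i, num(mdata$times[i]), num(row)), collapse = "\t"),
               con)
  }
  invisible(path)
}

.read_marker_csv <- function(path, units) {
  if (is.null(units))
    stop("CSV marker input carries no unit metadata; pass units = 'm' ",
         "or 'mm' explicitly")
  scale <- .unit_scale(units)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV marker file needs a 'time' column")
  times <- df$time
  if (any(diff(times) <= 0)) stop("non-monotone timestamps in ", path)
  cn <- setdiff(names(df), "time")
  base <- unique(sub("_[xyz]$", "", cn))
  arr <- array(NA_real_, c(nrow(df), length(base), 3),
               dimnames = list(NULL, base, c("x", "y", "z")))
  for (k in seq_along(base))
    for (d in 1:3) {
      col <- paste0(base[k], "_", c("x", "y", "z")[d])
      if (!col %in% names(df)) stop("missing column ", col, " in ", path)
      arr[, k, d] <- df[[col]] * scale
    }
  list(times = times, markers = arr,
       valid = !apply(is.na(arr), c(1, 2), any))
}

#' Write marker trajectories as CSV (time + <name>_x/_y/_z columns, m)
#'
#' @inheritParams write_trc
#' @export
write_marker_csv <- function(mdata, path) {
  arr <- mdata$markers
  mnames <- dimnames(arr)[[2]]
  df <- data.frame(time = mdata$times)
  for (k in seq_along(mnames))
    for (d in 1:3)
      df[[paste0(mnames[k], "_", c("x", "y", "z")[d])]] <- arr[, k, d]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a marker-set definition from YAML
#'
#' Layout: `markers: {NAME: {segment: SEG, offset: [x, y, z]}, ...}`
#' (offsets in m, in the segment frame).
#'
#' @param path YAML file.
#' @return A [marker_set()].
#' @export
read_marker_set_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- y$markers %||% y
  df <- do.call(rbind, lapply(names(mk), function(nm)
    data.frame(name = nm, segment = mk[[nm]]$segment,
               x = mk[[nm]]$offset[1], y = mk[[nm]]$offset[2],
               z = mk[[nm]]$offset[3])))
  marker_set(df)
}

#' @rdname read_marker_set_yaml
#' @param mset a [marker_set()] to write.
#' @export
write_marker_set_yaml <- function(mset, path) {
  mk <- stats::setNames(lapply(seq_len(nrow(mset)), function(i)
    list(segment = mset$segment[i],
         offset = as.numeric(mset[i, c("x", "y", "z")]))), mset$name)
  yaml::write_yaml(list(markers = mk), path)
  invisible(path)
}

## gait events <-> CSV (side,event,time)
write_events_csv <- function(events, path) {
  rows <- list()
  for (s in c("left", "right"))
    for (e in c("heel_strike", "toe_strike", "toe_off", "heel_off"))
      for (t in events[[s]][[e]])
        rows[[length(rows) + 1]] <- data.frame(side = s, event = e, time = t)
  df <- do.call(rbind, rows)
  df <- df[order(df$time), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  get <- function(s, e) df$time[df$side == s & df$event == e]
  gait_events(
    left = list(heel_strike = get("left", "heel_strike"),
                toe_strike = get("left", "toe_strike"),
                toe_off = get("left", "toe_off"),
                heel_off = get("left", "heel_off")),
    right = list(heel_strike = get("right", "heel_strike"),
                 toe_strike = get("right", "toe_strike"),
                 toe_off = get("right", "toe_off"),
                 heel_off = get("right", "heel_off")),
    validate = FALSE)
}

#' Write the stability-metrics report
#'
#' Writes `events.csv` (one row per heel strike: side, time, residual
#' orbital energy, ICaP offsets in the landing foot frame) and
#' `summary.json` (per-side means, stride average, asymmetry ratio and a
#' configuration echo) into `dir`.
#'
#' @param res an `orbital_energy_record` from [residual_orbital_energy()].
#' @param fps optional `foot_placement_summary`.
#' @param dir output directory (created if missing).
#' @param config_echo optional list echoed verbatim into the JSON summary.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(res, fps = NULL, dir,
                                 config_echo = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(res)
  if (!is.null(fps)) {
    key <- paste(tab$side, signif(tab$time, 9))
    fkey <- paste(fps$side, signif(fps$time, 9))
    idx <- match(key, fkey)
    tab$icap_anterior <- fps$anterior[idx]
    tab$icap_medial <- fps$medial[idx]
    tab$icap_lateral <- fps$lateral[idx]
  }
  utils::write.csv(tab, file.path(dir, "events.csv"), row.names = FALSE)
  s <- attr(res, "summary")
  jsonlite::write_json(list(
    E_res = list(left_hs = s[["left"]], right_hs = s[["right"]],
                 average = s[["average"]],
                 asymmetry = abs(s[["left"]] - s[["right"]]) /
                   max(abs(s[["average"]]), 1e-12)),
    omega_mode = attr(res, "omega_mode"),
    leg_length_m = attr(res, "leg_length"),
    icap_reference = if (!is.null(fps)) attr(fps, "reference") else NULL,
    config = config_echo,
    package_version = as.character(utils::packageVersion("gaitbench"))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

## reference motion / trajectory CSV helpers
write_motion_csv <- function(times, M, names, path) {
  df <- data.frame(time = times)
  for (j in seq_along(names)) df[[names[j]]] <- M[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
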