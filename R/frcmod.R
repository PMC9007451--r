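## AMBER frcmod-format parameter file writer/reader for the DIHE and
## ANGLE sections. Multi-term dihedrals follow the AMBER convention of
## negative-periodicity continuation rows: every row of a series except
## the last carries a negative PN field.

split_type_label <- function(label, n_parts) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  stop_unless(length(parts) == n_parts,
              "label '%s' must have %d dash-separated atom types", label,
              n_parts)
  for (p in parts) {
    if (nchar(p) > 2) {
      stop(sprintf("atom type '%s' exceeds the 2-character frcmod field",
                   p), call. = FALSE)
    }
  }
  parts
}

#' Write torsion and angle parameters as an AMBER frcmod file
#'
#' Emits `DIHE` records (atom types, divider 1, barrier, phase,
#' periodicity; negative-periodicity continuation rows for multi-term
#' series) and `ANGLE` records (atom types, force constant,
#' equilibrium angle). Values print to 4 decimals and round-trip
#' through [read_frcmod()] at that precision.
#'
#' @param series_list List of [torsion_series()] (labels are the
#'   dash-separated atom-type strings, e.g. `"cD-cD-cD-cD"`).
#' @param angle_list Named list of [harmonic_angle_param()], names as
#'   3-type labels (e.g. `"cD-cD-cD"`). May be empty.
#' @param path Output path.
#' @param title Header line.
#' @return `path`, invisibly.
#' @export
write_frcmod <- function(series_list = list(), angle_list = list(), path,
                         title = "parameters written by lipidtools") {
  lines <- c(title, "MASS", "", "BOND", "", "ANGLE")
  for (lab in names(angle_list)) {
    p <- angle_list[[lab]]
    stop_unless(inherits(p, "harmonic_angle_param"),
                "angle_list entries must be harmonic_angle_param")
    parts <- split_type_label(lab, 3L)
    lines <- c(lines, sprintf("%-2s-%-2s-%-2s  %10.4f  %10.4f",
                              parts[1], parts[2], parts[3],
                              p$force_constant, p$equilibrium))
  }
  lines <- c(lines, "", "DIHE")
  for (s in series_list) {
    stop_unless(inherits(s, "torsion_series"),
                "series_list entries must be torsion_series")
    parts <- split_type_label(s$label, 4L)
    nt <- length(s$terms)
    for (i in seq_len(nt)) {
      t <- s$terms[[i]]
      pn <- if (i < nt) -t$periodicity else t$periodicity
      lines <- c(lines, sprintf(
        "%-2s-%-2s-%-2s-%-2s %4d %10.4f %10.4f %10.1f",
        parts[1], parts[2], parts[3], parts[4], 1L, t$barrier, t$phase,
        as.numeric(pn)))
    }
  }
  lines <- c(lines, "", "IMPROPER", "", "NONBON", "")
  atomic_write(lines, path)
  invisible(path)
}

#' Read an AMBER frcmod file (DIHE and ANGLE sections)
#'
#' @param path frcmod file path.
#' @return List with `dihedrals` (named list of [torsion_series()])
#'   and `angles` (named list of [harmonic_angle_param()]).
#' @export
read_frcmod <- function(path) {
  lines <- readLines(path)
  section <- ""
  dihe_rows <- list()
  angles <- list()
  for (ln in lines[-1]) {
    trimmed <- trimws(ln)
    if (trimmed %in% c("MASS", "BOND", "ANGLE", "DIHE", "IMPROPER",
                       "NONBON")) {
      section <- trimmed
      next
    }
    if (trimmed == "") next
    if (section == "ANGLE") {
      label <- gsub(" ", "", substr(ln, 1, 8))
      rest <- scan(text = substr(ln, 9, nchar(ln)), quiet = TRUE)
      angles[[label]] <- harmonic_angle_param(rest[1], rest[2])
    } else if (section == "DIHE") {
      label <- gsub(" ", "", substr(ln, 1, 11))
      rest <- scan(text = substr(ln, 12, nchar(ln)), quiet = TRUE)
      dihe_rows[[length(dihe_rows) + 1L]] <- list(
        label = label, barrier = rest[2], phase = rest[3],
        periodicity = rest[4])
    }
  }
  dihedrals <- list()
  current <- list()
  cur_label <- NULL
  for (row in dihe_rows) {
    if (!is.null(cur_label) && row$label != cur_label && length(current)) {
      ## shouldn't happen mid-series, but close out defensively
      dihedrals[[cur_label]] <- torsion_series(current, cur_label)
      current <- list()
    }
    cur_label <- row$label
    current[[length(current) + 1L]] <- torsion_term(
      abs(row$periodicity), row$barrier, row$phase %% 360)
    if (row$periodicity > 0) {
      dihedrals[[cur_label]] <- torsion_series(current, cur_label)
      current <- list()
      cur_label <- NULL
    }
  }
  if (length(current)) {
    dihedrals[[cur_label]] <- torsion_series(current, cur_label)
  }
  list(dihedrals = dihedrals, angles = angles)
}
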