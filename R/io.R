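# CSV readers/writers for trials and estimates.
#
# Dialect: comma-separated, UTF-8, '.' decimal, one header row of
# `name[unit]` labels, time in seconds from trial start.  Sensor files are
# SI; estimate files are reported in mm-based units.  Formatting is fixed so
# that re-running a pipeline with the same seeds produces byte-identical
# files.

fmt_num <- function(x) sprintf("%.8f", x)

write_csv_units <- function(d, units, path) {
  hdr <- paste0(names(d), ifelse(units == "", "", paste0("[", units, "]")))
  lines <- c(paste(hdr, collapse = ","),
             if (nrow(d)) do.call(paste,
               c(lapply(d, fmt_num), list(sep = ","))))
  writeLines(lines, path)
}

read_csv_units <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, check.names = FALSE)
  nm <- sub("\\[.*\\]$", "", names(d))
  names(d) <- nm
  miss <- setdiff(required, nm)
  if (length(miss))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

check_uniform_t <- function(t, file) {
  if (length(t) < 2) return(invisible(TRUE))
  dt <- diff(t)
  step <- stats::median(dt)
  bad <- which(dt > 1.5 * step + 1e-12 | dt < 0.5 * step - 1e-12)
  if (length(bad))
    stop("non-uniform timestamps in ", file, ": first gap after row ",
         bad[1] + 1, " (dt = ", signif(dt[bad[1]], 4), " s, expected ",
         signif(step, 4), " s)", call. = FALSE)
  invisible(TRUE)
}

#' Write a trial to CSV files
#'
#' Writes `plate.csv` (`t, Rx[N], Ry[N], Fz[N], Nx[Nm], Ny[Nm]`),
#' `support.csv` (`t, Xsdd[m/s2], Ysdd[m/s2]`), and, if present,
#' `head.csv` (`t, Xhdd[m/s2], Yhdd[m/s2]`), `imu.csv`
#' (`t, ax..az[m/s2], gx..gz[rad/s]`), per-plane ground-truth files
#' `truth_sagittal.csv` / `truth_frontal.csv` (mm-based, mirroring the
#' estimates schema) and a `meta.csv` key/value file (subject, fs, motion,
#' seed).
#'
#' @param trial a `com_trial`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "com_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_units(trial$plate,
                  c("", "N", "N", "N", "Nm", "Nm"),
                  file.path(dir, "plate.csv"))
  write_csv_units(trial$support, c("", "m/s2", "m/s2"),
                  file.path(dir, "support.csv"))
  if (!is.null(trial$head))
    write_csv_units(trial$head, c("", "m/s2", "m/s2"),
                    file.path(dir, "head.csv"))
  if (!is.null(trial$imu))
    write_csv_units(trial$imu,
                    c("", "m/s2", "m/s2", "m/s2",
                      "rad/s", "rad/s", "rad/s"),
                    file.path(dir, "imu.csv"))
  if (!is.null(trial$truth) && !is.null(trial$truth$model)) {
    for (pl in c("sagittal", "frontal")) {
      td <- trial$truth[[pl]]
      if (is.null(td$xb)) next
      d <- data.frame(t = td$t, xb = 1000 * td$xb, vb = 1000 * td$xbd,
                      ab = 1000 * td$xbdd, a1 = 1000 * td$x1dd,
                      a2 = 1000 * td$x2dd)
      write_csv_units(d, c("", "mm", "mm/s", "mm/s2", "mm/s2", "mm/s2"),
                      file.path(dir, paste0("truth_", pl, ".csv")))
    }
  }
  meta <- data.frame(
    key = c("mass_kg", "height_m", "g", "fs_hz", "motion", "seed"),
    value = c(trial$subject$M, trial$subject$H, trial$subject$g,
              trial$fs, trial$motion, trial$seed))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read a trial from CSV files
#'
#' Counterpart of [write_trial()]: validates the schemas (missing columns
#' and non-uniform timestamps are rejected with the offending column or
#' row), checks that all streams share one grid, and rebuilds the trial.
#'
#' @param dir directory holding the trial files.
#' @param subject optional [com_subject()]; by default rebuilt from
#'   `meta.csv`.
#' @return a `com_trial`.
#' @export
read_trial <- function(dir, subject = NULL) {
  plate <- read_csv_units(file.path(dir, "plate.csv"),
                          c("t", "Rx", "Ry", "Fz", "Nx", "Ny"))
  check_uniform_t(plate$t, "plate.csv")
  support_path <- file.path(dir, "support.csv")
  support <- if (file.exists(support_path)) {
    s <- read_csv_units(support_path, c("t", "Xsdd", "Ysdd"))
    check_uniform_t(s$t, "support.csv"); s
  } else data.frame(t = plate$t, Xsdd = 0, Ysdd = 0)
  head_path <- file.path(dir, "head.csv")
  head <- if (file.exists(head_path))
    read_csv_units(head_path, c("t", "Xhdd", "Yhdd")) else NULL
  imu_path <- file.path(dir, "imu.csv")
  imu <- if (file.exists(imu_path))
    read_csv_units(imu_path, c("t", "ax", "ay", "az", "gx", "gy", "gz"))
    else NULL
  meta_path <- file.path(dir, "meta.csv")
  motion <- "unknown"; seed <- NA_integer_
  fs <- 1 / stats::median(diff(plate$t))
  if (file.exists(meta_path)) {
    m <- read.csv(meta_path)
    get <- function(k) m$value[match(k, m$key)]
    if (is.null(subject))
      subject <- com_subject(as.numeric(get("mass_kg")),
                             as.numeric(get("height_m")),
                             as.numeric(get("g")))
    fs <- as.numeric(get("fs_hz"))
    motion <- as.character(get("motion"))
    seed <- as.integer(get("seed"))
  }
  if (is.null(subject))
    stop("no subject given and no meta.csv found in ", dir, call. = FALSE)
  for (d in list(support, head, imu))
    if (!is.null(d) && nrow(d) != nrow(plate))
      stop("sensor streams in ", dir, " are not on one grid", call. = FALSE)
  structure(list(plate = plate, head = head, imu = imu, support = support,
                 subject = subject, fs = fs, motion = motion, truth = NULL,
                 oracle = "file", model = NA_character_, seed = seed),
            class = "com_trial")
}

#' Write estimates (and optional metrics) to CSV
#'
#' Estimates schema: `t, xb[mm], vb[mm/s], ab[mm/s2]` plus `a1[mm/s2],
#' a2[mm/s2]` when the method provides segment accelerations.  Deterministic
#' column order and fixed decimal formatting.
#'
#' @param est a `com_estimate`.
#' @param path output CSV path.
#' @param metrics optional `com_metrics`, written next to `path` with
#'   suffix `_metrics.csv`.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(est, path, metrics = NULL) {
  stopifnot(inherits(est, "com_estimate"))
  d <- data.frame(t = est$t, xb = 1000 * est$data$xb,
                  vb = 1000 * est$data$vb, ab = 1000 * est$data$ab)
  units <- c("", "mm", "mm/s", "mm/s2")
  if (!is.null(est$data$a1)) {
    d$a1 <- 1000 * est$data$a1
    d$a2 <- 1000 * est$data$a2
    units <- c(units, "mm/s2", "mm/s2")
  }
  write_csv_units(d, units, path)
  if (!is.null(metrics)) {
    mpath <- sub("\\.csv$", "_metrics.csv", path)
    utils::write.csv(as.data.frame(metrics), mpath, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read an estimates (or truth) CSV
#'
#' @param path CSV written by [write_estimates()] or [write_trial()]'s
#'   truth files.
#' @return data frame with `t` (s) and mm-based value columns.
#' @export
read_estimates <- function(path) {
  d <- read_csv_units(path, c("t", "xb", "vb", "ab"))
  check_uniform_t(d$t, basename(path))
  d
}
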