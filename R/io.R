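#' Write a sedimentation velocity scan set to disk
#'
#' One columnar text file per scan (comment header with rotor speed, scan
#' time and channel; two columns radius/signal) plus a `manifest.csv`
#' describing geometry, conditions and the scan files, modelled on the
#' radial-scan exports of XL-type analytical ultracentrifuges.
#'
#' @param scans An `sv_scan_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_sv_scans <- function(scans, dir) {
  stopifnot(inherits(scans, "sv_scan_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(scans$scan_times))
  for (i in seq_along(scans$scan_times)) {
    files[i] <- sprintf("scan_%03d.txt", i)
    con <- file.path(dir, files[i])
    header <- c(sprintf("# rpm %g", scans$rpm),
                sprintf("# time_s %g", scans$scan_times[i]),
                sprintf("# channel %s", scans$channel))
    writeLines(c(header, paste(format(scans$radius, digits = 8),
                               format(scans$signal[i, ], digits = 8))), con)
  }
  manifest <- data.frame(
    file = files, time_s = scans$scan_times, rpm = scans$rpm,
    channel = scans$channel, meniscus = scans$geometry$meniscus,
    base = scans$geometry$base, pathlength = scans$geometry$pathlength,
    noise_sigma = scans$noise_sigma,
    temperature = scans$cond$temperature, density = scans$cond$density,
    viscosity = scans$cond$viscosity)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a sedimentation velocity scan set written by [write_sv_scans()]
#'
#' @param dir Directory containing `manifest.csv` and the scan files.
#' @return An `sv_scan_set`.
#' @export
read_sv_scans <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  sigs <- list(); radius <- NULL
  for (i in seq_len(nrow(manifest))) {
    lines <- readLines(file.path(dir, manifest$file[i]))
    lines <- lines[!grepl("^#", lines)]
    m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    radius <- m[, 1]
    sigs[[i]] <- m[, 2]
  }
  geometry <- cell_geometry(manifest$meniscus[1], manifest$base[1],
                            manifest$pathlength[1])
  cond <- solution_conditions(manifest$temperature[1], manifest$density[1],
                              manifest$viscosity[1])
  structure(list(radius = radius, scan_times = manifest$time_s,
                 signal = do.call(rbind, sigs), channel = manifest$channel[1],
                 rpm = manifest$rpm[1], omega = rpm_to_omega(manifest$rpm[1]),
                 geometry = geometry, cond = cond,
                 noise_sigma = manifest$noise_sigma[1], species = NULL),
            class = "sv_scan_set")
}

#' Write sedimentation equilibrium profiles as CSV
#'
#' Long-format CSV with one row per radial point
#' (profile, rpm, loading, reference_radius, radius, signal).
#'
#' @param se An `se_profile_set`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_se_csv <- function(se, file) {
  stopifnot(inherits(se, "se_profile_set"))
  rows <- do.call(rbind, lapply(seq_along(se$profiles), function(i) {
    p <- se$profiles[[i]]
    data.frame(profile = i, rpm = p$rpm, loading = p$loading,
               reference_radius = p$reference_radius,
               radius = p$radius, signal = p$signal)
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read sedimentation equilibrium profiles from CSV
#'
#' @param file CSV written by [write_se_csv()].
#' @return An `se_profile_set` (geometry and channel metadata reduced to
#'   what the CSV stores).
#' @export
read_se_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  profiles <- lapply(split(d, d$profile), function(g)
    list(rpm = g$rpm[1], omega = rpm_to_omega(g$rpm[1]),
         loading = g$loading[1], radius = g$radius, signal = g$signal,
         reference_radius = g$reference_radius[1]))
  names(profiles) <- NULL
  structure(list(profiles = profiles, geometry = NULL, cond = NULL,
                 vbar = NA_real_, channel = NA_character_,
                 noise_sigma = NA_real_, M_true = NA_real_),
            class = "se_profile_set")
}

#' Write an ITC titration as CSV
#'
#' Comment header with cell volume and concentrations; one row per
#' injection (volume in ml, heat in ucal).
#'
#' @param titration An `itc_titration`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_itc_csv <- function(titration, file) {
  stopifnot(inherits(titration, "itc_titration"))
  header <- c(sprintf("# V0_ml %g", titration$V0),
              sprintf("# cell_M %g", titration$Mt0),
              sprintf("# syringe_M %g", titration$Xt_syr))
  body <- paste(seq_along(titration$heats),
                titration$injection_volumes, titration$heats, sep = ",")
  writeLines(c(header, "injection,volume_ml,heat_ucal", body), file)
  invisible(file)
}

#' Read an ITC titration from CSV
#'
#' @param file CSV written by [write_itc_csv()].
#' @return An `itc_titration`.
#' @export
read_itc_csv <- function(file) {
  lines <- readLines(file)
  hdr <- lines[grepl("^#", lines)]
  getv <- function(key) as.numeric(sub(paste0("# ", key, " "), "",
                                       hdr[grepl(key, hdr)]))
  d <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  structure(list(V0 = getv("V0_ml"), Mt0 = getv("cell_M"),
                 Xt_syr = getv("syringe_M"),
                 injection_volumes = d$volume_ml, heats = d$heat_ucal,
                 truth = NULL),
            class = "itc_titration")
}

#' Write a C(S) distribution as CSV
#'
#' Two columns (s in Svedberg, c in signal per S) preceded by comment
#' lines recording the frictional ratio, regularization strength and fit
#' rmsd.
#'
#' @param csd A `cs_distribution`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_cs_csv <- function(csd, file) {
  stopifnot(inherits(csd, "cs_distribution"))
  header <- c(sprintf("# ff0 %g", csd$ff0),
              sprintf("# lambda %g", csd$lambda),
              sprintf("# fit_rmsd %g", csd$fit_rmsd),
              sprintf("# channel %s", csd$channel))
  writeLines(c(header, "s,c",
               paste(csd$s_grid, csd$c, sep = ",")), file)
  invisible(file)
}

#' Read a C(S) distribution from CSV
#'
#' @param file CSV written by [write_cs_csv()].
#' @return A `cs_distribution`.
#' @export
read_cs_csv <- function(file) {
  lines <- readLines(file)
  hdr <- lines[grepl("^#", lines)]
  getv <- function(key) sub(paste0("# ", key, " "), "", hdr[grepl(key, hdr)])
  d <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  ds <- diff(d$s)
  ds <- c(ds[1], (ds[-length(ds)] + ds[-1]) / 2, ds[length(ds)])
  structure(list(s_grid = d$s, c = d$c, amplitudes = d$c * ds,
                 ff0 = as.numeric(getv("ff0")),
                 lambda = as.numeric(getv("lambda")),
                 fit_rmsd = as.numeric(getv("fit_rmsd")),
                 target_rmsd = NA_real_,
                 total_signal = sum(d$c * ds), channel = getv("channel")),
            class = "cs_distribution")
}
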