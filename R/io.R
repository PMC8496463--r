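# Delimited-text I/O for the instrument and station data streams. CSV is the
# interchange format; the raw-table reader is deliberately permissive about
# delimiter, decimal mark and header spelling because instrument exports
# vary.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(first, gregexpr(",", first))),
              ";" = lengths(regmatches(first, gregexpr(";", first))),
              "\t" = lengths(regmatches(first, gregexpr("\t", first))))
  names(counts) <- c(",", ";", "\t")
  delim <- names(which.max(counts))
  if (max(counts) == 0L) delim <- ","
  delim
}

normalize_header <- function(x) {
  y <- tolower(gsub("[^A-Za-z0-9']+", "", x))
  map <- c(
    "wavelength" = "wavelength", "wavelengthnm" = "wavelength",
    "par" = "par", "f" = "f", "fluorescence" = "f", "fluorescencef" = "f",
    "fm" = "fm_prime", "fm'" = "fm_prime", "fmfm'" = "fm_prime",
    "fmprime" = "fm_prime",
    "yield" = "yield", "yieldmax" = "yieldmax",
    "parii" = "par_ii", "etrii" = "etr_ii", "npq" = "npq",
    "station" = "station", "location" = "station", "sample" = "station",
    "replicate" = "replicate", "rep" = "replicate",
    "zerooffset" = "zero_offset", "offset" = "zero_offset"
  )
  out <- map[y]
  out[is.na(out)] <- x[is.na(out)]
  unname(out)
}

#' Read a raw multi-color PAM step table
#'
#' Reads the supplementary-style raw table (one row per light step) with
#' columns wavelength, PAR, F, Fm (Fm'), and optionally Yield, Yieldmax,
#' PAR(II), ETR(II), NPQ, station/replicate identifiers and a zero-offset
#' column. Delimiter (comma, semicolon, tab) and decimal mark (point or
#' comma) are auto-detected, header spelling variants are accepted, and a
#' zero-offset column, when present, is subtracted from both fluorescence
#' columns. Rows that fail validation (non-positive Fm', F exceeding Fm',
#' unparseable numbers) are never silently dropped: they are collected into
#' a `rejects` attribute with a reason code.
#'
#' @param path file path
#' @return data.frame with normalized column names (`wavelength`, `par`,
#'   `f`, `fm_prime`, ...); attribute `rejects` holds the rejected rows and
#'   their `reject_reason`
#' @export
read_raw_pam <- function(path) {
  delim <- sniff_delim(path)
  # quote = "\"" only: apostrophes are legitimate header characters (Fm')
  raw <- utils::read.table(path, sep = delim, header = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  names(raw) <- normalize_header(names(raw))
  mandatory <- c("wavelength", "par", "f", "fm_prime")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    stop("raw PAM table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  num_cols <- intersect(
    c("wavelength", "par", "f", "fm_prime", "yield", "yieldmax",
      "par_ii", "etr_ii", "npq", "zero_offset"),
    names(raw)
  )
  # decimal-comma dialects: only if no decimal points are present
  has_point <- any(grepl(".", unlist(raw[num_cols]), fixed = TRUE))
  for (cc in num_cols) {
    v <- raw[[cc]]
    if (!has_point) v <- gsub(",", ".", v, fixed = TRUE)
    raw[[cc]] <- suppressWarnings(as.numeric(v))
  }
  if ("zero_offset" %in% names(raw)) {
    off <- ifelse(is.finite(raw$zero_offset), raw$zero_offset, 0)
    raw$f <- raw$f - off
    raw$fm_prime <- raw$fm_prime - off
  }
  reason <- rep(NA_character_, nrow(raw))
  bad_num <- !stats::complete.cases(raw[mandatory])
  reason[bad_num] <- "unparseable_or_missing_value"
  bad_fm <- !bad_num & raw$fm_prime <= 0
  reason[bad_fm] <- "nonpositive_fm_prime"
  bad_f <- !bad_num & !bad_fm & raw$f > raw$fm_prime
  reason[bad_f] <- "f_exceeds_fm_prime"
  rejects <- raw[!is.na(reason), , drop = FALSE]
  if (nrow(rejects)) rejects$reject_reason <- reason[!is.na(reason)]
  ok <- raw[is.na(reason), , drop = FALSE]
  attr(ok, "rejects") <- rejects
  ok
}

#' Read vertical profiles from long-format CSV
#'
#' Long format: columns `station`, `depth_m`, `replicate` (optional),
#' `wavelength_nm` (a number, or the literal `"PAR"` for broadband rows) and
#' `value`.
#'
#' @param path file path
#' @return list with data.frames `par` (station, depth, par) and `spectral`
#'   (station, replicate, depth, wavelength, value); either may have 0 rows
#' @export
read_light_profiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("station", "depth_m", "wavelength_nm", "value") %in% names(d)))
  if (is.null(d$replicate)) d$replicate <- 1L
  is_par <- toupper(trimws(as.character(d$wavelength_nm))) == "PAR"
  par <- data.frame(station = d$station[is_par], depth = d$depth_m[is_par],
                    par = d$value[is_par])
  sp <- d[!is_par, ]
  spectral <- data.frame(
    station = sp$station, replicate = sp$replicate, depth = sp$depth_m,
    wavelength = as.numeric(sp$wavelength_nm), value = sp$value
  )
  list(par = par, spectral = spectral)
}

#' @rdname read_light_profiles
#' @export
read_density_profiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("station", "depth_m", "value") %in% names(d)))
  data.frame(station = d$station, depth = d$depth_m, density = d$value)
}

#' Write a synthetic campaign to a directory of CSV files
#'
#' Serializes every stream of a [simulate_campaign()] bundle in the same CSV
#' dialects the package readers consume, plus a YAML scenario file recording
#' the seed. Numeric columns keep full precision (15 significant digits).
#'
#' @param campaign a `campaign` bundle
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = NA),
                     p, row.names = FALSE, quote = FALSE)
    p
  }
  files <- c(
    w(campaign$rlc, "rlc.csv"),
    w(campaign$induction, "induction.csv"),
    w(campaign$stations, "stations.csv"),
    w(with(campaign$par_profiles,
           data.frame(station = station, depth_m = depth, replicate = 1L,
                      wavelength_nm = "PAR", value = par)) |>
        rbind(with(campaign$spectral_profiles,
                   data.frame(station = station, depth_m = depth,
                              replicate = replicate, wavelength_nm = wavelength,
                              value = value))),
      "light_profiles.csv"),
    w(with(campaign$density_profiles,
           data.frame(station = station, depth_m = depth, value = density)),
      "density_profiles.csv"),
    w(campaign$params_true, "params_true.csv")
  )
  scen <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(
    seed = campaign$truth$seed,
    n_stations = nrow(campaign$stations),
    wavelengths = campaign$wavelengths
  ), scen)
  invisible(c(files, scen))
}
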