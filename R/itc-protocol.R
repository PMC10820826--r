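# Containers for ITC titration experiments. Internally everything is SI
# (litres, molar, kelvin); constructors take the units practitioners use at
# the instrument (microlitres, micromolar, degrees Celsius). Heats are kept
# in microcalories, the unit integrated injection heats are exported in.

#' Define an ITC titration protocol
#'
#' Describes the injection schedule of an isothermal titration calorimetry
#' experiment: the calorimeter cell, the syringe and cell species
#' concentrations, the per-injection volumes and the experiment temperature.
#' The defaults mirror a typical peptide-into-protein experiment
#' (0.7 mM syringe peptide titrated into 50 uM protein at 25 C, 20 x 2 uL
#' injections into a 200 uL cell).
#'
#' @param cell_volume_ul Calorimeter cell volume in microlitres.
#' @param syringe_conc_um Total concentration of the titrant (syringe
#'   species) in micromolar.
#' @param cell_conc_um Total concentration of the titrand (cell species,
#'   usually the macromolecule) in micromolar.
#' @param injection_volumes_ul Numeric vector of injection volumes in
#'   microlitres, one per injection (at least two).
#' @param temperature_c Experiment temperature in degrees Celsius; must fall
#'   between 0 and 100 C.
#'
#' @return An object of class `itc_protocol` with fields in SI units:
#'   `cell_volume` (L), `syringe_conc` (M), `cell_conc` (M),
#'   `injection_volumes` (L) and `temperature` (K).
#' @examples
#' prot <- itc_protocol()
#' prot
#' @export
itc_protocol <- function(cell_volume_ul = 200,
                         syringe_conc_um = 700,
                         cell_conc_um = 50,
                         injection_volumes_ul = rep(2, 20),
                         temperature_c = 25) {
  stopifnot(is.numeric(cell_volume_ul), length(cell_volume_ul) == 1L,
            is.numeric(syringe_conc_um), length(syringe_conc_um) == 1L,
            is.numeric(cell_conc_um), length(cell_conc_um) == 1L,
            is.numeric(injection_volumes_ul), is.numeric(temperature_c))
  if (cell_volume_ul <= 0 || syringe_conc_um <= 0 || cell_conc_um <= 0)
    stop("cell volume and both concentrations must be strictly positive")
  if (length(injection_volumes_ul) < 2L)
    stop("an ITC protocol needs at least 2 injections")
  if (any(injection_volumes_ul <= 0))
    stop("all injection volumes must be strictly positive (zero-volume injections are not allowed)")
  temperature_k <- temperature_c + 273.15
  if (temperature_k < 273 || temperature_k > 373)
    stop("temperature must lie in [273, 373] K (0-100 C)")
  structure(
    list(
      cell_volume       = cell_volume_ul * 1e-6,
      syringe_conc      = syringe_conc_um * 1e-6,
      cell_conc         = cell_conc_um * 1e-6,
      injection_volumes = injection_volumes_ul * 1e-6,
      temperature       = temperature_k
    ),
    class = "itc_protocol"
  )
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat("ITC titration protocol\n")
  cat(sprintf("  cell: %.0f uL of %.3g uM titrand at %.2f K\n",
              x$cell_volume * 1e6, x$cell_conc * 1e6, x$temperature))
  cat(sprintf("  syringe: %.3g uM titrant, %d injections (%.3g uL total)\n",
              x$syringe_conc * 1e6, length(x$injection_volumes),
              sum(x$injection_volumes) * 1e6))
  invisible(x)
}

#' Bundle integrated injection heats with their protocol
#'
#' An isotherm pairs an [itc_protocol()] with the integrated heat of each
#' injection (in microcalories) and derives the molar ratio of total titrant
#' to total titrand in the cell after each injection, following the
#' displaced-volume dilution bookkeeping described in
#' `vignette("mintkit-methods")`.
#'
#' @param protocol An [itc_protocol()].
#' @param heats_ucal Numeric vector of integrated injection heats in
#'   microcalories, one per injection.
#' @return An object of class `isotherm` with fields `protocol`, `heats`
#'   (ucal) and `molar_ratios`.
#' @export
isotherm <- function(protocol, heats_ucal) {
  stopifnot(inherits(protocol, "itc_protocol"), is.numeric(heats_ucal))
  n_inj <- length(protocol$injection_volumes)
  if (length(heats_ucal) != n_inj)
    stop(sprintf("got %d heats for %d injections", length(heats_ucal), n_inj))
  if (any(!is.finite(heats_ucal)))
    stop("heats must be finite")
  comp <- cell_composition(protocol)
  structure(
    list(protocol = protocol,
         heats = as.numeric(heats_ucal),
         molar_ratios = comp$x_total / comp$m_total),
    class = "isotherm"
  )
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections, heats in [%.3g, %.3g] ucal\n",
              length(x$heats), min(x$heats), max(x$heats)))
  cat(sprintf("  molar ratio range %.3g - %.3g\n",
              min(x$molar_ratios), max(x$molar_ratios)))
  invisible(x)
}

# Total (bound + free) concentrations of the cell species M and the titrant X
# in the cell after each injection, under the perfusion (displaced-volume)
# convention: injecting v into a constant-volume cell V0 dilutes existing
# contents by V0/(V0+v) and delivers syringe material at v/(V0+v).
cell_composition <- function(protocol) {
  v0 <- protocol$cell_volume
  m <- protocol$cell_conc
  x <- 0
  n_inj <- length(protocol$injection_volumes)
  m_total <- x_total <- dilution <- numeric(n_inj)
  for (i in seq_len(n_inj)) {
    v <- protocol$injection_volumes[i]
    d <- v0 / (v0 + v)
    m <- m * d
    x <- x * d + protocol$syringe_conc * v / (v0 + v)
    m_total[i] <- m
    x_total[i] <- x
    dilution[i] <- d
  }
  list(m_total = m_total, x_total = x_total, dilution = dilution)
}

#' Read an ITC injection table from CSV
#'
#' Expects one row per injection with columns `injection_volume_uL` and
#' `heat_ucal`. Experiment metadata (`cell_volume_uL`, `syringe_conc_uM`,
#' `cell_conc_uM`, `temperature_C`) is taken either from a sidecar JSON file
#' (`<path>.json` or the `meta` argument) or from `key,value` header rows
#' preceding the injection table.
#'
#' @param path Path to the CSV file.
#' @param meta Optional path to a JSON file with the metadata keys above;
#'   defaults to `<path>.json` when that file exists.
#' @return An [isotherm()].
#' @export
read_itc_csv <- function(path, meta = NULL) {
  if (!file.exists(path)) stop(sprintf("ITC input not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty ITC input: %s", path))
  if (is.null(meta)) {
    side <- paste0(path, ".json")
    if (file.exists(side)) meta <- side
  }
  header_keys <- c("cell_volume_uL", "syringe_conc_uM", "cell_conc_uM",
                   "temperature_C")
  md <- list()
  if (!is.null(meta)) {
    md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  }
  # key,value header rows before the injection table
  is_kv <- grepl("^[A-Za-z_]+,", lines) &
    vapply(strsplit(lines, ","), function(p) p[1] %in% header_keys, logical(1))
  for (ln in lines[is_kv]) {
    p <- strsplit(ln, ",")[[1]]
    md[[p[1]]] <- as.numeric(p[2])
  }
  body <- lines[!is_kv]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("injection_volume_uL", "heat_ucal")
  if (!all(need %in% names(tab)))
    stop(sprintf("ITC CSV %s must contain columns %s", path,
                 paste(need, collapse = ", ")))
  missing_md <- setdiff(header_keys, names(md))
  if (length(missing_md))
    stop(sprintf("ITC metadata missing keys: %s (supply a sidecar JSON or header rows)",
                 paste(missing_md, collapse = ", ")))
  prot <- itc_protocol(
    cell_volume_ul = md$cell_volume_uL,
    syringe_conc_um = md$syringe_conc_uM,
    cell_conc_um = md$cell_conc_uM,
    injection_volumes_ul = tab$injection_volume_uL,
    temperature_c = md$temperature_C
  )
  isotherm(prot, tab$heat_ucal)
}

#' Write an ITC isotherm to CSV with a sidecar JSON
#'
#' Inverse of [read_itc_csv()]: writes the injection table to `path` and the
#' protocol metadata to `<path>.json`. Heats are written at full double
#' precision so the round trip is lossless.
#'
#' @param iso An [isotherm()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_itc_csv <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  prot <- iso$protocol
  tab <- data.frame(
    injection_volume_uL = formatC(prot$injection_volumes * 1e6,
                                  format = "g", digits = 15),
    heat_ucal = formatC(iso$heats, format = "g", digits = 17)
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(cell_volume_uL = prot$cell_volume * 1e6,
         syringe_conc_uM = prot$syringe_conc * 1e6,
         cell_conc_uM = prot$cell_conc * 1e6,
         temperature_C = prot$temperature - 273.15),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
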