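# End-to-end runs wiring the three stages into reproducible file-in /
# file-out pipelines. Every run writes a resolved-config snapshot next to
# its outputs; input problems raise conditions of class
# "mintkit_input_error" (the command-line wrapper maps them to exit code
# 2, and processing failures to 3).

input_error <- function(fmt, ...) {
  stop(structure(class = c("mintkit_input_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

write_config_snapshot <- function(config, out_dir) {
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

#' Fit an ITC input file and write a report
#'
#' Reads an injection CSV ([read_itc_csv()]), fits the one-site model
#' ([itc_fit()]) and writes `itc_fit.json`, `itc_fit.csv` (observed vs
#' fitted heats) and a resolved-config snapshot to `out_dir`.
#'
#' @param input_csv Path to the injection CSV.
#' @param out_dir Output directory (created if needed).
#' @param discard_first,fit_offset Passed to [itc_fit()].
#' @param meta Optional sidecar metadata JSON path for the CSV.
#' @return Invisibly, a list with `status` (0 success, 3 fit failed to
#'   converge), `fit` and the output paths.
#' @export
run_itc <- function(input_csv, out_dir, discard_first = FALSE,
                    fit_offset = FALSE, meta = NULL) {
  if (!file.exists(input_csv))
    input_error("ITC input not found: %s", input_csv)
  iso <- tryCatch(read_itc_csv(input_csv, meta = meta),
                  error = function(e)
                    input_error("failed to read %s: %s", input_csv,
                                conditionMessage(e)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- itc_fit(iso, discard_first = discard_first,
                 fit_offset = fit_offset)
  json_path <- file.path(out_dir, "itc_fit.json")
  csv_path <- file.path(out_dir, "itc_fit.csv")
  write_itc_report(fit, json_path, csv_path)
  write_config_snapshot(list(subcommand = "itc-fit", input = input_csv,
                             discard_first = discard_first,
                             fit_offset = fit_offset), out_dir)
  invisible(list(status = if (fit$converged) 0L else 3L, fit = fit,
                 json = json_path, csv = csv_path))
}

#' Screen a manifest of prediction bundles
#'
#' Runs [triage()] over every bundle listed in a screening manifest and
#' writes one summary row per candidate pair. Pairs whose bundle fails to
#' load become rows with verdict `rejected`; the run continues.
#'
#' The screening manifest is a JSON array (or `{"pairs": [...]}`) of
#' per-pair bundle manifests as read by [read_bundle_manifest()], given
#' either inline or as paths.
#'
#' @param manifest_path Path to the screening manifest JSON, or a
#'   character vector of per-pair bundle manifest paths.
#' @param out_csv Output summary CSV path.
#' @param thresholds A [triage_thresholds()].
#' @return Invisibly, a list with `status` (always 0 once the manifest is
#'   readable), `summary` (the data.frame) and `results` (per-pair
#'   [triage()] results or `NULL` for rejected pairs).
#' @export
run_screen <- function(manifest_path, out_csv,
                       thresholds = triage_thresholds()) {
  if (is.character(manifest_path) && length(manifest_path) == 1L &&
      grepl("\\.json$", manifest_path)) {
    if (!file.exists(manifest_path))
      input_error("screening manifest not found: %s", manifest_path)
    mf <- tryCatch(jsonlite::read_json(manifest_path,
                                       simplifyVector = TRUE),
                   error = function(e)
                     input_error("unreadable manifest %s: %s",
                                 manifest_path, conditionMessage(e)))
    if (is.list(mf) && !is.null(mf$pairs)) mf <- mf$pairs
    base <- dirname(manifest_path)
    paths <- vapply(unlist(mf, use.names = FALSE), function(p)
      if (file.exists(p)) p else file.path(base, p), character(1))
  } else {
    paths <- as.character(manifest_path)
  }
  empty <- data.frame(pair_id = character(), mean_iptm = numeric(),
                      min_interchain_pae = numeric(),
                      frac_below_cutoff = numeric(),
                      consistency_rmsd = numeric(),
                      n_contacts = integer(), verdict = character(),
                      stringsAsFactors = FALSE)
  rows <- list(); results <- list()
  for (p in paths) {
    res <- tryCatch({
      bundle <- read_bundle_manifest(p)
      triage(bundle, thresholds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[p]] <- data.frame(
        pair_id = sub("\\.json$", "", basename(p)), mean_iptm = NA_real_,
        min_interchain_pae = NA_real_, frac_below_cutoff = NA_real_,
        consistency_rmsd = NA_real_, n_contacts = NA_integer_,
        verdict = "rejected", stringsAsFactors = FALSE)
      results[[p]] <- NULL
    } else {
      rows[[p]] <- triage_summary_row(res)
      results[[p]] <- res
    }
  }
  summary <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else empty
  dir.create(dirname(out_csv), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary, out_csv, row.names = FALSE)
  write_config_snapshot(list(subcommand = "triage",
                             thresholds = unclass(thresholds),
                             n_pairs = nrow(summary)),
                        dirname(out_csv))
  invisible(list(status = 0L, summary = summary, results = results))
}

#' Detect fusion events in a movie file and write outputs
#'
#' Reads a movie ([read_movie()]), runs the detection pipeline
#' ([detect_fusion_events()]) and writes `events.csv`, the 10-s release
#' series `release_series.csv`, the per-area density and a resolved-config
#' snapshot to `out_dir`. Without stimulation metadata the density covers
#' the whole acquisition (with a warning).
#'
#' @param movie_path Path to a `.tif`/`.tiff`/`.bin` movie.
#' @param out_dir Output directory.
#' @param config A [detection_config()].
#' @param mask Optional logical matrix (or path to a TIFF mask) for the
#'   footprint; default [estimate_footprint()].
#' @param meta Optional sidecar JSON path.
#' @return Invisibly, a list with `status` (0), `result`
#'   (the [detect_fusion_events()] object), `density_per_um2` and output
#'   paths.
#' @export
run_fusion <- function(movie_path, out_dir, config = detection_config(),
                       mask = NULL, meta = NULL) {
  if (!file.exists(movie_path))
    input_error("movie not found: %s", movie_path)
  mov <- tryCatch(read_movie(movie_path, meta = meta),
                  error = function(e)
                    input_error("failed to read %s: %s", movie_path,
                                conditionMessage(e)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- detect_fusion_events(mov, config)
  if (is.character(mask)) {
    mask <- tiff::readTIFF(mask) > 0.5
  }
  if (is.null(mask)) mask <- estimate_footprint(mov)
  density <- events_per_area(result, mov, mask)
  series <- cumulative_release(result)
  write_events_csv(result, file.path(out_dir, "events.csv"))
  utils::write.csv(
    data.frame(bin_start_s = series$bin_start_s, count = series$counts,
               cumulative = series$cumulative),
    file.path(out_dir, "release_series.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_completed = sum(result$events$completed),
         n_ongoing = sum(!result$events$completed),
         density_per_um2 = density,
         footprint_px = sum(mask)),
    file.path(out_dir, "fusion_summary.json"), auto_unbox = TRUE,
    digits = NA)
  write_config_snapshot(list(subcommand = "fusion-call",
                             input = movie_path,
                             config = unclass(config)), out_dir)
  invisible(list(status = 0L, result = result, density_per_um2 = density,
                 events_csv = file.path(out_dir, "events.csv")))
}

#' Compare two groups of per-cell event densities from CSV
#'
#' Each CSV needs a `density_per_um2` (or single numeric) column; writes a
#' comparison JSON with the U statistic and two-sided p-value.
#'
#' @param csv_a,csv_b Input CSV paths.
#' @param out_json Output JSON path.
#' @return Invisibly, the [mann_whitney_u()] result with `status`.
#' @export
run_fusion_compare <- function(csv_a, csv_b, out_json) {
  read_group <- function(p) {
    if (!file.exists(p)) input_error("group CSV not found: %s", p)
    tab <- utils::read.csv(p)
    col <- if ("density_per_um2" %in% names(tab)) "density_per_um2"
           else names(tab)[vapply(tab, is.numeric, logical(1))][1]
    if (is.na(col)) input_error("no numeric column in %s", p)
    tab[[col]]
  }
  cmp <- mann_whitney_u(read_group(csv_a), read_group(csv_b))
  dir.create(dirname(out_json), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_a = length(cmp$group_a_values), n_b = length(cmp$group_b_values),
         u_statistic = cmp$u_statistic, u_prime = cmp$u_prime,
         p_value = cmp$p_value, method = cmp$method),
    out_json, auto_unbox = TRUE, digits = NA)
  cmp$status <- 0L
  invisible(cmp)
}
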