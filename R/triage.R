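# Screening verdicts: combine iPTM, inter-chain PAE signal, model
# consistency and contact chemistry into a per-pair triage result.

#' Thresholds for predicted-complex triage
#'
#' Operationalises the screening judgment used when scanning large
#' candidate-interactor sets with AlphaFold2-Multimer: a candidate is
#' promoted when its across-model mean iPTM clears `iptm` AND the
#' inter-chain PAE shows a genuine signal (minimum inter-chain PAE at most
#' `min_pae` and at least a fraction `min_frac_below` of inter-chain
#' entries below `pae_cutoff`). A "strong PAE signal" is a visual call in
#' practice; these defaults encode it conservatively and are all
#' configurable.
#'
#' @param iptm Mean-iPTM gate (default 0.3).
#' @param pae_cutoff Angstrom cutoff defining "low" inter-chain PAE
#'   (default 10).
#' @param min_pae Maximum allowed minimum inter-chain PAE (default 10).
#' @param min_frac_below Minimum fraction of inter-chain entries below
#'   `pae_cutoff` (default 0.01).
#' @param per_model_iptm Gate every model's iPTM instead of the mean
#'   (default `FALSE`, the averaged reading).
#' @param contact_cutoff Heavy-atom contact distance for the supporting
#'   contact report (default 4.0).
#' @return A list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(iptm = 0.3, pae_cutoff = 10, min_pae = 10,
                              min_frac_below = 0.01, per_model_iptm = FALSE,
                              contact_cutoff = 4.0) {
  structure(list(iptm = iptm, pae_cutoff = pae_cutoff, min_pae = min_pae,
                 min_frac_below = min_frac_below,
                 per_model_iptm = per_model_iptm,
                 contact_cutoff = contact_cutoff),
            class = "triage_thresholds")
}

#' Triage a prediction bundle into a direct-interactor verdict
#'
#' Applies the two gating criteria (mean iPTM and inter-chain PAE signal;
#' see [triage_thresholds()]) and reports cross-model consistency RMSD and
#' interface contact chemistry as supporting, non-gating evidence --
#' mirroring a two-stage screen in which gated candidates are confirmed by
#' eye. The verdict is `interactor_candidate` when both gates pass,
#' `no_call` otherwise; `rejected` is reserved for bundles that fail to
#' load (see [run_screen()]).
#'
#' Bundle-level PAE statistics aggregate per-model block statistics: the
#' minimum over models of the per-model minimum, and the mean over models
#' of the per-model fraction below cutoff, so improving any single model's
#' confidence can only help a candidate.
#'
#' @param bundle A [prediction_bundle()].
#' @param thresholds A [triage_thresholds()].
#' @return An object of class `triage_result` with fields `pair_id`,
#'   `mean_iptm`, `min_interchain_pae`, `frac_interchain_pae_below_cutoff`,
#'   `consistency_rmsd` (`NA` for single-model bundles), `n_contacts`,
#'   `contact_classes`, `mean_plddt` and `verdict`.
#' @export
triage <- function(bundle, thresholds = triage_thresholds()) {
  stopifnot(inherits(bundle, "prediction_bundle"),
            inherits(thresholds, "triage_thresholds"))
  bait <- bundle$chain_map$bait
  cand <- bundle$chain_map$candidate
  miptm <- mean_iptm(bundle)
  stats_per_model <- lapply(bundle$models, interchain_pae, bait, cand,
                            cutoff = thresholds$pae_cutoff)
  min_pae <- min(vapply(stats_per_model, `[[`, numeric(1), "min"))
  frac_below <- mean(vapply(stats_per_model, `[[`, numeric(1),
                            "frac_below_cutoff"))
  consistency <- if (length(bundle$models) >= 2L)
    as.numeric(model_consistency(bundle)) else NA_real_
  contacts <- interface_contacts(bundle$models[[1]], bait, cand,
                                 distance_cutoff = thresholds$contact_cutoff)
  classes <- c(hydrophobic = sum(contacts$class == "hydrophobic"),
               polar = sum(contacts$class == "polar"),
               electrostatic = sum(contacts$class == "electrostatic"))
  plddt_all <- unlist(lapply(bundle$models, `[[`, "plddt"))
  mean_plddt <- if (length(plddt_all)) mean(plddt_all) else NA_real_

  iptm_ok <- if (thresholds$per_model_iptm) {
    vals <- vapply(bundle$models, `[[`, numeric(1), "iptm")
    all(!is.na(vals)) && all(vals >= thresholds$iptm)
  } else miptm >= thresholds$iptm
  pae_ok <- (min_pae <= thresholds$min_pae) &&
    (frac_below >= thresholds$min_frac_below)
  verdict <- if (iptm_ok && pae_ok) "interactor_candidate" else "no_call"

  structure(
    list(pair_id = bundle$pair_id, mean_iptm = miptm,
         min_interchain_pae = min_pae,
         frac_interchain_pae_below_cutoff = frac_below,
         consistency_rmsd = consistency,
         n_contacts = nrow(contacts), contact_classes = classes,
         contacts = contacts, mean_plddt = mean_plddt,
         verdict = verdict, thresholds = thresholds),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("Triage of '%s': %s\n", x$pair_id, toupper(x$verdict)))
  cat(sprintf("  mean iPTM %.3f | min inter-chain PAE %.2f A | frac < %g A: %.3f\n",
              x$mean_iptm, x$min_interchain_pae, x$thresholds$pae_cutoff,
              x$frac_interchain_pae_below_cutoff))
  cat(sprintf("  consistency RMSD %.2f A | %d interface contacts (%d hydrophobic, %d polar, %d electrostatic)\n",
              x$consistency_rmsd, x$n_contacts,
              x$contact_classes["hydrophobic"], x$contact_classes["polar"],
              x$contact_classes["electrostatic"]))
  invisible(x)
}

#' Write a triage result to JSON
#'
#' @param result A [triage()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_triage_json <- function(result, path) {
  stopifnot(inherits(result, "triage_result"))
  out <- result[c("pair_id", "mean_iptm", "min_interchain_pae",
                  "frac_interchain_pae_below_cutoff", "consistency_rmsd",
                  "n_contacts", "mean_plddt", "verdict")]
  out$contact_classes <- as.list(result$contact_classes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# One summary row per pair, the machine analog of a screening supplementary
# table.
triage_summary_row <- function(result) {
  data.frame(pair_id = result$pair_id,
             mean_iptm = result$mean_iptm,
             min_interchain_pae = result$min_interchain_pae,
             frac_below_cutoff = result$frac_interchain_pae_below_cutoff,
             consistency_rmsd = result$consistency_rmsd,
             n_contacts = result$n_contacts,
             verdict = result$verdict,
             stringsAsFactors = FALSE)
}
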