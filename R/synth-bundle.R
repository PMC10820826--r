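# Synthetic predicted-complex bundles: an idealized receptor with an
# alpha-helical partner docked against it (the helix-on-domain motif
# geometry typical of peptide-motif complexes), written to disk in the
# formats the triage readers consume, with designed confidence scores.

#' Describe a synthetic triage scenario
#'
#' @param receptor_size Receptor (bait) length in residues (>= 3).
#' @param partner_size Partner (candidate) helix length in residues
#'   (>= 3).
#' @param designed_iptm Numeric vector of per-model iPTM values; its
#'   length sets the number of models (default `c(0.6, 0.6, 0.6)`).
#' @param interchain_pae_level Constant PAE (angstroms) filling the
#'   inter-chain blocks (default 5).
#' @param background_pae_level Ceiling for intra-chain PAE (default 3 in
#'   constant mode; the cap of the smooth-decay mode).
#' @param partner_displacement Per-model rigid displacement of the partner
#'   chain in angstroms (scalar or one per model; default 0).
#' @param coordinate_noise_sd Per-model i.i.d. Gaussian noise applied to
#'   partner-chain coordinates, angstroms (default 0).
#' @param pae_mode `"constant"` (distance-independent per block, default)
#'   or `"smooth"` (intra-chain PAE grows with sequence separation up to
#'   the background level).
#' @param seed Integer seed.
#' @return A list of class `triage_scenario`.
#' @export
triage_scenario <- function(receptor_size = 120, partner_size = 20,
                            designed_iptm = c(0.6, 0.6, 0.6),
                            interchain_pae_level = 5,
                            background_pae_level = 3,
                            partner_displacement = 0,
                            coordinate_noise_sd = 0,
                            pae_mode = c("constant", "smooth"),
                            seed = 1L) {
  if (receptor_size < 3 || partner_size < 3)
    stop("chain sizes must be at least 3 residues")
  if (interchain_pae_level < 0 || background_pae_level < 0)
    stop("PAE levels must be non-negative")
  n_models <- length(designed_iptm)
  if (length(partner_displacement) == 1L)
    partner_displacement <- rep(partner_displacement, n_models)
  if (length(partner_displacement) != n_models)
    stop("partner_displacement must be scalar or one value per model")
  structure(list(receptor_size = receptor_size, partner_size = partner_size,
                 designed_iptm = designed_iptm,
                 interchain_pae_level = interchain_pae_level,
                 background_pae_level = background_pae_level,
                 partner_displacement = partner_displacement,
                 coordinate_noise_sd = coordinate_noise_sd,
                 pae_mode = match.arg(pae_mode), seed = as.integer(seed)),
            class = "triage_scenario")
}

# Idealized receptor: a gently curved extended backbone (N, CA, C, O per
# residue plus charged side-chain tips on a repeating sequence) lying
# along x. Residue chemistry cycles so interfaces exhibit hydrophobic,
# polar and electrostatic contacts.
receptor_coords <- function(n_res) {
  seq_cycle <- c("ALA", "LEU", "LYS", "SER", "GLU")
  rows <- list()
  for (i in seq_len(n_res)) {
    resid <- seq_cycle[(i - 1L) %% length(seq_cycle) + 1L]
    cx <- 3.0 * i
    cy <- 1.5 * sin(i / 8)   # gentle curvature: avoids collinearity
    cz <- 0
    at <- rbind(
      c("N",  cx - 1.2, cy + 0.9, cz),
      c("CA", cx,       cy,       cz),
      c("C",  cx + 1.2, cy + 0.9, cz),
      c("O",  cx + 1.3, cy + 2.1, cz))
    if (resid == "LYS") at <- rbind(at, c("NZ", cx, cy - 2.2, cz + 1.2))
    if (resid == "GLU") at <- rbind(at, c("OE1", cx, cy - 2.2, cz - 1.2),
                                    c("OE2", cx + 0.8, cy - 2.8, cz - 1.2))
    if (resid == "LEU") at <- rbind(at, c("CD1", cx, cy - 1.8, cz + 0.8))
    if (resid == "SER") at <- rbind(at, c("OG", cx, cy - 1.6, cz))
    rows[[i]] <- data.frame(chain = "A", resno = i, resid = resid,
                            elety = at[, 1],
                            x = as.numeric(at[, 2]),
                            y = as.numeric(at[, 3]),
                            z = as.numeric(at[, 4]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Acidic alpha-helical partner: ideal helix (1.5 A rise, 100 deg/residue,
# 2.3 A CA radius) with its axis parallel to the receptor, docked against
# the receptor's side-chain face.
partner_coords <- function(n_res, receptor_len) {
  seq_cycle <- c("GLU", "GLU", "ASP", "ILE", "ASP", "GLN", "ILE", "VAL",
                 "ALA", "GLU")
  x0 <- 3.0 * (receptor_len / 2 - n_res * 0.25)  # centred on the receptor
  rows <- list()
  for (i in seq_len(n_res)) {
    resid <- seq_cycle[(i - 1L) %% length(seq_cycle) + 1L]
    phi <- i * 100 * pi / 180
    cx <- x0 + 1.5 * i
    cy <- -7.4 + 2.3 * cos(phi)  # docked: closest approach ~3.3 A
    cz <- 2.3 * sin(phi)
    at <- rbind(
      c("N",  cx - 0.9, cy + 0.6, cz),
      c("CA", cx,       cy,       cz),
      c("C",  cx + 0.9, cy + 0.6, cz),
      c("O",  cx + 1.0, cy + 1.8, cz))
    if (resid %in% c("GLU", "ASP")) {
      tip <- if (resid == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
      at <- rbind(at, c(tip[1], cx, cy + 1.6, cz + 0.8),
                  c(tip[2], cx + 0.7, cy + 2.2, cz + 0.8))
    }
    if (resid %in% c("ILE", "VAL"))
      at <- rbind(at, c("CG1", cx, cy + 1.4, cz - 0.8))
    rows[[i]] <- data.frame(chain = "B", resno = i, resid = resid,
                            elety = at[, 1],
                            x = as.numeric(at[, 2]),
                            y = as.numeric(at[, 3]),
                            z = as.numeric(at[, 4]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

build_scenario_pae <- function(scenario) {
  na <- scenario$receptor_size; nb <- scenario$partner_size
  n <- na + nb
  pae <- matrix(scenario$interchain_pae_level, n, n)
  fill_intra <- function(idx) {
    if (scenario$pae_mode == "constant") {
      pae[idx, idx] <<- scenario$background_pae_level
    } else {
      sep <- abs(outer(seq_along(idx), seq_along(idx), "-"))
      pae[idx, idx] <<- pmin(scenario$background_pae_level, 0.5 + 0.25 * sep)
    }
  }
  fill_intra(seq_len(na))
  fill_intra(na + seq_len(nb))
  pae
}

#' Generate a synthetic prediction bundle on disk
#'
#' Builds per-rank coordinate (PDB) and score (JSON) files for a
#' receptor + helical-partner complex with the scenario's designed iPTM
#' values, constant inter-chain PAE blocks and per-model partner
#' perturbations, plus a manifest JSON tying them together. Generation
#' fails if the perturbed chains clash (any inter-chain atom pair closer
#' than 1.5 A).
#'
#' @param scenario A [triage_scenario()].
#' @param dir Output directory (created if needed).
#' @param pair_id Pair identifier (default `"synthetic_pair"`).
#' @return List with `bundle` (the in-memory [prediction_bundle()]),
#'   `manifest` (manifest JSON path) and `dir`.
#' @export
gen_prediction_bundle <- function(scenario, dir = tempfile("bundle_"),
                                  pair_id = "synthetic_pair") {
  stopifnot(inherits(scenario, "triage_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(scenario$seed)
  rec <- receptor_coords(scenario$receptor_size)
  par0 <- partner_coords(scenario$partner_size, scenario$receptor_size)
  # adaptive docking: nudge the helix along y until the closest approach
  # sits in the contact range regardless of the chain lengths
  for (it in 1:100) {
    d0 <- min_interchain_distance(rec, par0)
    if (d0 >= 3.2 && d0 <= 3.8) break
    par0$y <- par0$y + if (d0 < 3.2) -0.2 else 0.2
  }
  pae <- build_scenario_pae(scenario)
  n_models <- length(scenario$designed_iptm)
  model_paths <- score_paths <- character(n_models)
  for (k in seq_len(n_models)) {
    par_k <- par0
    par_k$z <- par_k$z + scenario$partner_displacement[k]
    if (scenario$coordinate_noise_sd > 0) {
      nz <- nrow(par_k)
      par_k$x <- par_k$x + stats::rnorm(nz, sd = scenario$coordinate_noise_sd)
      par_k$y <- par_k$y + stats::rnorm(nz, sd = scenario$coordinate_noise_sd)
      par_k$z <- par_k$z + stats::rnorm(nz, sd = scenario$coordinate_noise_sd)
    }
    atoms <- rbind(rec, par_k)
    d_min <- min_interchain_distance(rec, par_k)
    if (d_min < 1.5)
      stop(sprintf("scenario produces clashing chains (closest approach %.2f A)",
                   d_min))
    model_paths[k] <- file.path(dir, sprintf("model_%d.pdb", k))
    score_paths[k] <- file.path(dir, sprintf("scores_%d.json", k))
    plddt <- c(rep(90, scenario$receptor_size), rep(75, scenario$partner_size))
    write_model_pdb(atoms, plddt, model_paths[k])
    jsonlite::write_json(
      list(iptm = scenario$designed_iptm[k], ptm = scenario$designed_iptm[k],
           pae = pae),
      score_paths[k], auto_unbox = TRUE, digits = NA)
  }
  chain_map <- list(bait = "A", candidate = "B")
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(pair_id = pair_id, chain_map = chain_map,
         models = data.frame(model_path = basename(model_paths),
                             scores_path = basename(score_paths))),
    manifest, auto_unbox = TRUE, digits = NA)
  bundle <- load_prediction_bundle(model_paths, score_paths, chain_map,
                                   pair_id = pair_id)
  list(bundle = bundle, manifest = manifest, dir = dir)
}

min_interchain_distance <- function(a, b) {
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

# Write a minimal all-ATOM PDB with pLDDT in the B-factor column.
write_model_pdb <- function(atoms, plddt_per_res, path) {
  res_key <- paste(atoms$chain, atoms$resno)
  b <- plddt_per_res[match(res_key, unique(res_key))]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, chain = atoms$chain,
                   resid = atoms$resid, elety = atoms$elety, b = b)
  invisible(path)
}

#' Load a prediction bundle from a manifest JSON
#'
#' The manifest lists `pair_id`, `chain_map` (`bait`, `candidate`) and a
#' `models` table with `model_path` and `scores_path` (relative paths are
#' resolved against the manifest's directory).
#'
#' @param manifest_path Path to the manifest JSON.
#' @return A [prediction_bundle()].
#' @export
read_bundle_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path))
  mf <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(mf$models) || !nrow(as.data.frame(mf$models)))
    stop(sprintf("manifest %s lists no models", manifest_path))
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  models <- as.data.frame(mf$models)
  load_prediction_bundle(resolve(models$model_path),
                         resolve(models$scores_path),
                         chain_map = mf$chain_map,
                         pair_id = mf$pair_id)
}
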