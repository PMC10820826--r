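# Containers for predicted-complex models (AlphaFold2-Multimer style
# output): per-model coordinates, per-residue confidence (pLDDT), the PAE
# matrix and the iPTM/pTM ranking scores, plus the bundle of ranked models
# for one candidate pair.

#' Construct a single predicted-complex model
#'
#' @param atoms data.frame with columns `chain`, `resno` (1-based, author
#'   numbering, strictly increasing within a chain), `resid` (3-letter
#'   residue name), `elety` (atom name), `elesy` (element symbol) and
#'   `x`, `y`, `z` in angstroms.
#' @param pae Square predicted-aligned-error matrix (angstroms), indexed by
#'   concatenated residue order (rows = aligned-on residue); entries >= 0.
#' @param iptm Interface predicted TM-score in `[0, 1]`, or `NA` if absent.
#' @param ptm Predicted TM-score in `[0, 1]`, or `NA`.
#' @param plddt Per-residue confidence in `[0, 100]` (one value per
#'   residue, concatenated order), or `NULL`.
#' @param model_rank Integer rank (>= 1) of the model in its bundle.
#' @return An object of class `predicted_complex`. Also carries a
#'   `residues` data.frame mapping (chain, resno) to PAE row/column index.
#' @export
predicted_complex <- function(atoms, pae, iptm = NA_real_, ptm = NA_real_,
                              plddt = NULL, model_rank = 1L) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in%
                  names(atoms)))
  if (!"elesy" %in% names(atoms))
    atoms$elesy <- guess_element(atoms$elety)
  if (any(!nzchar(as.character(atoms$chain))) || anyNA(atoms$chain))
    stop("every atom needs a non-empty chain id")
  residues <- unique(atoms[, c("chain", "resno")])
  for (ch in unique(residues$chain)) {
    r <- residues$resno[residues$chain == ch]
    if (any(diff(r) <= 0))
      stop(sprintf("residue indices must be strictly increasing within chain %s", ch))
  }
  residues$index <- seq_len(nrow(residues))
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae))
    stop("pae must be square")
  if (nrow(pae) != nrow(residues))
    stop(sprintf("pae dimension (%d) does not match residue count (%d)",
                 nrow(pae), nrow(residues)))
  if (any(pae < 0)) stop("pae entries must be non-negative")
  if (!is.na(iptm) && (iptm < 0 || iptm > 1)) stop("iptm must lie in [0, 1]")
  if (!is.null(plddt)) {
    if (length(plddt) != nrow(residues))
      stop("plddt must have one value per residue")
    if (any(plddt < 0 | plddt > 100)) stop("plddt must lie in [0, 100]")
  }
  structure(
    list(model_rank = as.integer(model_rank), atoms = atoms,
         residues = residues, pae = pae, iptm = as.numeric(iptm),
         ptm = as.numeric(ptm), plddt = plddt),
    class = "predicted_complex"
  )
}

# Standard PDB convention: element is the first letter of the atom name
# once leading digits are stripped (all-heavy-atom models here).
guess_element <- function(elety) {
  substr(gsub("^[0-9]+", "", as.character(elety)), 1, 1)
}

#' @export
print.predicted_complex <- function(x, ...) {
  cat(sprintf("Predicted complex model (rank %d): %d chains, %d residues, %d atoms\n",
              x$model_rank, length(unique(x$atoms$chain)), nrow(x$residues),
              nrow(x$atoms)))
  cat(sprintf("  iPTM %.3g, pTM %.3g, PAE %dx%d\n", x$iptm, x$ptm,
              nrow(x$pae), ncol(x$pae)))
  invisible(x)
}

#' Construct a prediction bundle for one candidate pair
#'
#' @param pair_id Identifier for the (bait, candidate) pair.
#' @param models List of [predicted_complex()] models; sorted by
#'   `model_rank`. All models must share an identical chain/residue
#'   composition.
#' @param chain_map Named list with character vectors `bait` and
#'   `candidate` giving the chain ids of each side.
#' @return An object of class `prediction_bundle`.
#' @export
prediction_bundle <- function(pair_id, models, chain_map) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "predicted_complex")),
            is.list(chain_map), all(c("bait", "candidate") %in% names(chain_map)))
  models <- models[order(vapply(models, `[[`, integer(1), "model_rank"))]
  ref <- models[[1]]$residues[, c("chain", "resno")]
  for (m in models[-1]) {
    if (!identical(m$residues[, c("chain", "resno")], ref))
      stop("all models in a bundle must share the same chain/residue composition")
  }
  chains <- unique(ref$chain)
  mapped <- c(chain_map$bait, chain_map$candidate)
  unknown <- setdiff(mapped, chains)
  if (length(unknown))
    stop(sprintf("chain_map names chains absent from the models: %s",
                 paste(unknown, collapse = ", ")))
  if (length(intersect(chain_map$bait, chain_map$candidate)))
    stop("bait and candidate chain sets must be disjoint")
  structure(list(pair_id = pair_id, models = models, chain_map = chain_map),
            class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("Prediction bundle '%s': %d models, bait chains {%s}, candidate chains {%s}\n",
              x$pair_id, length(x$models),
              paste(x$chain_map$bait, collapse = ","),
              paste(x$chain_map$candidate, collapse = ",")))
  invisible(x)
}

#' Load a prediction bundle from coordinate and score files
#'
#' Reads ranked model coordinates (PDB or mmCIF, chosen by file extension)
#' and their score files (JSON; both the compact `{"pae": [[...]]}` dialect
#' and the `{"predicted_aligned_error": [[...]]}` dialect are accepted, with
#' `iptm`/`ptm` when present). Per-residue pLDDT is taken from the
#' coordinate B-factor column, the AlphaFold convention.
#'
#' @param model_paths Character vector of coordinate file paths, one per
#'   model, in rank order.
#' @param score_paths Character vector of score JSON paths, parallel to
#'   `model_paths`.
#' @param chain_map Named list with `bait` and `candidate` chain id vectors.
#' @param pair_id Identifier for the pair; defaults to the basename of the
#'   first model file.
#' @return A [prediction_bundle()].
#' @export
load_prediction_bundle <- function(model_paths, score_paths, chain_map,
                                   pair_id = NULL) {
  stopifnot(length(model_paths) >= 1L,
            length(model_paths) == length(score_paths))
  if (is.null(pair_id))
    pair_id <- sub("\\.(pdb|cif)$", "", basename(model_paths[1]))
  models <- vector("list", length(model_paths))
  for (i in seq_along(model_paths)) {
    coords <- read_structure_file(model_paths[i])
    scores <- read_scores_json(score_paths[i])
    n_res <- nrow(unique(coords$atoms[, c("chain", "resno")]))
    if (nrow(scores$pae) != n_res)
      stop(sprintf("PAE dimension (%d) in %s does not match residue count (%d) in %s",
                   nrow(scores$pae), score_paths[i], n_res, model_paths[i]))
    models[[i]] <- predicted_complex(
      atoms = coords$atoms, pae = scores$pae, iptm = scores$iptm,
      ptm = scores$ptm, plddt = coords$plddt, model_rank = i)
  }
  prediction_bundle(pair_id, models, chain_map)
}

# Coordinate reader dispatching on extension; bio3d handles both formats.
read_structure_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("coordinate file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  pdb <- switch(ext,
    pdb = bio3d::read.pdb(path, verbose = FALSE),
    cif = bio3d::read.cif(path, verbose = FALSE),
    stop(sprintf("unsupported coordinate format '.%s' in %s", ext, path)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety,
                      elesy = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                     guess_element(at$elety), at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  res_key <- !duplicated(paste(atoms$chain, atoms$resno))
  plddt <- at$b[res_key]
  if (all(is.na(plddt)) || any(plddt < 0 | plddt > 100, na.rm = TRUE))
    plddt <- NULL
  list(atoms = atoms, plddt = plddt)
}

read_scores_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("score file not found: %s", path))
  scores <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e)
                       stop(sprintf("failed to parse score file %s: %s",
                                    path, conditionMessage(e)), call. = FALSE))
  # AlphaFold writes either a bare object or a length-1 array of objects.
  if (is.data.frame(scores)) scores <- as.list(scores[1, , drop = TRUE])
  if (is.list(scores) && is.null(names(scores)) && length(scores) == 1L)
    scores <- scores[[1]]
  pae <- scores$pae
  if (is.null(pae)) pae <- scores$predicted_aligned_error
  if (is.null(pae))
    stop(sprintf("score file %s carries no PAE matrix (keys 'pae' or 'predicted_aligned_error')",
                 path))
  pae <- as.matrix(pae)
  iptm <- if (!is.null(scores$iptm)) as.numeric(scores$iptm) else NA_real_
  ptm <- if (!is.null(scores$ptm)) as.numeric(scores$ptm) else NA_real_
  list(pae = pae, iptm = iptm, ptm = ptm)
}

# Residue-level PAE indices for a chain set, via the bundle bookkeeping.
residue_indices <- function(model, chains) {
  idx <- model$residues$index[model$residues$chain %in% chains]
  if (!length(idx))
    stop(sprintf("no residues found for chain(s) %s",
                 paste(chains, collapse = ", ")))
  idx
}
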