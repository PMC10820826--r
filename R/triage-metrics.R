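# Confidence and interface evidence extracted from predicted-complex
# models: across-model iPTM, inter-chain PAE block statistics, and
# chemistry-classified interface contacts.

#' Across-model mean iPTM of a prediction bundle
#'
#' @param bundle A [prediction_bundle()]; at least one model must carry an
#'   iPTM value.
#' @return Arithmetic mean of the per-model iPTM scores (missing values
#'   dropped).
#' @export
mean_iptm <- function(bundle) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  vals <- vapply(bundle$models, `[[`, numeric(1), "iptm")
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no model in the bundle carries an iPTM value")
  mean(vals)
}

#' Inter-chain PAE block statistics of one model
#'
#' Pools the two off-diagonal PAE blocks between the bait and candidate
#' chain sets (bait rows x candidate columns, and the transpose block;
#' PAE is treated as asymmetric, so both are kept) and summarises them. Low
#' values indicate a confident relative placement of the two chains.
#'
#' @param model A [predicted_complex()].
#' @param bait_chains,candidate_chains Non-empty, disjoint chain id sets.
#' @param cutoff Angstrom cutoff for `frac_below_cutoff` (default 10).
#' @return List with `min`, `mean` and `frac_below_cutoff` of the pooled
#'   inter-chain PAE entries.
#' @export
interchain_pae <- function(model, bait_chains, candidate_chains,
                           cutoff = 10) {
  stopifnot(inherits(model, "predicted_complex"))
  if (!length(bait_chains) || !length(candidate_chains))
    stop("both chain sets must be non-empty")
  if (length(intersect(bait_chains, candidate_chains)))
    stop("bait and candidate chain sets must be disjoint")
  i <- residue_indices(model, bait_chains)
  j <- residue_indices(model, candidate_chains)
  block <- c(model$pae[i, j], model$pae[j, i])
  list(min = min(block), mean = mean(block),
       frac_below_cutoff = mean(block < cutoff))
}

# Side-chain atoms engaged in salt bridges (charged-group N/O).
ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))

#' Enumerate and classify inter-chain interface contacts
#'
#' Finds all heavy-atom (non-hydrogen) pairs across the bait/candidate
#' interface within `distance_cutoff` and classifies each contacting
#' residue pair by the most specific interaction chemistry it exhibits:
#'
#' * `electrostatic` - an Asp/Glu side-chain carboxylate oxygen within the
#'   salt-bridge distance (4.0 A) of an Arg/Lys/His side-chain nitrogen;
#' * `polar` - any N/O donor-acceptor pair within hydrogen-bond distance
#'   (3.5 A);
#' * `hydrophobic` - contacting through carbon-carbon pairs only.
#'
#' @param model A [predicted_complex()].
#' @param bait_chains,candidate_chains Disjoint chain id sets.
#' @param distance_cutoff Heavy-atom contact cutoff in angstroms
#'   (default 4.0).
#' @param hbond_cutoff N/O-N/O hydrogen-bond distance (default 3.5).
#' @param salt_bridge_cutoff Charged-group N-O distance (default 4.0).
#' @return data.frame with one row per contacting residue pair:
#'   `bait_chain`, `bait_resno`, `bait_resid`, `cand_chain`, `cand_resno`,
#'   `cand_resid`, `min_dist`, `n_atom_pairs`, `class`. Empty selections
#'   give a zero-row frame, not an error.
#' @export
interface_contacts <- function(model, bait_chains, candidate_chains,
                               distance_cutoff = 4.0, hbond_cutoff = 3.5,
                               salt_bridge_cutoff = 4.0) {
  stopifnot(inherits(model, "predicted_complex"))
  if (length(intersect(bait_chains, candidate_chains)))
    stop("bait and candidate chain sets must be disjoint")
  at <- model$atoms
  heavy <- toupper(at$elesy) != "H"
  a <- at[heavy & at$chain %in% bait_chains, , drop = FALSE]
  b <- at[heavy & at$chain %in% candidate_chains, , drop = FALSE]
  empty <- data.frame(bait_chain = character(), bait_resno = integer(),
                      bait_resid = character(), cand_chain = character(),
                      cand_resno = integer(), cand_resid = character(),
                      min_dist = numeric(), n_atom_pairs = integer(),
                      class = character(), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)

  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  hit <- which(d <= distance_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)

  ia <- hit[, 1]; ib <- hit[, 2]
  pair_key <- paste(a$chain[ia], a$resno[ia], b$chain[ib], b$resno[ib],
                    sep = "|")
  dist <- d[hit]

  is_sc_acid <- function(tab, idx) {
    resid <- tab$resid[idx]; ety <- tab$elety[idx]
    mapply(function(r, e) r %in% names(ACIDIC_O) && e %in% ACIDIC_O[[r]],
           resid, ety, USE.NAMES = FALSE)
  }
  is_sc_base <- function(tab, idx) {
    resid <- tab$resid[idx]; ety <- tab$elety[idx]
    mapply(function(r, e) r %in% names(BASIC_N) && e %in% BASIC_N[[r]],
           resid, ety, USE.NAMES = FALSE)
  }
  # classification evidence per atom pair (evaluated on the full pair set,
  # including pairs beyond distance_cutoff for the salt-bridge reach when
  # salt_bridge_cutoff > distance_cutoff)
  salt_hits <- which(d <= salt_bridge_cutoff, arr.ind = TRUE)
  sa <- salt_hits[, 1]; sb <- salt_hits[, 2]
  salt_pair <- (is_sc_acid(a, sa) & is_sc_base(b, sb)) |
    (is_sc_base(a, sa) & is_sc_acid(b, sb))
  salt_keys <- unique(paste(a$chain[sa], a$resno[sa], b$chain[sb],
                            b$resno[sb], sep = "|")[salt_pair])

  ea <- toupper(a$elesy[ia]); eb <- toupper(b$elesy[ib])
  polar_pair <- ea %in% c("N", "O") & eb %in% c("N", "O") &
    dist <= hbond_cutoff
  polar_keys <- unique(pair_key[polar_pair])

  keys <- unique(pair_key)
  parts <- strsplit(keys, "|", fixed = TRUE)
  cls <- ifelse(keys %in% salt_keys, "electrostatic",
                ifelse(keys %in% polar_keys, "polar", "hydrophobic"))
  resid_of <- function(tab) {
    key <- paste(tab$chain, tab$resno)
    stats::setNames(as.character(tab$resid), key)[!duplicated(key)]
  }
  ra <- resid_of(a); rb <- resid_of(b)
  out <- data.frame(
    bait_chain = vapply(parts, `[`, "", 1),
    bait_resno = as.integer(vapply(parts, `[`, "", 2)),
    cand_chain = vapply(parts, `[`, "", 3),
    cand_resno = as.integer(vapply(parts, `[`, "", 4)),
    min_dist = vapply(keys, function(k) min(dist[pair_key == k]), 0),
    n_atom_pairs = vapply(keys, function(k) sum(pair_key == k), 0L),
    class = cls, stringsAsFactors = FALSE, row.names = NULL
  )
  out$bait_resid <- unname(ra[paste(out$bait_chain, out$bait_resno)])
  out$cand_resid <- unname(rb[paste(out$cand_chain, out$cand_resno)])
  out[, c("bait_chain", "bait_resno", "bait_resid", "cand_chain",
          "cand_resno", "cand_resid", "min_dist", "n_atom_pairs", "class")]
}
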