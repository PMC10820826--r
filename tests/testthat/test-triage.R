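# Triage metrics and verdict logic on constructed and generated bundles.

# Minimal two-chain CA-only model with a designed PAE matrix.
toy_model <- function(na = 6, nb = 4, pae = NULL, iptm = 0.5, rank = 1L) {
  mk_chain <- function(chain, n, z) {
    data.frame(chain = chain, resno = seq_len(n), resid = "ALA",
               elety = "CA", elesy = "C",
               x = 3.8 * seq_len(n) + rnorm(n, sd = 0.1),
               y = rnorm(n, sd = 0.5), z = z + rnorm(n, sd = 0.5),
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk_chain("A", na, 0), mk_chain("B", nb, 6))
  if (is.null(pae)) pae <- matrix(10, na + nb, na + nb)
  predicted_complex(atoms, pae, iptm = iptm, ptm = iptm, model_rank = rank)
}

block_pae <- function(na, nb, intra = 3, inter = 20) {
  n <- na + nb
  pae <- matrix(inter, n, n)
  pae[1:na, 1:na] <- intra
  pae[(na + 1):n, (na + 1):n] <- intra
  pae
}

test_that("mean_iptm averages over models and rejects score-free bundles", {
  mods <- list(toy_model(iptm = 0.2, rank = 1L),
               toy_model(iptm = 0.3, rank = 2L),
               toy_model(iptm = 0.4, rank = 3L))
  b <- prediction_bundle("p", mods, list(bait = "A", candidate = "B"))
  expect_equal(mean_iptm(b), 0.3)
  b1 <- prediction_bundle("p1", mods[2], list(bait = "A", candidate = "B"))
  expect_equal(mean_iptm(b1), 0.3)
  expect_equal(mean_iptm(prediction_bundle(
    "p2", list(toy_model(iptm = 0.31), toy_model(iptm = 0.28, rank = 2L),
               toy_model(iptm = 0.35, rank = 3L)),
    list(bait = "A", candidate = "B"))), mean(c(0.31, 0.28, 0.35)))
  none <- prediction_bundle("p3", list(toy_model(iptm = NA)),
                            list(bait = "A", candidate = "B"))
  expect_error(mean_iptm(none), "no model")
})

test_that("inter-chain PAE statistics pool both off-diagonal blocks", {
  m5 <- toy_model(6, 4, block_pae(6, 4, intra = 3, inter = 5))
  s5 <- interchain_pae(m5, "A", "B", cutoff = 10)
  expect_equal(s5, list(min = 5, mean = 5, frac_below_cutoff = 1))
  m30 <- toy_model(6, 4, block_pae(6, 4, intra = 3, inter = 30))
  expect_equal(interchain_pae(m30, "A", "B", cutoff = 10)$frac_below_cutoff, 0)
  expect_error(interchain_pae(m5, "A", "C"), "no residues")
  expect_error(interchain_pae(m5, "A", "A"), "disjoint")
})

test_that("a low-error stripe contributes exactly its block-area fraction", {
  na <- 120; nb <- 20
  pae <- block_pae(na, nb, intra = 2, inter = 28)
  stripe_rows <- 41:53  # 13 bait residues confidently placed vs partner
  pae[stripe_rows, (na + 1):(na + nb)] <- 4
  m <- toy_model(na, nb, pae)
  s <- interchain_pae(m, "A", "B", cutoff = 10)
  expect_equal(s$min, 4)
  expect_equal(s$frac_below_cutoff, (13 * nb) / (2 * na * nb))
  # pooled blocks make the statistics invariant to bait/candidate swap
  expect_equal(interchain_pae(m, "B", "A", cutoff = 10), s)
})

test_that("PAE bookkeeping rejects dimension mismatches by naming both counts", {
  atoms <- toy_model(4, 3)$atoms
  expect_error(predicted_complex(atoms, matrix(5, 6, 6)),
               "pae dimension \\(6\\) does not match residue count \\(7\\)")
  expect_error(predicted_complex(atoms, matrix(-1, 7, 7)), "non-negative")
})

test_that("model consistency recovers designed displacements and noise scaling", {
  g0 <- gen_prediction_bundle(triage_scenario(seed = 10), dir = withr::local_tempdir())
  expect_equal(as.numeric(model_consistency(g0$bundle)), 0, tolerance = 1e-9)
  gd <- gen_prediction_bundle(
    triage_scenario(partner_displacement = c(0, 0, 10), seed = 11),
    dir = withr::local_tempdir())
  expect_equal(as.numeric(model_consistency(gd$bundle)), 10,
               tolerance = 1e-6)
  # i.i.d. coordinate noise of sd sigma on both models of a pair gives
  # candidate RMSD ~ sigma * sqrt(6)
  sigma <- 0.4
  rmsds <- vapply(1:6, function(s) {
    g <- gen_prediction_bundle(
      triage_scenario(partner_size = 50, coordinate_noise_sd = sigma,
                      seed = 100 + s),
      dir = withr::local_tempdir())
    as.numeric(model_consistency(g$bundle))
  }, numeric(1))
  expect_lt(abs(mean(rmsds) - sigma * sqrt(6)) / (sigma * sqrt(6)), 0.2)
})

test_that("single-chain and undersized inputs are rejected by the right ops", {
  atoms <- toy_model(6, 4)$atoms
  solo <- atoms[atoms$chain == "A", ]
  m <- predicted_complex(solo, matrix(3, 6, 6), iptm = 0.5)
  b <- prediction_bundle("solo", list(m), list(bait = "A", candidate = character(0)))
  expect_error(interchain_pae(m, "A", "B"), "no residues")
  expect_error(model_consistency(b), "at least 2")
})

test_that("contact classification follows the distance chemistry rules", {
  two_atoms <- function(elety_b, resid_b, elesy_b, dist) {
    atoms <- data.frame(
      chain = c("A", "B"), resno = c(1L, 1L),
      resid = c("GLU", resid_b),
      elety = c("OE1", elety_b), elesy = c("O", elesy_b),
      x = c(0, dist), y = 0, z = 0, stringsAsFactors = FALSE)
    predicted_complex(atoms, matrix(5, 2, 2), iptm = 0.5)
  }
  # bare 3.0 A heavy-atom pair -> one contact
  plain <- interface_contacts(two_atoms("CB", "ALA", "C", 3.0), "A", "B")
  expect_equal(nrow(plain), 1)
  expect_equal(plain$class, "hydrophobic")
  # Glu OE1 at 3.2 A from Arg NH1 -> electrostatic
  salt <- interface_contacts(two_atoms("NH1", "ARG", "N", 3.2), "A", "B")
  expect_equal(salt$class, "electrostatic")
  # backbone N at 3.2 A -> polar, not electrostatic
  polar <- interface_contacts(two_atoms("N", "ALA", "N", 3.2), "A", "B")
  expect_equal(polar$class, "polar")
  # beyond cutoff -> empty, and empty selections are not errors
  expect_equal(nrow(interface_contacts(two_atoms("CB", "ALA", "C", 4.5),
                                       "A", "B")), 0)
})

test_that("contact enumeration equals the brute-force all-pairs oracle", {
  g <- gen_prediction_bundle(triage_scenario(seed = 21),
                             dir = withr::local_tempdir())
  m <- g$bundle$models[[1]]
  got <- interface_contacts(m, "A", "B")
  oracle <- brute_force_contact_pairs(m, "A", "B", cutoff = 4.0)
  got_keys <- sort(paste(got$bait_chain, got$bait_resno, got$cand_chain,
                         got$cand_resno, sep = "|"))
  expect_identical(got_keys, oracle$residue_pairs)
  expect_equal(sum(got$n_atom_pairs), oracle$n_atom_pairs)
})

test_that("triage verdicts follow the iPTM and PAE gates", {
  dir <- withr::local_tempdir()
  strong <- gen_prediction_bundle(triage_scenario(seed = 1), file.path(dir, "s"))
  expect_equal(triage(strong$bundle)$verdict, "interactor_candidate")
  weak <- gen_prediction_bundle(
    triage_scenario(designed_iptm = c(0.1, 0.1, 0.1),
                    interchain_pae_level = 30, seed = 2),
    file.path(dir, "w"))
  expect_equal(triage(weak$bundle)$verdict, "no_call")
  # boundary: mean iPTM exactly at threshold, sparse 9 A stripe
  na <- 120; nb <- 20
  pae <- block_pae(na, nb, intra = 2, inter = 28)
  pae[50:52, (na + 1):(na + nb)] <- 9
  set.seed(3)
  mods <- lapply(1:3, function(k) toy_model(na, nb, pae, iptm = 0.3, rank = k))
  at_thr <- prediction_bundle("boundary", mods,
                              list(bait = "A", candidate = "B"))
  expect_equal(triage(at_thr)$verdict, "interactor_candidate")
  mods_lo <- lapply(1:3, function(k) toy_model(na, nb, pae, iptm = 0.29, rank = k))
  below <- prediction_bundle("boundary_lo", mods_lo,
                             list(bait = "A", candidate = "B"))
  expect_equal(triage(below)$verdict, "no_call")
})

test_that("raising iPTM or lowering PAE never demotes a candidate", {
  set.seed(99)
  na <- 30; nb <- 10
  for (i in 1:40) {
    pae <- matrix(runif((na + nb)^2, 2, 30), na + nb)
    iptm <- runif(3, 0.1, 0.9)
    mods <- lapply(1:3, function(k) toy_model(na, nb, pae, iptm[k], rank = k))
    b <- prediction_bundle("mono", mods, list(bait = "A", candidate = "B"))
    before <- triage(b)$verdict
    # helpful perturbation: raise one model's iPTM, lower some PAE entries
    k <- sample(3, 1)
    mods2 <- mods
    pae2 <- pae
    sel <- sample(length(pae2), 50)
    pae2[sel] <- pae2[sel] * runif(50, 0.2, 1)
    mods2[[k]] <- toy_model(na, nb, pae2,
                            min(1, iptm[k] + runif(1, 0, 0.3)), rank = k)
    for (j in setdiff(1:3, k))
      mods2[[j]] <- toy_model(na, nb, pae2, iptm[j], rank = j)
    b2 <- prediction_bundle("mono2", mods2, list(bait = "A", candidate = "B"))
    after <- triage(b2)$verdict
    if (before == "interactor_candidate") {
      expect_equal(after, "interactor_candidate")
    }
  }
})

test_that("bundle loading round-trips generated files and flags bad scores", {
  dir <- withr::local_tempdir()
  g <- gen_prediction_bundle(triage_scenario(seed = 5), dir)
  b <- g$bundle
  expect_length(b$models, 3)
  expect_equal(dim(b$models[[1]]$pae), c(140, 140))
  # coordinates survive the PDB round trip to 1e-3 A
  reread <- read_bundle_manifest(g$manifest)
  expect_equal(reread$models[[1]]$atoms$x, b$models[[1]]$atoms$x,
               tolerance = 1e-3)
  expect_equal(reread$models[[2]]$iptm, 0.6)
  expect_equal(reread$models[[1]]$plddt[1], 90)
  # truncated score file -> parse error naming the file
  bad <- file.path(dir, "scores_1.json")
  writeLines(substr(paste(readLines(bad), collapse = ""), 1, 50), bad)
  expect_error(
    load_prediction_bundle(file.path(dir, sprintf("model_%d.pdb", 1:3)),
                           file.path(dir, sprintf("scores_%d.json", 1:3)),
                           list(bait = "A", candidate = "B")),
    "scores_1.json")
  # missing iptm is recorded as absent; the bundle still loads
  jsonlite::write_json(list(pae = matrix(5, 140, 140)),
                       file.path(dir, "scores_noiptm.json"), digits = NA)
  b2 <- load_prediction_bundle(
    file.path(dir, "model_2.pdb"), file.path(dir, "scores_noiptm.json"),
    list(bait = "A", candidate = "B"))
  expect_true(is.na(b2$models[[1]]$iptm))
  expect_error(mean_iptm(b2), "no model")
})

test_that("the AlphaFold score dialect with predicted_aligned_error parses", {
  dir <- withr::local_tempdir()
  g <- gen_prediction_bundle(triage_scenario(seed = 6), dir)
  scores <- jsonlite::read_json(file.path(dir, "scores_1.json"),
                                simplifyVector = TRUE)
  jsonlite::write_json(list(predicted_aligned_error = scores$pae,
                            iptm = 0.44, ptm = 0.5),
                       file.path(dir, "scores_alt.json"), auto_unbox = TRUE,
                       digits = NA)
  b <- load_prediction_bundle(file.path(dir, "model_1.pdb"),
                              file.path(dir, "scores_alt.json"),
                              list(bait = "A", candidate = "B"))
  expect_equal(b$models[[1]]$iptm, 0.44)
  expect_equal(dim(b$models[[1]]$pae), c(140, 140))
})
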