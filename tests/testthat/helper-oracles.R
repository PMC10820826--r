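# Independent oracles used to validate the package implementations.
# Every oracle takes a deliberately different computational route from the
# code it checks (bisection vs closed-form quadratic, grid search vs SVD,
# double loops vs vectorised linear algebra, enumeration vs rank formulas).

# --- ITC: equilibrium by bisection on the free-ligand concentration -----

bisection_isotherm_oracle <- function(kd, n, dh, protocol) {
  v0 <- protocol$cell_volume
  m <- protocol$cell_conc
  x <- 0
  prev <- 0
  q <- numeric(length(protocol$injection_volumes))
  for (i in seq_along(protocol$injection_volumes)) {
    v <- protocol$injection_volumes[i]
    d <- v0 / (v0 + v)
    m <- m * d
    x <- x * d + protocol$syringe_conc * v / (v0 + v)
    f <- function(xf) xf + n * m * xf / (kd + xf) - x
    # plain bisection, no uniroot
    lo <- 0; hi <- x
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    xf <- (lo + hi) / 2
    mx <- n * m * xf / (kd + xf)
    q[i] <- dh * 1e9 * v0 * (mx - prev * d)
    prev <- mx
  }
  q
}

# --- Superposition: rotation-grid search with Nelder-Mead refinement ----

euler_rotation <- function(a, b, c) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# Best RMSD over rotations: coarse Euler grid, then simplex refinement of
# the best grid point. Translation is optimal at matched centroids.
rotation_grid_rmsd <- function(reference, moving, step_deg = 15) {
  a <- sweep(reference, 2, colMeans(reference))
  b <- sweep(moving, 2, colMeans(moving))
  rmsd_for <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((b %*% t(r) - a)^2)))
  }
  step <- step_deg * pi / 180
  grid1 <- seq(0, 2 * pi - step, by = step)
  gridb <- seq(0, pi, by = step)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (aa in grid1) for (bb in gridb) for (cc in grid1) {
    v <- rmsd_for(c(aa, bb, cc))
    if (v < best) { best <- v; best_ang <- c(aa, bb, cc) }
  }
  ref <- stats::optim(best_ang, rmsd_for, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(best, ref$value)
}

# --- Contacts: quadratic-loop all-pairs scan ----------------------------

brute_force_contact_pairs <- function(model, bait_chains, candidate_chains,
                                      cutoff = 4.0) {
  at <- model$atoms
  at <- at[toupper(at$elesy) != "H", , drop = FALSE]
  a <- at[at$chain %in% bait_chains, , drop = FALSE]
  b <- at[at$chain %in% candidate_chains, , drop = FALSE]
  pairs <- character(0)
  n_atom_pairs <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      dd <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                   (a$z[i] - b$z[j])^2)
      if (dd <= cutoff) {
        n_atom_pairs <- n_atom_pairs + 1L
        pairs <- c(pairs, paste(a$chain[i], a$resno[i], b$chain[j],
                                b$resno[j], sep = "|"))
      }
    }
  }
  list(residue_pairs = sort(unique(pairs)), n_atom_pairs = n_atom_pairs)
}

# --- Clustering: breadth-first connected components ---------------------

bfs_cluster_oracle <- function(puncta, spatial_eps = 1, temporal_eps = 2,
                               min_size = 3) {
  n <- nrow(puncta)
  if (n == 0L) return(list(sizes = integer(0), membership = integer(0)))
  neighbour <- function(i, j) {
    abs(puncta$x[i] - puncta$x[j]) <= spatial_eps &&
      abs(puncta$y[i] - puncta$y[j]) <= spatial_eps &&
      abs(puncta$t[i] - puncta$t[j]) <= temporal_eps
  }
  membership <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(membership[s])) next
    comp <- comp + 1L
    queue <- s
    membership[s] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (is.na(membership[j]) && neighbour(cur, j)) {
          membership[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  sizes <- tabulate(membership)
  keep <- which(sizes >= min_size)
  list(sizes = sizes, membership = membership,
       n_kept = length(keep),
       kept_sizes = sort(sizes[keep], decreasing = TRUE))
}

# --- Mann-Whitney: exact p by enumeration of all labelings --------------

mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

mw_exact_p_enumeration <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_obs <- mw_u_stat(a, b)
  idx <- utils::combn(na + nb, na)
  half <- na * nb / 2
  count <- 0L
  for (k in seq_len(ncol(idx))) {
    u <- mw_u_stat(pooled[idx[, k]], pooled[-idx[, k]])
    # two-sided: as or more extreme in |U - n_a n_b / 2|
    if (abs(u - half) >= abs(u_obs - half) - 1e-12) count <- count + 1L
  }
  count / ncol(idx)
}

# --- Shared fixtures ----------------------------------------------------

# Small movie settings used by most fusion tests (fast but exercises the
# same interval/cluster arithmetic as the full-scale acquisition).
small_movie_args <- function(seed = 1L, n_events = 6, n_persistors = 2) {
  list(n_events = n_events, n_persistors = n_persistors,
       shape = c(64, 64), n_frames = 600, interval_length = 60,
       min_separation = 8, border = 8, seed = seed)
}

gen_small_movie <- function(seed = 1L, n_events = 6, n_persistors = 2,
                            stimulation_frame = 1L) {
  a <- small_movie_args(seed, n_events, n_persistors)
  sch <- do.call(random_fusion_schedule, a)
  gen_movie(sch, shape = a$shape, n_frames = a$n_frames,
            interval_length = a$interval_length,
            stimulation_frame = stimulation_frame)
}

small_movie_config <- function() detection_config(interval_length = 60)
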