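# Independent brute-force oracles: plain loops with their own periodic
# wrapping, kept deliberately separate from the package's vectorised code.

bf_wrap <- function(d, L) d - L * round(d / L)

bf_dist <- function(p, q, box) {
  sqrt(bf_wrap(p[1] - q[1], box[1])^2 +
       bf_wrap(p[2] - q[2], box[2])^2 +
       bf_wrap(p[3] - q[3], box[3])^2)
}

# minimum bead distance between residue a of molecule ma and residue b of
# molecule mb, by exhaustive scan
bf_residue_min_dist <- function(frame, ma, a, mb, b) {
  box <- frame_box(frame)
  pa <- as.matrix(frame[frame$molecule == ma & frame$resid == a,
                        c("x", "y", "z")])
  pb <- as.matrix(frame[frame$molecule == mb & frame$resid == b,
                        c("x", "y", "z")])
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      best <- min(best, bf_dist(pa[i, ], pb[j, ], box))
    }
  }
  best
}

bf_min_dist_matrix <- function(frame, molecules) {
  resids <- sort(unique(frame$resid[frame$molecule == molecules[1]]))
  n <- length(resids)
  keys <- as.vector(t(outer(molecules, resids, paste, sep = ":")))
  out <- matrix(NA_real_, length(keys), length(keys),
                dimnames = list(keys, keys))
  for (ka in seq_along(keys)) {
    for (kb in ka:length(keys)) {
      ma <- sub(":.*", "", keys[ka]); a <- as.integer(sub(".*:", "", keys[ka]))
      mb <- sub(":.*", "", keys[kb]); b <- as.integer(sub(".*:", "", keys[kb]))
      d <- bf_residue_min_dist(frame, ma, a, mb, b)
      out[ka, kb] <- d
      out[kb, ka] <- d
    }
  }
  out
}

# contact percentages by direct tallying: a residue pair (i, j) is in
# contact for molecule pair (A, B) if either orientation's minimum bead
# distance is <= cutoff
bf_contact_percent <- function(frames, molecules, cutoff = 1.2) {
  resids <- sort(unique(frames[[1]]$resid[
    frames[[1]]$molecule == molecules[1]]))
  n <- length(resids)
  contacts <- matrix(0, n, n)
  total <- 0
  pairs <- combn(molecules, 2)
  for (f in frames) {
    for (k in seq_len(ncol(pairs))) {
      total <- total + 1
      for (i in seq_len(n)) {
        for (j in i:n) {
          hit <- bf_residue_min_dist(f, pairs[1, k], resids[i],
                                     pairs[2, k], resids[j]) <= cutoff ||
                 bf_residue_min_dist(f, pairs[1, k], resids[j],
                                     pairs[2, k], resids[i]) <= cutoff
          if (hit) {
            contacts[i, j] <- contacts[i, j] + 1
            if (i != j) contacts[j, i] <- contacts[j, i] + 1
          }
        }
      }
    }
  }
  100 * contacts / total
}

# total nonbonded energy between two bead index sets by double loop
bf_group_energy <- function(frame, idx_a, idx_b, params) {
  box <- frame_box(frame)
  tot <- 0
  for (i in idx_a) {
    for (j in idx_b) {
      d <- bf_dist(c(frame$x[i], frame$y[i], frame$z[i]),
                   c(frame$x[j], frame$y[j], frame$z[j]), box)
      if (d > 0 && d < params$cutoff) {
        tot <- tot + pair_energy(d, frame$type[i], frame$type[j], params,
                                 q_i = frame$charge[i],
                                 q_j = frame$charge[j])
      }
    }
  }
  tot
}

# empirical Kolmogorov-Smirnov distance to a grid-defined target density
bf_ks_distance <- function(samples, zg, log_dens) {
  dens <- exp(log_dens - max(log_dens))
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2)
  cdf <- c(0, cdf / cdf[length(cdf)])
  emp <- ecdf(samples)
  max(abs(emp(zg) - cdf))
}
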