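# Internal geometry and validation helpers shared across modules.
# All lengths are nm, energies kJ/mol, times ns.

# Minimum-image displacement for a rectangular periodic box.
min_image <- function(d, box_len) {
  if (is.null(box_len) || !is.finite(box_len) || box_len <= 0) {
    return(d)
  }
  d - box_len * round(d / box_len)
}

# Pairwise minimum-image distance matrix between two coordinate matrices
# (n x 3 and m x 3). `box` is a length-3 vector or NULL for no periodicity.
pair_dist_matrix <- function(xyz_a, xyz_b, box = NULL) {
  xyz_a <- as.matrix(xyz_a)
  xyz_b <- as.matrix(xyz_b)
  dx <- outer(xyz_a[, 1], xyz_b[, 1], "-")
  dy <- outer(xyz_a[, 2], xyz_b[, 2], "-")
  dz <- outer(xyz_a[, 3], xyz_b[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box[1])
    dy <- min_image(dy, box[2])
    dz <- min_image(dz, box[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

# log(sum(exp(x))) along rows/cols without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

col_logsumexp <- function(mat) {
  m <- apply(mat, 2, max)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    shifted <- sweep(mat[, finite, drop = FALSE], 2, m[finite], "-")
    out[finite] <- m[finite] + log(colSums(exp(shifted)))
  }
  out
}

# Largest-remainder apportionment of `n` items to fractions `p` (sums to 1).
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) {
    abort("Mole fractions must sum to 1.", class = "cyclomem_input_error")
  }
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

# Derive a 32-bit-safe child seed from a base seed and a stream index.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 104729) %% 2147483647)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (positive && x <= 0)) {
    abort(sprintf("`%s` must be a finite %snumeric scalar.", name,
                  if (positive) "positive " else ""),
          class = "cyclomem_input_error")
  }
  invisible(x)
}
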