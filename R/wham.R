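# Free-energy profile along the membrane normal from umbrella windows via
# the self-consistent weighted histogram analysis method (WHAM), with
# complete-histogram bootstrap error bars. Convention: the reaction
# coordinate is the peptide-membrane COM separation with the membrane COM
# at 0, water at +2 nm, membrane centre at -2 nm; the profile is shifted
# so the water-plateau reference is exactly 0.

#' WHAM configuration
#'
#' @param bin_width Histogram bin width (nm).
#' @param grid_range Length-2 range of the PMF grid (nm); default spans
#'   the samples.
#' @param tolerance Convergence tolerance on the window free-energy
#'   constants (kJ/mol).
#' @param max_iterations Iteration cap.
#' @param temperature Temperature (K).
#' @param n_bootstrap Bootstrap replicate count.
#' @param seed Integer seed for the bootstrap resampling.
#' @param reference_range Length-2 z-range whose mean PMF defines zero
#'   (default `c(1.8, 2)`: the outermost 0.2 nm of the water side).
#' @return A `wham_config` list.
#' @export
wham_config <- function(bin_width = 0.02, grid_range = NULL,
                        tolerance = 1e-6, max_iterations = 100000,
                        temperature = 310, n_bootstrap = 100, seed = 1L,
                        reference_range = c(1.8, 2.0)) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  assert_scalar_number(tolerance, "tolerance", positive = TRUE)
  if (n_bootstrap < 1) {
    abort("`n_bootstrap` must be >= 1.", class = "cyclomem_input_error")
  }
  structure(list(bin_width = bin_width, grid_range = grid_range,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 temperature = temperature,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed),
                 reference_range = reference_range),
            class = "wham_config")
}

#' Umbrella window centres on a regular spacing
#'
#' Inclusive arithmetic sequence from `z_min` to `z_max`; the span must be
#' an integer multiple of the spacing (no silent truncation). Additional
#' windows (e.g. extra centres added to improve histogram overlap) are
#' appended via `extra`.
#'
#' @param z_min,z_max Range (nm).
#' @param spacing Spacing (nm), > 0.
#' @param extra Optional extra centres.
#' @return Sorted numeric vector of centres.
#' @examples
#' length(make_window_centers(-2, 2, 0.1))  # 41
#' @export
make_window_centers <- function(z_min, z_max, spacing, extra = NULL) {
  if (!is.numeric(spacing) || spacing <= 0) {
    abort("`spacing` must be > 0.", class = "cyclomem_input_error")
  }
  if (z_min >= z_max) {
    abort("`z_min` must be < `z_max`.", class = "cyclomem_input_error")
  }
  steps <- (z_max - z_min) / spacing
  if (abs(steps - round(steps)) > 1e-8) {
    abort(sprintf(
      "Span %g is not an integer multiple of spacing %g; adjust the range or pass extra centres explicitly.",
      z_max - z_min, spacing), class = "cyclomem_input_error")
  }
  centers <- z_min + spacing * seq(0, round(steps))
  sort(c(centers, extra))
}

# core self-consistent iteration on precomputed histograms
# h: windows x bins counts; bias: windows x bins (kJ/mol)
# Works with the Boltzmann weight matrix W = exp(-bias/kT) (entries in
# [0, 1], no overflow) and re-centres the window constants each sweep.
wham_iterate <- function(h, bias, kT, tolerance, max_iterations,
                         f_init = NULL) {
  n_w <- nrow(h)
  N <- rowSums(h)
  h_tot <- colSums(h)
  f <- f_init %||% rep(0, n_w)
  W <- exp(-bias / kT)
  resid <- Inf
  log_p <- rep(-Inf, length(h_tot))
  for (it in seq_len(max_iterations)) {
    g <- N * exp((f - max(f)) / kT)
    denom <- as.vector(g %*% W)
    p <- ifelse(denom > 0, h_tot / denom, 0)
    overlap <- as.vector(W %*% p)
    f_new <- -kT * log(overlap)
    if (any(!is.finite(f_new))) {
      abort("A window has no overlap with any populated bin.",
            class = "cyclomem_input_error")
    }
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tolerance) {
      log_p <- ifelse(p > 0, log(p), -Inf)
      return(list(f = f, log_p = log_p, iterations = it, residual = resid,
                  converged = TRUE))
    }
  }
  log_p <- ifelse(p > 0, log(p), -Inf)
  list(f = f, log_p = log_p, iterations = max_iterations, residual = resid,
       converged = FALSE)
}

# common bin grid: covers [rng[1], rng[2]] with a whole number of bins
wham_breaks <- function(rng, bin_width) {
  n_bins <- max(1L, ceiling((rng[2] - rng[1]) / bin_width - 1e-9))
  # the half-width epsilon keeps boundary samples inside the first bin
  rng[1] - 1e-9 + bin_width * seq(0, n_bins)
}

window_histograms <- function(windows, breaks) {
  t(vapply(windows$samples, function(s) {
    hist(s[s >= breaks[1] & s <= breaks[length(breaks)]],
         breaks = breaks, plot = FALSE)$counts
  }, numeric(length(breaks) - 1)))
}

#' Potential of mean force by WHAM
#'
#' Bins every window's samples on a common grid and iterates the standard
#' WHAM self-consistent equations (unbiased bin probabilities from
#' reweighted histogram counts; per-window free-energy constants from the
#' probabilities) until the largest change in the constants drops below
#' the tolerance. The PMF is `-kBT log p(z)` shifted so the mean over the
#' reference range (water plateau) is exactly 0. Bins never visited by any
#' window are returned as `NA` and flagged.
#'
#' @param windows An [umbrella_windows()] tibble.
#' @param config A [wham_config()].
#' @param errors Compute bootstrap errors (see [bootstrap_errors()]).
#' @return A `pmf_profile` tibble: `z`, `pmf`, and `se` when `errors`;
#'   attributes carry the window constants, iteration count and reference.
#' @export
wham <- function(windows, config = wham_config(), errors = FALSE) {
  stopifnot(nrow(windows) >= 1)
  rng <- config$grid_range %||% range(unlist(windows$samples))
  breaks <- wham_breaks(rng, config$bin_width)
  z <- (breaks[-1] + breaks[-length(breaks)]) / 2
  h <- window_histograms(windows, breaks)
  if (all(colSums(h) == 0)) {
    abort("No samples fall inside the PMF grid.",
          class = "cyclomem_input_error")
  }
  bias <- 0.5 * outer(windows$force_constant,
                      rep(1, length(z))) *
    (outer(windows$center, z, function(c, zz) (zz - c)^2))
  kT <- kBT(windows$temperature[1])
  fit <- wham_iterate(h, bias, kT, config$tolerance, config$max_iterations)
  if (!fit$converged) {
    abort(sprintf(
      "WHAM did not converge within %d iterations (last residual %.3g kJ/mol).",
      config$max_iterations, fit$residual),
      class = "cyclomem_convergence_error")
  }
  pmf <- -kT * fit$log_p
  pmf[!is.finite(pmf)] <- NA_real_
  shift <- reference_shift(z, pmf, config$reference_range)
  pmf <- pmf - shift
  out <- tibble::tibble(z = z, pmf = pmf)
  if (any(is.na(pmf))) {
    warn(sprintf("%d PMF bin(s) have no samples and are NA.",
                 sum(is.na(pmf))))
  }
  out <- structure(out,
                   f = fit$f, iterations = fit$iterations,
                   temperature = windows$temperature[1],
                   reference_range = config$reference_range,
                   bin_width = config$bin_width,
                   n_windows = nrow(windows),
                   class = c("pmf_profile", class(tibble::tibble())))
  if (errors) {
    out$se <- bootstrap_errors(windows, config, breaks = breaks,
                               f_init = fit$f)
    attr(out, "n_bootstrap") <- config$n_bootstrap
  }
  out
}

reference_shift <- function(z, pmf, reference_range) {
  ref <- which(z >= reference_range[1] & z <= reference_range[2] &
               !is.na(pmf))
  if (length(ref) == 0) {
    # fall back to the minimum: reference must exist for a defined profile
    ref <- which(!is.na(pmf))
  }
  mean(pmf[ref])
}

#' Bootstrap standard errors of a WHAM profile
#'
#' Complete-histogram bootstrap: each replicate resamples every window's
#' samples with replacement, recomputes the histograms and re-converges
#' WHAM (warm-started), and the per-bin standard deviation across
#' replicates is reported. Deterministic given the config seed. Replicates
#' that fail to converge are dropped with a warning; more than 20% dropped
#' is an error.
#'
#' @param windows An [umbrella_windows()] tibble.
#' @param config A [wham_config()].
#' @param breaks Optional precomputed bin breaks.
#' @param f_init Optional warm-start window constants.
#' @return Numeric vector of per-bin standard errors (kJ/mol).
#' @export
bootstrap_errors <- function(windows, config = wham_config(), breaks = NULL,
                             f_init = NULL) {
  if (is.null(breaks)) {
    rng <- config$grid_range %||% range(unlist(windows$samples))
    breaks <- wham_breaks(rng, config$bin_width)
  }
  z <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bias <- 0.5 * outer(windows$force_constant, rep(1, length(z))) *
    (outer(windows$center, z, function(c, zz) (zz - c)^2))
  kT <- kBT(windows$temperature[1])
  reps <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_bootstrap), function(r) {
      res <- windows
      res$samples <- lapply(windows$samples, function(s) {
        s[sample.int(length(s), replace = TRUE)]
      })
      h <- window_histograms(res, breaks)
      fit <- wham_iterate(h, bias, kT, config$tolerance,
                          config$max_iterations, f_init = f_init)
      if (!fit$converged) return(NULL)
      pmf <- -kT * fit$log_p
      pmf[!is.finite(pmf)] <- NA_real_
      pmf - reference_shift(z, pmf, config$reference_range)
    })
  })
  failed <- vapply(reps, is.null, logical(1))
  if (any(failed)) {
    warn(sprintf("%d bootstrap replicate(s) failed to converge and were dropped.",
                 sum(failed)))
    if (mean(failed) > 0.2) {
      abort("More than 20% of bootstrap replicates failed to converge.",
            class = "cyclomem_convergence_error")
    }
  }
  mat <- do.call(rbind, reps[!failed])
  if (nrow(mat) == 1) {
    warn("Single bootstrap replicate: errors are degenerate zeros.")
    return(rep(0, ncol(mat)))
  }
  apply(mat, 2, sd, na.rm = TRUE)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "PMF profile: %d bins over [%.3f, %.3f] nm, %d window(s), %d iteration(s)\n",
    nrow(x), min(x$z), max(x$z), attr(x, "n_windows"),
    attr(x, "iterations")))
  NextMethod()
}

#' @rdname wham
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @export
glance.pmf_profile <- function(x, ...) {
  ok <- !is.na(x$pmf)
  tibble::tibble(
    n_bins = nrow(x), n_defined = sum(ok),
    pmf_min = min(x$pmf[ok]), z_at_min = x$z[ok][which.min(x$pmf[ok])],
    pmf_max = max(x$pmf[ok]), z_at_max = x$z[ok][which.max(x$pmf[ok])],
    barrier = max(x$pmf[ok]) - min(x$pmf[ok]),
    iterations = attr(x, "iterations"))
}
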