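#' TCSPC photon-count cube
#'
#' Container for a 3-D photon-count histogram indexed `(time_bin, row, col)`
#' with its acquisition metadata and provenance.
#'
#' @param counts Non-negative integer 3-D array; `dim(counts)[1]` must equal
#'   `acq$n_bins`.
#' @param acq An [acq_config()].
#' @param provenance List: generator seed and config digest, or source path.
#' @return An object of class `tcspc_cube`.
#' @export
tcspc_cube <- function(counts, acq, provenance = list()) {
  stopifnot(inherits(acq, "acq_config"))
  if (length(dim(counts)) != 3)
    stop("counts must be a 3-D array (time_bin, row, col)", call. = FALSE)
  if (dim(counts)[1] != acq$n_bins)
    stop(sprintf("first axis (%d) must equal acq$n_bins (%d)",
                 dim(counts)[1], acq$n_bins), call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integer-valued", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, acq = acq, provenance = provenance),
            class = "tcspc_cube")
}

#' @export
print.tcspc_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<tcspc_cube> %d bins x %d x %d px, %.3g photons total\n",
              d[1], d[2], d[3], sum(as.numeric(x$counts))))
  invisible(x)
}

#' Simulate a TCSPC acquisition of a nucleus phantom
#'
#' Forward model of the acquisition: per pixel, the ground-truth decay is
#' convolved with the IRF ([convolve_with_irf()]), scaled so focus pixels
#' receive `cfg$photons_per_pixel` expected signal photons, background counts
#' are added inside the nucleus, and the result is Poisson-sampled. The
#' pile-up budget is checked (expected photons per pixel per excitation cycle
#' against `acq$pileup_budget`) and the result recorded in the cube
#' provenance; exceeding the budget raises a warning, not an error,
#' mirroring the avoidance (rather than correction) strategy of TCSPC
#' practice.
#'
#' @param phantom A [generate_phantom()] / [generate_fret_phantom()] result.
#' @param irf An [irf()].
#' @param acq An [acq_config()].
#' @param seed Integer seed for the photon noise (independent of the
#'   phantom's geometry seed).
#' @return A [tcspc_cube()].
#' @export
simulate_cube <- function(phantom, irf, acq, seed = 1L) {
  stopifnot(inherits(phantom, "nucleus_phantom"), inherits(irf, "irf"),
            inherits(acq, "acq_config"))
  cfg <- phantom$config
  size <- nrow(phantom$labels)
  foc_idx <- which(phantom$labels == LABEL_FOCUS)
  nuc_idx <- which(phantom$labels == LABEL_NUCLEOPLASM |
                   phantom$labels == LABEL_NUCLEOLUS)
  n_bins <- acq$n_bins

  w <- irf$weights
  if (length(w) < n_bins) w <- c(w, numeric(n_bins - length(w)))
  fw <- stats::fft(w)

  # expected signal per focus pixel (photons_per_pixel total) + background
  expected_peak <- 0
  mu_focus <- matrix(0, n_bins, length(foc_idx))
  for (k in seq_along(foc_idx)) {
    i <- foc_idx[k]
    shape <- if (phantom$truth$type == "mono") {
      conv_shape(wrapped_binned_exp(phantom$truth$tau[i], acq), fw)
    } else {
      conv_shape(phantom$truth$a1[i] *
                   wrapped_binned_exp(phantom$truth$tau_fret[i], acq) +
                 phantom$truth$a2[i] *
                   wrapped_binned_exp(phantom$truth$tau0[i], acq),
                 fw)
    }
    mu <- shape * (cfg$photons_per_pixel / sum(shape)) + cfg$background_rate
    mu_focus[, k] <- mu
    expected_peak <- max(expected_peak, sum(mu))
  }

  pileup_ratio <- expected_peak / acq$n_excitations
  pileup_ok <- pileup_ratio <= acq$pileup_budget
  if (!pileup_ok)
    warning(sprintf(paste0("pile-up budget exceeded: expected %.3g photons ",
                           "per excitation cycle > budget %.3g"),
                    pileup_ratio, acq$pileup_budget), call. = FALSE)

  counts <- with_seed(seed, {
    cnt <- matrix(0L, n_bins, size * size)
    if (length(nuc_idx) > 0 && cfg$background_rate > 0)
      cnt[, nuc_idx] <- as.integer(
        stats::rpois(n_bins * length(nuc_idx), cfg$background_rate))
    if (length(foc_idx) > 0)
      cnt[, foc_idx] <- as.integer(
        stats::rpois(length(mu_focus), as.vector(mu_focus)))
    dim(cnt) <- c(n_bins, size, size)
    cnt
  })

  tcspc_cube(counts, acq,
             provenance = list(source = "simulate_cube",
                               phantom_stage = phantom$stage,
                               geometry_seed = phantom$seed,
                               noise_seed = seed,
                               pileup_ratio = pileup_ratio,
                               pileup_ok = pileup_ok))
}
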