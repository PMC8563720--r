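#' Per-pixel decay fitting configuration
#'
#' Defaults follow common TCSPC analysis practice for this assay: minimum
#' signal threshold 30 counts, spatial binning factor 1 (the decay of each
#' pixel is aggregated over its 3x3 neighborhood before fitting), Poisson
#' maximum-likelihood objective.
#'
#' @param model `"mono"` or `"bi"` exponential decay model.
#' @param threshold_counts Minimum signal of the (binned) pixel decay needed
#'   to attempt a fit; pixels below are masked out, not errors.
#' @param threshold_on Apply the threshold to the `"total"` counts of the
#'   binned decay (default; better conditioned) or to its `"peak"` bin
#'   (SPCImage-compatible semantics).
#' @param binning_factor Integer b >= 0; the decay is summed over the
#'   (2b+1) x (2b+1) spatial neighborhood before fitting.
#' @param objective `"poisson_mle"` (minimized Poisson deviance; correct at
#'   low counts) or `"wls"` (model-weighted, i.e. Pearson, least squares;
#'   agrees with the MLE at high counts).
#' @param fix_tau0 Optional fixed slow lifetime (ns) for bi-exponential fits,
#'   e.g. taken from a donor-only control via [estimate_tau0_donor_only()].
#'   `NULL` (default) fits tau0 freely per pixel.
#' @param max_iterations Optimizer iteration cap.
#' @param convergence_tol Relative convergence tolerance of the optimizer.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(model = c("mono", "bi"), threshold_counts = 30,
                       threshold_on = c("total", "peak"),
                       binning_factor = 1L,
                       objective = c("poisson_mle", "wls"),
                       fix_tau0 = NULL, max_iterations = 400L,
                       convergence_tol = 1e-9) {
  model <- match.arg(model)
  threshold_on <- match.arg(threshold_on)
  objective <- match.arg(objective)
  stopifnot(threshold_counts >= 0, binning_factor >= 0)
  if (!is.null(fix_tau0) && fix_tau0 <= 0)
    stop("fix_tau0 must be > 0", call. = FALSE)
  structure(list(model = model, threshold_counts = threshold_counts,
                 threshold_on = threshold_on,
                 binning_factor = as.integer(binning_factor),
                 objective = objective, fix_tau0 = fix_tau0,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "fit_config")
}

# Negative Poisson log-likelihood (up to the data-only constant).
nll_poisson <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  sum(mu) - sum(y[y > 0] * log(mu[y > 0]))
}

# Model-weighted (Pearson) least squares. Data-estimated (Neyman, 1/y)
# weights are deliberately not used: with ~20 counts per bin they bias
# lifetimes low by several percent, because downward-fluctuating bins get
# inflated weight.
nll_wls <- function(y, mu) sum((y - mu)^2 / pmax(mu, 1))

# d(nll_wls)/d(mu): branch on the weight floor.
wls_resid <- function(y, mu) {
  ifelse(mu > 1,
         -2 * (y - mu) / mu - (y - mu)^2 / mu^2,
         -2 * (y - mu))
}

# Pearson reduced chi-square over bins with expected counts >= 1 (floor
# avoids division blow-ups in empty tail bins).
chi2_reduced <- function(y, mu, n_par) {
  use <- mu >= 1
  n_used <- sum(use)
  dof <- n_used - n_par
  if (dof <= 0) return(NA_real_)
  sum((y[use] - mu[use])^2 / mu[use]) / dof
}

# Bounded quasi-Newton optimization of a positive-parameter model. The
# search runs in log coordinates, which puts lifetimes (~1), amplitudes
# (~1e3) and backgrounds (~1e-2) on comparable scales (L-BFGS-B has no
# parscale); a zero lower bound is replaced by a floor of 1e-9, numerically
# indistinguishable from 0 at photon-count scale. The solution is re-polished
# and, on abnormal termination, restarted once from a deterministically
# perturbed start. Returns NULL on hard failure.
run_box_optim <- function(fn, gr, th0, lower, upper, cfg) {
  ctl <- list(maxit = cfg$max_iterations,
              factr = max(cfg$convergence_tol / .Machine$double.eps, 10))
  lo <- log(pmax(lower, 1e-9))
  hi <- log(pmin(upper, 1e12))
  clamp <- function(v) pmin(pmax(v, lo), hi)
  fn_v <- function(v) fn(exp(v))
  gr_v <- function(v) {
    th <- exp(v)
    gr(th) * th
  }
  try_once <- function(start)
    tryCatch(stats::optim(clamp(start), fn_v, gr_v, method = "L-BFGS-B",
                          lower = lo, upper = hi, control = ctl),
             error = function(e) NULL)
  v0 <- log(pmax(th0, 1e-9))
  res <- try_once(v0)
  if (is.null(res) || res$convergence != 0) {
    # deterministic perturbed restart (no RNG: fits stay reproducible)
    res2 <- try_once(v0 + 0.25 * (-1)^seq_along(v0))
    if (!is.null(res2) &&
        (is.null(res) || res2$value <= res$value)) res <- res2
  }
  if (is.null(res)) return(NULL)
  polish <- try_once(res$par)
  if (!is.null(polish) && polish$value <= res$value) res <- polish
  res$par <- exp(res$par)
  res
}

# Moment-based initial estimates shared by the fitters: background from the
# pre-rise bins, tau from the mean arrival delay past the peak.
init_estimates <- function(y, acq) {
  n <- length(y)
  t_mid <- (seq_len(n) - 0.5) * acq$bin_width
  k_peak <- which.max(stats::filter(y, rep(1 / 3, 3), sides = 2) |>
                        (\(v) ifelse(is.na(v), y, v))())
  pre <- seq_len(max(1L, k_peak - ceiling(0.3 / acq$bin_width)))
  bg0 <- if (length(pre) >= 3) mean(y[pre]) else 0
  post <- y[k_peak:n] - bg0
  post[post < 0] <- 0
  tau0 <- if (sum(post) > 0) {
    sum((t_mid[k_peak:n] - t_mid[k_peak]) * post) / sum(post)
  } else 2
  tau0 <- min(max(tau0, 0.2), 8)
  amp0 <- max(sum(y) - n * bg0, 1) / tau0
  list(tau = tau0, amplitude = amp0, background = max(bg0, 1e-6),
       k_peak = k_peak)
}

masked_fit <- function(n_photons, cls) {
  structure(list(tau = NA_real_, amplitude = NA_real_, background = NA_real_,
                 chi2_reduced = NA_real_, n_photons = n_photons,
                 converged = FALSE, fitted = FALSE),
            class = cls)
}

passes_threshold <- function(decay, cfg) {
  if (cfg$threshold_on == "total") sum(decay) >= cfg$threshold_counts
  else max(decay) >= cfg$threshold_counts
}

#' Fit a mono-exponential decay to one TCSPC histogram
#'
#' Estimates amplitude, lifetime and background of a single-exponential decay
#' convolved with the IRF ([convolve_with_irf()]), by Poisson maximum
#' likelihood or Neyman-weighted least squares. Pixels whose signal is below
#' `cfg$threshold_counts` return a masked (unfitted) result rather than an
#' error. The reduced chi-square is the Pearson statistic over bins with
#' expected counts >= 1, divided by (bins used - 3).
#'
#' @param decay Integer vector of counts per time bin, length `acq$n_bins`.
#' @param irf An [irf()].
#' @param acq An [acq_config()].
#' @param cfg A [fit_config()].
#' @return An object of class `decay_fit`: `tau`, `amplitude`, `background`,
#'   `chi2_reduced`, `n_photons`, `converged`, `fitted`.
#' @export
fit_mono <- function(decay, irf, acq, cfg = fit_config()) {
  stopifnot(length(decay) == acq$n_bins)
  n_photons <- sum(decay)
  if (!passes_threshold(decay, cfg)) return(masked_fit(n_photons, "decay_fit"))
  w <- irf$weights
  if (length(w) < acq$n_bins) w <- c(w, numeric(acq$n_bins - length(w)))
  fw <- stats::fft(w)
  y <- decay
  poiss <- cfg$objective == "poisson_mle"
  # theta = (tau, amplitude, background)
  fn <- function(th) {
    mu <- th[2] * conv_shape(wrapped_binned_exp(th[1], acq), fw) + th[3]
    if (poiss) nll_poisson(y, mu) else nll_wls(y, mu)
  }
  gr <- function(th) {
    s <- conv_shape(wrapped_binned_exp(th[1], acq), fw)
    ds <- conv_shape(wrapped_binned_exp_grad(th[1], acq), fw)
    mu <- pmax(th[2] * s + th[3], 1e-12)
    r <- if (poiss) 1 - y / mu else wls_resid(y, mu)
    c(th[2] * sum(r * ds), sum(r * s), sum(r))
  }
  ini <- init_estimates(decay, acq)
  th0 <- c(ini$tau, ini$amplitude, ini$background)
  res <- run_box_optim(fn, gr, th0, lower = c(0.05, 1e-9, 0),
                       upper = c(20, Inf, Inf), cfg = cfg)
  if (is.null(res))
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          background = NA_real_, chi2_reduced = NA_real_,
                          n_photons = n_photons, converged = FALSE,
                          fitted = TRUE),
                     class = "decay_fit"))
  mu_hat <- res$par[2] *
    conv_shape(wrapped_binned_exp(res$par[1], acq), fw) + res$par[3]
  structure(list(tau = res$par[1], amplitude = res$par[2],
                 background = res$par[3],
                 chi2_reduced = chi2_reduced(decay, mu_hat, 3L),
                 n_photons = n_photons,
                 converged = res$convergence == 0, fitted = TRUE),
            class = "decay_fit")
}

#' Fit a bi-exponential donor decay to one TCSPC histogram
#'
#' Fits `a1, a2, tau_fret` (and `tau0` unless `cfg$fix_tau0` is set) of the
#' two-component donor decay. The fast/slow convention is enforced by
#' parameterizing `tau_fret = rho * tau0` with `rho` in (0, 1]; fits landing
#' at `rho > 0.95` are flagged as component collapse (the two lifetimes are
#' not distinguishable), which downstream FRET mapping treats as invalid.
#'
#' @inheritParams fit_mono
#' @return An object of class `bi_decay_fit`: `params` ([bi_params()]),
#'   `chi2_reduced`, `n_photons`, `converged`, `collapsed`, `fitted`.
#' @export
fit_bi <- function(decay, irf, acq, cfg = fit_config(model = "bi")) {
  stopifnot(length(decay) == acq$n_bins)
  n_photons <- sum(decay)
  if (!passes_threshold(decay, cfg)) {
    out <- masked_fit(n_photons, "bi_decay_fit")
    out$params <- NULL
    out$collapsed <- FALSE
    return(out)
  }
  w <- irf$weights
  if (length(w) < acq$n_bins) w <- c(w, numeric(acq$n_bins - length(w)))
  fw <- stats::fft(w)
  y <- decay
  poiss <- cfg$objective == "poisson_mle"
  fixed_tau0 <- cfg$fix_tau0
  free_tau0 <- is.null(fixed_tau0)
  # theta layout: (a1, a2, rho, B) with fixed tau0, else (a1, a2, rho, tau0, B)
  model_mu <- function(th) {
    tau0 <- if (free_tau0) th[4] else fixed_tau0
    bg <- th[length(th)]
    th[1] * conv_shape(wrapped_binned_exp(th[3] * tau0, acq), fw) +
      th[2] * conv_shape(wrapped_binned_exp(tau0, acq), fw) + bg
  }
  fn <- function(th) {
    mu <- model_mu(th)
    if (poiss) nll_poisson(y, mu) else nll_wls(y, mu)
  }
  gr <- function(th) {
    tau0 <- if (free_tau0) th[4] else fixed_tau0
    rho <- th[3]
    s1 <- conv_shape(wrapped_binned_exp(rho * tau0, acq), fw)
    s0 <- conv_shape(wrapped_binned_exp(tau0, acq), fw)
    ds1 <- conv_shape(wrapped_binned_exp_grad(rho * tau0, acq), fw)
    mu <- pmax(th[1] * s1 + th[2] * s0 + th[length(th)], 1e-12)
    r <- if (poiss) 1 - y / mu else wls_resid(y, mu)
    g_a1 <- sum(r * s1)
    g_a2 <- sum(r * s0)
    g_rho <- th[1] * tau0 * sum(r * ds1)
    if (free_tau0) {
      ds0 <- conv_shape(wrapped_binned_exp_grad(tau0, acq), fw)
      g_t0 <- th[1] * rho * sum(r * ds1) + th[2] * sum(r * ds0)
      c(g_a1, g_a2, g_rho, g_t0, sum(r))
    } else {
      c(g_a1, g_a2, g_rho, sum(r))
    }
  }
  ini <- init_estimates(decay, acq)
  tau0_init <- if (free_tau0) min(max(ini$tau * 1.15, 0.3), 10)
               else fixed_tau0
  a_init <- ini$amplitude / 2
  th0 <- if (free_tau0)
    c(a_init, a_init, 0.7, tau0_init, ini$background)
  else c(a_init, a_init, 0.7, ini$background)
  lower <- if (free_tau0) c(0, 0, 0.02, 0.1, 0) else c(0, 0, 0.02, 0)
  upper <- if (free_tau0) c(Inf, Inf, 1, 20, Inf) else c(Inf, Inf, 1, Inf)
  res <- run_box_optim(fn, gr, th0, lower, upper, cfg)
  fail <- structure(list(params = NULL, chi2_reduced = NA_real_,
                         n_photons = n_photons, converged = FALSE,
                         collapsed = FALSE, fitted = TRUE),
                    class = "bi_decay_fit")
  if (is.null(res)) return(fail)
  th <- res$par
  tau0_hat <- if (free_tau0) th[4] else fixed_tau0
  rho_hat <- th[3]
  n_par <- if (free_tau0) 5L else 4L
  mu_hat <- model_mu(th)
  params <- tryCatch(
    bi_params(a1 = th[1], a2 = th[2], tau_fret = rho_hat * tau0_hat,
              tau0 = tau0_hat, background = th[length(th)]),
    error = function(e) NULL)
  if (is.null(params)) return(fail)
  structure(list(params = params,
                 chi2_reduced = chi2_reduced(decay, mu_hat, n_par),
                 n_photons = n_photons, converged = res$convergence == 0,
                 collapsed = rho_hat > 0.95, fitted = TRUE),
            class = "bi_decay_fit")
}

# Aggregate each pixel's decay over its (2b+1)^2 neighborhood. counts is
# (n_bins, H, W); returns a function(row, col) -> binned decay, plus the
# matrix of binned per-pixel totals used for thresholding.
binned_access <- function(counts, b) {
  d <- dim(counts)
  totals <- apply(counts, c(2, 3), sum)
  binned_totals <- box_sum(totals, b)
  decay_at <- function(row, col) {
    ys <- max(1, row - b):min(d[2], row + b)
    xs <- max(1, col - b):min(d[3], col + b)
    block <- counts[, ys, xs, drop = FALSE]
    dim(block) <- c(d[1], length(ys) * length(xs))
    as.integer(rowSums(block))
  }
  list(decay_at = decay_at, totals = totals, binned_totals = binned_totals)
}

#' Fit every pixel of a TCSPC cube
#'
#' Applies [fit_mono()] or [fit_bi()] per pixel after spatial binning: each
#' pixel's decay is summed over its (2b+1) x (2b+1) neighborhood
#' (`cfg$binning_factor = b`), the photon threshold is applied to the
#' aggregated signal, and pixels below threshold are masked. Deterministic
#' given its inputs. A summary of fitted / masked / failed pixel counts is
#' emitted as a message.
#'
#' @param cube A [tcspc_cube()].
#' @param irf An [irf()].
#' @param cfg A [fit_config()]; `cfg$model` selects the result type.
#' @return For `model = "mono"` an object of class `lifetime_map`: `tau_map`,
#'   `mask` (above threshold and converged), `chi2_map`, `intensity_map`
#'   (raw per-pixel totals), `amplitude_map`, `background_map`. For
#'   `model = "bi"` an object of class `bi_fit_image` with per-pixel
#'   parameter matrices `a1`, `a2`, `tau_fret`, `tau0`, `background`,
#'   `chi2_map`, `mask`, `collapsed`, `intensity_map`.
#' @export
fit_image <- function(cube, irf, cfg = fit_config()) {
  stopifnot(inherits(cube, "tcspc_cube"))
  acq <- cube$acq
  d <- dim(cube$counts)
  acc <- binned_access(cube$counts, cfg$binning_factor)
  cand <- which(acc$binned_totals >= cfg$threshold_counts, arr.ind = TRUE)
  nmat <- function() matrix(NA_real_, d[2], d[3])
  mask <- matrix(FALSE, d[2], d[3])
  n_failed <- 0L
  if (cfg$model == "mono") {
    tau_map <- nmat(); chi2_map <- nmat(); amp_map <- nmat(); bg_map <- nmat()
    for (k in seq_len(nrow(cand))) {
      rw <- cand[k, 1]; cl <- cand[k, 2]
      dec <- acc$decay_at(rw, cl)
      f <- fit_mono(dec, irf, acq, cfg)
      if (!f$fitted || !f$converged) {
        n_failed <- n_failed + f$fitted
        next
      }
      mask[rw, cl] <- TRUE
      tau_map[rw, cl] <- f$tau
      chi2_map[rw, cl] <- f$chi2_reduced
      amp_map[rw, cl] <- f$amplitude
      bg_map[rw, cl] <- f$background
    }
    out <- structure(list(tau_map = tau_map, mask = mask,
                          chi2_map = chi2_map, intensity_map = acc$totals,
                          amplitude_map = amp_map, background_map = bg_map,
                          fit_config = cfg),
                     class = "lifetime_map")
  } else {
    a1 <- nmat(); a2 <- nmat(); tf <- nmat(); t0 <- nmat(); bg <- nmat()
    chi2_map <- nmat(); collapsed <- matrix(FALSE, d[2], d[3])
    for (k in seq_len(nrow(cand))) {
      rw <- cand[k, 1]; cl <- cand[k, 2]
      dec <- acc$decay_at(rw, cl)
      f <- fit_bi(dec, irf, acq, cfg)
      if (!f$fitted || !f$converged || is.null(f$params)) {
        n_failed <- n_failed + f$fitted
        next
      }
      mask[rw, cl] <- TRUE
      a1[rw, cl] <- f$params$a1
      a2[rw, cl] <- f$params$a2
      tf[rw, cl] <- f$params$tau_fret
      t0[rw, cl] <- f$params$tau0
      bg[rw, cl] <- f$params$background
      chi2_map[rw, cl] <- f$chi2_reduced
      collapsed[rw, cl] <- f$collapsed
    }
    out <- structure(list(a1 = a1, a2 = a2, tau_fret = tf, tau0 = t0,
                          background = bg, chi2_map = chi2_map, mask = mask,
                          collapsed = collapsed,
                          intensity_map = acc$totals, fit_config = cfg),
                     class = "bi_fit_image")
  }
  n_above <- nrow(cand)
  message(sprintf("fit_image (%s): %d pixels above threshold, %d fitted, %d failed, %d masked below threshold",
                  cfg$model, n_above, sum(mask), n_failed,
                  prod(d[2:3]) - n_above))
  if (n_above == 0L)
    warning("no pixel above threshold: all-masked result", call. = FALSE)
  out
}

#' Donor-only reference lifetime from a lifetime map
#'
#' Intensity-weighted mean lifetime over the valid pixels of a donor-only
#' specimen's mono-exponential [fit_image()] result. Used as the fixed
#' unquenched reference tau0 when computing FRET efficiency maps.
#'
#' @param map A `lifetime_map`.
#' @return Reference lifetime, ns.
#' @export
estimate_tau0_donor_only <- function(map) {
  stopifnot(inherits(map, "lifetime_map"))
  if (!any(map$mask)) stop("empty mask: no valid pixels", call. = FALSE)
  stats::weighted.mean(map$tau_map[map$mask], map$intensity_map[map$mask])
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$fitted) cat("<decay_fit> masked (below threshold),",
                     x$n_photons, "photons\n")
  else cat(sprintf("<decay_fit> tau = %.4f ns, chi2_red = %.3f, %d photons, converged: %s\n",
                   x$tau, x$chi2_reduced, x$n_photons, x$converged))
  invisible(x)
}

#' @export
print.bi_decay_fit <- function(x, ...) {
  if (!x$fitted || is.null(x$params)) {
    cat("<bi_decay_fit> not fitted\n")
  } else {
    cat(sprintf("<bi_decay_fit> tau_fret = %.4f, tau0 = %.4f ns, a1/(a1+a2) = %.3f, chi2_red = %.3f%s\n",
                x$params$tau_fret, x$params$tau0,
                x$params$a1 / (x$params$a1 + x$params$a2), x$chi2_reduced,
                if (x$collapsed) " [collapsed]" else ""))
  }
  invisible(x)
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf("<lifetime_map> %dx%d px, %d valid; tau %.3f-%.3f ns\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              suppressWarnings(min(x$tau_map, na.rm = TRUE)),
              suppressWarnings(max(x$tau_map, na.rm = TRUE))))
  invisible(x)
}
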