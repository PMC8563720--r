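#' Configuration for synthetic nucleus phantoms
#'
#' Defaults encode the replication-labeling geometry seen in S-phase
#' pulse-labeling experiments: early S-phase nuclei show many small foci
#' scattered through the nucleoplasm; mid and late S-phase nuclei show fewer,
#' larger foci that cluster and sit preferentially at the nuclear and
#' nucleolar periphery. Ground-truth focus lifetimes are set per stage
#' (defaults 2.46 / 2.37 / 2.23 ns for early / mid / late) and converted to a
#' refractive-index map through the inverse Strickler-Berg relation, so that
#' compaction (RI) is the underlying ground truth and lifetime its readout.
#'
#' @param image_size Frame side length in pixels (square frame).
#' @param n_foci Named integer vector: foci per stage.
#' @param focus_radius_px Named list of `c(min, max)` focus radii per stage,
#'   pixels.
#' @param peripheral_fraction Fraction of mid/late foci placed in the rim
#'   band at the nuclear/nucleolar boundary.
#' @param rim_width_px Width of the peripheral rim band, pixels (Chebyshev
#'   distance to the boundary).
#' @param tau_by_stage Named numeric: ground-truth mean focus lifetime per
#'   stage, ns.
#' @param ri_by_class Named numeric: refractive index per stage class. The
#'   default is derived from `tau_by_stage` via [strickler_berg_ri()] at the
#'   photophysics reference, so that late > mid > early.
#' @param ri_jitter_sd Per-pixel Gaussian jitter of focus RI (models local
#'   compaction heterogeneity).
#' @param ri_outside,ri_nucleoplasm,ri_nucleolus Baseline RI of the
#'   surrounding medium, unlabeled nucleoplasm, and nucleoli.
#' @param photons_per_pixel Target mean total photon count per focus pixel.
#' @param background_rate Background counts per time bin inside the nucleus.
#'   The default keeps unlabeled nucleoplasm well below the analysis
#'   threshold of 30 counts even after 3x3 binning, consistent with control
#'   measurements in which autofluorescence never exceeded the threshold.
#' @param fret_fraction Amplitude fraction a1/(a1+a2) of the FRET component
#'   in donor+acceptor phantoms.
#' @param fret_efficiency Ground-truth FRET efficiency of interacting donor
#'   molecules. Default from [default_photophysics()] (tau_fret 2.01 ns on a
#'   2.47 ns donor).
#' @param proximity_fraction In sequential-labeling FRET phantoms, the
#'   fraction of donor foci lying within the acceptor-proximity field.
#' @param photophysics Reference constants, see [default_photophysics()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           n_foci = c(early = 300L, mid = 60L, late = 40L),
                           focus_radius_px = list(early = c(1, 2),
                                                  mid = c(2, 4),
                                                  late = c(3, 5)),
                           peripheral_fraction = 0.7,
                           rim_width_px = 5L,
                           tau_by_stage = c(early = 2.46, mid = 2.37,
                                            late = 2.23),
                           ri_by_class = NULL,
                           ri_jitter_sd = 0.003,
                           ri_outside = 1.333,
                           ri_nucleoplasm = 1.355,
                           ri_nucleolus = 1.40,
                           photons_per_pixel = 2000,
                           background_rate = 0.005,
                           fret_fraction = 0.5,
                           fret_efficiency = default_photophysics()$fret_efficiency,
                           proximity_fraction = 0.3,
                           photophysics = default_photophysics()) {
  image_size <- as.integer(image_size)
  # tolerate JSON-config shapes: named lists instead of named vectors
  if (is.list(n_foci)) n_foci <- unlist(n_foci)
  if (is.list(tau_by_stage)) tau_by_stage <- unlist(tau_by_stage)
  if (!is.null(ri_by_class) && is.list(ri_by_class))
    ri_by_class <- unlist(ri_by_class)
  stopifnot(image_size > 0, photons_per_pixel > 0,
            peripheral_fraction >= 0, peripheral_fraction <= 1,
            background_rate >= 0,
            fret_fraction >= 0, fret_fraction <= 1,
            fret_efficiency >= 0, fret_efficiency < 1,
            proximity_fraction >= 0, proximity_fraction <= 1)
  stages <- c("early", "mid", "late")
  if (!all(stages %in% names(n_foci)))
    stop("n_foci must name early, mid and late", call. = FALSE)
  if (is.null(ri_by_class)) {
    ri_by_class <- strickler_berg_ri(tau_by_stage[stages],
                                     photophysics$tau_donor,
                                     photophysics$n_ref)
    names(ri_by_class) <- stages
  }
  structure(list(image_size = image_size, n_foci = n_foci,
                 focus_radius_px = focus_radius_px,
                 peripheral_fraction = peripheral_fraction,
                 rim_width_px = as.integer(rim_width_px),
                 tau_by_stage = tau_by_stage, ri_by_class = ri_by_class,
                 ri_jitter_sd = ri_jitter_sd, ri_outside = ri_outside,
                 ri_nucleoplasm = ri_nucleoplasm,
                 ri_nucleolus = ri_nucleolus,
                 photons_per_pixel = photons_per_pixel,
                 background_rate = background_rate,
                 fret_fraction = fret_fraction,
                 fret_efficiency = fret_efficiency,
                 proximity_fraction = proximity_fraction,
                 photophysics = photophysics),
            class = "phantom_config")
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Label codes for the compartment mask.
LABEL_OUTSIDE <- 0L
LABEL_NUCLEOPLASM <- 1L
LABEL_NUCLEOLUS <- 2L
LABEL_FOCUS <- 3L

# Elliptical nucleus with low-frequency radial boundary jitter plus 2-3
# elliptical nucleoli. Returns the integer label matrix (rows = y, cols = x).
make_nucleus_geometry <- function(size) {
  cx <- size / 2 + stats::runif(1, -size * 0.02, size * 0.02)
  cy <- size / 2 + stats::runif(1, -size * 0.02, size * 0.02)
  a <- size * stats::runif(1, 0.36, 0.42)   # semi-axis along x
  b <- size * stats::runif(1, 0.28, 0.34)   # semi-axis along y
  harm <- 2:5
  eps <- stats::rnorm(length(harm), 0, 0.02)
  phi <- stats::runif(length(harm), 0, 2 * pi)

  xs <- matrix(rep(seq_len(size), each = size), nrow = size)  # col index
  ys <- matrix(rep(seq_len(size), times = size), nrow = size) # row index
  dx <- (xs - cx) / a
  dy <- (ys - cy) / b
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  jit <- Reduce(`+`, lapply(seq_along(harm), function(i)
    eps[i] * cos(harm[i] * theta + phi[i])))
  labels <- matrix(LABEL_OUTSIDE, size, size)
  labels[rho <= 1 + jit] <- LABEL_NUCLEOPLASM

  n_nucleoli <- sample(2:3, 1)
  placed <- 0L
  centers <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  while (placed < n_nucleoli && attempts < 200L) {
    attempts <- attempts + 1L
    r <- size * stats::runif(1, 0.06, 0.10)
    # keep the nucleolus well inside the nucleus
    th <- stats::runif(1, 0, 2 * pi)
    rr <- stats::runif(1, 0, 0.55)
    nx <- cx + rr * a * cos(th)
    ny <- cy + rr * b * sin(th)
    if (placed > 0 &&
        any(sqrt((centers[, 1] - nx)^2 + (centers[, 2] - ny)^2) <
            (centers[, 3] + r + 3)))
      next
    centers <- rbind(centers, c(nx, ny, r))
    ar <- stats::runif(1, 0.8, 1.25)  # nucleolus axis ratio
    inside <- ((xs - nx) / r)^2 + ((ys - ny) / (r * ar))^2 <= 1
    labels[inside & labels == LABEL_NUCLEOPLASM] <- LABEL_NUCLEOLUS
    placed <- placed + 1L
  }
  labels
}

# Square (Chebyshev) erosion of a logical matrix by radius r, via an
# integral-image box sum: a pixel survives iff its (2r+1)^2 window is all
# TRUE.
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  sz <- dim(mask)
  padded <- matrix(0, sz[1] + 2 * r, sz[2] + 2 * r)
  padded[(r + 1):(r + sz[1]), (r + 1):(r + sz[2])] <- mask
  s <- box_sum(padded, r)
  core <- s[(r + 1):(r + sz[1]), (r + 1):(r + sz[2])]
  core == (2 * r + 1)^2
}

# Box (moving-window) sum with window (2r+1)^2 and zero padding.
box_sum <- function(m, r) {
  if (r <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  cs <- matrix(0, n1 + 1, n2 + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i1 <- pmin(seq_len(n1) + r, n1) + 1L
  i0 <- pmax(seq_len(n1) - r - 1L, 0L) + 1L
  j1 <- pmin(seq_len(n2) + r, n2) + 1L
  j0 <- pmax(seq_len(n2) - r - 1L, 0L) + 1L
  cs[i1, j1] - cs[i0, j1] - cs[i1, j0] + cs[i0, j0]
}

# Pixels of the nucleoplasm within rim_width of the nuclear or nucleolar
# boundary (peripheral placement band for mid/late S-phase foci).
rim_band <- function(labels, rim_width) {
  nucleo <- labels == LABEL_NUCLEOPLASM
  eroded <- erode_mask(nucleo, rim_width)
  nucleo & !eroded
}

# Stamp circular foci onto the label mask. Returns the updated labels plus a
# focus-id map and a data frame of focus metadata.
place_foci <- function(labels, centers, radii) {
  size <- nrow(labels)
  focus_id <- matrix(NA_integer_, size, size)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    x0 <- centers[i, 1]; y0 <- centers[i, 2]
    xr <- max(1, floor(x0 - r)):min(size, ceiling(x0 + r))
    yr <- max(1, floor(y0 - r)):min(size, ceiling(y0 + r))
    for (x in xr) for (y in yr) {
      if ((x - x0)^2 + (y - y0)^2 <= r^2 &&
          labels[y, x] %in% c(LABEL_NUCLEOPLASM, LABEL_FOCUS)) {
        labels[y, x] <- LABEL_FOCUS
        focus_id[y, x] <- i
      }
    }
  }
  list(labels = labels, focus_id = focus_id)
}

sample_focus_centers <- function(stage, cfg, labels) {
  n <- cfg$n_foci[[stage]]
  nucleo_idx <- which(labels == LABEL_NUCLEOPLASM)
  if (length(nucleo_idx) < 20 * n)
    stop(sprintf(paste0("cannot place %d foci: only %d nucleoplasm pixels ",
                        "available"), n, length(nucleo_idx)), call. = FALSE)
  size <- nrow(labels)
  to_xy <- function(idx) cbind(((idx - 1L) %/% size) + 1L,  # x = col
                               ((idx - 1L) %% size) + 1L)   # y = row
  if (stage == "early") {
    # numerous small foci scattered uniformly through the nucleoplasm
    idx <- sample(nucleo_idx, n)
    return(to_xy(idx))
  }
  # mid/late: peripheral rim placement plus interior clusters
  rim <- rim_band(labels, cfg$rim_width_px)
  rim_idx <- which(rim)
  n_rim <- round(cfg$peripheral_fraction * n)
  n_int <- n - n_rim
  if (length(rim_idx) < n_rim)
    stop("rim band too small for requested peripheral foci", call. = FALSE)
  centers <- to_xy(sample(rim_idx, n_rim))
  if (n_int > 0) {
    interior_idx <- setdiff(nucleo_idx, rim_idx)
    n_clusters <- max(1L, ceiling(n_int / 5))
    seeds <- to_xy(sample(interior_idx, n_clusters))
    k <- 0L
    guard <- 0L
    int_centers <- matrix(0L, n_int, 2)
    while (k < n_int && guard < 200L * n_int) {
      guard <- guard + 1L
      s <- seeds[sample.int(n_clusters, 1), ]
      cand <- round(s + stats::rnorm(2, 0, 6))
      if (any(cand < 1) || any(cand > size)) next
      if (labels[cand[2], cand[1]] != LABEL_NUCLEOPLASM) next
      k <- k + 1L
      int_centers[k, ] <- cand
    }
    if (k < n_int)
      stop("could not place clustered interior foci", call. = FALSE)
    centers <- rbind(centers, int_centers)
  }
  centers
}

#' Generate a synthetic replication-labeled nucleus
#'
#' Builds a nucleus phantom for one S-phase stage: an elliptical nucleus with
#' jittered boundary and 2-3 nucleoli, replication-labeled foci placed with
#' the stage-appropriate geometry, a per-pixel refractive-index map, and
#' mono-exponential ground-truth decay parameters on focus pixels (lifetime
#' from the RI map through [strickler_berg_lifetime()]).
#'
#' @param stage `"early"`, `"mid"` or `"late"`.
#' @param cfg A [phantom_config()].
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   phantom. Geometry uses this seed only, so photon noise can be resampled
#'   independently in [simulate_cube()].
#' @return An object of class `nucleus_phantom` with elements `labels`
#'   (integer compartment matrix: 0 outside, 1 nucleoplasm, 2 nucleolus,
#'   3 labeled focus), `ri_map`, `truth` (list of per-pixel parameter
#'   matrices, NA off foci), `focus_id`, `foci` (metadata), `stage`, `seed`,
#'   `config`.
#' @export
generate_phantom <- function(stage = c("early", "mid", "late"),
                             cfg = phantom_config(), seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(seed, {
    labels <- make_nucleus_geometry(cfg$image_size)
    centers <- sample_focus_centers(stage, cfg, labels)
    rr <- cfg$focus_radius_px[[stage]]
    radii <- stats::runif(nrow(centers), rr[1], rr[2])
    st <- place_foci(labels, centers, radii)
    ri <- baseline_ri(st$labels, cfg)
    foc <- st$labels == LABEL_FOCUS
    ri[foc] <- cfg$ri_by_class[[stage]] +
      stats::rnorm(sum(foc), 0, cfg$ri_jitter_sd)
    tau <- matrix(NA_real_, cfg$image_size, cfg$image_size)
    tau[foc] <- strickler_berg_lifetime(ri[foc], cfg$photophysics$tau_donor,
                                        cfg$photophysics$n_ref)
    amp <- matrix(NA_real_, cfg$image_size, cfg$image_size)
    amp[foc] <- 1
    structure(list(labels = st$labels, ri_map = ri,
                   truth = list(type = "mono", tau = tau, amplitude = amp),
                   focus_id = st$focus_id,
                   foci = data.frame(id = seq_len(nrow(centers)),
                                     x = centers[, 1], y = centers[, 2],
                                     radius = radii),
                   stage = stage, seed = seed, config = cfg),
              class = "nucleus_phantom")
  })
}

baseline_ri <- function(labels, cfg) {
  ri <- matrix(cfg$ri_outside, nrow(labels), ncol(labels))
  ri[labels == LABEL_NUCLEOPLASM] <- cfg$ri_nucleoplasm
  ri[labels == LABEL_NUCLEOLUS] <- cfg$ri_nucleolus
  ri
}

#' Generate a donor+acceptor (FRET) nucleus phantom
#'
#' Like [generate_phantom()] but with bi-exponential ground truth on donor
#' foci. In simultaneous-labeling mode every donor focus is within FRET range
#' of acceptor-labeled chromatin, so all focus pixels carry the two-component
#' mixture (`a1/(a1+a2) = cfg$fret_fraction`, quenched lifetime from
#' `cfg$fret_efficiency`). In sequential-labeling mode only a random subset
#' of donor foci (fraction `cfg$proximity_fraction`, Bernoulli per focus)
#' falls inside the acceptor-proximity field; the remaining foci are pure
#' donor (`a1 = 0`). Donor focus refractive index is pinned at the
#' photophysics reference, so the unquenched lifetime is `tau_donor`
#' (default 2.47 ns): the FRET assay reads proximity, not compaction.
#'
#' @param stage_donor S-phase pattern used for the donor focus geometry.
#' @param stage_acceptor S-phase stage of the acceptor labeling (metadata;
#'   the acceptor decay itself is not modeled, as the readout is donor-side).
#' @param cfg A [phantom_config()].
#' @param seed Integer seed.
#' @param mode `"simultaneous"` or `"sequential"` labeling scheme.
#' @return A `nucleus_phantom` whose `truth` has `type = "bi"` and matrices
#'   `a1`, `a2`, `tau_fret`, `tau0`, plus the ground-truth `efficiency` map
#'   (0 on non-interacting foci) for recovery tests. With
#'   `cfg$fret_fraction = 0` the truth degenerates to the donor-only
#'   mono-exponential case.
#' @export
generate_fret_phantom <- function(stage_donor = "early",
                                  stage_acceptor = "late",
                                  cfg = phantom_config(), seed = 1L,
                                  mode = c("simultaneous", "sequential")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "phantom_config"))
  ph <- generate_phantom(stage_donor, cfg, seed)
  size <- cfg$image_size
  with_seed(seed + 104729L, {  # child stream for FRET assignment and RI
    foc <- ph$labels == LABEL_FOCUS
    ri <- ph$ri_map
    # donor reference environment on foci (tiny physiological jitter)
    ri[foc] <- cfg$photophysics$n_ref +
      stats::rnorm(sum(foc), 0, cfg$ri_jitter_sd)
    tau0 <- matrix(NA_real_, size, size)
    tau0[foc] <- strickler_berg_lifetime(ri[foc], cfg$photophysics$tau_donor,
                                         cfg$photophysics$n_ref)
    n_foci <- nrow(ph$foci)
    in_proximity <- if (mode == "simultaneous") rep(TRUE, n_foci)
                    else stats::runif(n_foci) < cfg$proximity_fraction
    fid <- ph$focus_id
    fid[is.na(fid)] <- 1L
    prox_map <- matrix(in_proximity[fid], size, size)
    fret_px <- foc & !is.na(ph$focus_id) & prox_map
    a1 <- matrix(NA_real_, size, size)
    a2 <- matrix(NA_real_, size, size)
    tf <- matrix(NA_real_, size, size)
    eff <- matrix(NA_real_, size, size)
    a1[foc] <- 0
    a2[foc] <- 1
    eff[foc] <- 0
    tf[foc] <- tau0[foc]  # placeholder; no fast component where a1 = 0
    if (cfg$fret_fraction > 0 && any(fret_px)) {
      a1[fret_px] <- cfg$fret_fraction
      a2[fret_px] <- 1 - cfg$fret_fraction
      tf[fret_px] <- (1 - cfg$fret_efficiency) * tau0[fret_px]
      eff[fret_px] <- cfg$fret_efficiency
    }
    ph$ri_map <- ri
    ph$truth <- list(type = "bi", a1 = a1, a2 = a2, tau_fret = tf,
                     tau0 = tau0, efficiency = eff)
    ph$fret <- list(mode = mode, stage_acceptor = stage_acceptor,
                    in_proximity = in_proximity)
    ph
  })
}

#' @export
print.nucleus_phantom <- function(x, ...) {
  cat(sprintf("<nucleus_phantom> %dx%d, stage %s, %d foci (%d focus px), seed %d\n",
              nrow(x$labels), ncol(x$labels), x$stage, nrow(x$foci),
              sum(x$labels == LABEL_FOCUS), x$seed))
  if (!is.null(x$fret))
    cat(sprintf("  FRET %s labeling; %d/%d foci in acceptor proximity\n",
                x$fret$mode, sum(x$fret$in_proximity),
                length(x$fret$in_proximity)))
  invisible(x)
}
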