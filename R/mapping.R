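#' Discrete segmentation scheme for scalar maps
#'
#' Ordered class boundaries with labels and display colors. Intervals are
#' half-open, `[low, high)`: a value equal to an interior boundary belongs to
#' the class above it. Values below the first boundary or at/above the last
#' fall into the dedicated overflow classes `"under"` and `"over"`, which are
#' reported rather than silently clipped.
#'
#' @param boundaries Strictly increasing numeric vector of class edges.
#' @param labels Class names; length must be `length(boundaries) - 1`.
#' @param colors Display color per class (any R color name or hex).
#' @return An object of class `segmentation_scheme`.
#' @seealso [lifetime_scheme()], [fret_scheme()]
#' @export
segmentation_scheme <- function(boundaries, labels, colors = NULL) {
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing", call. = FALSE)
  if (length(labels) != length(boundaries) - 1)
    stop("need one label per interval", call. = FALSE)
  if (is.null(colors)) colors <- grDevices::hcl.colors(length(labels))
  if (length(colors) != length(labels))
    stop("need one color per class", call. = FALSE)
  structure(list(boundaries = boundaries, labels = labels, colors = colors),
            class = "segmentation_scheme")
}

#' Lifetime segmentation scheme (short / intermediate / long)
#'
#' Three lifetime classes used for color-coded chromatin compaction maps:
#' short 2.1-2.35 ns (red, densely packed), intermediate 2.35-2.55 ns
#' (green), long 2.55-2.75 ns (blue, relaxed chromatin).
#'
#' @return A [segmentation_scheme()].
#' @export
lifetime_scheme <- function() {
  segmentation_scheme(c(2.1, 2.35, 2.55, 2.75),
                      c("short", "intermediate", "long"),
                      c("red", "green", "blue"))
}

#' FRET efficiency segmentation scheme (low / intermediate / high)
#'
#' Three FRET efficiency classes: low below 50%, intermediate 50-70%, high
#' over 70% (blue, green, red). Under the half-open convention E = 0.70
#' is classed as high.
#'
#' @return A [segmentation_scheme()].
#' @export
fret_scheme <- function() {
  segmentation_scheme(c(0, 0.5, 0.7, 1 + 1e-9),
                      c("low", "intermediate", "high"),
                      c("blue", "green", "red"))
}

#' Segment a scalar map into discrete classes
#'
#' Assigns each unmasked pixel the class of the half-open interval
#' `[low, high)` containing its value; out-of-range values go to the
#' overflow classes `"under"` / `"over"`.
#'
#' @param values Numeric matrix (NA allowed).
#' @param scheme A [segmentation_scheme()].
#' @param mask Optional logical matrix; pixels outside it are unclassified.
#' @return An object of class `class_map`: integer `codes` matrix (0 =
#'   under, 1..K = scheme classes, K+1 = over, NA = masked), `labels`
#'   (including overflow), and the `scheme`.
#' @export
segment_map <- function(values, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "segmentation_scheme"))
  codes <- matrix(NA_integer_, nrow(values), ncol(values))
  ok <- !is.na(values)
  if (!is.null(mask)) ok <- ok & mask
  codes[ok] <- findInterval(values[ok], scheme$boundaries,
                            rightmost.closed = FALSE)
  structure(list(codes = codes,
                 labels = c("under", scheme$labels, "over"),
                 scheme = scheme),
            class = "class_map")
}

#' Class pixel counts of a class map
#'
#' @param cm A `class_map` from [segment_map()].
#' @return Data frame with columns `class` and `n_pixels`, one row per class
#'   including the overflow classes.
#' @export
class_counts <- function(cm) {
  stopifnot(inherits(cm, "class_map"))
  k <- length(cm$labels)
  tab <- tabulate(cm$codes + 1L, nbins = k)
  data.frame(class = cm$labels, n_pixels = tab)
}

#' FRET efficiency map from per-pixel bi-exponential fits
#'
#' Computes per-pixel donor FRET efficiency `E = 1 - tau_fret / tau0` (with
#' `tau0` either per pixel or a fixed donor-only reference) and classifies it
#' with the FRET scheme. Collapsed fits (tau_fret indistinguishable from
#' tau0) are masked out. Pixels whose fitted FRET amplitude fraction
#' `a1/(a1+a2)` is below `min_fret_fraction` are treated as non-interacting
#' donor (E = 0, class low): with a negligible fast component, tau_fret is
#' unidentifiable and must not be propagated into E.
#'
#' @param bi_fits A `bi_fit_image` from [fit_image()] with `model = "bi"`.
#' @param tau0_ref Optional fixed unquenched lifetime (ns), e.g. from
#'   [estimate_tau0_donor_only()]; default uses each pixel's fitted tau0.
#' @param scheme Segmentation scheme; default [fret_scheme()].
#' @param min_fret_fraction Amplitude-fraction floor below which a pixel is
#'   reported through the donor-only path.
#' @return An object of class `fret_map`: `efficiency_map`, `class_map`,
#'   `mask`, `intensity_map`.
#' @export
compute_fret_map <- function(bi_fits, tau0_ref = NULL, scheme = fret_scheme(),
                             min_fret_fraction = 0.05) {
  stopifnot(inherits(bi_fits, "bi_fit_image"))
  if (!is.null(tau0_ref) && tau0_ref <= 0)
    stop("tau0_ref must be > 0", call. = FALSE)
  mask <- bi_fits$mask & !bi_fits$collapsed
  eff <- matrix(NA_real_, nrow(mask), ncol(mask))
  tau0 <- if (is.null(tau0_ref)) bi_fits$tau0[mask] else tau0_ref
  eff[mask] <- pmax(0, 1 - bi_fits$tau_fret[mask] / tau0)
  frac <- bi_fits$a1 / (bi_fits$a1 + bi_fits$a2)
  donor_only <- mask & !is.na(frac) & frac < min_fret_fraction
  eff[donor_only] <- 0
  structure(list(efficiency_map = eff,
                 class_map = segment_map(eff, scheme, mask),
                 mask = mask, intensity_map = bi_fits$intensity_map),
            class = "fret_map")
}

#' Histogram of a per-pixel scalar map
#'
#' Bin edges are aligned to integer multiples of `bin_width`; counts sum to
#' the number of unmasked pixels.
#'
#' @param values Numeric matrix (NA = masked).
#' @param bin_width Histogram bin width (> 0). Default 0.02, suitable both
#'   for lifetimes in ns and efficiencies as fractions.
#' @param mask Optional logical matrix restricting the pixels used.
#' @return Data frame with columns `bin_center` and `count`.
#' @export
map_histogram <- function(values, bin_width = 0.02, mask = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  v <- values
  if (!is.null(mask)) v[!mask] <- NA
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no unmasked pixels to histogram", call. = FALSE)
  k <- floor(v / bin_width)
  tab <- table(k)
  kk <- as.numeric(names(tab))
  data.frame(bin_center = (kk + 0.5) * bin_width,
             count = as.integer(tab))
}

#' Per-group lifetime summary
#'
#' Summarizes a lifetime (or FRET) map over pixel groups: pixel count,
#' mean lifetime (intensity-weighted by default, using per-pixel photon
#' counts as weights) and its SD, plus mean FRET efficiency when available.
#' Pairwise differences of group means, in picoseconds, are attached as the
#' `"pairwise"` attribute (stage comparisons such as early vs late).
#'
#' @param map A `lifetime_map` (or a `fret_map`, summarizing E instead).
#' @param groups Matrix of per-pixel group labels (character or factor);
#'   pixels with NA group are ignored.
#' @param weighted Use intensity weights for the means (default TRUE).
#' @return A data frame of class `summary_table` with columns `group`,
#'   `n_pixels`, `mean_tau_ns`, `sd_tau_ns`, `mean_E`.
#' @export
summarize_by_group <- function(map, groups, weighted = TRUE) {
  is_fret <- inherits(map, "fret_map")
  vals <- if (is_fret) map$efficiency_map else map$tau_map
  mask <- map$mask
  wts <- map$intensity_map
  gl <- groups
  use <- mask & !is.na(gl)
  if (!any(use)) stop("no unmasked grouped pixels", call. = FALSE)
  gvals <- split(seq_along(vals)[use], as.character(gl[use]))
  rows <- lapply(names(gvals), function(g) {
    idx <- gvals[[g]]
    v <- vals[idx]
    w <- if (weighted) wts[idx] else rep(1, length(idx))
    m <- stats::weighted.mean(v, w)
    s <- sqrt(stats::weighted.mean((v - m)^2, w))
    data.frame(group = g, n_pixels = length(idx),
               mean_tau_ns = if (is_fret) NA_real_ else m,
               sd_tau_ns = if (is_fret) NA_real_ else s,
               mean_E = if (is_fret) m else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) > 1 && !is_fret) {
    pr <- utils::combn(nrow(out), 2)
    attr(out, "pairwise") <- data.frame(
      group1 = out$group[pr[1, ]], group2 = out$group[pr[2, ]],
      diff_ps = 1000 * (out$mean_tau_ns[pr[1, ]] - out$mean_tau_ns[pr[2, ]]))
  }
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Render a class map to an RGB image
#'
#' Deterministic mapping from class codes to colors: scheme colors for the
#' regular classes, dark gray / white for the `under` / `over` overflow
#' classes, black for masked pixels.
#'
#' @param cm A `class_map` from [segment_map()].
#' @param scheme Scheme supplying the class colors; defaults to the one the
#'   map was made with.
#' @return Numeric array `(rows, cols, 3)` with values in `[0, 1]` and a
#'   `"legend"` attribute (data frame of label and color).
#' @export
render_class_map <- function(cm, scheme = cm$scheme) {
  stopifnot(inherits(cm, "class_map"))
  pal <- c("gray25", scheme$colors, "white")
  rgbm <- grDevices::col2rgb(pal) / 255
  img <- array(0, c(nrow(cm$codes), ncol(cm$codes), 3))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(cm$codes), ncol(cm$codes))
    ok <- !is.na(cm$codes)
    plane[ok] <- rgbm[ch, cm$codes[ok] + 1L]
    img[, , ch] <- plane
  }
  attr(img, "legend") <- data.frame(label = c(cm$labels, "masked"),
                                    color = c(pal, "black"))
  img
}
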