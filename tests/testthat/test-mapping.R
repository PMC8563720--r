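test_that("lifetime segmentation follows the half-open interval convention", {
  sch <- lifetime_scheme()
  vals <- matrix(c(2.2, 2.35, 2.6, 2.0, 2.9, NA), 2)
  cm <- segment_map(vals, sch)
  lab <- cm$labels[cm$codes + 1L]
  expect_identical(lab[1], "short")         # 2.2
  expect_identical(lab[2], "intermediate")  # 2.35 on the boundary
  expect_identical(lab[3], "long")          # 2.6
  expect_identical(lab[4], "under")         # 2.0 below the first edge
  expect_identical(lab[5], "over")          # 2.9 at/above the last edge
  expect_true(is.na(cm$codes[6]))
})

test_that("segmentation partitions the unmasked domain", {
  set.seed(21)
  vals <- matrix(runif(400, 1.9, 3.0), 20)
  mask <- matrix(runif(400) > 0.3, 20)
  cm <- segment_map(vals, lifetime_scheme(), mask)
  expect_identical(!is.na(cm$codes), mask)
  cc <- class_counts(cm)
  expect_identical(sum(cc$n_pixels), sum(mask))
})

test_that("FRET classes match the stated ranges", {
  sch <- fret_scheme()
  vals <- matrix(c(0.2, 0.5, 0.69, 0.70, 0.95, 0.0), 2)
  cm <- segment_map(vals, sch)
  lab <- cm$labels[cm$codes + 1L]
  expect_identical(lab, c("low", "intermediate", "intermediate",
                          "high", "high", "low"))
})

test_that("compute_fret_map turns bi fits into efficiency and classes", {
  mk <- function(a1, a2, tf, t0, collapsed = FALSE) {
    m <- function(x) matrix(x, 1, 1)
    structure(list(a1 = m(a1), a2 = m(a2), tau_fret = m(tf), tau0 = m(t0),
                   background = m(0), chi2_map = m(1),
                   mask = m(TRUE), collapsed = m(collapsed),
                   intensity_map = m(1000)),
              class = "bi_fit_image")
  }
  # tau_fret = tau0 -> E = 0, class low
  fm <- compute_fret_map(mk(0.5, 0.5, 2.47, 2.47))
  expect_equal(fm$efficiency_map[1, 1], 0)
  expect_identical(fm$class_map$labels[fm$class_map$codes[1, 1] + 1L], "low")
  # tau_fret 0.5, tau0 2.5 -> E = 0.8, class high
  fm2 <- compute_fret_map(mk(0.5, 0.5, 0.5, 2.5))
  expect_equal(fm2$efficiency_map[1, 1], 0.8)
  expect_identical(fm2$class_map$labels[fm2$class_map$codes[1, 1] + 1L],
                   "high")
  # collapsed fits are masked out
  fm3 <- compute_fret_map(mk(0.5, 0.5, 2.4, 2.47, collapsed = TRUE))
  expect_false(any(fm3$mask))
  # negligible a1 goes through the donor-only path: E = 0, not tau_fret
  fm4 <- compute_fret_map(mk(0.001, 1, 0.3, 2.47))
  expect_equal(fm4$efficiency_map[1, 1], 0)
  expect_error(compute_fret_map(mk(1, 1, 1, 2), tau0_ref = -2), "tau0_ref")
})

test_that("map_histogram conserves counts on aligned bins", {
  set.seed(4)
  vals <- matrix(c(runif(300, 2.0, 2.8), rep(NA, 100)), 20)
  h <- map_histogram(vals, 0.02)
  expect_identical(sum(h$count), 300L)
  # edges aligned to multiples of the bin width
  expect_true(all(abs((h$bin_center / 0.02) %% 1 - 0.5) < 1e-9))
  # uniform map -> single nonzero bin containing the value
  h1 <- map_histogram(matrix(2.46, 5, 5), 0.02)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$count, 25L)
  expect_true(abs(h1$bin_center - 2.46) <= 0.01 + 1e-9)
  # invariant under pixel-order permutation
  perm <- matrix(sample(as.vector(vals)), 20)
  expect_identical(map_histogram(perm, 0.02), h)
  expect_error(map_histogram(vals, -1), "bin_width")
})

test_that("histogram of a bimodal FRET phantom shows both modes", {
  # two ground-truth efficiency populations, directly from generator truth
  cfg <- small_cfg()
  ph <- generate_fret_phantom("early", "late", cfg, seed = 8,
                              mode = "sequential")
  foc <- ph$labels == 3L
  e <- ph$truth$efficiency
  e[!foc] <- NA
  h <- map_histogram(e, 0.02)
  top <- h[order(-h$count), ][1:2, ]
  modes <- sort(top$bin_center)
  expect_lt(abs(modes[1] - 0), 0.02 + 1e-9)
  expect_lt(abs(modes[2] - cfg$fret_efficiency), 0.02 + 1e-9)
})

test_that("summarize_by_group computes weighted means and pairwise diffs", {
  m <- function(x, n = 2) matrix(x, n)
  lm <- structure(list(tau_map = m(c(2.46, 2.46, 2.0, 3.0)),
                       mask = m(rep(TRUE, 4)),
                       intensity_map = m(c(10, 10, 100, 300))),
                  class = "lifetime_map")
  g <- m(c("a", "a", "b", "b"))
  s <- summarize_by_group(lm, g)
  expect_equal(s$mean_tau_ns[s$group == "a"], 2.46)
  expect_equal(s$sd_tau_ns[s$group == "a"], 0)
  expect_equal(s$mean_tau_ns[s$group == "b"], 2.75)  # weighted 100:300
  pw <- attr(s, "pairwise")
  expect_equal(abs(pw$diff_ps), 1000 * abs(2.46 - 2.75))
  # permuting group labels permutes rows but not values
  g2 <- m(c("b", "b", "a", "a"))
  lm2 <- lm
  lm2$tau_map <- m(c(2.0, 3.0, 2.46, 2.46))
  lm2$intensity_map <- m(c(100, 300, 10, 10))
  s2 <- summarize_by_group(lm2, g2)
  expect_equal(s2$mean_tau_ns[s2$group == "a"], 2.46)
  expect_equal(s2$mean_tau_ns[s2$group == "b"], 2.75)
})

test_that("render_class_map maps classes to colors bijectively", {
  vals <- matrix(c(2.2, 2.4, 2.6, 2.0, 2.9, NA), 2)
  cm <- segment_map(vals, lifetime_scheme())
  img <- render_class_map(cm)
  expect_identical(dim(img), c(2L, 3L, 3L))
  # masked pixel is black
  expect_equal(img[2, 3, ], c(0, 0, 0))
  # distinct non-black colors: at most classes + 2 overflow
  cols <- apply(matrix(img, ncol = 3), 1, paste, collapse = ",")
  nonblack <- setdiff(unique(cols), "0,0,0")
  expect_lte(length(nonblack), length(lifetime_scheme()$labels) + 2)
  # class counts in the rendered image equal class counts in the map
  cc <- class_counts(cm)
  for (k in which(cc$n_pixels > 0)) {
    code <- k - 1L
    px <- which(cm$codes == code)
    colk <- unique(cols[px])
    expect_length(colk, 1)
    expect_identical(sum(cols == colk & !is.na(as.vector(cm$codes))),
                     cc$n_pixels[k])
  }
  # all-masked map renders all black
  cm0 <- segment_map(matrix(NA_real_, 2, 2), lifetime_scheme())
  img0 <- render_class_map(cm0)
  expect_true(all(img0 == 0))
})

test_that("scheme constructors validate their inputs", {
  expect_error(segmentation_scheme(c(1, 1), "x"), "increasing")
  expect_error(segmentation_scheme(c(1, 2, 3), "x"), "label")
  expect_error(segmentation_scheme(c(1, 2), c("x"), c("red", "blue")),
               "color")
})
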