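# Synthetic municipality generator: determinism, generative-model checks
# and ground-truth recovery.

test_that("site generation is deterministic and respects the extent", {
  cfg <- synthetic_config(n_samples = 40, extent = c(2000, 1000))
  a <- generate_sites(cfg, seed = 7)
  b <- generate_sites(cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_sites(cfg, seed = 8)))
  expect_true(all(a$x >= 0 & a$x <= 2000))
  expect_true(all(a$y >= 0 & a$y <= 1000))
  one <- generate_sites(synthetic_config(n_samples = 1), seed = 1)
  expect_equal(nrow(one), 1)
})

test_that("the noiseless field is background plus Gaussian hot spots", {
  bg <- c(As = 6, Cd = 0.35)
  h <- list(list(center = c(500, 500), amplitude = c(As = 60, Cd = 7),
                 range = 100))
  cfg <- synthetic_config(n_samples = 2, extent = c(1000, 1000),
                          hotspots = h, background = bg,
                          background_frac = 1, lognormal_sigma = 0)
  # far from the hot spot: exactly background
  far <- noiseless_concentration(0, 0, cfg)
  expect_equal(unname(far[1, "As"]), 6, tolerance = 1e-4)
  # at the center: background + amplitude
  ctr <- noiseless_concentration(500, 500, cfg)
  expect_equal(unname(ctr[1, "As"]), 66)
  expect_equal(unname(ctr[1, "Cd"]), 7.35)
  # one decay length out: background + amplitude * exp(-1/2)
  off <- noiseless_concentration(600, 500, cfg)
  expect_equal(unname(off[1, "As"]), 6 + 60 * exp(-0.5))
  # sigma = 0: generated concentrations equal the noiseless field
  sites <- data.frame(x = c(0, 500), y = c(0, 500))
  s <- generate_concentrations(sites, cfg, seed = 1)
  expect_equal(s$As, c(6, 66), tolerance = 1e-4)
})

test_that("lognormal noise has the stated log-scale distribution", {
  cfg <- synthetic_config(n_samples = 500, lognormal_sigma = 0.3)
  sites <- generate_sites(cfg, seed = 3)
  s <- generate_concentrations(sites, cfg, seed = 3)
  mu <- noiseless_concentration(sites$x, sites$y, cfg)
  # log-residuals are N(0, sigma^2): the mean over 500 draws per element
  # must sit within 3 standard errors of zero
  for (e in c("As", "Cd", "Pb", "Cr")) {
    resid <- log(s[[e]]) - log(mu[, e])
    expect_lt(abs(mean(resid)), 3 * 0.3 / sqrt(500))
    expect_true(all(s[[e]] > 0))
  }
})

test_that("the dose-response has its asymptotes and half-maximum", {
  dr <- synthetic_config()$dose_response
  expect_equal(dose_response_expectation(0, dr)$g, dr$max_g)
  at_ec50 <- dose_response_expectation(dr$ec50, dr)
  expect_equal(at_ec50$g, dr$max_g / 2)
  expect_equal(at_ec50$length_mm, dr$max_length_mm / 2)
  far <- dose_response_expectation(1000 * dr$ec50, dr)
  expect_lt(compute_pvi(far$length_mm, far$g), 1e-4)
  # monotone decreasing in t
  t <- seq(0, 10, by = 0.25)
  expect_true(all(diff(dose_response_expectation(t, dr)$g) < 0))
})

test_that("simulated bioassays satisfy the record invariants", {
  cfg <- synthetic_config(n_samples = 30)
  sites <- generate_sites(cfg, seed = 11)
  s <- generate_concentrations(sites, cfg, seed = 11)
  b <- simulate_bioassay(s, cfg$background, cfg, seed = 11)
  expect_s3_class(b, "pte_bioassay")
  expect_equal(nrow(b), 30 * 3)
  expect_true(all(b$germinated >= 0 & b$germinated <= b$total))
  expect_true(all(lengths(b$lengths_mm) <= b$germinated))
  expect_true(all(unlist(b$lengths_mm) > 0))
  expect_identical(b$germinated,
                   simulate_bioassay(s, cfg$background, cfg,
                                     seed = 11)$germinated)
})

test_that("a study bundle passes the package validators and is reproducible", {
  cfg <- synthetic_config(n_samples = 20)
  d1 <- file.path(tempdir(), "study1"); d2 <- file.path(tempdir(), "study2")
  study <- generate_study(cfg, seed = 5, dir = d1)
  generate_study(cfg, seed = 5, dir = d2)
  for (f in c("samples.csv", "bioassay.csv", "background.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the written files parse back through the readers
  s <- read_samples(file.path(d1, "samples.csv"))
  expect_equal(nrow(s), 20)
  b <- read_bioassay(file.path(d1, "bioassay.csv"))
  expect_equal(length(unique(b$sample_id)), 20)
  cb <- read_background(file.path(d1, "background.csv"))
  expect_equal(cb, study$background)
  expect_true(all(c("pli_true", "pvi_true", "zone_true") %in%
                    names(study$truth)))
})

test_that("ground-truth zones reflect the noiseless dose-response", {
  cfg <- synthetic_config(n_samples = 50)
  study <- generate_study(cfg, seed = 2)
  tr <- study$truth
  # recompute the truth independently from the noiseless field
  mu <- noiseless_concentration(study$samples$x, study$samples$y, cfg)
  pli <- apply(mu, 1, function(co) exp(mean(log(co / cfg$background))))
  expect_equal(tr$pli_true, pli, tolerance = 1e-12, ignore_attr = TRUE)
  ex <- dose_response_expectation(pli, cfg$dose_response)
  expect_equal(tr$pvi_true, 0.1 * ex$length_mm * ex$g, ignore_attr = TRUE)
  expect_equal(as.character(tr$zone_true),
               as.character(classify_zone(tr$pli_true, tr$pvi_true)))
})

test_that("pipeline PVI and PLI are strongly negatively associated", {
  cfg <- synthetic_config(n_samples = 100, lognormal_sigma = 0.2)
  study <- generate_study(cfg, seed = 19)
  idx <- compute_indices(study$samples, study$background)
  vig <- compute_bioassay(study$bioassay)
  rho <- cor(idx$pli, vig$pvi[match(idx$sample_id, vig$sample_id)],
             method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("red zones concentrate near hot-spot centers", {
  cfg <- synthetic_config(n_samples = 150)
  reds_near <- reds_far <- 0L; n_near <- n_far <- 0L
  for (seed in 1:5) {
    study <- generate_study(cfg, seed = seed)
    idx <- compute_indices(study$samples, study$background)
    vig <- compute_bioassay(study$bioassay)
    z <- zone_samples(idx, vig)
    dmin <- rep(Inf, nrow(study$samples))
    rng <- rep(NA_real_, nrow(study$samples))
    for (h in cfg$hotspots) {
      d <- sqrt((study$samples$x - h$center[1])^2 +
                  (study$samples$y - h$center[2])^2)
      upd <- d < dmin
      dmin[upd] <- d[upd]; rng[upd] <- h$range
    }
    near <- dmin <= rng; far <- dmin > 3 * rng
    reds_near <- reds_near + sum(z$zone[near] == "red")
    n_near <- n_near + sum(near)
    reds_far <- reds_far + sum(z$zone[far] == "red")
    n_far <- n_far + sum(far)
  }
  expect_gt(reds_near / n_near, reds_far / n_far)
})
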