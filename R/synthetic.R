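# Synthetic municipality generator: hot-spot structured concentrations with
# multiplicative lognormal noise and a monotone dose-response bioassay, with
# known ground truth for end-to-end testing.

#' Reference background values shipped with the package
#'
#' @return named numeric vector (mg/kg) for As, Cd, Pb, Cr.
#' @export
default_background <- function() {
  c(As = 6.0, Cd = 0.35, Pb = 59.2, Cr = 69)
}

default_hotspots <- function(extent, background) {
  # amplitudes sized so per-element PI maxima near a source reach the
  # two-to-three-digit range seen around active mining areas
  amp_full <- background * c(As = 147, Cd = 185, Pb = 7, Cr = 3.3)
  r <- 0.10 * min(extent)
  list(
    list(center = c(0.25, 0.30) * extent, amplitude = amp_full,        range = r),
    list(center = c(0.70, 0.60) * extent, amplitude = 0.5 * amp_full,  range = r),
    list(center = c(0.45, 0.85) * extent, amplitude = 0.25 * amp_full, range = 0.75 * r)
  )
}

#' Configuration of a synthetic study
#'
#' Bundles every knob of the generator. Defaults describe a
#' municipality-like survey: samples scattered uniformly over a 4 x 4 km
#' extent, three Gaussian-kernel hot spots standing in for mine/tailings
#' point sources, unimpacted soil sitting somewhat below the geochemical
#' background (`background_frac`), multiplicative lognormal concentration
#' noise, and a Hill-type dose-response linking the sample's PLI to seed
#' germination and radicle elongation (three replicate dishes of ten seeds,
#' as in the standard Petri-dish assay; a 90%-germination seed lot).
#'
#' @param n_samples number of soil samples, >= 1.
#' @param extent planar `(width, height)` of the study area.
#' @param hotspots list of `list(center = c(x, y), amplitude = named mg/kg
#'   vector, range = decay length)`; each contributes
#'   `amplitude * exp(-d^2 / (2 * range^2))` to the noiseless field.
#' @param background named background-value vector (mg/kg), the PI
#'   denominators; default [default_background()].
#' @param background_frac noiseless far-field concentration as a fraction
#'   of `background`; default 0.7 (clean soils sit below to very near the
#'   background value).
#' @param lognormal_sigma sd of the multiplicative log-noise; default 0.3.
#' @param dose_response list with `ec50` (PLI at half-maximal response),
#'   `hill` (slope), `max_g` (asymptotic germination %, default 90),
#'   `max_length_mm` (asymptotic radicle length).
#' @param replicate_noise_sd coefficient of variation of individual radicle
#'   lengths around the replicate expectation; default 0.15.
#' @param n_replicates replicate dishes per sample; default 3.
#' @param seeds_per_dish seeds per dish; default 10.
#' @return object of class `synthetic_config`.
#' @examples
#' synthetic_config(n_samples = 25)
#' @export
synthetic_config <- function(n_samples = 60,
                             extent = c(4000, 4000),
                             hotspots = NULL,
                             background = default_background(),
                             background_frac = 0.7,
                             lognormal_sigma = 0.3,
                             dose_response = list(ec50 = 2, hill = 2,
                                                  max_g = 90,
                                                  max_length_mm = 40),
                             replicate_noise_sd = 0.15,
                             n_replicates = 3,
                             seeds_per_dish = 10) {
  stopifnot(n_samples >= 1, length(extent) == 2, all(extent > 0),
            all(background > 0), background_frac > 0,
            lognormal_sigma >= 0, replicate_noise_sd >= 0,
            n_replicates >= 1, seeds_per_dish >= 1)
  dr <- dose_response
  stopifnot(dr$ec50 > 0, dr$hill > 0, dr$max_g > 0, dr$max_g <= 100,
            dr$max_length_mm > 0)
  if (is.null(hotspots)) hotspots <- default_hotspots(extent, background)
  for (h in hotspots) {
    stopifnot(length(h$center) == 2, all(h$amplitude >= 0), h$range > 0)
  }
  structure(list(n_samples = as.integer(n_samples), extent = extent,
                 hotspots = hotspots, background = background,
                 background_frac = background_frac,
                 lognormal_sigma = lognormal_sigma,
                 dose_response = dr,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seeds_per_dish = as.integer(seeds_per_dish)),
            class = "synthetic_config")
}

# stage-specific seeds derived from one master seed so that stages are
# independently reproducible
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 7919L * stage) %% .Machine$integer.max
}

#' Draw sampling locations
#'
#' Uniform points over the configured extent; deterministic given the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return data frame with columns `x`, `y` (`n_samples` rows).
#' @export
generate_sites <- function(config, seed = 1) {
  set.seed(stage_seed(seed, 1L))
  data.frame(x = stats::runif(config$n_samples, 0, config$extent[1]),
             y = stats::runif(config$n_samples, 0, config$extent[2]))
}

#' Noiseless concentration field at given locations
#'
#' The generative mean: far-field background level plus the sum of the
#' Gaussian hot-spot kernels, per element.
#'
#' @param x,y locations.
#' @param config a [synthetic_config()].
#' @return matrix, locations x elements, mg/kg.
#' @export
noiseless_concentration <- function(x, y, config) {
  elems <- names(config$background)
  mu <- matrix(rep(config$background_frac * config$background,
                   each = length(x)),
               nrow = length(x), dimnames = list(NULL, elems))
  for (h in config$hotspots) {
    d2 <- (x - h$center[1])^2 + (y - h$center[2])^2
    kern <- exp(-d2 / (2 * h$range^2))
    amp <- h$amplitude[elems]
    amp[is.na(amp)] <- 0
    mu <- mu + outer(kern, amp)
  }
  mu
}

#' Generate a soil-sample table with hot-spot structure
#'
#' Concentrations are the noiseless field multiplied by lognormal noise
#' `exp(N(0, sigma^2))`, hence strictly positive.
#'
#' @param sites data frame with `x`, `y` (see [generate_sites()]).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param site_label site label for the generated table.
#' @return a `pte_samples` data frame.
#' @export
generate_concentrations <- function(sites, config, seed = 1,
                                    site_label = "synthetic") {
  mu <- noiseless_concentration(sites$x, sites$y, config)
  set.seed(stage_seed(seed, 2L))
  noise <- matrix(stats::rnorm(length(mu), 0, config$lognormal_sigma),
                  nrow = nrow(mu))
  conc <- mu * exp(noise)
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(sites))),
                    site = site_label, x = sites$x, y = sites$y,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mu))) out[[colnames(mu)[j]]] <- conc[, j]
  validate_samples(as_pte_samples(out))
}

#' Hill-type dose-response of the bioassay
#'
#' Expected response fraction at toxicity score `t` (the sample's PLI):
#' \deqn{f(t) = 1 / (1 + (t / ec50)^{hill})}
#' so the response is half-maximal at `t = ec50` and vanishes for
#' `t >> ec50`.
#'
#' @param t toxicity score (PLI units), >= 0.
#' @param dr dose-response parameter list (see [synthetic_config()]).
#' @return list with `g` (expected germination %) and `length_mm`
#'   (expected radicle length).
#' @export
dose_response_expectation <- function(t, dr) {
  f <- 1 / (1 + (t / dr$ec50)^dr$hill)
  list(g = dr$max_g * f, length_mm = dr$max_length_mm * f)
}

rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate the seed bioassay for a sample table
#'
#' Each sample's toxicity score is its PLI (computed with the indices
#' machinery against `background`). Expected germination and radicle length
#' follow the Hill dose-response; germinated counts are binomial per
#' replicate dish and individual radicle lengths are positive-truncated
#' normal around the expectation.
#'
#' @param samples a `pte_samples` data frame.
#' @param background named background vector (PI denominators).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return a `pte_bioassay` data frame.
#' @export
simulate_bioassay <- function(samples, background, config, seed = 1) {
  idx <- compute_indices(samples, background)
  t <- idx$pli
  ex <- dose_response_expectation(t, config$dose_response)
  set.seed(stage_seed(seed, 3L))
  rows <- vector("list", nrow(samples) * config$n_replicates)
  k <- 0L
  for (i in seq_len(nrow(samples))) {
    for (r in seq_len(config$n_replicates)) {
      germ <- stats::rbinom(1, config$seeds_per_dish, ex$g[i] / 100)
      lens <- rtruncnorm_pos(germ, ex$length_mm[i],
                             config$replicate_noise_sd * ex$length_mm[i])
      k <- k + 1L
      rows[[k]] <- list(sample_id = samples$sample_id[i], replicate = r,
                        germinated = germ, total = config$seeds_per_dish,
                        lengths = lens)
    }
  }
  out <- data.frame(sample_id = vapply(rows, `[[`, character(1), "sample_id"),
                    replicate = vapply(rows, `[[`, integer(1), "replicate"),
                    germinated = vapply(rows, `[[`, integer(1), "germinated"),
                    total = vapply(rows, `[[`, integer(1), "total"),
                    stringsAsFactors = FALSE)
  out$lengths_mm <- lapply(rows, `[[`, "lengths")
  validate_bioassay(out)
  class(out) <- c("pte_bioassay", "data.frame")
  out
}

#' Generate a complete synthetic study with ground truth
#'
#' Runs sites, concentrations and bioassay generation from one master seed
#' and computes the ground-truth zone of every sample from the *noiseless*
#' concentration field: true PLI against the background table and true PVI
#' from the noise-free dose-response.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed; each stage derives its own sub-seed, so
#'   runs are byte-reproducible.
#' @param dir optional directory; when given, writes `samples.csv`,
#'   `bioassay.csv`, `background.csv` and `truth.csv` there.
#' @param rules [zoning_rules()] used for the ground-truth zones.
#' @return object of class `pte_study`: list with `samples`, `bioassay`,
#'   `background`, `truth` (data frame `sample_id`, `pli_true`, `pvi_true`,
#'   `zone_true`), `config`, `seed`.
#' @examples
#' study <- generate_study(synthetic_config(n_samples = 10), seed = 42)
#' study$truth$zone_true
#' @export
generate_study <- function(config = synthetic_config(), seed = 1,
                           dir = NULL, rules = zoning_rules()) {
  sites <- generate_sites(config, seed)
  samples <- generate_concentrations(sites, config, seed)
  bioassay <- simulate_bioassay(samples, config$background, config, seed)
  mu <- noiseless_concentration(sites$x, sites$y, config)
  pli_true <- apply(mu, 1, function(conc) {
    compute_pli(compute_pi(conc, config$background[colnames(mu)]))
  })
  ex <- dose_response_expectation(pli_true, config$dose_response)
  pvi_true <- compute_pvi(ex$length_mm, ex$g)
  truth <- data.frame(sample_id = samples$sample_id,
                      pli_true = pli_true, pvi_true = pvi_true,
                      stringsAsFactors = FALSE)
  truth$zone_true <- classify_zone(pli_true, pvi_true, rules)
  study <- structure(list(samples = samples, bioassay = bioassay,
                          background = config$background, truth = truth,
                          config = config, seed = seed),
                     class = "pte_study")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_samples(samples, file.path(dir, "samples.csv"))
    write_bioassay(bioassay, file.path(dir, "bioassay.csv"))
    utils::write.csv(data.frame(element = names(config$background),
                                background = unname(config$background)),
                     file.path(dir, "background.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  study
}

#' @export
print.pte_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$samples), "samples,",
      length(x$config$hotspots), "hot spots, seed", x$seed, "\n")
  cat("Ground-truth zones:\n")
  print(table(x$truth$zone_true))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic study config:", x$n_samples, "samples over",
      paste(x$extent, collapse = " x "), "units;",
      length(x$hotspots), "hot spots; sigma =", x$lognormal_sigma, "\n")
  cat("Dose-response: ec50 =", x$dose_response$ec50,
      "hill =", x$dose_response$hill,
      "max G% =", x$dose_response$max_g,
      "max length =", x$dose_response$max_length_mm, "mm\n")
  invisible(x)
}
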