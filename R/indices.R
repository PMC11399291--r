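# Pollution Index (PI), Pollution Load Index (PLI), rank classification and
# clean-up-standard screening.

PI_BREAKS <- c(0, 1, 2, 3, 5, Inf)
PI_RANKS <- c("absent", "low", "moderate", "strong", "very_strong")

#' Pollution Index of one element
#'
#' The PI of an element in a sample is the measured concentration divided by
#' the element's geochemical background value:
#' \deqn{PI_i = C_{PTE,i} / C_{B,i}}
#' It is dimensionless and scale-invariant: rescaling concentration and
#' background jointly leaves PI unchanged.
#'
#' @param conc measured concentration, mg/kg (vectorized).
#' @param background background concentration, mg/kg; must be > 0.
#' @return dimensionless PI, same length as the recycled inputs.
#' @examples
#' compute_pi(10, 5)           # 2
#' compute_pi(c(6, 12, 3), 6)  # 1 2 0.5
#' @seealso [classify_pi()], [compute_pli()]
#' @export
compute_pi <- function(conc, background) {
  if (any(!is.na(background) & background <= 0)) {
    stop("background must be > 0", call. = FALSE)
  }
  if (any(!is.na(conc) & conc < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  conc / background
}

#' Classify a Pollution Index into a pollution rank
#'
#' Five ranks tile the non-negative axis without overlap:
#' absent \eqn{[0,1)}, low \eqn{[1,2)}, moderate \eqn{[2,3)},
#' strong \eqn{[3,5)}, very strong \eqn{[5,\infty)}. Boundaries are
#' inclusive on the left (PI = 1 is "low", PI = 5 is "very_strong").
#'
#' @param pi dimensionless Pollution Index (vectorized), >= 0.
#' @return factor with levels `absent < low < moderate < strong < very_strong`.
#' @examples
#' classify_pi(c(0.5, 1, 2.9, 4.99, 5))
#' @export
classify_pi <- function(pi) {
  if (any(!is.na(pi) & pi < 0)) stop("PI must be >= 0", call. = FALSE)
  cut(pi, breaks = PI_BREAKS, labels = PI_RANKS,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Pollution Load Index
#'
#' The PLI of a sample is the geometric mean of its per-element Pollution
#' Indices:
#' \deqn{PLI = (PI_1 \times PI_2 \times \cdots \times PI_n)^{1/n}}
#' Computed in log space for numerical stability, so
#' \eqn{\log PLI = \mathrm{mean}(\log PI)} whenever all PIs are positive.
#' A single zero PI annihilates the geometric mean; the function returns 0
#' in that case with a warning rather than flooring the input.
#'
#' @param pis numeric vector of Pollution Indices, all >= 0, non-empty.
#'   `NA`s propagate to an `NA` result.
#' @return the dimensionless PLI (scalar).
#' @examples
#' compute_pli(c(1, 1, 1, 1))  # 1
#' compute_pli(c(2, 8, 1, 4))  # 64^0.25 = 2.8284...
#' @export
compute_pli <- function(pis) {
  if (length(pis) == 0L) stop("PLI needs at least one PI", call. = FALSE)
  if (anyNA(pis)) return(NA_real_)
  if (any(pis < 0)) stop("PI values must be >= 0", call. = FALSE)
  if (any(pis == 0)) {
    warning("a zero PI annihilates the geometric mean; PLI = 0", call. = FALSE)
    return(0)
  }
  exp(mean(log(pis)))
}

#' Is a sample polluted according to its PLI?
#'
#' PLI values above the threshold (default 1) indicate pollution; values at
#' or below it indicate element loads close to the background level. The
#' boundary itself is classified as not polluted (strict inequality).
#'
#' @param pli dimensionless PLI (vectorized), >= 0.
#' @param threshold dimensionless threshold, default 1.
#' @return logical vector.
#' @examples
#' classify_pollution(c(0.9, 1, 3.5))
#' @export
classify_pollution <- function(pli, threshold = 1) {
  if (any(!is.na(pli) & pli < 0)) stop("PLI must be >= 0", call. = FALSE)
  pli > threshold
}

#' Per-sample pollution indices for a sample table
#'
#' Computes PI per element, its rank, and the PLI over `elements` for every
#' sample. A sample missing a concentration for one of the PLI elements
#' keeps its per-element PIs but gets an `NA` PLI (the geometric mean needs
#' all elements), with a warning.
#'
#' @param samples a `pte_samples` data frame (see [read_samples()]).
#' @param background named numeric vector of background values
#'   (see [read_background()]).
#' @param elements element subset to use for the PLI; default all elements
#'   shared by `samples` and `background`.
#' @param threshold PLI pollution threshold, default 1.
#' @return data frame of class `pte_indices`: `sample_id`, `site`, one
#'   `pi_<El>` and `rank_<El>` column per element, `pli`, `polluted`.
#' @examples
#' s <- generate_study(synthetic_config(n_samples = 5), seed = 1)
#' compute_indices(s$samples, s$background)
#' @export
compute_indices <- function(samples, background,
                            elements = NULL, threshold = 1) {
  have <- sample_elements(samples)
  if (is.null(elements)) {
    elements <- intersect(have, names(background))
  }
  missing_bg <- setdiff(elements, names(background))
  if (length(missing_bg)) {
    stop("no background value for element(s): ",
         paste(missing_bg, collapse = ", "), call. = FALSE)
  }
  missing_el <- setdiff(elements, have)
  if (length(missing_el)) {
    stop("element(s) not in sample table: ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = samples$sample_id, site = samples$site,
                    stringsAsFactors = FALSE)
  pimat <- matrix(NA_real_, nrow = nrow(samples), ncol = length(elements),
                  dimnames = list(NULL, elements))
  for (e in elements) {
    pimat[, e] <- compute_pi(samples[[e]], background[[e]])
    out[[paste0("pi_", e)]] <- pimat[, e]
    out[[paste0("rank_", e)]] <- classify_pi(pimat[, e])
  }
  incomplete <- apply(pimat, 1, anyNA)
  if (any(incomplete)) {
    warning(sum(incomplete), " sample(s) with missing concentrations ",
            "excluded from PLI (per-element PIs retained)", call. = FALSE)
  }
  out$pli <- apply(pimat, 1, function(p) {
    if (anyNA(p)) NA_real_ else compute_pli(p)
  })
  out$polluted <- classify_pollution(out$pli, threshold)
  attr(out, "elements") <- elements
  attr(out, "threshold") <- threshold
  class(out) <- c("pte_indices", "data.frame")
  out
}

#' Tidy (long) form of an index result
#'
#' One row per sample x element, joined with the concentrations, suitable
#' for CSV export.
#'
#' @param indices a `pte_indices` data frame from [compute_indices()].
#' @param samples the matching `pte_samples` data frame.
#' @return data frame: `sample_id`, `site`, `element`, `conc`, `pi`, `rank`,
#'   `pli`, `polluted`.
#' @export
tidy_indices <- function(indices, samples) {
  elements <- attr(indices, "elements")
  rows <- lapply(elements, function(e) {
    data.frame(sample_id = indices$sample_id, site = indices$site,
               element = e,
               conc = samples[[e]][match(indices$sample_id, samples$sample_id)],
               pi = indices[[paste0("pi_", e)]],
               rank = as.character(indices[[paste0("rank_", e)]]),
               pli = indices$pli, polluted = indices$polluted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$sample_id, out$element), , drop = FALSE]
}

#' Soil clean-up standard exceedance screening
#'
#' Counts, per element and land use, how many samples exceed the regulatory
#' limit. A sample exactly at the limit is compliant (strict `>`), the usual
#' regulatory convention. Percentages are reported both as raw fractions and
#' rounded to the nearest integer percent.
#'
#' @param samples a `pte_samples` data frame.
#' @param scs an `scs_table` from [read_scs()].
#' @param elements elements to screen; default all sample elements. Every
#'   requested element must be present in `scs`.
#' @return data frame: `element`, `land_use`, `limit`, `n_exceed`, `n`,
#'   `frac`, `pct`.
#' @export
scs_exceedance <- function(samples, scs, elements = sample_elements(samples)) {
  missing_el <- setdiff(elements, scs$element)
  if (length(missing_el)) {
    stop("no clean-up standard for element(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (e in elements) {
    conc <- samples[[e]]
    n <- sum(!is.na(conc))
    for (use in c("residential", "industrial")) {
      lim <- scs[[use]][match(e, scs$element)]
      k <- sum(conc > lim, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        element = e, land_use = use, limit = lim,
        n_exceed = k, n = n,
        frac = if (n > 0) k / n else NA_real_,
        pct = if (n > 0) round(100 * k / n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-site summary of concentrations, indices and ranks
#'
#' For each site (municipality) reports min/median/max concentration and PI
#' per element, the percentage of samples flagged polluted by PLI, and the
#' percentage of samples per PI rank per element. Medians use the standard
#' midpoint convention for even sample counts.
#'
#' @param samples a `pte_samples` data frame.
#' @param indices the matching `pte_indices` data frame.
#' @return object of class `pte_site_summary`: a list with data frames
#'   `elements` (site x element ranges), `sites` (per-site pollution
#'   percentages) and `ranks` (per-site rank percentages).
#' @export
summarize_site <- function(samples, indices) {
  elements <- attr(indices, "elements")
  site <- ifelse(is.na(samples$site), "(all)", samples$site)
  isite <- ifelse(is.na(indices$site), "(all)", indices$site)
  erow <- list(); srow <- list(); rrow <- list()
  for (s in unique(site)) {
    sel <- site == s
    seli <- isite == s
    n <- sum(seli)
    for (e in elements) {
      conc <- samples[[e]][sel]
      pi <- indices[[paste0("pi_", e)]][seli]
      erow[[length(erow) + 1L]] <- data.frame(
        site = s, element = e, n = n,
        conc_min = min(conc, na.rm = TRUE),
        conc_median = stats::median(conc, na.rm = TRUE),
        conc_max = max(conc, na.rm = TRUE),
        pi_min = min(pi, na.rm = TRUE),
        pi_median = stats::median(pi, na.rm = TRUE),
        pi_max = max(pi, na.rm = TRUE),
        stringsAsFactors = FALSE)
      rk <- table(indices[[paste0("rank_", e)]][seli])
      rrow[[length(rrow) + 1L]] <- data.frame(
        site = s, element = e, rank = names(rk),
        n_rank = as.integer(rk),
        pct = 100 * as.integer(rk) / n,
        stringsAsFactors = FALSE)
    }
    pol <- indices$polluted[seli]
    srow[[length(srow) + 1L]] <- data.frame(
      site = s, n = n,
      n_polluted = sum(pol, na.rm = TRUE),
      pct_polluted = 100 * sum(pol, na.rm = TRUE) / sum(!is.na(pol)),
      stringsAsFactors = FALSE)
  }
  structure(list(elements = do.call(rbind, erow),
                 sites = do.call(rbind, srow),
                 ranks = do.call(rbind, rrow)),
            class = "pte_site_summary")
}

#' @export
print.pte_site_summary <- function(x, ...) {
  cat("Per-site element ranges:\n")
  print(x$elements, row.names = FALSE)
  cat("\nPollution by PLI:\n")
  print(x$sites, row.names = FALSE)
  invisible(x)
}

#' @export
print.pte_indices <- function(x, ...) {
  elements <- attr(x, "elements")
  cat("Pollution indices for", nrow(x), "samples over elements:",
      paste(elements, collapse = ", "), "\n")
  cat(sprintf("PLI range %.3g-%.3g; %d/%d polluted (PLI > %g)\n",
              suppressWarnings(min(x$pli, na.rm = TRUE)),
              suppressWarnings(max(x$pli, na.rm = TRUE)),
              sum(x$polluted, na.rm = TRUE), sum(!is.na(x$polluted)),
              attr(x, "threshold")))
  NextMethod()
}
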