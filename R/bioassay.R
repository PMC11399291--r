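# Seed-germination phytotoxicity bioassay: germination rate, radicle
# elongation and the Plant Vigor Index.

#' Germination rate
#'
#' Percentage of seeds that germinated within 24 h on the soil-water
#' extract:
#' \deqn{G\% = 100 \cdot \mathrm{germinated} / \mathrm{total}}
#'
#' @param germinated germinated-seed count (vectorized).
#' @param total total seeds per dish; must be > 0.
#' @return percentage in \eqn{[0, 100]}.
#' @examples
#' germination_rate(9, 10)  # 90
#' @export
germination_rate <- function(germinated, total) {
  if (any(!is.na(total) & total <= 0)) {
    stop("total seeds must be > 0", call. = FALSE)
  }
  bad <- !is.na(germinated) & !is.na(total) &
    (germinated < 0 | germinated > total)
  if (any(bad)) stop("germinated must lie in [0, total]", call. = FALSE)
  100 * germinated / total
}

#' Mean radicle length
#'
#' Arithmetic mean of the measured radicle lengths (mm) of the germinated
#' seeds. Non-germinated seeds contribute no length record, consistent with
#' the separate germination-rate factor in the Plant Vigor Index. An empty
#' set of measurements (no germination) yields 0 with a warning.
#'
#' @param lengths_mm numeric vector of radicle lengths in mm, all >= 0.
#' @return mean length in mm.
#' @examples
#' mean_radicle_length(c(10, 20, 30))  # 20
#' @export
mean_radicle_length <- function(lengths_mm) {
  if (any(!is.na(lengths_mm) & lengths_mm < 0)) {
    stop("radicle lengths must be >= 0", call. = FALSE)
  }
  if (length(lengths_mm) == 0L) {
    warning("no radicle lengths (no germination); mean length = 0",
            call. = FALSE)
    return(0)
  }
  mean(lengths_mm)
}

#' Plant Vigor Index
#'
#' \deqn{PVI = \bar{L}\,[\mathrm{cm}] \times G\%}
#' Lengths are handled in mm throughout the package and converted to cm
#' here, so `compute_pvi(L_mm, G) == 0.1 * L_mm * G` exactly. On this scale
#' a fully healthy assay (100% germination, 10 cm radicles) scores 1000 and
#' heavily intoxicated soils fall below 10.
#'
#' @param mean_length_mm mean radicle length in mm (vectorized).
#' @param g_pct germination rate in percent.
#' @return dimensionless PVI.
#' @examples
#' compute_pvi(50, 90)    # 450
#' compute_pvi(100, 100)  # 1000
#' @export
compute_pvi <- function(mean_length_mm, g_pct) {
  stopifnot(all(is.na(mean_length_mm) | mean_length_mm >= 0),
            all(is.na(g_pct) | g_pct >= 0))
  (mean_length_mm / 10) * g_pct
}

#' Is a soil phytotoxic according to its PVI?
#'
#' PVI values below the threshold (default 80) mark soils with a
#' significant impact on germination and seedling development. The boundary
#' itself is not phytotoxic (strict "below").
#'
#' @param pvi dimensionless PVI (vectorized), >= 0.
#' @param threshold default 80.
#' @return logical vector.
#' @examples
#' classify_phytotoxicity(c(79.9, 80, 450))
#' @export
classify_phytotoxicity <- function(pvi, threshold = 80) {
  if (any(!is.na(pvi) & pvi < 0)) stop("PVI must be >= 0", call. = FALSE)
  pvi < threshold
}

#' Reduce a bioassay table to per-sample vigor results
#'
#' Aggregates replicate dishes to one germination rate, mean radicle length
#' and PVI per sample.
#'
#' Two aggregation conventions are offered. `"replicate_mean"` (default)
#' averages replicate-level germination rates and replicate-level mean
#' lengths with equal replicate weight; `"pooled"` pools counts and length
#' measurements across replicates before computing the rates. They differ
#' only when replicates have unequal seed totals or germination counts.
#'
#' Optionally, rates and lengths can be expressed relative to a
#' deionized-water control sample (`control` = its sample_id); this is off
#' by default since the index is defined on absolute values.
#'
#' @param bioassay a `pte_bioassay` data frame (see [read_bioassay()]).
#' @param method `"replicate_mean"` or `"pooled"`.
#' @param control optional sample_id of the water control. When given,
#'   `g_pct` and `mean_length_mm` are re-expressed as percent-of-control
#'   (the control itself scores 100 on both, hence PVI = 1000, the top of
#'   the healthy scale).
#' @param threshold PVI phytotoxicity threshold, default 80.
#' @return data frame of class `pte_vigor`: `sample_id`, `g_pct`,
#'   `mean_length_mm`, `pvi`, `phytotoxic`.
#' @examples
#' s <- generate_study(synthetic_config(n_samples = 4), seed = 1)
#' compute_bioassay(s$bioassay)
#' @export
compute_bioassay <- function(bioassay,
                             method = c("replicate_mean", "pooled"),
                             control = NULL, threshold = 80) {
  method <- match.arg(method)
  validate_bioassay(bioassay)
  ids <- unique(bioassay$sample_id)
  g <- len <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sel <- bioassay$sample_id == ids[i]
    germ <- bioassay$germinated[sel]
    tot <- bioassay$total[sel]
    lengths <- bioassay$lengths_mm[sel]
    if (method == "replicate_mean") {
      g[i] <- mean(germination_rate(germ, tot))
      rep_means <- vapply(lengths, function(l) {
        if (length(l) == 0L) 0 else mean(l)
      }, numeric(1))
      # replicates with zero germination carry no elongation information;
      # average lengths over replicates that produced seedlings
      measured <- vapply(lengths, length, integer(1)) > 0
      len[i] <- if (any(measured)) mean(rep_means[measured]) else 0
    } else {
      g[i] <- germination_rate(sum(germ), sum(tot))
      pooled <- unlist(lengths)
      len[i] <- if (length(pooled)) mean(pooled) else 0
    }
  }
  if (!any(vapply(bioassay$lengths_mm, length, integer(1)) > 0)) {
    warning("bioassay contains no radicle length measurements", call. = FALSE)
  }
  if (!is.null(control)) {
    # express both factors as percent-of-control; the water control then
    # anchors the top of the vigor scale at PVI = (100/10) * 100 = 1000
    j <- match(control, ids)
    if (is.na(j)) stop("control sample '", control, "' not in bioassay",
                       call. = FALSE)
    if (g[j] <= 0 || len[j] <= 0) {
      stop("control sample has zero germination or length; cannot normalize",
           call. = FALSE)
    }
    g <- 100 * g / g[j]
    len <- 100 * len / len[j]
  }
  out <- data.frame(sample_id = ids, g_pct = g, mean_length_mm = len,
                    pvi = compute_pvi(len, g),
                    stringsAsFactors = FALSE)
  out$phytotoxic <- classify_phytotoxicity(out$pvi, threshold)
  class(out) <- c("pte_vigor", "data.frame")
  out
}

#' @export
print.pte_vigor <- function(x, ...) {
  cat("Plant vigor for", nrow(x), "samples;",
      sum(x$phytotoxic, na.rm = TRUE), "phytotoxic\n")
  NextMethod()
}
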