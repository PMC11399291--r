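# Red/yellow/green environmental-management zoning from PLI and PVI.

ZONE_LEVELS <- c("green", "yellow", "red")

#' Classify a location into a management zone
#'
#' The default rule combines the two indicators:
#' * **red** — PLI above the pollution threshold *and* PVI below the
#'   phytotoxicity threshold: severe enrichment with a toxic plant response;
#'   remediation priority.
#' * **green** — PLI at or below the threshold *and* PVI at or above it:
#'   low pollution, healthy bioassay; prevention focus.
#' * **yellow** — discordant indicators (enrichment without measured
#'   toxicity, or vice versa): protect and restore.
#'
#' The rule is pluggable: pass `rule` to substitute a stricter predicate
#' (e.g. one additionally requiring a very-strong PI for red).
#'
#' @param pli dimensionless PLI (vectorized), >= 0.
#' @param pvi dimensionless PVI (vectorized), >= 0.
#' @param rules a [zoning_rules()] object.
#' @param rule optional function `(pli, pvi, rules)` returning a character
#'   vector in `c("green", "yellow", "red")`; defaults to the two-threshold
#'   rule above.
#' @return ordered factor with levels `green < yellow < red` (`NA` where an
#'   input is `NA`).
#' @examples
#' classify_zone(c(3.5, 0.5, 1.5), c(20, 400, 200))
#' @export
classify_zone <- function(pli, pvi, rules = zoning_rules(), rule = NULL) {
  if (any(!is.na(pli) & pli < 0)) stop("PLI must be >= 0", call. = FALSE)
  if (any(!is.na(pvi) & pvi < 0)) stop("PVI must be >= 0", call. = FALSE)
  if (is.null(rule)) rule <- default_zone_rule
  z <- rule(pli, pvi, rules)
  factor(z, levels = ZONE_LEVELS, ordered = TRUE)
}

default_zone_rule <- function(pli, pvi, rules) {
  polluted <- pli > rules$pli_polluted_threshold
  toxic <- pvi < rules$pvi_toxic_threshold
  ifelse(is.na(polluted) | is.na(toxic), NA_character_,
         ifelse(polluted & toxic, "red",
                ifelse(!polluted & !toxic, "green", "yellow")))
}

#' Zone two raster fields into a categorical zone raster
#'
#' Applies [classify_zone()] cell by cell to a PLI field and a PVI field
#' sharing the same grid geometry. Cells masked in either input are nodata.
#'
#' @param pli_field,pvi_field `raster_field`s on identical grids.
#' @param rules a [zoning_rules()] object.
#' @param rule optional rule predicate, see [classify_zone()].
#' @return object of class `zone_raster`: the grid geometry, an integer
#'   zone matrix coded 1 = red, 2 = yellow, 3 = green, 0 = nodata, and an
#'   `area_summary` data frame.
#' @export
zone_map <- function(pli_field, pvi_field, rules = zoning_rules(),
                     rule = NULL) {
  if (!same_geometry(pli_field, pvi_field)) {
    stop("PLI and PVI rasters have different grid geometry", call. = FALSE)
  }
  mask <- pli_field$mask & pvi_field$mask &
    !is.na(pli_field$values) & !is.na(pvi_field$values)
  z <- classify_zone(pmax(pli_field$values, 0), pmax(pvi_field$values, 0),
                     rules, rule)
  code <- c(red = 1L, yellow = 2L, green = 3L)[as.character(z)]
  code[is.na(code)] <- 0L
  code[!mask] <- 0L
  zmat <- matrix(code, pli_field$grid$nrows, pli_field$grid$ncols)
  out <- structure(list(grid = pli_field$grid, zone = zmat, mask = mask),
                   class = "zone_raster")
  out$area_summary <- zone_summary(out)
  out
}

#' Area summary of a zone raster
#'
#' @param zones a `zone_raster`.
#' @param cell_area area of one cell; default `cell_size^2` of the grid.
#' @return data frame: `zone`, `cells`, `area`, `fraction` (of unmasked
#'   cells; fractions sum to 1 when any cell is unmasked).
#' @export
zone_summary <- function(zones, cell_area = NULL) {
  if (is.null(cell_area)) cell_area <- zones$grid$cell_size^2
  codes <- c(red = 1L, yellow = 2L, green = 3L)
  n_unmasked <- sum(zones$zone != 0L)
  counts <- vapply(codes, function(k) sum(zones$zone == k), integer(1))
  data.frame(zone = names(codes),
             cells = as.integer(counts),
             area = counts * cell_area,
             fraction = if (n_unmasked > 0) counts / n_unmasked else
               rep(NA_real_, 3),
             stringsAsFactors = FALSE)
}

#' Sample-level zoning
#'
#' Zones each sample from its PLI and PVI without any interpolation — the
#' path supported directly by per-sample tables.
#'
#' @param indices a `pte_indices` data frame (see [compute_indices()]).
#' @param vigor a `pte_vigor` data frame (see [compute_bioassay()]); matched
#'   to `indices` by `sample_id`.
#' @param rules a [zoning_rules()] object.
#' @param rule optional rule predicate, see [classify_zone()].
#' @return data frame: `sample_id`, `site`, `pli`, `pvi`, `zone`.
#' @export
zone_samples <- function(indices, vigor, rules = zoning_rules(), rule = NULL) {
  m <- match(indices$sample_id, vigor$sample_id)
  pvi <- vigor$pvi[m]
  out <- data.frame(sample_id = indices$sample_id, site = indices$site,
                    pli = indices$pli, pvi = pvi,
                    stringsAsFactors = FALSE)
  out$zone <- classify_zone(out$pli, out$pvi, rules, rule)
  out
}

#' @export
print.zone_raster <- function(x, ...) {
  g <- x$grid
  cat(sprintf("zone_raster: %d x %d cells of %g units\n",
              g$nrows, g$ncols, g$cell_size))
  print(x$area_summary, row.names = FALSE)
  invisible(x)
}

#' Plot a zone raster
#'
#' Color-mapped map of the red/yellow/green zones; nodata cells are blank.
#'
#' @param x a `zone_raster`.
#' @param points optional two-column matrix of sampling points to overlay.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.zone_raster <- function(x, points = NULL, main = "Environmental zoning",
                             ...) {
  cc <- grid_centers(structure(list(grid = x$grid), class = "raster_field"))
  z <- x$zone
  z[z == 0L] <- NA_integer_
  graphics::image(cc$x, cc$y, t(z), asp = 1, xlab = "x", ylab = "y",
                  main = main, zlim = c(1, 3),
                  col = c("#d7191c", "#ffd700", "#1a9641"), ...)
  if (!is.null(points)) {
    graphics::points(points[, 1], points[, 2], pch = 3, cex = 0.6)
  }
  invisible(x)
}

#' Write a zone raster as an ESRI ASCII grid
#'
#' Integer codes 1 = red, 2 = yellow, 3 = green, 0 = nodata.
#'
#' @param zones a `zone_raster`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_zone_ascii <- function(zones, path) {
  f <- new_raster_field(zones$grid, matrix(as.numeric(zones$zone),
                                           zones$grid$nrows, zones$grid$ncols),
                        matrix(TRUE, zones$grid$nrows, zones$grid$ncols))
  write_esri_ascii(f, path, nodata = 0)
}
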