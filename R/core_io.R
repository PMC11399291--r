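#' @keywords internal
"_PACKAGE"

# Canonical element order used throughout the package. Unknown elements are
# allowed everywhere; this vector only fixes a display/default ordering.
PTE_ELEMENTS <- c("As", "Cd", "Pb", "Cr")

#' Normalize element symbols to canonical chemical capitalization
#'
#' `"as"`, `"AS"` and `"As"` all refer to arsenic; readers normalize symbols
#' so that sample tables, background tables and clean-up standards join
#' reliably. Symbols not in the built-in As/Cd/Pb/Cr set are passed through
#' with first-letter capitalization (e.g. `"hg"` becomes `"Hg"`).
#'
#' @param x character vector of element symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_element(c("as", "CD", "pb", "Hg"))
#' @export
normalize_element <- function(x) {
  x <- trimws(as.character(x))
  bad <- !nzchar(x)
  out <- paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  out[bad] <- NA_character_
  out
}

element_columns <- function(df, reserved) {
  setdiff(names(df), reserved)
}

#' Read a soil-sample table
#'
#' Reads a delimited table with one row per soil sample: an identifier, a
#' site (municipality) label, planar x/y coordinates and one column per
#' element with concentrations in mg/kg. Coordinates are abstract projected
#' planar units; the package performs no CRS transforms. Any column not named
#' in `schema` is treated as an element concentration column and its name is
#' normalized with [normalize_element()].
#'
#' @param path path to a CSV file.
#' @param schema named list mapping the canonical field names `sample_id`,
#'   `site`, `x`, `y` to the column names used in the file. `site`, `x` and
#'   `y` are optional in the file; missing coordinate columns simply disable
#'   the spatial stages downstream.
#' @return a `data.frame` of class `pte_samples` with columns `sample_id`,
#'   `site`, `x`, `y` followed by one numeric column per element (mg/kg).
#'   Row order of the file is preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sample_id = c("s1", "s2"), site = "demo",
#'                      x = c(0, 10), y = c(0, 5),
#'                      As = c(12, 3), Cd = c(0.4, 0.2)),
#'           f, row.names = FALSE)
#' read_samples(f)
#' @export
read_samples <- function(path, schema = list(sample_id = "sample_id",
                                             site = "site", x = "x", y = "y")) {
  df <- read_csv_checked(path)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    warning("empty samples file: ", path, call. = FALSE)
    return(as_pte_samples(empty_samples()))
  }
  if (is.null(schema$sample_id) || !schema$sample_id %in% names(df)) {
    stop("samples table is missing required column '",
         if (is.null(schema$sample_id)) "sample_id" else schema$sample_id,
         "'", call. = FALSE)
  }
  reserved <- character(0)
  out <- data.frame(sample_id = as.character(df[[schema$sample_id]]),
                    stringsAsFactors = FALSE)
  reserved <- c(reserved, schema$sample_id)
  for (field in c("site", "x", "y")) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(df)) {
      out[[field]] <- if (field == "site") as.character(df[[col]]) else as.numeric(df[[col]])
      reserved <- c(reserved, col)
    } else {
      out[[field]] <- if (field == "site") NA_character_ else NA_real_
    }
  }
  elems <- element_columns(df, reserved)
  if (length(elems) == 0L) {
    stop("samples table has no element concentration columns", call. = FALSE)
  }
  for (e in elems) {
    out[[normalize_element(e)]] <- as.numeric(df[[e]])
  }
  validate_samples(as_pte_samples(out))
}

empty_samples <- function() {
  data.frame(sample_id = character(0), site = character(0),
             x = numeric(0), y = numeric(0), stringsAsFactors = FALSE)
}

as_pte_samples <- function(df) {
  class(df) <- c("pte_samples", "data.frame")
  df
}

#' List the element columns of a sample table
#'
#' @param samples a `pte_samples` data frame from [read_samples()] or
#'   [generate_concentrations()].
#' @return character vector of element symbols present.
#' @export
sample_elements <- function(samples) {
  setdiff(names(samples), c("sample_id", "site", "x", "y"))
}

validate_samples <- function(samples) {
  elems <- sample_elements(samples)
  for (e in elems) {
    v <- samples[[e]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad)) {
      stop("negative ", e, " concentration for sample '",
           samples$sample_id[bad[1]], "' (row ", bad[1], ")", call. = FALSE)
    }
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         samples$sample_id[anyDuplicated(samples$sample_id)], call. = FALSE)
  }
  xy <- cbind(samples$x, samples$y)
  if (any(is.infinite(xy))) {
    stop("non-finite coordinates in samples table", call. = FALSE)
  }
  samples
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame())
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Write a soil-sample table
#'
#' Inverse of [read_samples()]: writes the canonical CSV layout so that a
#' round trip reproduces the record list field for field.
#'
#' @param samples a `pte_samples` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a background-value table
#'
#' The background value of an element is its natural (pre-anthropogenic)
#' soil concentration, the denominator of the Pollution Index. The file has
#' columns `element` and `background` (mg/kg).
#'
#' A reference table inferred from published ranges for three Antioquian
#' municipalities ships with the package; it is a synthetic stand-in meant to
#' be replaced by locally established values:
#' `system.file("extdata", "background_synthetic.csv", package = "ptezone")`.
#'
#' @param path CSV path.
#' @return named numeric vector, element symbol to background mg/kg.
#' @export
read_background <- function(path) {
  df <- read_csv_checked(path)
  if (!all(c("element", "background") %in% names(df))) {
    stop("background table needs columns 'element' and 'background'", call. = FALSE)
  }
  cb <- stats::setNames(as.numeric(df$background), normalize_element(df$element))
  validate_background(cb)
}

validate_background <- function(cb) {
  if (length(cb) == 0L) stop("background table is empty", call. = FALSE)
  if (any(!is.finite(cb)) || any(cb <= 0)) {
    stop("background values must be finite and > 0 (PI divides by them)",
         call. = FALSE)
  }
  cb
}

#' Read a soil clean-up standards table
#'
#' Soil clean-up standards (SCSs) are regulatory concentration limits per
#' land use. The file has columns `element`, `residential`, `industrial`
#' (mg/kg). A default table compiled from multi-country standards ships as
#' `system.file("extdata", "scs_default.csv", package = "ptezone")`.
#'
#' @param path CSV path.
#' @return data frame of class `scs_table` with columns `element`,
#'   `residential`, `industrial`.
#' @export
read_scs <- function(path) {
  df <- read_csv_checked(path)
  need <- c("element", "residential", "industrial")
  if (!all(need %in% names(df))) {
    stop("SCS table needs columns 'element', 'residential', 'industrial'",
         call. = FALSE)
  }
  out <- data.frame(element = normalize_element(df$element),
                    residential = as.numeric(df$residential),
                    industrial = as.numeric(df$industrial),
                    stringsAsFactors = FALSE)
  if (any(out$residential <= 0) || any(out$industrial <= 0)) {
    stop("SCS limits must be > 0", call. = FALSE)
  }
  bad <- out$residential > out$industrial
  if (any(bad)) {
    stop("SCS residential limit exceeds industrial limit for: ",
         paste(out$element[bad], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("scs_table", "data.frame")
  out
}

#' Read a seed-bioassay table
#'
#' Long-format CSV with one row per sample x replicate: columns `sample_id`,
#' `replicate`, `germinated`, `total` and `lengths_mm` (radicle lengths of
#' the germinated seeds, semicolon-joined, in mm). The assay design mirrors
#' Petri-dish germination tests: 10 seeds per dish, three replicate dishes
#' per soil-water extract, germination scored at 24 h and radicle elongation
#' after a further 24 h.
#'
#' @param path CSV path.
#' @return data frame of class `pte_bioassay` with columns `sample_id`,
#'   `replicate`, `germinated`, `total` and list-column `lengths_mm`.
#' @export
read_bioassay <- function(path) {
  df <- read_csv_checked(path)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    warning("empty bioassay file: ", path, call. = FALSE)
    out <- data.frame(sample_id = character(0), replicate = integer(0),
                      germinated = integer(0), total = integer(0))
    out$lengths_mm <- list()
    class(out) <- c("pte_bioassay", "data.frame")
    return(out)
  }
  need <- c("sample_id", "replicate", "germinated", "total", "lengths_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("bioassay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    replicate = as.integer(df$replicate),
                    germinated = as.integer(df$germinated),
                    total = as.integer(df$total),
                    stringsAsFactors = FALSE)
  out$lengths_mm <- parse_lengths(df$lengths_mm)
  validate_bioassay(out)
  class(out) <- c("pte_bioassay", "data.frame")
  out
}

parse_lengths <- function(x) {
  lapply(as.character(x), function(s) {
    s <- trimws(s)
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

validate_bioassay <- function(df) {
  if (any(df$total <= 0)) {
    stop("bioassay replicate with total seeds <= 0 for sample '",
         df$sample_id[which(df$total <= 0)[1]], "'", call. = FALSE)
  }
  bad <- df$germinated < 0 | df$germinated > df$total
  if (any(bad)) {
    stop("germinated count outside [0, total] for sample '",
         df$sample_id[which(bad)[1]], "'", call. = FALSE)
  }
  nlen <- vapply(df$lengths_mm, length, integer(1))
  if (any(nlen > df$germinated)) {
    stop("more radicle lengths than germinated seeds for sample '",
         df$sample_id[which(nlen > df$germinated)[1]], "'", call. = FALSE)
  }
  neg <- vapply(df$lengths_mm, function(l) any(!is.na(l) & l < 0), logical(1))
  if (any(neg)) {
    stop("negative radicle length for sample '",
         df$sample_id[which(neg)[1]], "'", call. = FALSE)
  }
  invisible(df)
}

#' Write a seed-bioassay table
#'
#' @param bioassay a `pte_bioassay` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bioassay <- function(bioassay, path) {
  flat <- data.frame(sample_id = bioassay$sample_id,
                     replicate = bioassay$replicate,
                     germinated = bioassay$germinated,
                     total = bioassay$total,
                     lengths_mm = vapply(bioassay$lengths_mm, function(l) {
                       paste(format(l, trim = TRUE, scientific = FALSE),
                             collapse = ";")
                     }, character(1)),
                     stringsAsFactors = FALSE)
  flat$lengths_mm[vapply(bioassay$lengths_mm, length, integer(1)) == 0] <- ""
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zoning rule thresholds
#'
#' The two thresholds that drive the red/yellow/green classification: a
#' sample (or raster cell) is *polluted* when its Pollution Load Index
#' exceeds `pli_polluted_threshold` (PLI > 1 indicates pollution) and
#' *phytotoxic* when its Plant Vigor Index falls below `pvi_toxic_threshold`
#' (PVI below 80 marks significant impact on germination and seedling
#' development).
#'
#' @param pli_polluted_threshold dimensionless PLI threshold, default 1.
#' @param pvi_toxic_threshold dimensionless PVI threshold, default 80.
#' @return object of class `zoning_rules`.
#' @examples
#' zoning_rules()
#' zoning_rules(pli_polluted_threshold = 2)
#' @export
zoning_rules <- function(pli_polluted_threshold = 1, pvi_toxic_threshold = 80) {
  stopifnot(is.numeric(pli_polluted_threshold), pli_polluted_threshold > 0,
            is.numeric(pvi_toxic_threshold), pvi_toxic_threshold > 0)
  structure(list(pli_polluted_threshold = pli_polluted_threshold,
                 pvi_toxic_threshold = pvi_toxic_threshold),
            class = "zoning_rules")
}

#' @export
print.zoning_rules <- function(x, ...) {
  cat("Zoning rules: polluted if PLI >", x$pli_polluted_threshold,
      "; phytotoxic if PVI <", x$pvi_toxic_threshold, "\n")
  invisible(x)
}
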