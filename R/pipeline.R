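# Pipeline orchestration: indices -> bioassay -> interpolation -> zoning,
# from file paths or a YAML config, with CSV/ASCII/PNG outputs and a
# markdown report.

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `samples`, `background`, `scs`, `bioassay` (paths),
#' `out_dir`, `elements` (subset for the PLI), `idw` (`power`,
#' `max_neighbors`, `grid_n`, `buffer_radius`), `rules`
#' (`pli_polluted_threshold`, `pvi_toxic_threshold`), `seed`, and a
#' `synthetic` block forwarded to [synthetic_config()].
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

log_stage <- function(stage, ...) {
  message(sprintf("[ptezone:%s] %s", stage, paste0(...)))
}

#' Run the full zoning pipeline
#'
#' Orchestrates every applicable stage and writes all tabular, raster and
#' report outputs under `out_dir`:
#'
#' 1. **indices** — per-sample PI/PLI (`indices.csv` tidy long form),
#'    per-site summary (`site_summary.csv`), SCS exceedance screening
#'    (`exceedance.csv`, if an SCS table was given).
#' 2. **bioassay** — per-sample G%, radicle length, PVI (`vigor.csv`, if a
#'    bioassay table was given).
#' 3. **interpolate** — IDW surfaces of PLI and PVI clipped to the sampling
#'    buffer (`pli.asc`, `pvi.asc`, PNG quicklooks), skipped when
#'    coordinates are absent.
#' 4. **zone** — sample-level zoning (`zones_samples.csv`) and, when both
#'    surfaces exist, the raster zone map (`zones.asc`, `zones.png`) with
#'    its area summary (`zone_summary.csv`).
#' 5. **report** — `report.md` assembling the tables.
#'
#' Stages degrade gracefully: without a bioassay the pipeline stops after
#' the index stage and marks zoning unavailable; without coordinates the
#' spatial stages are skipped but sample-level zoning is still produced.
#' A failing stage aborts with an error naming the stage. Inputs are never
#' modified.
#'
#' @param config list (or path to a YAML file, see [read_config()]) with at
#'   least `samples` and `background` paths and an `out_dir`.
#' @return invisibly, a list with every intermediate result and a character
#'   vector `outputs` of the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(!is.null(config$samples), !is.null(config$background),
            !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  rules <- do.call(zoning_rules, as.list(config$rules %||% list()))

  res <- list()
  res$samples <- with_stage("read", {
    s <- read_samples(config$samples)
    log_stage("read", nrow(s), " samples, elements: ",
              paste(sample_elements(s), collapse = ", "))
    s
  })
  res$background <- with_stage("read", read_background(config$background))

  res$indices <- with_stage("indices", {
    idx <- compute_indices(res$samples, res$background,
                           elements = config$elements,
                           threshold = rules$pli_polluted_threshold)
    utils::write.csv(tidy_indices(idx, res$samples),
                     emit(file.path(out_dir, "indices.csv")),
                     row.names = FALSE)
    idx
  })
  res$site_summary <- with_stage("indices", {
    ss <- summarize_site(res$samples, res$indices)
    utils::write.csv(ss$elements,
                     emit(file.path(out_dir, "site_summary.csv")),
                     row.names = FALSE)
    ss
  })
  if (!is.null(config$scs)) {
    res$exceedance <- with_stage("indices", {
      ex <- scs_exceedance(res$samples, read_scs(config$scs),
                           elements = intersect(sample_elements(res$samples),
                                                read_scs(config$scs)$element))
      utils::write.csv(ex, emit(file.path(out_dir, "exceedance.csv")),
                       row.names = FALSE)
      ex
    })
  }

  has_bioassay <- !is.null(config$bioassay)
  if (has_bioassay) {
    res$vigor <- with_stage("bioassay", {
      v <- compute_bioassay(read_bioassay(config$bioassay),
                            threshold = rules$pvi_toxic_threshold)
      utils::write.csv(as.data.frame(v),
                       emit(file.path(out_dir, "vigor.csv")),
                       row.names = FALSE)
      log_stage("bioassay", nrow(v), " samples, ",
                sum(v$phytotoxic), " phytotoxic")
      v
    })
  } else {
    log_stage("bioassay", "no bioassay table; zoning unavailable")
  }

  have_xy <- all(is.finite(res$samples$x)) && all(is.finite(res$samples$y)) &&
    nrow(res$samples) >= 3
  if (have_xy) {
    res$fields <- with_stage("interpolate", {
      idw_cfg <- config$idw %||% list()
      grid <- default_grid(res$samples$x, res$samples$y,
                           n = idw_cfg$grid_n %||% 100)
      radius <- idw_cfg$buffer_radius %||%
        default_buffer_radius(res$samples$x, res$samples$y)
      interp <- function(v) {
        ok <- !is.na(v)
        f <- idw_interpolate(res$samples$x[ok], res$samples$y[ok], v[ok],
                             grid = grid, power = idw_cfg$power %||% 2,
                             max_neighbors = idw_cfg$max_neighbors %||% Inf)
        clip_to_buffer(f, res$samples$x[ok], res$samples$y[ok], radius)
      }
      fields <- list(pli = interp(res$indices$pli))
      write_esri_ascii(fields$pli, emit(file.path(out_dir, "pli.asc")))
      quicklook(fields$pli, res$samples,
                emit(file.path(out_dir, "pli.png")), "PLI")
      if (has_bioassay) {
        m <- match(res$samples$sample_id, res$vigor$sample_id)
        fields$pvi <- interp(res$vigor$pvi[m])
        write_esri_ascii(fields$pvi, emit(file.path(out_dir, "pvi.asc")))
        quicklook(fields$pvi, res$samples,
                  emit(file.path(out_dir, "pvi.png")), "PVI")
      }
      log_stage("interpolate", "grid ", grid$nrows, " x ", grid$ncols,
                ", buffer radius ", signif(radius, 4))
      fields
    })
  } else {
    log_stage("interpolate", "no usable coordinates; spatial stages skipped")
  }

  if (has_bioassay) {
    res$zones_samples <- with_stage("zone", {
      z <- zone_samples(res$indices, res$vigor, rules)
      utils::write.csv(z, emit(file.path(out_dir, "zones_samples.csv")),
                       row.names = FALSE)
      z
    })
    if (have_xy && !is.null(res$fields$pvi)) {
      res$zones <- with_stage("zone", {
        zr <- zone_map(res$fields$pli, res$fields$pvi, rules)
        write_zone_ascii(zr, emit(file.path(out_dir, "zones.asc")))
        utils::write.csv(zr$area_summary,
                         emit(file.path(out_dir, "zone_summary.csv")),
                         row.names = FALSE)
        grDevices::png(emit(file.path(out_dir, "zones.png")),
                       width = 700, height = 600)
        plot(zr, points = cbind(res$samples$x, res$samples$y))
        grDevices::dev.off()
        zr
      })
    }
  }

  with_stage("report", {
    write_report(res, rules, emit(file.path(out_dir, "report.md")),
                 has_bioassay, have_xy)
  })
  res$outputs <- outputs
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

quicklook <- function(field, samples, path, title) {
  grDevices::png(path, width = 700, height = 600)
  plot(field, points = cbind(samples$x, samples$y), main = title)
  grDevices::dev.off()
  invisible(path)
}

md_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, body), collapse = "\n")
}

write_report <- function(res, rules, path, has_bioassay, have_xy) {
  lines <- c("# Environmental zoning report", "",
             sprintf("Samples: %d. Elements: %s. Rules: PLI > %g polluted, PVI < %g phytotoxic.",
                     nrow(res$samples),
                     paste(attr(res$indices, "elements"), collapse = ", "),
                     rules$pli_polluted_threshold, rules$pvi_toxic_threshold),
             "", "## Site summary", "",
             md_table(res$site_summary$elements), "",
             "## Pollution by PLI", "",
             md_table(res$site_summary$sites), "")
  if (!is.null(res$exceedance)) {
    lines <- c(lines, "## Clean-up standard exceedance", "",
               md_table(res$exceedance), "")
  }
  if (has_bioassay) {
    lines <- c(lines, "## Plant vigor", "",
               md_table(as.data.frame(res$vigor)), "",
               "## Sample-level zoning", "",
               md_table(res$zones_samples), "")
    if (!is.null(res$zones)) {
      lines <- c(lines, "## Zone areas", "",
                 md_table(res$zones$area_summary), "")
    }
  } else {
    lines <- c(lines, "## Zoning", "",
               "Zoning unavailable: no bioassay table was provided.", "")
  }
  if (!have_xy) {
    lines <- c(lines,
               "Spatial stages were skipped (no usable coordinates).", "")
  }
  writeLines(lines, path)
  invisible(path)
}
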