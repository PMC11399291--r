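# Fixture builders shared by the test files. Everything is generated in
# code; no stored data.

write_samples_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_samples_df <- function() {
  data.frame(sample_id = c("a1", "a2", "a3"),
             site = "demo",
             x = c(0, 100, 50), y = c(0, 0, 80),
             As = c(12, 3, 30), Cd = c(0.7, 0.2, 1.4),
             Pb = c(40, 10, 120), Cr = c(50, 20, 90),
             stringsAsFactors = FALSE)
}

tiny_samples <- function() {
  read_samples(write_samples_csv(tiny_samples_df()))
}

tiny_background <- function() c(As = 6, Cd = 0.35, Pb = 59.2, Cr = 69)

bioassay_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("sample_id,replicate,germinated,total,lengths_mm", rows), path)
  path
}

# independent brute-force IDW oracle: plain per-cell loops, no shared code
# with the package implementation
idw_brute_force <- function(x, y, v, grid, power = 2, max_neighbors = Inf,
                            snap_tol = 1e-9 * grid$cell_size) {
  out <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (r in seq_len(grid$nrows)) {
    for (c in seq_len(grid$ncols)) {
      cx <- grid$origin[1] + (c - 0.5) * grid$cell_size
      cy <- grid$origin[2] + (r - 0.5) * grid$cell_size
      d <- sqrt((x - cx)^2 + (y - cy)^2)
      if (any(d <= snap_tol)) {
        out[r, c] <- v[which.min(d)]
        next
      }
      ord <- order(d)
      use <- ord[seq_len(min(max_neighbors, length(d)))]
      w <- d[use]^(-power)
      out[r, c] <- sum(w * v[use]) / sum(w)
    }
  }
  out
}

uniform_field <- function(value, n = 10, cell = 1) {
  g <- grid_spec(c(0, 0), cell, n, n)
  ptezone:::new_raster_field(g, matrix(value, n, n), matrix(TRUE, n, n))
}
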