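## Portable plain-text serialization: gridded dose/mask container, DVH CSV,
## run-length mask export, comparison-report writer.

.GRID_MAGIC <- "latticeRT grid 1"

#' Write / read a dose grid in the portable text container
#'
#' One file per grid: a small `key: value` header (dims, spacing, origin,
#' fractionation, scale, label, content hash) followed by the voxel values
#' in column-major order. A write-then-read round trip reproduces values,
#' spacing and origin exactly.
#'
#' @param grid a [DoseGrid-class].
#' @param path file path.
#' @return `readDoseGrid` returns the [DoseGrid-class];
#'   `writeDoseGrid` returns `path` invisibly.
#' @export
writeDoseGrid <- function(grid, path) {
  stopifnot(is(grid, "DoseGrid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    .GRID_MAGIC,
    paste("dims:", paste(dim(grid@values), collapse = " ")),
    paste("spacing:", paste(sprintf("%.17g", grid@spacing), collapse = " ")),
    paste("origin:", paste(sprintf("%.17g", grid@origin), collapse = " ")),
    paste("nFractions:", grid@nFractions),
    paste("scale:", grid@scale),
    paste("label:", grid@label),
    paste("hash:", configHash(as.vector(grid@values))),
    "values:"
  ), con)
  writeLines(sprintf("%.17g", as.vector(grid@values)), con)
  invisible(path)
}

#' @rdname writeDoseGrid
#' @export
readDoseGrid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 9 || lines[1] != .GRID_MAGIC)
    stop("not a latticeRT grid file: bad magic line")
  hdr <- lines[2:8]
  getField <- function(key) {
    m <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("malformed grid header: missing field '", key, "'")
    trimws(sub(paste0("^", key, ":"), "", m[1]))
  }
  dims <- as.integer(strsplit(getField("dims"), " +")[[1]])
  if (length(dims) != 3 || any(is.na(dims)))
    stop("malformed grid header: bad field 'dims'")
  spacing <- as.numeric(strsplit(getField("spacing"), " +")[[1]])
  origin <- as.numeric(strsplit(getField("origin"), " +")[[1]])
  nFx <- suppressWarnings(as.integer(getField("nFractions")))
  vstart <- which(lines == "values:")[1]
  if (is.na(vstart)) stop("malformed grid file: missing 'values:' section")
  vals <- suppressWarnings(as.numeric(lines[(vstart + 1):length(lines)]))
  if (length(vals) != prod(dims) || any(is.na(vals)))
    stop("truncated or corrupt grid file: expected ", prod(dims),
         " values, got ", length(vals))
  doseGrid(array(vals, dims), spacing, origin, nFx,
           scale = getField("scale"), label = getField("label"))
}

#' Write / read a structure mask in the grid container
#'
#' Masks reuse the dose container with 0/1 values.
#'
#' @param mask logical 3D array; @param spacing,origin grid geometry (mm);
#' @param path file path; @param label stored label.
#' @return `readMask` returns a list with `mask`, `spacing`, `origin`.
#' @export
writeMask <- function(mask, spacing, path, origin = c(0, 0, 0),
                      label = "mask") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  g <- doseGrid(array(as.numeric(mask), dim(mask)), spacing, origin,
                label = label)
  writeDoseGrid(g, path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  g <- readDoseGrid(path)
  list(mask = g@values > 0.5, spacing = g@spacing, origin = g@origin)
}

#' Per-slice run-length text export of a mask
#'
#' Human-inspectable encoding: one line per run of consecutive TRUE voxels
#' along x, as `z y x_start x_end` (1-based, inclusive).
#'
#' @param mask logical 3D array.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeMaskRLE <- function(mask, path) {
  d <- dim(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# latticeRT mask RLE; dims:", paste(d, collapse = " ")),
             con)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    r <- rle(mask[, j, k])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      writeLines(sprintf("%d %d %d %d", k, j, starts[keep], ends[keep]), con)
  }
  invisible(path)
}

#' Write / read a DVH as CSV
#'
#' Columns: bin lower edge (Gy), differential volume (cm3), cumulative
#' volume (cm3), cumulative volume (%). Structure name and dose scale are
#' stored in `#`-comment header lines.
#'
#' @param dvh a [DVH-class]; @param path file path.
#' @return `readDVH` returns the [DVH-class].
#' @export
writeDVH <- function(dvh, path) {
  stopifnot(is(dvh, "DVH"))
  cum <- rev(cumsum(rev(dvh@volume)))
  total <- sum(dvh@volume)
  df <- data.frame(
    bin_edge_gy = sprintf("%.17g", dvh@breaks[-length(dvh@breaks)]),
    differential_cm3 = sprintf("%.17g", dvh@volume),
    cumulative_cm3 = sprintf("%.17g", cum),
    cumulative_pct = sprintf("%.17g",
                             if (total > 0) 100 * cum / total else 0 * cum))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# structure:", dvh@structure),
               paste("# scale:", dvh@scale),
               paste("# bin_width:",
                     sprintf("%.17g", diff(dvh@breaks)[1]))), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDVH
#' @export
readDVH <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (!length(m)) default else trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  df <- read.csv(path, comment.char = "#")
  edges <- as.numeric(df$bin_edge_gy)
  width <- as.numeric(meta("bin_width", diff(edges)[1]))
  new("DVH", breaks = c(edges, edges[length(edges)] + width),
      volume = as.numeric(df$differential_cm3),
      structure = meta("structure", "structure"),
      scale = meta("scale", "physical"))
}

#' Write a comparison report to a directory
#'
#' Writes the summary table as CSV (full precision, header lines carrying
#' the seed and configuration hash), the ordering checks, and a short
#' human-readable text summary with probabilities printed to two
#' significant figures.
#'
#' @param report a [ComparisonReport-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeComparisonReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabPath <- file.path(dir, "comparison.csv")
  con <- file(tabPath, "w")
  writeLines(c(paste("# seed:", report@seed),
               paste("# config:", report@configHash)), con)
  write.csv(format(reportTable(report), digits = 17), con,
            row.names = FALSE, quote = FALSE)
  close(con)
  write.csv(checkOrderings(report), file.path(dir, "orderings.csv"),
            row.names = FALSE)
  tab <- reportTable(report)
  txt <- c(sprintf("Plan comparison (seed %d, config %s)", report@seed,
                   report@configHash),
           sprintf("%-5s %-9s %-12s %-9s", "plan", "TCP", "NTCP(chest)",
                   "NTCP(skin)"),
           sprintf("%-5s %-9.2g %-12.2g %-9.2g", tab$plan, tab$tcp,
                   tab$ntcpChestWall, tab$ntcpSkin))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
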