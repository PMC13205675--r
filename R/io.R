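#' Write a hyperspectral map as long-format CSV
#'
#' Columns `x`, `y` (1-based grid indices), `wavenumber`, `intensity`;
#' a header comment records the pixel order (row-major, y outer, x inner)
#' and grid steps.
#'
#' @param map A `hyperspectral_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(map, path) {
  stopifnot(inherits(map, "hyperspectral_map"))
  ix <- rep(rep(seq_len(map$nx), times = map$ny), each = length(map$wavenumbers))
  iy <- rep(rep(seq_len(map$ny), each = map$nx), each = length(map$wavenumbers))
  df <- data.frame(x = ix, y = iy,
                   wavenumber = rep(map$wavenumbers, times = map$nx * map$ny),
                   intensity = as.numeric(map$A))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel order: row-major, y outer, x inner; x_step_um=%.17g; y_step_um=%.17g",
                     map$x_step, map$y_step), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a hyperspectral map from long-format CSV
#'
#' Expects columns `x`, `y`, `wavenumber`, `intensity`; validates that the
#' (x, y) grid is complete and rectangular and that every pixel shares the
#' same wavenumber axis. Missing pixels are reported by coordinate.
#'
#' @param path CSV path (as written by [write_cube()]; `#` lines are
#'   comments).
#' @param x_step,y_step Grid steps in micrometres; overridden by a
#'   [write_cube()] header when present.
#' @return A `hyperspectral_map`.
#' @export
read_cube <- function(path, x_step = 1, y_step = 1) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    mt <- regmatches(first, regexec("x_step_um=([0-9.eE+-]+); y_step_um=([0-9.eE+-]+)", first))[[1]]
    if (length(mt) == 3L) { x_step <- as.numeric(mt[2]); y_step <- as.numeric(mt[3]) }
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x", "y", "wavenumber", "intensity")
  if (!all(need %in% names(df))) {
    stop("read_cube: need columns x, y, wavenumber, intensity", call. = FALSE)
  }
  wn <- sort(unique(df$wavenumber))
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  nx <- length(xs); ny <- length(ys)
  if (!identical(as.integer(xs), seq_len(nx)) || !identical(as.integer(ys), seq_len(ny))) {
    stop("read_cube: grid indices must be 1..nx and 1..ny", call. = FALSE)
  }
  if (nrow(df) != nx * ny * length(wn)) {
    # locate a missing pixel for the error message
    have <- table(factor(paste(df$x, df$y, sep = ","),
                         levels = as.vector(outer(xs, ys, paste, sep = ","))))
    missing <- names(have)[have < length(wn)][1]
    stop(sprintf("read_cube: ragged grid; pixel (x,y) = (%s) is incomplete", missing),
         call. = FALSE)
  }
  ord <- order(df$y, df$x, df$wavenumber)
  df <- df[ord, ]
  A <- matrix(df$intensity, nrow = length(wn), ncol = nx * ny)
  hyperspectral_map(wn, A, nx, ny, x_step, y_step)
}

#' Read a numeric matrix as a height or stiffness map
#'
#' Accepts whitespace- or comma-separated numeric text, or a single-page
#' float TIFF (requires the `tiff` package). Non-numeric cells are reported
#' with their row and column.
#'
#' @param path Input file.
#' @param kind `"height"` or `"stiffness"`.
#' @param pixel_spacing Grid spacing in micrometres.
#' @return A [height_map()] or [stiffness_map()].
#' @export
read_matrix <- function(path, kind = c("height", "stiffness"), pixel_spacing = 5) {
  kind <- match.arg(kind)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("read_matrix: reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    Z <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(Z)) > 2L) stop("read_matrix: expected a single-channel TIFF", call. = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (!length(lines)) stop("read_matrix: empty file", call. = FALSE)
    sep <- if (grepl(",", lines[1])) "," else "[[:space:]]+"
    rows <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1]])
    ncols <- unique(lengths(rows))
    if (length(ncols) != 1L) stop("read_matrix: ragged rows (truncated file?)", call. = FALSE)
    Z <- matrix(NA_real_, length(rows), ncols)
    for (i in seq_along(rows)) {
      v <- suppressWarnings(as.numeric(rows[[i]]))
      bad <- which(is.na(v) & toupper(rows[[i]]) != "NA")
      if (length(bad)) {
        stop(sprintf("read_matrix: non-numeric cell at row %d, column %d ('%s')",
                     i, bad[1], rows[[i]][bad[1]]), call. = FALSE)
      }
      Z[i, ] <- v
    }
  }
  if (kind == "height") height_map(Z, pixel_spacing) else stiffness_map(Z, pixel_spacing)
}

#' Write a height/stiffness map as tab-separated text
#'
#' @param map A `height_map` or `stiffness_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(map, path) {
  Z <- if (inherits(map, "height_map")) map$Z else if (inherits(map, "stiffness_map")) map$E
  else as.matrix(map)
  utils::write.table(format(Z, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# FNV-1a hash of a string, hex-encoded (stable config fingerprints without
# external digest dependencies)
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h a double, avoiding
    # 32-bit signed overflow in bitwXor
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619; split to stay within the
    # 2^53 exact-integer range of doubles
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + (hi16 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Write an analysis report as JSON
#'
#' Embeds the package version, a fingerprint of the configuration, any
#' seeds found in the config, and warnings, alongside the result payload,
#' so a report fully identifies the run that produced it.
#'
#' @param result Named list of results (must be JSON-representable).
#' @param path Output path.
#' @param config Named list of parameters used (hashed and embedded).
#' @param warnings Character vector of warnings to record.
#' @return The report list, invisibly.
#' @export
write_report <- function(result, path, config = list(), warnings = character()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  seeds <- config[grepl("seed", names(config), ignore.case = TRUE)]
  report <- list(
    tool = "ovamat",
    version = as.character(utils::packageVersion("ovamat")),
    config = config,
    config_hash = .fnv1a(as.character(cfg_json)),
    seeds = seeds,
    warnings = warnings,
    result = result
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
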