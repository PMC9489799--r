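# Localization-table and image-stack I/O.
#
# Localization tables are plain data.frames with columns
#   frame, x, y, intensity, precision, source_id
# in nm / photons; on disk they use the de-facto SMLM reconstruction header
#   "frame,x [nm],y [nm],intensity [photon],uncertainty [nm],source_id"
# so tables exported by common reconstruction software drop in.

.loc_cols <- c("frame", "x", "y", "intensity", "precision", "source_id")
.loc_header <- "frame,x [nm],y [nm],intensity [photon],uncertainty [nm],source_id"

#' Construct a localization table
#'
#' @param frame integer frame index per localization (0-based, `< n_frames`).
#' @param x,y coordinates in nm (origin at the field-of-view lower-left
#'   corner, x rightward, y upward).
#' @param intensity fitted signal in photons.
#' @param precision localization uncertainty (sigma) in nm; must be positive.
#' @param source_id optional ground-truth aggregate id; `-1` for background
#'   or unknown, `-2` for fiducial localizations.
#' @return A data.frame with columns `frame, x, y, intensity, precision,
#'   source_id`.
#' @export
localization_table <- function(frame = integer(), x = numeric(),
                               y = numeric(), intensity = numeric(),
                               precision = numeric(),
                               source_id = rep(-1L, length(frame))) {
  tab <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                    y = as.numeric(y), intensity = as.numeric(intensity),
                    precision = as.numeric(precision),
                    source_id = as.integer(source_id))
  validate_localizations(tab)
}

#' Validate a localization table
#'
#' Checks the structural invariants: required columns present, finite
#' coordinates, non-negative frames and strictly positive precisions.
#'
#' @param table a localization data.frame.
#' @param n_frames optional number of frames; frames must lie in
#'   `[0, n_frames)` when given.
#' @return The table, invisibly unchanged.
#' @export
validate_localizations <- function(table, n_frames = NULL) {
  missing_cols <- setdiff(.loc_cols, names(table))
  if (length(missing_cols))
    stop("localization table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(table)) {
    if (any(!is.finite(table$x)) || any(!is.finite(table$y)))
      stop("localization coordinates must be finite", call. = FALSE)
    if (any(table$frame < 0))
      stop("frame indices must be >= 0", call. = FALSE)
    if (!is.null(n_frames) && any(table$frame >= n_frames))
      stop("frame indices must be < n_frames", call. = FALSE)
    bad <- which(!is.finite(table$precision) | table$precision <= 0)
    if (length(bad))
      stop("precision must be > 0 for every row (first bad row: ", bad[1L],
           ")", call. = FALSE)
  }
  table
}

#' Write a localization table to CSV
#'
#' Produces byte-deterministic output: fixed column order, fixed numeric
#' formatting (three decimals for nm and photon columns), LF line endings.
#'
#' @param table a valid localization table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  validate_localizations(table)
  lines <- .loc_header
  if (nrow(table)) {
    body <- sprintf("%d,%.3f,%.3f,%.3f,%.3f,%d",
                    as.integer(table$frame), table$x, table$y,
                    table$intensity, table$precision,
                    as.integer(table$source_id))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

.parse_numeric_column <- function(values, column, rows) {
  suppress <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(suppress) & !is.na(values) & values != "NA")
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                 values[bad[1L]], column, rows[bad[1L]]), call. = FALSE)
  suppress
}

#' Read a localization table from CSV
#'
#' Accepts the package's own dialect (nm coordinates) and a `"pixels"`
#' dialect whose x/y columns are multiplied by `pixel_size`. Recognised
#' headers for each field: `frame`; `x`/`x [nm]`/`x [px]`; the analogous y
#' names; `intensity`/`intensity [photon]`; `uncertainty [nm]`/`precision`/
#' `uncertainty`; `source_id`. Missing `intensity` is filled with `NA` and
#' flagged by a warning. A missing precision column is an error by default,
#' because precision silently defaulted would corrupt the filtering stage;
#' pass a numeric `fill_precision` (e.g. the configured maximum precision) to
#' substitute it explicitly.
#'
#' @param path CSV file path.
#' @param dialect `"nm"` (default) or `"pixels"`.
#' @param pixel_size pixel size in nm, required for the `"pixels"` dialect.
#' @param fill_precision optional numeric used when the precision column is
#'   absent; by default its absence is an error.
#' @return A localization table data.frame.
#' @export
read_localizations <- function(path, dialect = c("nm", "pixels"),
                               pixel_size = NULL, fill_precision = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  stringsAsFactors = FALSE)
  nm <- tolower(trimws(names(raw)))
  find_col <- function(aliases) {
    hit <- which(nm %in% aliases)
    if (length(hit)) hit[1L] else NA_integer_
  }
  idx <- c(frame = find_col("frame"),
           x = find_col(c("x", "x [nm]", "x [px]", "x_nm")),
           y = find_col(c("y", "y [nm]", "y [px]", "y_nm")),
           intensity = find_col(c("intensity", "intensity [photon]",
                                  "photons", "signal")),
           precision = find_col(c("uncertainty [nm]", "uncertainty",
                                  "precision", "precision [nm]")),
           source_id = find_col("source_id"))
  for (req in c("frame", "x", "y"))
    if (is.na(idx[[req]]))
      stop("localization file lacks mandatory column '", req, "'",
           call. = FALSE)
  n <- nrow(raw)
  rows <- seq_len(n)
  grab <- function(key) .parse_numeric_column(raw[[idx[[key]]]], key, rows)
  tab <- data.frame(frame = as.integer(grab("frame")),
                    x = grab("x"), y = grab("y"))
  if (dialect == "pixels") {
    if (is.null(pixel_size))
      stop("dialect 'pixels' requires pixel_size", call. = FALSE)
    tab$x <- tab$x * pixel_size
    tab$y <- tab$y * pixel_size
  }
  if (is.na(idx[["intensity"]])) {
    warning("intensity column absent; filled with NA", call. = FALSE)
    tab$intensity <- NA_real_
  } else tab$intensity <- grab("intensity")
  if (is.na(idx[["precision"]])) {
    if (is.null(fill_precision))
      stop("precision column absent; pass fill_precision to substitute a ",
           "value explicitly", call. = FALSE)
    warning("precision column absent; filled with ", fill_precision,
            " nm", call. = FALSE)
    tab$precision <- as.numeric(fill_precision)
  } else tab$precision <- grab("precision")
  tab$source_id <- if (is.na(idx[["source_id"]])) -1L else
    as.integer(grab("source_id"))
  validate_localizations(tab)
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' @param stack a numeric array `[ny, nx, n_frames]` (or a matrix for a
#'   single frame) of photon/ADU counts in `[0, 65535]`.
#' @param path output TIFF path.
#' @return `path`, invisibly. Values outside the 16-bit range are clipped
#'   with a warning.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  if (any(stack < 0 | stack > 65535)) {
    warning("stack values clipped to the 16-bit range", call. = FALSE)
    stack <- pmin(pmax(stack, 0), 65535)
  }
  pages <- lapply(seq_len(dim(stack)[3L]),
                  function(f) round(stack[, , f]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file path.
#' @return A numeric array `[ny, nx, n_frames]` of integer counts.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale channels
    p
  })
  array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}
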