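# Readers/writers for the delimited formats shared by all pipeline stages.
# All persisted coordinates and distances are nanometres.

#' Construct a localisation table
#'
#' A localisation table is the point-cloud container used throughout the
#' package: one row per detected fluorophore with planar coordinates in
#' nanometres, a mark (channel) label, and an optional region-of-interest
#' identifier grouping localisations that belong to the same fibre.
#'
#' @param x,y Numeric coordinates in nm. Must be finite.
#' @param mark Character vector of mark/class labels (e.g. `"H3K27me3"`,
#'   `"H3K36me3"`, `"histone"`, `"RPolPser2"`). Must be non-empty strings.
#' @param roi Optional ROI identifiers; `NA` means "no ROI", in which case
#'   all localisations are treated as one group.
#' @return A data frame of class `localisation_table` with columns
#'   `x`, `y`, `mark`, `roi`.
#' @export
localisation_table <- function(x, y, mark, roi = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  mark <- as.character(mark)
  n <- length(x)
  if (length(y) != n || length(mark) != n)
    stop("x, y and mark must have equal length")
  if (n > 0L && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("localisation coordinates must be finite")
  if (n > 0L && any(is.na(mark) | !nzchar(mark)))
    stop("mark labels must be non-empty")
  if (is.null(roi)) roi <- rep(NA_character_, n)
  roi <- as.character(roi)
  if (length(roi) != n) stop("roi must match the number of localisations")
  out <- data.frame(x = x, y = y, mark = mark, roi = roi,
                    stringsAsFactors = FALSE)
  class(out) <- c("localisation_table", "data.frame")
  attr(out, "units") <- "nm"
  out
}

#' @export
print.localisation_table <- function(x, ...) {
  cat(sprintf("Localisation table: %d localisations, %d mark(s)%s [nm]\n",
              nrow(x), length(unique(x$mark)),
              if (all(is.na(x$roi))) "" else
                sprintf(", %d ROI(s)", length(unique(x$roi)))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# Split row indices by ROI; a table with no ROI labels is one group.
roi_groups <- function(table) {
  if (all(is.na(table$roi))) return(list("<all>" = seq_len(nrow(table))))
  split(seq_len(nrow(table)), table$roi)
}

#' Read a localisation table from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row. Default column
#' names are `x[nm]`, `y[nm]`, `mark`, `roi`; `column_map` adapts other
#' conventions (e.g. ThunderSTORM exports). Extra columns (z, frame,
#' photons, ...) are ignored. Rows whose coordinates are not finite are
#' dropped with a message reporting the count.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector mapping the canonical names
#'   `x`, `y`, `mark`, `roi` to the column names used in the file, e.g.
#'   `c(x = "x [nm]", y = "y [nm]", mark = "channel")`. Unmapped names use
#'   the defaults.
#' @param unit_scale Factor multiplying the file's coordinates into nm
#'   (e.g. 1000 for coordinates stored in micrometres).
#' @return A [localisation_table()].
#' @export
read_localisations <- function(path, column_map = NULL, unit_scale = 1) {
  stopifnot(is.numeric(unit_scale), length(unit_scale) == 1L, unit_scale > 0)
  raw <- read_delimited(path)
  cols <- c(x = "x[nm]", y = "y[nm]", mark = "mark", roi = "roi")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad)) stop("unknown column_map entries: ",
                          paste(bad, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  for (nm in c("x", "y", "mark")) {
    if (!cols[[nm]] %in% names(raw))
      stop(sprintf("column '%s' (mapped from '%s') not found in %s",
                   cols[[nm]], nm, path))
  }
  x <- suppressWarnings(as.numeric(raw[[cols[["x"]]]])) * unit_scale
  y <- suppressWarnings(as.numeric(raw[[cols[["y"]]]])) * unit_scale
  mark <- as.character(raw[[cols[["mark"]]]])
  roi <- if (cols[["roi"]] %in% names(raw))
    as.character(raw[[cols[["roi"]]]]) else rep(NA_character_, nrow(raw))
  keep <- is.finite(x) & is.finite(y) & !is.na(mark) & nzchar(mark)
  n_rejected <- sum(!keep)
  if (n_rejected > 0L)
    message(sprintf("read_localisations: rejected %d row(s) with non-finite coordinates or empty marks",
                    n_rejected))
  if (!any(keep)) stop("no parsable localisation rows in ", path)
  out <- localisation_table(x[keep], y[keep], mark[keep], roi[keep])
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a localisation table
#'
#' @param table A [localisation_table()].
#' @param path Output file path (CSV with the default header
#'   `x[nm],y[nm],mark,roi`).
#' @export
write_localisations <- function(table, path) {
  stopifnot(inherits(table, "localisation_table"))
  df <- data.frame(`x[nm]` = format_full(table$x),
                   `y[nm]` = format_full(table$y),
                   mark = table$mark, roi = table$roi,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a polyline ROI
#'
#' A polyline ROI is an ordered open polygonal chain traced along a fibre,
#' used to extract intensity profiles and to group localisations.
#'
#' @param roi_id Identifier.
#' @param vertices Two-column matrix (x, y in nm), at least 2 rows,
#'   consecutive vertices distinct.
#' @return An object of class `polyline_roi` with fields `roi_id`,
#'   `vertices` and `arc_length` (nm).
#' @export
polyline_roi <- function(roi_id, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L)
    stop("vertices must be a two-column (x, y) matrix")
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 2L)
    stop(sprintf("ROI '%s' has fewer than 2 vertices", roi_id))
  if (!all(is.finite(vertices)))
    stop(sprintf("ROI '%s' has non-finite vertices", roi_id))
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (any(seg == 0))
    stop(sprintf("ROI '%s' has identical consecutive vertices", roi_id))
  structure(list(roi_id = as.character(roi_id), vertices = vertices,
                 arc_length = sum(seg)),
            class = "polyline_roi")
}

#' Total arc length of a polyline ROI in nm
#' @param roi A [polyline_roi()].
#' @export
arc_length <- function(roi) {
  stopifnot(inherits(roi, "polyline_roi"))
  roi$arc_length
}

#' Read polyline ROIs from CSV
#'
#' Expects columns `roi`, `x_nm`, `y_nm`; consecutive rows sharing a `roi`
#' value form that ROI's ordered vertex list.
#'
#' @param path CSV file path.
#' @return Named list of [polyline_roi()] objects.
#' @export
read_polyline_rois <- function(path) {
  raw <- read_delimited(path)
  need <- c("roi", "x_nm", "y_nm")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("ROI file missing column(s): ",
                         paste(miss, collapse = ", "))
  ids <- unique(as.character(raw$roi))
  out <- lapply(ids, function(id) {
    rows <- raw[as.character(raw$roi) == id, , drop = FALSE]
    polyline_roi(id, cbind(as.numeric(rows$x_nm), as.numeric(rows$y_nm)))
  })
  names(out) <- ids
  out
}

#' Write polyline ROIs to CSV
#' @param rois List of [polyline_roi()] objects.
#' @param path Output path.
#' @export
write_polyline_rois <- function(rois, path) {
  if (inherits(rois, "polyline_roi")) rois <- list(rois)
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(roi = r$roi_id, x_nm = format_full(r$vertices[, 1]),
               y_nm = format_full(r$vertices[, 2]),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a paired-channel intensity profile
#'
#' Holds two intensity series sampled at a uniform arc-length step along
#' one fibre ROI: `channel_a` conventionally the pan-histone (chromatin)
#' channel and `channel_b` the histone-mark channel.
#'
#' @param roi_id Identifier.
#' @param step Arc-length sampling interval in nm (> 0).
#' @param channel_a,channel_b Equal-length non-negative intensity vectors
#'   (length >= 2).
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(roi_id, step, channel_a, channel_b) {
  step <- as.numeric(step)
  channel_a <- as.numeric(channel_a)
  channel_b <- as.numeric(channel_b)
  if (!is.finite(step) || step <= 0) stop("step must be > 0")
  n <- length(channel_a)
  if (length(channel_b) != n)
    stop("channel_a and channel_b must have equal length")
  if (n < 2L) stop("profiles need at least 2 samples")
  if (!all(is.finite(channel_a)) || !all(is.finite(channel_b)))
    stop("intensities must be finite")
  structure(list(roi_id = as.character(roi_id), step = step,
                 channel_a = channel_a, channel_b = channel_b, n = n),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile '%s': %d samples at %g nm (%g nm span)\n",
              x$roi_id, x$n, x$step, (x$n - 1) * x$step))
  invisible(x)
}

#' Read paired-channel profiles from CSV
#'
#' Expects columns `position_nm`, `channel_a`, `channel_b` and optionally
#' `roi` (one profile per distinct `roi` value). Positions must be
#' uniformly spaced within each profile.
#'
#' @param path CSV file path.
#' @return Named list of [intensity_profile()] objects.
#' @export
read_profiles <- function(path) {
  raw <- read_delimited(path)
  need <- c("position_nm", "channel_a", "channel_b")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("profile file missing column(s): ",
                         paste(miss, collapse = ", "))
  ids <- if ("roi" %in% names(raw)) unique(as.character(raw$roi)) else "profile1"
  out <- lapply(ids, function(id) {
    rows <- if ("roi" %in% names(raw))
      raw[as.character(raw$roi) == id, , drop = FALSE] else raw
    pos <- as.numeric(rows$position_nm)
    steps <- diff(pos)
    if (length(steps) < 1L) stop("profile '", id, "' has fewer than 2 samples")
    if (max(abs(steps - steps[1])) > 1e-6 * steps[1])
      stop("profile '", id, "' is not uniformly sampled")
    intensity_profile(id, steps[1], as.numeric(rows$channel_a),
                      as.numeric(rows$channel_b))
  })
  names(out) <- ids
  out
}

#' Write paired-channel profiles to CSV
#' @param profiles List of [intensity_profile()] (or one).
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "intensity_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(roi = p$roi_id,
               position_nm = format_full((seq_len(p$n) - 1) * p$step),
               channel_a = format_full(p$channel_a),
               channel_b = format_full(p$channel_b),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Generic result serialisation: '#'-prefixed "key = value" metadata lines
# followed by one CSV table. Numbers are written at 17 significant digits so
# read-back reproduces values exactly.

#' Write a stage result to structured text
#'
#' Every analysis result in the package (cluster sets, mark connection
#' functions, overlap results, knn results, ...) serialises to the same
#' structured-text layout: comment lines `# key = value` holding scalar
#' metadata, then a CSV table. [read_results()] parses it back; numeric
#' values round-trip exactly.
#'
#' @param result A stage result object (see methods list) or a plain list
#'   with elements `meta` (named scalars) and `table` (data frame).
#' @param path Output file path.
#' @export
write_results <- function(result, path) UseMethod("write_results")

#' @export
write_results.default <- function(result, path) {
  if (is.list(result) && !is.null(result$meta)) {
    write_sections(result$meta, result$table, class(result)[1], path)
  } else stop("no write_results method for class ",
              paste(class(result), collapse = "/"))
  invisible(path)
}

#' Read back a result written by [write_results()]
#' @param path File path.
#' @return List with `type`, `meta` (named list, numerics restored) and
#'   `table` (data frame).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  body <- lines[!grepl("^# ", lines)]
  meta <- list()
  type <- NA_character_
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(val))
    if (key == "type") type <- val
    else meta[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eEInfNa]+$", val)) num else val
  }
  tab <- if (length(body) > 1L)
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
  else NULL
  list(type = type, meta = meta, table = tab)
}

write_sections <- function(meta, table, type, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# type = %s", type), con)
  for (key in names(meta)) {
    val <- meta[[key]]
    val <- if (is.numeric(val)) format_full(val) else as.character(val)
    writeLines(sprintf("# %s = %s", key, val), con)
  }
  if (!is.null(table) && nrow(table) > 0L) {
    num <- vapply(table, is.numeric, logical(1))
    table[num] <- lapply(table[num], format_full)
    utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  } else if (!is.null(table)) {
    writeLines(paste(names(table), collapse = ","), con)
  }
  invisible(path)
}

format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

# Delimiter sniffing: comma unless the header has tabs.
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
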