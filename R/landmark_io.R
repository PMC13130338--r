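# Landmark data model and file I/O (tpsDig TPS dialect, long-format CSV).

#' Construct a single-specimen landmark configuration
#'
#' A configuration is a `k x 2` matrix of planar landmark coordinates with a
#' specimen identifier. If a digitizing scale (mm/pixel) is known the stored
#' coordinates are *post-scale*, i.e. already multiplied by it.
#'
#' @param coords Numeric `k x 2` matrix, `k >= 3`, all values finite.
#' @param specimen_id Character scalar label.
#' @param scale Optional positive scalar recording the mm/pixel factor that
#'   has already been applied to `coords`.
#' @return An object of class `landmark_config`: the coordinate matrix with
#'   attributes `specimen_id` and `scale`.
#' @examples
#' cfg <- landmark_config(cbind(c(0, 1, 0), c(0, 0, 1)), "spec1")
#' centroid_size(cfg)
#' @export
landmark_config <- function(coords, specimen_id = "0", scale = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop("'coords' must be a numeric k x 2 matrix")
  if (nrow(coords) < 3L)
    stop("a landmark configuration needs at least 3 landmarks, got ", nrow(coords))
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in configuration '", specimen_id,
         "'; missing landmarks are not supported")
  if (!is.null(scale)) {
    scale <- as.numeric(scale)
    if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
      stop("'scale' must be a positive scalar")
  }
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(coords,
            specimen_id = as.character(specimen_id)[1L],
            scale = scale,
            class = c("landmark_config", "matrix", "array"))
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> specimen '", attr(x, "specimen_id"), "', k = ",
      nrow(x), "\n", sep = "")
  print(unclass(structure(x, specimen_id = NULL, scale = NULL)), ...)
  invisible(x)
}

#' Construct a sample (group) of landmark configurations
#'
#' @param configurations List of [landmark_config] objects (or bare `k x 2`
#'   matrices, which are promoted with index-derived ids). All must share the
#'   same landmark count; specimen ids must be unique.
#' @param group_label Character scalar naming the group.
#' @return An object of class `landmark_sample`: a list with elements
#'   `group_label` and `configurations`.
#' @export
landmark_sample <- function(configurations, group_label = "group") {
  if (!is.list(configurations) || length(configurations) == 0L)
    stop("'configurations' must be a non-empty list")
  configurations <- lapply(seq_along(configurations), function(i) {
    cf <- configurations[[i]]
    if (inherits(cf, "landmark_config")) cf
    else landmark_config(cf, specimen_id = as.character(i - 1L))
  })
  ks <- vapply(configurations, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("configurations have differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  ids <- vapply(configurations, function(cf) attr(cf, "specimen_id"), character(1))
  if (anyDuplicated(ids))
    stop("duplicated specimen ids within sample: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(group_label = as.character(group_label)[1L],
                 configurations = configurations),
            class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  cat("<landmark_sample> group '", x$group_label, "': n = ",
      length(x$configurations), " specimens, k = ",
      nrow(x$configurations[[1L]]), " landmarks\n", sep = "")
  invisible(x)
}

#' @export
length.landmark_sample <- function(x) length(x$configurations)

#' Stack a landmark sample into a k x 2 x n array
#'
#' @param sample A [landmark_sample].
#' @return Numeric array with specimen ids as the third dimnames.
#' @export
sample_array <- function(sample) {
  stopifnot(inherits(sample, "landmark_sample"))
  cfs <- sample$configurations
  k <- nrow(cfs[[1L]])
  arr <- array(unlist(lapply(cfs, function(m) as.numeric(unclass(m)))),
               dim = c(k, 2L, length(cfs)))
  dimnames(arr) <- list(NULL, c("x", "y"),
                        vapply(cfs, function(cf) attr(cf, "specimen_id"),
                               character(1)))
  arr
}

#' Specimen identifiers of a sample
#' @param sample A [landmark_sample].
#' @return Character vector of ids, in sample order.
#' @export
specimen_ids <- function(sample) {
  vapply(sample$configurations, function(cf) attr(cf, "specimen_id"), character(1))
}

# Known tpsDig record keys handled by the reader; other KEY=value lines are
# ignored with a warning (tpsDig emits several optional keys).
.tps_known_keys <- c("IMAGE", "ID", "SCALE")

#' Read landmark data in the tpsDig TPS text format
#'
#' Parses records of the form `LM=<k>` followed by `k` lines of two
#' whitespace-separated reals, then optional `IMAGE=`, `ID=` and `SCALE=`
#' lines. When `SCALE=` is present the record's coordinates are multiplied by
#' it (pixel -> mm). `ID=` becomes the specimen id; records without one get
#' their 0-based record index as id. Unknown `KEY=value` lines are skipped
#' with a warning. Coordinates are taken exactly as stored: no y-axis flip is
#' applied, since any fixed flip common to all specimens cancels in the
#' similarity-invariant analysis.
#'
#' @param path Path to a TPS text file.
#' @param group_label Group label for the returned sample; defaults to the
#'   file name without extension.
#' @return A [landmark_sample].
#' @export
read_tps <- function(path, group_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(group_label))
    group_label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  record <- 0L
  unknown <- character(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected 'LM=<k>', got '", ln, "'")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("TPS parse error at line ", i, ": bad landmark count in '", ln, "'")
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^[A-Za-z]+\\s*=", trimws(lines[i])))
        stop("TPS parse error in record ", record,
             ": found ", j - 1L, " of ", k, " declared coordinate lines")
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals))
        stop("TPS parse error at line ", i, ": non-numeric or malformed ",
             "coordinate line '", trimws(lines[i]), "'")
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- as.character(record)
    scale <- NULL
    while (i <= length(lines) && grepl("^[A-Za-z]+\\s*=", trimws(lines[i])) &&
           !grepl("^LM\\s*=", trimws(lines[i]), ignore.case = TRUE)) {
      kv <- trimws(lines[i])
      key <- toupper(sub("\\s*=.*$", "", kv))
      val <- sub("^[A-Za-z]+\\s*=\\s*", "", kv)
      if (key == "ID") id <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0)
          stop("TPS parse error at line ", i, ": bad SCALE '", val, "'")
      } else if (key != "IMAGE") unknown <- c(unknown, key)
      i <- i + 1L
    }
    if (!is.null(scale)) coords <- coords * scale
    configs[[length(configs) + 1L]] <- landmark_config(coords, id, scale)
    record <- record + 1L
  }
  if (length(unknown))
    warning("ignored unknown TPS keys: ", paste(unique(unknown), collapse = ", "))
  if (length(configs) == 0L) stop("no TPS records found in ", path)
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("TPS records have differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  landmark_sample(configs, group_label)
}

#' Write a landmark sample in TPS format
#'
#' Emits one `LM=` record per specimen with coordinates at full precision
#' (15 significant digits), an `ID=` line, and a `SCALE=` line when the
#' configuration carries one (coordinates are written post-scale, so a
#' round-trip through [read_tps] does not rescale: SCALE is recorded as 1
#' on write to keep the file self-consistent).
#'
#' @param sample A [landmark_sample].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(sample, path) {
  stopifnot(inherits(sample, "landmark_sample"))
  out <- character(0)
  for (cf in sample$configurations) {
    out <- c(out,
             sprintf("LM=%d", nrow(cf)),
             sprintf("%.15g %.15g", cf[, 1L], cf[, 2L]),
             sprintf("ID=%s", attr(cf, "specimen_id")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read landmarks from a long-format CSV
#'
#' Expects columns `specimen_id`, `landmark_index` (1-based), `x`, `y`. Rows
#' are grouped by specimen and ordered by landmark index `1..k`; every
#' specimen must supply every index exactly once.
#'
#' @param path CSV file path.
#' @param group_label Group label; defaults to the file name.
#' @return A [landmark_sample].
#' @export
read_csv_landmarks <- function(path, group_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(group_label))
    group_label <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  df$specimen_id <- as.character(df$specimen_id)
  k <- max(df$landmark_index)
  ids <- unique(df$specimen_id)  # file order
  configs <- lapply(ids, function(id) {
    rows <- df[df$specimen_id == id, ]
    if (anyDuplicated(rows$landmark_index))
      stop("duplicate (specimen, landmark_index) row for specimen '", id,
           "', index ", rows$landmark_index[duplicated(rows$landmark_index)][1L])
    missing <- setdiff(seq_len(k), rows$landmark_index)
    if (length(missing))
      stop("specimen '", id, "' is missing landmark index ",
           paste(missing, collapse = ", "))
    rows <- rows[order(rows$landmark_index), ]
    landmark_config(cbind(rows$x, rows$y), id)
  })
  landmark_sample(configs, group_label)
}

#' Write a landmark sample as long-format CSV
#'
#' @param sample A [landmark_sample].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_csv_landmarks <- function(sample, path) {
  stopifnot(inherits(sample, "landmark_sample"))
  k <- nrow(sample$configurations[[1L]])
  df <- do.call(rbind, lapply(sample$configurations, function(cf) {
    data.frame(specimen_id = attr(cf, "specimen_id"),
               landmark_index = seq_len(k),
               x = cf[, 1L], y = cf[, 2L])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
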