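# Plain-text I/O: ESRI ASCII grids for raster layers (with a code<->label
# sidecar CSV for categorical layers), CSV score tables, JSON weights and
# reports, YAML pipeline configuration. All round-trips are exact.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA
  out
}

write_asc <- function(values, path, cell_size, nodata = -9999) {
  stopifnot(is.matrix(values))
  vals <- values
  vals[is.na(vals)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", fmt_num(cell_size)),
    sprintf("NODATA_value %s", fmt_num(nodata))
  )
  body <- apply(vals, 1, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("Malformed ASCII grid ", path, ": expected ", nr * nc,
         " values, found ", length(vals), ".", call. = FALSE)
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, cell_size = as.numeric(kv[["cellsize"]]))
}

#' Write / read a continuous ES layer as an ASCII grid
#'
#' The grid body is the ESRI ASCII raster format; ES id, epoch and the
#' normalized flag ride in the file name convention chosen by the caller and
#' are re-supplied on read.
#'
#' @param layer An [es_layer()].
#' @param path Output `.asc` path.
#' @return The path (write) or an [es_layer()] (read), invisibly for write.
#' @export
write_es_layer <- function(layer, path) {
  stopifnot(inherits(layer, "es_layer"))
  write_asc(layer$values, path, layer$cell_size)
}

#' @rdname write_es_layer
#' @param es_id,epoch,normalized Metadata to attach on read.
#' @export
read_es_layer <- function(path, es_id, epoch, normalized = TRUE) {
  g <- read_asc(path)
  es_layer(g$values, es_id, epoch, g$cell_size, normalized = normalized)
}

#' Write / read a categorical land-cover layer
#'
#' The grid stores integer class ids; the sidecar CSV (`<path>.classes.csv`)
#' maps ids to CORINE-style class codes and labels, since raster bands are
#' numeric.
#'
#' @param layer An [lc_layer()].
#' @param path Output `.asc` path.
#' @param labels Optional tibble `class_code`, `label` for the sidecar.
#' @return The path (write) or an [lc_layer()] (read).
#' @export
write_lc_layer <- function(layer, path, labels = NULL) {
  stopifnot(inherits(layer, "lc_layer"))
  codes <- sort(unique(layer$values[!is.na(layer$values)]))
  ids <- matrix(match(layer$values, codes), nrow(layer$values))
  write_asc(ids, path, layer$cell_size)
  side <- tibble::tibble(code_id = seq_along(codes), class_code = codes)
  if (!is.null(labels)) side <- dplyr::left_join(side, labels, by = "class_code")
  readr::write_csv(side, paste0(path, ".classes.csv"))
  invisible(path)
}

#' @rdname write_lc_layer
#' @param epoch Epoch label to attach on read.
#' @export
read_lc_layer <- function(path, epoch) {
  g <- read_asc(path)
  side <- readr::read_csv(paste0(path, ".classes.csv"),
                          show_col_types = FALSE,
                          col_types = readr::cols(class_code = "c"))
  codes <- stats::setNames(side$class_code, side$code_id)
  vals <- matrix(codes[as.character(g$values)], nrow(g$values))
  lc_layer(vals, epoch, g$cell_size)
}

#' Write / read a zone map
#' @param zones A [zone_map()].
#' @param path Output `.asc` path.
#' @return The path (write) or a [zone_map()] (read).
#' @export
write_zone_map <- function(zones, path) {
  stopifnot(inherits(zones, "zone_map"))
  write_asc(zones$values, path, zones$cell_size)
}

#' @rdname write_zone_map
#' @export
read_zone_map <- function(path) {
  g <- read_asc(path)
  zone_map(g$values, g$cell_size)
}

check_table <- function(df, path, cols, score_range, id_col = "es_id",
                        id_set = es_ids()) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("Malformed table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_id <- which(!(df[[id_col]] %in% id_set))
  if (length(bad_id)) {
    stop("Unknown ", id_col, " '", df[[id_col]][bad_id[1]], "' in ", path,
         " at row ", bad_id[1], ".", call. = FALSE)
  }
  bad <- which(df$score < score_range[1] | df$score > score_range[2] |
                 df$score != round(df$score))
  if (length(bad)) {
    stop("Score out of range [", score_range[1], ", ", score_range[2],
         "] in ", path, " at row ", bad[1], ".", call. = FALSE)
  }
  invisible(df)
}

#' Read stakeholder importance scores from CSV
#'
#' Long format `stakeholder,es_id,score` with integer scores on the 0-9
#' importance scale; unknown ES ids and out-of-range scores are rejected with
#' the offending row number.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_importance_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_table(df, path, c("stakeholder", "es_id", "score"), c(0, 9))
}

#' Read stakeholder capacity scores from CSV
#'
#' Long format `stakeholder,class_code,es_id,score` with integer scores on
#' the 0-5 capacity scale.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_capacity_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(class_code = "c"))
  check_table(df, path, c("stakeholder", "class_code", "es_id", "score"), c(0, 5))
}

#' Write / read AHP weights as JSON
#'
#' @param weights An `ahp_weights` object or a tibble `es_id`, `weight`.
#' @param path JSON path.
#' @return The path (write) or an `ahp_weights`-like tibble (read).
#' @export
write_weights_json <- function(weights, path) {
  payload <- list(
    weights = purrr::map2(weights$es_id, weights$weight,
                          function(id, w) list(es_id = id, weight = w)),
    lambda_max = attr(weights, "lambda_max"),
    consistency_ratio = attr(weights, "consistency_ratio")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- tibble::tibble(
    es_id = vapply(p$weights, `[[`, "", "es_id"),
    weight = vapply(p$weights, `[[`, 0, "weight")
  )
  attr(out, "lambda_max") <- p$lambda_max
  attr(out, "consistency_ratio") <- p$consistency_ratio
  class(out) <- c("ahp_weights", class(out))
  out
}
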