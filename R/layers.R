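#' Ecosystem-service indicator identifiers
#'
#' The eight ES indicators handled by the package: climate regulation (CR),
#' water purification (WP), habitat quality (HQ), drought regulation (DR),
#' recreation (R), food provisioning (FP), erosion prevention (EP) and
#' pollination (P).
#'
#' @return Character vector of the eight ES ids.
#' @export
#' @examples
#' es_ids()
es_ids <- function() {
  c("CR", "WP", "HQ", "DR", "R", "FP", "EP", "P")
}

#' Long-form labels for the ES ids
#' @return Named character vector mapping ES id to label.
#' @export
es_labels <- function() {
  c(
    CR = "climate regulation", WP = "water purification",
    HQ = "habitat quality", DR = "drought regulation",
    R = "recreation", FP = "food provisioning",
    EP = "erosion prevention", P = "pollination"
  )
}

# ---- grid layer constructors -------------------------------------------------

new_grid_layer <- function(values, cell_size, class, extra = list()) {
  stopifnot(is.matrix(values), nrow(values) > 0, ncol(values) > 0)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres).", call. = FALSE)
  }
  structure(
    c(list(values = values, cell_size = as.numeric(cell_size)), extra),
    class = c(class, "asebio_grid")
  )
}

#' Categorical land-cover layer
#'
#' A grid of land-cover class codes (CORINE level-3 style strings such as
#' `"3.2.2"`) for one epoch. `NA` cells are nodata and are honoured by every
#' downstream operation.
#'
#' @param values Character matrix of class codes; `NA` marks nodata.
#' @param epoch Epoch label (e.g. `"1990"`).
#' @param cell_size Cell size in metres (default 100).
#' @return An object of class `lc_layer`.
#' @export
lc_layer <- function(values, epoch, cell_size = 100) {
  if (!is.character(values)) storage.mode(values) <- "character"
  new_grid_layer(values, cell_size, "lc_layer",
                 list(epoch = as.character(epoch)))
}

#' Continuous ES potential layer
#'
#' A grid holding one ES indicator for one epoch, either in raw biophysical
#' units or normalized to the common \[0, 1\] potential scale.
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param es_id One of [es_ids()].
#' @param epoch Epoch label.
#' @param cell_size Cell size in metres.
#' @param normalized Logical; `TRUE` once values are on the \[0, 1\] scale.
#' @return An object of class `es_layer`.
#' @export
es_layer <- function(values, es_id, epoch, cell_size = 100, normalized = FALSE) {
  es_id <- match.arg(es_id, es_ids())
  storage.mode(values) <- "double"
  if (isTRUE(normalized)) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9)) {
      stop("Normalized ES layer for ", es_id, " has values outside [0, 1].",
           call. = FALSE)
    }
  }
  new_grid_layer(values, cell_size, "es_layer",
                 list(es_id = es_id, epoch = as.character(epoch),
                      normalized = isTRUE(normalized)))
}

#' Composite index layer
#'
#' Grid of weighted-overlay index values for one epoch, together with the
#' weight vector used to build it.
#'
#' @param values Numeric matrix in \[0, 1\]; `NA` marks nodata.
#' @param epoch Epoch label.
#' @param weights The weight tibble used (es_id, weight), kept for provenance.
#' @param cell_size Cell size in metres.
#' @return An object of class `index_layer`.
#' @export
index_layer <- function(values, epoch, weights = NULL, cell_size = 100) {
  storage.mode(values) <- "double"
  new_grid_layer(values, cell_size, "index_layer",
                 list(epoch = as.character(epoch), weights = weights))
}

#' Zone map
#'
#' Integer zone ids per pixel (NUTS-3 analogue); valid pixels are partitioned
#' into contiguous zones, `NA` is nodata.
#'
#' @param values Integer matrix of zone ids.
#' @param cell_size Cell size in metres.
#' @return An object of class `zone_map`.
#' @export
zone_map <- function(values, cell_size = 100) {
  storage.mode(values) <- "integer"
  new_grid_layer(values, cell_size, "zone_map", list())
}

# ---- shared helpers ----------------------------------------------------------

#' @export
dim.asebio_grid <- function(x) dim(x$values)

grid_mask <- function(x) !is.na(x$values)

check_aligned <- function(a, b, what = "layers") {
  if (!identical(dim(a$values), dim(b$values))) {
    stop(sprintf("Misaligned %s: grids are %s vs %s.", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")), call. = FALSE)
  }
  if (!isTRUE(all.equal(a$cell_size, b$cell_size))) {
    stop(sprintf("Misaligned %s: cell sizes differ (%g vs %g).", what,
                 a$cell_size, b$cell_size), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.asebio_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d cells (%g m)", class(x)[1], d[1], d[2], x$cell_size))
  if (!is.null(x$es_id)) cat(", es_id:", x$es_id)
  if (!is.null(x$epoch)) cat(", epoch:", x$epoch)
  if (isTRUE(x$normalized)) cat(", normalized")
  cat(sprintf("\n  valid: %d / %d cells\n", sum(grid_mask(x)), length(x$values)))
  invisible(x)
}

#' Long tibble view of a grid layer
#'
#' @param x A grid layer (`lc_layer`, `es_layer`, `index_layer` or `zone_map`).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value` plus any layer metadata
#'   (`es_id`, `epoch`); nodata cells are kept as `NA` so the grid round-trips.
#' @exportS3Method tibble::as_tibble
as_tibble.asebio_grid <- function(x, ...) {
  d <- dim(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values)
  )
  if (!is.null(x$es_id)) out$es_id <- x$es_id
  if (!is.null(x$epoch)) out$epoch <- x$epoch
  out
}

# pooled vector of valid values
valid_values <- function(x) x$values[grid_mask(x)]
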