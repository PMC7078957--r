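#' Expression matrix container
#'
#' A light container for single-cell cytometry intensities: a cells x
#' channels numeric matrix plus the channel metadata needed throughout the
#' normalization pipeline. A whole-matrix `transform_state` flag records
#' whether values are on the raw instrument scale (`"raw"`) or have been
#' arcsinh-transformed (`"arcsinh"`); all modeling operates on the arcsinh
#' scale while FCS files are written on the raw scale.
#'
#' @param values Numeric matrix, one row per cell, one column per channel.
#'   No missing or non-finite entries are allowed.
#' @param channel_ids Character vector of unique detector names ($PnN),
#'   one per column.
#' @param marker_names Character vector of human-readable marker names
#'   ($PnS), parallel to `channel_ids`. Defaults to `channel_ids`.
#' @param transform_state Either `"raw"` or `"arcsinh"`.
#' @param source_file Path of the originating FCS file, or a synthetic tag.
#' @param keywords Optional named list of FCS keywords carried from a read.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, channel_ids, marker_names = channel_ids,
                        transform_state = c("raw", "arcsinh"),
                        source_file = NA_character_, keywords = list()) {
  transform_state <- match.arg(transform_state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  channel_ids <- as.character(channel_ids)
  marker_names <- as.character(marker_names)
  if (ncol(values) != length(channel_ids))
    stop2("`values` must have one column per channel id (",
          ncol(values), " columns vs ", length(channel_ids), " ids)")
  if (length(marker_names) != length(channel_ids))
    stop2("`marker_names` must be parallel to `channel_ids`")
  if (anyDuplicated(channel_ids))
    stop2("channel ids must be unique")
  if (nrow(values) > 0 && !all(is.finite(values)))
    stop2("`values` contains missing or non-finite entries")
  colnames(values) <- channel_ids
  structure(
    list(values = values,
         channel_ids = channel_ids,
         marker_names = marker_names,
         transform_state = transform_state,
         source_file = source_file,
         keywords = keywords),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " channels [", x$transform_state, "]\n", sep = "")
  show <- paste0(x$channel_ids,
                 ifelse(x$marker_names != x$channel_ids,
                        paste0(" (", x$marker_names, ")"), ""))
  cat("  channels: ", paste(utils::head(show, 8), collapse = ", "),
      if (length(show) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Number of cells in an expression matrix
#' @param x An `expr_matrix`.
#' @return Integer cell count.
#' @export
n_cells <- function(x) nrow(x$values)

# Resolve marker names or channel ids to column indices.
# Marker names take precedence; unmatched names fall back to channel ids.
match_channels <- function(x, markers) {
  idx <- match(markers, x$marker_names)
  miss <- is.na(idx)
  idx[miss] <- match(markers[miss], x$channel_ids)
  if (anyNA(idx))
    stop2("markers not present in matrix: ",
          paste(markers[is.na(idx)], collapse = ", "))
  idx
}

# Stack several expr_matrix objects sharing a channel layout.
rbind_expr <- function(mats) {
  stopifnot(length(mats) >= 1)
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(m$channel_ids, ref$channel_ids))
      stop2("cannot combine matrices with different channel layouts")
    if (!identical(m$transform_state, ref$transform_state))
      stop2("cannot combine matrices with different transform states")
  }
  expr_matrix(do.call(rbind, lapply(mats, function(m) m$values)),
              ref$channel_ids, ref$marker_names, ref$transform_state,
              source_file = "aggregate")
}

#' Arcsinh transform specification
#'
#' The variance-stabilizing transform used throughout cytometry:
#' `asinh(x / cofactor)`. A cofactor of 5 is the standard choice for mass
#' cytometry. Channels not listed in `channels` (for example `Time` or
#' `Event_length`) pass through every pipeline stage unchanged.
#'
#' @param cofactor Positive scale divisor; default 5.
#' @param channels Channel ids (or marker names) to transform; `NULL` means
#'   all channels.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(cofactor = 5, channels = NULL) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop2("`cofactor` must be a single positive number")
  structure(list(cofactor = as.double(cofactor), channels = channels),
            class = "transform_spec")
}

#' Apply the arcsinh transform
#'
#' Replaces each raw intensity x in the selected channels by
#' `asinh(x / cofactor)` and flags the matrix as transformed. Negative raw
#' values (possible after instrument preprocessing) are transformed as-is;
#' asinh is defined on all reals and strictly increasing.
#'
#' @param x An `expr_matrix` with `transform_state = "raw"`.
#' @param spec A [transform_spec()].
#' @return The transformed `expr_matrix` (`transform_state = "arcsinh"`).
#' @export
apply_transform <- function(x, spec = transform_spec()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(spec, "transform_spec"))
  if (x$transform_state != "raw")
    stop2("matrix is already arcsinh-transformed")
  cols <- if (is.null(spec$channels)) seq_along(x$channel_ids)
          else match_channels(x, spec$channels)
  x$values[, cols] <- asinh(x$values[, cols] / spec$cofactor)
  x$transform_state <- "arcsinh"
  x
}

#' Invert the arcsinh transform
#'
#' Maps transformed values back to the raw scale via
#' `cofactor * sinh(y)`, so normalized data can be written to FCS files on
#' the original scale. Inverse of [apply_transform()] up to float precision.
#'
#' @param x An `expr_matrix` with `transform_state = "arcsinh"`.
#' @param spec The same [transform_spec()] used for the forward transform.
#' @return The raw-scale `expr_matrix`.
#' @export
invert_transform <- function(x, spec = transform_spec()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(spec, "transform_spec"))
  if (x$transform_state != "arcsinh")
    stop2("matrix is on the raw scale; nothing to invert")
  cols <- if (is.null(spec$channels)) seq_along(x$channel_ids)
          else match_channels(x, spec$channels)
  x$values[, cols] <- spec$cofactor * sinh(x$values[, cols])
  x$transform_state <- "raw"
  x
}
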