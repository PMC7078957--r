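# FCS 3.0/3.1 reading and FCS 3.1 writing.
#
# The reader understands list-mode data segments of type F (32-bit float),
# D (64-bit float) and I (uniform 16- or 32-bit unsigned integers), with
# either byte order. The writer emits FCS 3.1, $DATATYPE=F, $MODE=L, which
# is lossless for normalized fractional values. Compensation/spillover
# handling is out of scope (mass cytometry context).

FCS_DELIM <- "/"

# -- TEXT segment parsing ------------------------------------------------

# Parse the TEXT segment bytes into a named list. The first byte is the
# delimiter; a doubled delimiter inside a value is an escaped literal.
parse_fcs_text <- function(raw) {
  if (length(raw) < 3) stop2("FCS format error: TEXT segment too short")
  delim <- rawToChar(raw[1])
  s <- rawToChar(raw[-1])
  Encoding(s) <- "latin1"
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  cur <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == delim) {
      if (i < n && chars[i + 1] == delim) {  # escaped literal delimiter
        cur <- c(cur, delim)
        i <- i + 2L
      } else {                               # token boundary
        tokens <- c(tokens, paste(cur, collapse = ""))
        cur <- character(0)
        i <- i + 1L
      }
    } else {
      cur <- c(cur, chars[i])
      i <- i + 1L
    }
  }
  if (length(cur) && nzchar(trimws(paste(cur, collapse = ""))))
    stop2("FCS format error: TEXT segment not delimiter-terminated")
  # drop a trailing empty token from the final closing delimiter padding
  while (length(tokens) && !nzchar(trimws(tokens[length(tokens)])))
    tokens <- tokens[-length(tokens)]
  if (length(tokens) %% 2 == 1)
    stop2("FCS format error: odd number of TEXT tokens")
  if (length(tokens) == 0)
    stop2("FCS format error: empty TEXT segment")
  kw <- as.list(tokens[seq(2, length(tokens), by = 2)])
  names(kw) <- trimws(tokens[seq(1, length(tokens), by = 2)])
  kw
}

kw_get <- function(kw, key, default = NULL) {
  hit <- which(toupper(names(kw)) == toupper(key))
  if (length(hit)) kw[[hit[1]]] else default
}

#' Read an FCS file
#'
#' Parses an FCS 3.0/3.1 file into an [expr_matrix()] on the raw scale.
#' Channel names come from the `$PnN` keywords; marker names from `$PnS`,
#' falling back to the channel name when `$PnS` is absent. All TEXT-segment
#' keywords are retained in the returned object's `keywords` field.
#'
#' @param path Path to the FCS file.
#' @return An `expr_matrix` with `transform_state = "raw"`.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path))
    stop2("cannot read FCS file (no such file): ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58)
    stop2("FCS format error in ", path, ": file shorter than an FCS header")
  version <- rawToChar(raw[1:6])
  if (!startsWith(version, "FCS"))
    stop2("FCS format error in ", path, ": missing FCS version string")
  off <- function(i) {
    s <- trimws(rawToChar(raw[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.double(s))
  }
  tb <- off(1); te <- off(2); db <- off(3); de <- off(4)
  if (is.na(tb) || is.na(te) || te <= tb)
    stop2("FCS format error in ", path, ": bad TEXT segment offsets")
  kw <- parse_fcs_text(raw[(tb + 1):(te + 1)])

  npar <- as.integer(kw_get(kw, "$PAR") %||% NA)
  ntot <- as.integer(kw_get(kw, "$TOT") %||% NA)
  dtype <- kw_get(kw, "$DATATYPE", "F")
  byteord <- kw_get(kw, "$BYTEORD", "4,3,2,1")
  if (is.na(npar) || is.na(ntot))
    stop2("FCS format error in ", path, ": $PAR/$TOT missing")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop2("FCS format error in ", path,
                         ": unsupported $BYTEORD ", byteord))
  if (is.na(db) || db == 0) db <- as.double(kw_get(kw, "$BEGINDATA", 0))
  if (is.na(de) || de == 0) de <- as.double(kw_get(kw, "$ENDDATA", 0))

  chan <- vapply(seq_len(npar), function(i)
    kw_get(kw, paste0("$P", i, "N")) %||% paste0("P", i), character(1))
  mark <- vapply(seq_len(npar), function(i)
    kw_get(kw, paste0("$P", i, "S")) %||% chan[i], character(1))

  n_values <- ntot * npar
  if (n_values == 0) {
    vals <- matrix(numeric(0), nrow = 0, ncol = npar)
  } else {
    bytes <- raw[(db + 1):(de + 1)]
    vec <- switch(dtype,
      "F" = readBin(bytes, "numeric", n = n_values, size = 4, endian = endian),
      "D" = readBin(bytes, "numeric", n = n_values, size = 8, endian = endian),
      "I" = {
        bits <- unique(vapply(seq_len(npar), function(i)
          as.integer(kw_get(kw, paste0("$P", i, "B"))), integer(1)))
        if (length(bits) != 1)
          stop2("FCS format error in ", path, ": mixed $PnB widths unsupported")
        if (bits == 16)
          as.double(readBin(bytes, "integer", n = n_values, size = 2,
                            signed = FALSE, endian = endian))
        else if (bits == 32) {
          v <- as.double(readBin(bytes, "integer", n = n_values, size = 4,
                                 endian = endian))
          v[v < 0] <- v[v < 0] + 2^32
          v
        } else stop2("FCS format error in ", path,
                     ": unsupported $PnB ", bits)
      },
      stop2("FCS format error in ", path, ": unsupported $DATATYPE ", dtype))
    if (length(vec) < n_values)
      stop2("FCS format error in ", path, ": data segment truncated")
    vals <- matrix(vec, nrow = ntot, ncol = npar, byrow = TRUE)
  }
  expr_matrix(vals, chan, mark, transform_state = "raw",
              source_file = normalizePath(path), keywords = kw)
}

# -- writing -------------------------------------------------------------

fcs_escape <- function(x) gsub(FCS_DELIM, paste0(FCS_DELIM, FCS_DELIM), x,
                               fixed = TRUE)

#' Write an FCS 3.1 file
#'
#' Writes an [expr_matrix()] as FCS 3.1, list mode, `$DATATYPE=F` (32-bit
#' float, big-endian), preserving channel order, `$PnN`/`$PnS` names, and
#' any non-structural keywords carried in `x$keywords`. The matrix must be
#' on the raw scale: normalized (arcsinh-scale) values have to be passed
#' through [invert_transform()] first so files hold instrument-scale data.
#'
#' @param x An `expr_matrix` with `transform_state = "raw"`.
#' @param path Output path.
#' @param clip_min Optional lower clip bound applied to all values on write
#'   (e.g. 0 to remove negative intensities); default `NULL`, no clipping.
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(x, path, clip_min = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$transform_state != "raw")
    stop2("refusing to write arcsinh-scale values; call invert_transform() first")
  vals <- x$values
  if (!is.null(clip_min)) vals[vals < clip_min] <- clip_min
  np <- ncol(vals); nt <- nrow(vals)

  kw <- list()
  # structural keywords are regenerated, not copied
  structural <- c("$BEGINANALYSIS", "$ENDANALYSIS", "$BEGINSTEXT", "$ENDSTEXT",
                  "$BEGINDATA", "$ENDDATA", "$BYTEORD", "$DATATYPE", "$MODE",
                  "$NEXTDATA", "$PAR", "$TOT")
  carried <- x$keywords[!toupper(names(x$keywords)) %in% structural]
  carried <- carried[!grepl("^\\$P[0-9]+[BENRS]$", toupper(names(carried)))]

  kw[["$BEGINANALYSIS"]] <- "0"; kw[["$ENDANALYSIS"]] <- "0"
  kw[["$BEGINSTEXT"]] <- "0"; kw[["$ENDSTEXT"]] <- "0"
  kw[["$BEGINDATA"]] <- strrep("0", 10)  # placeholder, fixed width
  kw[["$ENDDATA"]] <- strrep("0", 10)
  kw[["$BYTEORD"]] <- "4,3,2,1"
  kw[["$DATATYPE"]] <- "F"
  kw[["$MODE"]] <- "L"
  kw[["$NEXTDATA"]] <- "0"
  kw[["$PAR"]] <- as.character(np)
  kw[["$TOT"]] <- as.character(nt)
  for (i in seq_len(np)) {
    rng <- if (nt > 0) max(1, ceiling(max(vals[, i]))) else 262144
    kw[[paste0("$P", i, "B")]] <- "32"
    kw[[paste0("$P", i, "E")]] <- "0,0"
    kw[[paste0("$P", i, "N")]] <- x$channel_ids[i]
    kw[[paste0("$P", i, "R")]] <- as.character(rng)
    if (!identical(x$marker_names[i], x$channel_ids[i]))
      kw[[paste0("$P", i, "S")]] <- x$marker_names[i]
  }
  for (nm in names(carried)) kw[[nm]] <- as.character(carried[[nm]])

  build_text <- function(kw) {
    paste0(FCS_DELIM,
           paste0(vapply(names(kw), function(k)
             paste0(fcs_escape(k), FCS_DELIM, fcs_escape(kw[[k]]), FCS_DELIM),
             character(1)), collapse = ""))
  }
  text0 <- build_text(kw)
  text_start <- 58
  text_end <- text_start + nchar(text0, type = "bytes") - 1
  data_start <- if (nt > 0) text_end + 1 else 0
  data_end <- if (nt > 0) data_start + 4 * nt * np - 1 else 0
  kw[["$BEGINDATA"]] <- formatC(data_start, width = 10, flag = "0", format = "d")
  kw[["$ENDDATA"]] <- formatC(data_end, width = 10, flag = "0", format = "d")
  text <- build_text(kw)
  stopifnot(nchar(text, type = "bytes") == nchar(text0, type = "bytes"))

  hdr_num <- function(v) formatC(v, width = 8, format = "d")
  header <- paste0("FCS3.1    ",
                   hdr_num(text_start), hdr_num(text_end),
                   hdr_num(data_start), hdr_num(data_end),
                   hdr_num(0), hdr_num(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (nt > 0)
    writeBin(as.vector(t(vals)), con, size = 4, endian = "big")
  invisible(path)
}
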