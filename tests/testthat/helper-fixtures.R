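# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles are deliberately coded along different
# routes than the implementation they check.

# Small expression matrix with reproducible random content.
make_em <- function(n = 100, p = 3, seed = 1, state = "raw", scale = 10) {
  set.seed(seed)
  expr_matrix(matrix(runif(n * p) * scale, n, p),
              channel_ids = paste0("Ch", seq_len(p)),
              marker_names = paste0("CD", seq_len(p)),
              transform_state = state)
}

# Independent FCS writer for reader fixtures: FCS 3.0, $DATATYPE=D,
# little-endian, backslash delimiter, TEXT at a padded offset - a layout
# deliberately different from the package writer in every free choice.
write_fcs_reference <- function(path, vals, pnn, pns = list()) {
  np <- ncol(vals); nt <- nrow(vals)
  kv <- c("$DATATYPE", "D", "$BYTEORD", "1,2,3,4", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", np, "$TOT", nt)
  for (i in seq_len(np)) {
    kv <- c(kv, paste0("$P", i, "B"), "64",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "N"), pnn[i],
            paste0("$P", i, "R"), "1024")
    if (!is.null(pns[[as.character(i)]]))
      kv <- c(kv, paste0("$P", i, "S"), pns[[as.character(i)]])
  }
  text_start <- 256
  n_data <- 8 * nt * np
  # sizes of $BEGINDATA/$ENDDATA values are stabilized with fixed width
  kv <- c(kv, "$BEGINDATA", "@@@@@@@@", "$ENDDATA", "########",
          "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0")
  text <- paste0("\\", paste(kv, collapse = "\\"), "\\")
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- if (nt > 0) data_start + n_data - 1 else 0
  text <- sub("@@@@@@@@", formatC(data_start, width = 8, flag = "0"), text,
              fixed = TRUE)
  text <- sub("########", formatC(data_end, width = 8, flag = "0"), text,
              fixed = TRUE)
  header <- paste0("FCS3.0    ",
                   formatC(text_start, width = 8),
                   formatC(text_end, width = 8),
                   formatC(if (nt > 0) data_start else 0, width = 8),
                   formatC(data_end, width = 8),
                   formatC(0, width = 8), formatC(0, width = 8))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_start - nchar(header)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (nt > 0) writeBin(as.vector(t(vals)), con, size = 8, endian = "little")
  invisible(path)
}

# Minimal independent keyword scraper: pulls one keyword value straight
# from the file bytes without the package's parser.
scrape_keyword <- function(path, key) {
  raw <- readBin(path, "raw", n = file.size(path))
  tb <- as.integer(trimws(rawToChar(raw[11:18])))
  te <- as.integer(trimws(rawToChar(raw[19:26])))
  delim <- rawToChar(raw[tb + 1])
  toks <- strsplit(rawToChar(raw[(tb + 2):(te + 1)]), delim,
                   fixed = TRUE)[[1]]
  hit <- which(toks == key)
  if (!length(hit)) return(NULL)
  toks[hit[1] + 1]
}

# Transportation-plan EMD oracle: north-west-corner allocation of the
# two aligned probability vectors (optimal for the convex |i-j| ground
# cost in 1D), coded independently of the cumulative-difference formula.
emd_nw_oracle <- function(pa, pb) {
  stopifnot(length(pa) == length(pb))
  i <- 1L; j <- 1L
  cost <- 0
  a <- pa / sum(pa); b <- pb / sum(pb)
  while (i <= length(a) && j <= length(b)) {
    m <- min(a[i], b[j])
    cost <- cost + m * abs(i - j)
    a[i] <- a[i] - m
    b[j] <- b[j] - m
    if (a[i] <= 1e-14) i <- i + 1L
    else j <- j + 1L
  }
  cost
}

# Random strictly-monotone knot set on roughly [0, 8].
random_monotone_knots <- function(n_knots, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- cumsum(c(runif(1, 0, 0.5), runif(n_knots - 1, 0.05, 1)))
  x <- x / max(x) * runif(1, 4, 8)
  y <- cumsum(c(runif(1, 0, 0.5), runif(n_knots - 1, 0, 1)))
  y <- y / max(y) * runif(1, 4, 8)
  list(x = x, y = y)
}

# Study configuration used for synthetic preset runs throughout the
# tests: a scaled-down analogue of the default 10x10/25-cluster setup,
# sized for the 4-population, 4-marker synthetic world.
preset_params <- function(k = 4, ...) {
  norm_params(xdim = 6, ydim = 6, k = k, total_cells = 9000, seed = 101, ...)
}

eval_markers <- paste0("Marker", 1:4)

# Train on a preset's controls and evaluate EMD before/after on its
# validation aliquots with ground-truth population labels.
run_preset <- function(spec, params = preset_params()) {
  ds <- generate_dataset(spec)
  ctl <- synthetic_controls(ds)
  val <- synthetic_validation(ds)
  lab <- synthetic_validation_labels(ds)
  model <- suppressWarnings(train_model(ctl, params))
  normed <- lapply(names(val), function(b) normalize_sample(val[[b]], b, model))
  names(normed) <- names(val)
  before <- max_pairwise_emd(val, lab, markers = eval_markers)
  after <- max_pairwise_emd(normed, lab, markers = eval_markers)
  list(dataset = ds, model = model, normed = normed,
       before = before, after = after,
       reduction = reduction_score(before, after))
}
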