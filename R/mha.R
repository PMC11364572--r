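# Minimal MetaImage (.mha / .mhd+raw) support for label volumes.
# Reads uncompressed and zlib-compressed data, axis-aligned direction
# matrices only; the ITK world frame is LPS, the package canonical frame
# (S, A, R). Writing always produces uncompressed data.

met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE), # values < 2^31 assumed
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE)
)

read_header_line <- function(con) {
  bytes <- raw()
  repeat { # byte-at-a-time keeps the connection position exact for readBin
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(NULL)
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  sub("\r$", "", rawToChar(bytes))
}

parse_mha_header <- function(con) {
  hdr <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line)) sc_stop("io", "truncated MetaImage header")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) sc_stop("io", "malformed MetaImage header line: '%s'", line)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  hdr
}

load_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- parse_mha_header(con)
  if (!is.null(hdr$NDims) && as.integer(hdr$NDims) != 3L)
    sc_stop("format", "%s: only 3D MetaImage volumes are supported", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  tp <- met_types[[hdr$ElementType %||% "MET_SHORT"]]
  if (is.null(tp)) sc_stop("format", "%s: unsupported ElementType %s", path, hdr$ElementType)
  n <- prod(dims)
  endian <- if (isTRUE(tolower(hdr$ElementByteOrderMSB %||% hdr$BinaryDataByteOrderMSB %||% "false") == "true"))
    "big" else "little"

  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) sc_stop("io", "MetaImage data file not found: %s", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  if (isTRUE(tolower(hdr$CompressedData %||% "false") == "true")) {
    comp <- readBin(raw_con, "raw", n = n * tp$size * 2L + 1024L)
    bytes <- memDecompress(comp, type = "gzip")
    vals <- readBin(bytes, tp$what, n = n, size = tp$size, signed = tp$signed, endian = endian)
  } else {
    vals <- readBin(raw_con, tp$what, n = n, size = tp$size, signed = tp$signed, endian = endian)
  }
  if (length(vals) < n) sc_stop("io", "%s: expected %d voxels, read %d", path, n, length(vals))
  arr <- array(vals, dim = dims)

  tm <- hdr$TransformMatrix %||% hdr$Orientation %||% "1 0 0 0 1 0 0 0 1"
  dirmat <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, 3, byrow = TRUE) # row i = LPS direction of axis i
  code <- lps_direction_code(dirmat, path)
  canonicalize_to_volume(arr, spacing, code, source = path)
}

# map an axis-aligned LPS direction matrix to a 3-letter anatomical code
lps_direction_code <- function(dirmat, path) {
  lets <- character(3)
  for (i in 1:3) {
    v <- dirmat[i, ]
    ax <- which.max(abs(v))
    if (abs(v[ax]) < 0.999 || sum(abs(v) > 1e-6) > 1L)
      sc_stop("orientation", "%s: oblique direction matrix not supported", path)
    lets[i] <- c("L", "P", "S", "R", "A", "I")[ax + ifelse(v[ax] > 0, 0, 3)]
  }
  paste(lets, collapse = "")
}

# reorient an array whose axes follow `code` into the canonical SAR frame
canonicalize_to_volume <- function(arr, spacing, code, source) {
  perm <- orientation_permutation(code) # disk axis i = canonical axis perm$axes[i]
  inv <- order(perm$axes)
  arr <- aperm(arr, inv)
  spacing <- spacing[inv]
  for (ax in which(perm$flip)) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- rev(seq_len(dim(arr)[ax]))
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  labeled_volume(arr, spacing, source = source)
}

write_metaimage <- function(arr, sp_disk, code, path) {
  perm <- orientation_permutation(code)
  canon_lps <- rbind(S = c(0, 0, 1), A = c(0, -1, 0), R = c(-1, 0, 0)) # canonical axis -> LPS vector
  dirmat <- matrix(0, 3, 3)
  for (i in 1:3) {
    cx <- perm$axes[i]
    dirmat[i, ] <- canon_lps[cx, ] * ifelse(perm$flip[cx], -1, 1)
  }
  mx <- max(arr)
  type <- if (mx < 256) "MET_UCHAR" else if (mx < 32768) "MET_SHORT" else "MET_INT"
  tp <- met_types[[type]]
  ext <- tolower(sub("^.*\\.", ".", basename(path)))
  local_data <- ext == ".mha"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s", paste(t(dirmat), collapse = " ")),
    sprintf("Offset = %s", paste(rep(0, 3), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(sp_disk, collapse = " ")),
    sprintf("DimSize = %s", paste(dim(arr), collapse = " ")),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s",
            if (local_data) "LOCAL" else sub("\\.mhd$", ".raw", basename(path)))
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  data_con <- if (local_data) con else {
    rc <- file(file.path(dirname(path), sub("\\.mhd$", ".raw", basename(path))), "wb")
    on.exit(close(rc), add = TRUE)
    rc
  }
  writeBin(as.vector(arr), data_con, size = tp$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
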