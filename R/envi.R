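# ENVI-dialect hypercube I/O: a plain-text .hdr file next to a flat binary
# data file. Supported interleaves: BSQ (band sequential), BIL (band
# interleaved by line), BIP (band interleaved by pixel); data types 4
# (float32) and 5 (float64), little or big endian.

envi_data_types <- c(float32 = 4L, float64 = 5L)

envi_paths <- function(path) {
  base <- sub("\\.(hdr|raw|dat|img)$", "", path)
  hdr <- paste0(base, ".hdr")
  dat_candidates <- c(paste0(base, ".raw"), base, paste0(base, ".dat"),
                      paste0(base, ".img"))
  list(base = base, hdr = hdr, dat = dat_candidates)
}

#' Write a hypercube as an ENVI header + binary pair
#'
#' @param cube A [hypercube].
#' @param path Output path; the extension is replaced so that `<base>.hdr`
#'   and `<base>.raw` are written.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type `"float32"` (ENVI type 4, the default) or `"float64"`
#'   (type 5). float32 round-trips with single precision; use float64 when
#'   bit-exact values matter.
#' @return Invisibly, the `.hdr` path.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = c("float32", "float64")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- match.arg(data_type)
  p <- envi_paths(path)
  d <- dim(cube$values)
  # ENVI stores samples (cross-track) fastest; map the R rows x cols x bands
  # array to each interleave's axis order.
  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),   # sample, line, band
                 bil = c(2L, 3L, 1L),   # sample, band, line
                 bip = c(3L, 2L, 1L))   # band, sample, line
  vec <- as.vector(aperm(cube$values, perm))
  con <- file(p$dat[1L], "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(vec), con,
           size = if (data_type == "float32") 4L else 8L, endian = "little")
  hdr <- c(
    "ENVI",
    "description = {seedage hypercube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", envi_data_types[[data_type]]),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("state = %s", cube$state),
    "wavelength units = Nanometers",
    paste0("wavelength = {\n ",
           paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                 collapse = ",\n "),
           "}")
  )
  writeLines(hdr, p$hdr)
  invisible(p$hdr)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  fields <- list()
  # tokenize: key = value where value may be a {...} block spanning lines
  pat <- "(?s)([A-Za-z][A-Za-z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1L] == -1L) stop("ENVI header: no key = value fields found", call. = FALSE)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("(?s)^([^=]*)=.*$", "\\1", piece, perl = TRUE))
    val <- trimws(sub("(?s)^[^=]*=\\s*(.*)$", "\\1", piece, perl = TRUE))
    fields[[tolower(key)]] <- val
  }
  fields
}

#' Read an ENVI header + binary pair into a hypercube
#'
#' @param path Path to the `.hdr` file or its base name; the data file is
#'   looked up as `<base>.raw`, `<base>`, `<base>.dat` or `<base>.img`.
#' @return A [hypercube].
#' @export
read_cube <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stop("ENVI header not found: ", p$hdr, call. = FALSE)
  dat <- p$dat[file.exists(p$dat)][1L]
  if (is.na(dat)) stop("ENVI data file not found for ", p$base, call. = FALSE)
  f <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave", "wavelength")
  missing <- setdiff(need, names(f))
  if (length(missing) > 0L) {
    stop("ENVI header missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- as.integer(f[["samples"]])
  lines_n <- as.integer(f[["lines"]])
  bands <- as.integer(f[["bands"]])
  dtype <- as.integer(f[["data type"]])
  if (!dtype %in% envi_data_types) {
    stop("unsupported ENVI data type: ", dtype, call. = FALSE)
  }
  interleave <- tolower(f[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }
  endian <- if (!is.null(f[["byte order"]]) && as.integer(f[["byte order"]]) == 1L)
    "big" else "little"
  wl_txt <- gsub("[{}]", "", f[["wavelength"]])
  wavelengths <- as.numeric(strsplit(wl_txt, ",")[[1]])
  wavelengths <- wavelengths[!is.na(wavelengths)]
  if (length(wavelengths) != bands) {
    stop(sprintf("ENVI header: %d wavelengths for %d bands",
                 length(wavelengths), bands), call. = FALSE)
  }
  state <- f[["state"]] %||% "corrected"
  if (!state %in% c("raw", "corrected")) state <- "corrected"
  n <- samples * lines_n * bands
  size <- if (dtype == 4L) 4L else 8L
  expect_bytes <- as.numeric(n) * size
  if (file.size(dat) < expect_bytes) {
    stop(sprintf("ENVI data file too short: %d bytes, expected %d",
                 file.size(dat), expect_bytes), call. = FALSE)
  }
  con <- file(dat, "rb")
  on.exit(close(con), add = TRUE)
  vec <- readBin(con, what = "numeric", n = n, size = size, endian = endian)
  dims <- switch(interleave,
                 bsq = c(samples, lines_n, bands),
                 bil = c(samples, bands, lines_n),
                 bip = c(bands, samples, lines_n))
  inv <- switch(interleave,
                bsq = c(2L, 1L, 3L),
                bil = c(3L, 1L, 2L),
                bip = c(3L, 2L, 1L))
  values <- aperm(array(vec, dims), inv)
  hypercube(values, wavelengths, state = state)
}
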