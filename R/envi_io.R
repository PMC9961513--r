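#' Read and write hypercubes in ENVI header + binary layout
#'
#' The on-disk format is the de-facto standard for pushbroom imaging
#' spectrometers: a plain-text `.hdr` file describing dimensions,
#' interleave and the wavelength list, next to a flat binary file of
#' little-endian IEEE floats. `write_cube` emits band-sequential (BSQ)
#' 64-bit data; `read_cube` accepts BSQ and band-interleaved-by-line (BIL),
#' data types 4 (float32) and 5 (float64). The round trip is lossless.
#'
#' @param cube a [hypercube()].
#' @param path path of the binary file; the header is `<path>.hdr`.
#' @return `read_cube` returns a [hypercube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("reflectance = %d", as.integer(cube$is_reflectance)),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.17g", cube$wavelengths), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb"); on.exit(close(con))
  # BSQ order: sample fastest, then line, then band
  writeBin(as.vector(aperm(cube$data, c(2L, 1L, 3L))), con,
           size = 8L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop_input("%s is not an ENVI header", hdr_path)
  # join brace-delimited multi-line values onto one line
  m <- gregexpr("\\{[^}]*\\}", txt)
  regmatches(txt, m) <- lapply(regmatches(txt, m), gsub,
                               pattern = "\n", replacement = " ")
  get <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
                                 txt, perl = TRUE))[[1L]]
    if (length(m) < 2L) {
      if (required) stop_input("header %s missing field '%s'", hdr_path, key)
      return(NULL)
    }
    trimws(m[2L])
  }
  wl_raw <- get("wavelength")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1L]])
  list(samples = as.integer(get("samples")),
       lines = as.integer(get("lines")),
       bands = as.integer(get("bands")),
       data_type = as.integer(get("data type")),
       interleave = tolower(get("interleave")),
       offset = {o <- get("header offset", required = FALSE); if (is.null(o)) 0L else as.integer(o)},
       byte_order = as.integer(get("byte order")),
       reflectance = {r <- get("reflectance", required = FALSE); !is.null(r) && as.integer(r) == 1L},
       wavelengths = wl)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  h <- parse_envi_header(paste0(path, ".hdr"))
  if (h$bands != length(h$wavelengths))
    stop_input("header declares %d bands but %d wavelengths", h$bands,
               length(h$wavelengths))
  size <- switch(as.character(h$data_type), "4" = 4L, "5" = 8L,
                 stop_input("unsupported ENVI data type %d", h$data_type))
  endian <- if (h$byte_order == 0L) "little" else "big"
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb"); on.exit(close(con))
  if (h$offset > 0L) readBin(con, "raw", h$offset)
  v <- readBin(con, "double", n = n, size = size, endian = endian)
  if (length(v) != n)
    stop_input("%s holds %d values, header promises %d", path, length(v), n)
  data <- switch(h$interleave,
    bsq = aperm(array(v, c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(h$samples, h$bands, h$lines)), c(3L, 1L, 2L)),
    stop_input("unsupported interleave '%s' (bsq and bil accepted)", h$interleave))
  hypercube(data, h$wavelengths, is_reflectance = h$reflectance)
}
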