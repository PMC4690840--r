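# Minimal NRRD0004 reader/writer for axis-aligned 3D integer label volumes.
# Supports encodings: raw (little-endian), ascii, gzip. Space directions must
# be diagonal (axis-aligned); anything else is rejected as unsupported
# geometry, consistent with the package's exact voxel<->world convention.

nrrd_type_map <- c("unsigned char" = 1L, "uchar" = 1L, "uint8" = 1L,
                   "short" = 2L, "signed short" = 2L, "int16" = 2L,
                   "unsigned short" = 2L, "ushort" = 2L, "uint16" = 2L,
                   "int" = 4L, "signed int" = 4L, "int32" = 4L,
                   "unsigned int" = 4L, "uint" = 4L, "uint32" = 4L)

read_nrrd_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 3L)) stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  bytes <- nrrd_type_map[[type]]
  if (is.null(bytes)) stop(sprintf("unsupported NRRD type '%s'", type))
  signed <- !grepl("^u", type) && !grepl("unsigned", type)
  n <- prod(sizes)

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    offd <- mat; diag(offd) <- 0
    if (max(abs(offd)) > 1e-9 * max(abs(diag(mat))))
      stop("non-axis-aligned NRRD space directions: unsupported geometry")
    spacing <- diag(mat)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
    origin <- origin - 0.5 * spacing  # NRRD origin = center of first sample
  }

  enc <- tolower(fields[["encoding"]])
  if (enc %in% c("raw")) {
    vals <- readBin(con, "integer", n = n, size = bytes,
                    signed = if (bytes < 4) signed else TRUE,
                    endian = "little")
  } else if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[is.finite(vals)]
  } else if (enc %in% c("gz", "gzip")) {
    blob <- readBin(con, "raw", n = file.size(path))
    raw <- memDecompress(blob, type = "gzip")
    vals <- readBin(raw, "integer", n = n, size = bytes,
                    signed = if (bytes < 4) signed else TRUE,
                    endian = "little")
  } else stop(sprintf("unsupported NRRD encoding '%s'", enc))
  if (length(vals) < n) stop("truncated NRRD data")
  if (max(abs(vals - round(vals)), 0) > 1e-9)
    stop("non-integer labels in voxel data")
  label_image(array(as.integer(round(vals[seq_len(n)])), dim = sizes),
              spacing = spacing, origin = origin)
}

write_nrrd_image <- function(image, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  d <- dim(image$voxels)
  ctr <- image$origin + 0.5 * image$spacing
  hdr <- c("NRRD0004",
           "# generated by cardiomesh",
           "type: unsigned short",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   image$spacing[1], image$spacing[2], image$spacing[3]),
           "kinds: domain domain domain",
           "endian: little",
           sprintf("encoding: %s", encoding),
           sprintf("space origin: (%.17g,%.17g,%.17g)", ctr[1], ctr[2], ctr[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.integer(image$voxels), con, size = 2L, endian = "little")
  } else {
    writeLines(paste(as.vector(image$voxels), collapse = " "), con)
  }
  invisible(path)
}
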