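# MetaImage (MHD header + RAW) serialization of dose grids: 32-bit float
# little-endian by default, with origin/spacing preserved exactly. The
# companion statistics (outside/escaped tallies, histories) travel in a JSON
# sidecar written by the CLI.

#' Write a dose grid as a MetaImage MHD/RAW pair
#'
#' @param grid a `dose_grid`.
#' @param path output `.mhd` path (the raw file sits next to it).
#' @param element `"MET_FLOAT"` (default) or `"MET_DOUBLE"`.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path, element = c("MET_FLOAT", "MET_DOUBLE")) {
  stopifnot(inherits(grid, "dose_grid"))
  element <- match.arg(element)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", grid$dims[1], grid$dims[2], grid$dims[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g", grid$voxel, grid$voxel, grid$voxel),
    sprintf("Offset = %.17g %.17g %.17g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("ElementType = %s", element),
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con,
           size = if (element == "MET_FLOAT") 4L else 8L, endian = "little")
  invisible(path)
}

#' Read a MetaImage MHD/RAW pair into a dose grid
#'
#' @param path `.mhd` header path.
#' @return A `dose_grid` (no batch information).
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) stop("MHD header not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("MHD header missing key: ", k, call. = FALSE)
    vals[i]
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  offset <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  etype <- get("ElementType")
  size <- switch(etype, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 stop("unsupported ElementType: ", etype, call. = FALSE))
  if (length(unique(round(spacing, 12))) != 1) {
    stop("anisotropic spacing not supported", call. = FALSE)
  }
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(dims)
  if (file.info(raw_path)$size != n * size) {
    stop(sprintf("raw size mismatch: expected %d bytes, found %d",
                 n * size, file.info(raw_path)$size), call. = FALSE)
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = size, endian = "little")
  g <- new_dose_grid(array(v, dim = dims), voxel = spacing[1])
  g$origin <- offset
  g
}
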