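#' Read a scalar grid from disk
#'
#' NRRD is the persisted grid format: attached (`.nrrd`) or detached (`.nhdr`
#' plus data file) headers, `raw` or `ascii`/`text` encodings, with geometry
#' taken from `space origin` / `space directions` (axis-aligned directions
#' required) and the dose/density unit from the custom `dosemedium:unit` key.
#'
#' @param path file path.
#' @param format currently `"nrrd"`; inferred from the extension by default.
#' @return a [scalar_grid()].
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, format = c("auto", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("format error: file not found: %s", path))
  read_nrrd(path)
}

#' Write a scalar grid to disk
#'
#' @param grid a [scalar_grid()].
#' @param path output path (`.nrrd`).
#' @param encoding `"raw"` (little-endian doubles) or `"ascii"`.
#' @return `path`, invisibly. The file round-trips through [read_grid()].
#' @export
write_grid <- function(grid, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(grid, "scalar_grid"))
  d <- dim(grid$values)
  nd <- length(d)
  dirs <- vapply(seq_len(nd), function(a) {
    v <- rep(0, nd); v[a] <- grid$spacing[a]
    paste0("(", paste(format(v, trim = TRUE, digits = 15), collapse = ","), ")")
  }, character(1))
  hdr <- c(
    "NRRD0004",
    "type: double",
    sprintf("dimension: %d", nd),
    sprintf("sizes: %s", paste(d, collapse = " ")),
    sprintf("encoding: %s", encoding),
    "endian: little",
    sprintf("space dimension: %d", nd),
    sprintf("space directions: %s", paste(dirs, collapse = " ")),
    sprintf("space origin: (%s)",
            paste(format(grid$origin, trim = TRUE, digits = 15), collapse = ",")),
    sprintf("dosemedium:unit:=%s", grid$unit)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines("", con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(grid$values), digits = 17),
                     collapse = " "), con, sep = "\n")
  }
  invisible(path)
}

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(if (isOpen(con)) close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop(sprintf("format error: not an NRRD file (magic line '%s')", magic))
  fields <- list(); keys <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop("format error: NRRD header not terminated by a blank line")
    if (line == "") break
    if (startsWith(line, "#")) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      keys[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":="))
    } else if (grepl(": ", line, fixed = TRUE)) {
      kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
    } else {
      stop(sprintf("format error: malformed NRRD header line '%s'", line))
    }
  }
  need <- function(f) {
    if (is.null(fields[[f]]))
      stop(sprintf("format error: NRRD header missing required field '%s'", f))
    fields[[f]]
  }
  nd <- as.integer(need("dimension"))
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != nd || any(is.na(sizes)) || any(sizes < 1))
    stop("format error: NRRD field 'sizes' inconsistent with 'dimension'")
  encoding <- tolower(need("encoding"))
  type <- tolower(need("type"))

  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)|none", fields[["space directions"]]))[[1]]
    toks <- toks[toks != "none"]
    if (length(toks) != nd)
      stop("geometry error: 'space directions' does not list one vector per axis")
    spacing <- numeric(nd)
    for (a in seq_len(nd)) {
      v <- parse_nrrd_vector(toks[a])
      if (sum(abs(v) > 1e-12) != 1 || abs(v[a]) <= 1e-12)
        stop("geometry error: only axis-aligned 'space directions' are supported")
      spacing[a] <- v[a]
    }
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    stop("geometry error: NRRD header carries neither 'space directions' nor 'spacings'")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("geometry error: non-positive NRRD spacing")
  origin <- if (!is.null(fields[["space origin"]]))
    parse_nrrd_vector(fields[["space origin"]]) else rep(0, nd)
  if (length(origin) != nd)
    stop("geometry error: 'space origin' length does not match 'dimension'")

  n <- prod(sizes)
  read_payload <- function(con) {
    if (encoding == "raw") {
      endian <- tolower(fields[["endian"]] %||% "little")
      sz <- switch(type,
                   "double" = 8, "float" = 4,
                   "short" = 2, "int16" = 2, "int" = 4, "int32" = 4,
                   "uint16" = 2, "ushort" = 2,
                   stop(sprintf("format error: unsupported NRRD type '%s'", type)))
      what <- if (type %in% c("double", "float")) numeric() else integer()
      signed <- !type %in% c("uint16", "ushort")
      readBin(con, what, n = n, size = sz, endian = endian, signed = signed)
    } else if (encoding %in% c("ascii", "text", "txt")) {
      scan(con, what = numeric(), n = n, quiet = TRUE)
    } else {
      stop(sprintf("format error: unsupported NRRD encoding '%s'", encoding))
    }
  }
  if (!is.null(fields[["data file"]]) || !is.null(fields[["datafile"]])) {
    df <- fields[["data file"]] %||% fields[["datafile"]]
    df_path <- if (file.exists(df)) df else file.path(dirname(path), df)
    if (!file.exists(df_path))
      stop(sprintf("format error: detached data file not found: %s", df))
    dcon <- file(df_path, "rb"); on.exit(close(dcon), add = TRUE)
    vals <- read_payload(dcon)
  } else {
    vals <- read_payload(con)
  }
  if (length(vals) != n)
    stop("format error: NRRD data block shorter than 'sizes' promise")
  unit <- keys[["dosemedium:unit"]] %||% "dimensionless"
  if (!unit %in% c("Gy", "g/cm3", "HU", "percent", "dimensionless"))
    unit <- "dimensionless"
  scalar_grid(array(as.numeric(vals), sizes), origin = origin,
              spacing = spacing, unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
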