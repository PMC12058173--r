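# Minimal MATLAB level-5 (MAT-v5) container I/O.
#
# Supports what the package's containers need: double/complex numeric arrays
# (any dimensionality), character strings, cell arrays, and structs
# (including 1 x N struct arrays such as EEGLAB chanlocs).  Files are written
# uncompressed, little-endian; the reader additionally understands
# zlib-compressed elements and the common integer/single storage types, so it
# can read files produced by other writers.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L
MI_COMPRESSED <- 15L; MI_UTF8 <- 16L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_OBJECT <- 3L; MX_CHAR <- 4L
MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L

mat_pad8 <- function(r) {
  rem <- length(r) %% 8L
  if (rem) c(r, raw(8L - rem)) else r
}

mat_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

mat_element <- function(type, data) {
  c(mat_u32(type), mat_u32(length(data)), mat_pad8(data))
}

mat_num_data <- function(v) {
  writeBin(as.double(v), raw(), size = 8L, endian = "little")
}

#' Treat a list of records as a MATLAB struct array
#'
#' Marks an unnamed list of identically named lists so that [write_mat()]
#' stores it as a `1 x N` struct array (e.g. EEGLAB `chanlocs`) rather than a
#' cell array of scalar structs.
#'
#' @param records Unnamed list; each element a named list with the same
#'   field names.
#' @return The list with class `mat_struct_array`.
#' @export
mat_struct_array <- function(records) {
  if (length(records)) {
    fields <- names(records[[1]])
    ok <- vapply(records, function(r) identical(names(r), fields), TRUE)
    if (is.null(fields) || any(!nzchar(fields)) || !all(ok)) {
      stop("all records must be named lists sharing the same field names",
           call. = FALSE)
    }
  }
  structure(records, class = "mat_struct_array")
}

# Serialize one array (with its name) as a miMATRIX element.
mat_matrix_raw <- function(name, value) {
  if (is.null(value)) value <- numeric(0)
  body <- if (inherits(value, "mat_struct_array")) {
    mat_struct_body(value, array_dims = TRUE)
  } else if (is.list(value) && !is.null(names(value)) &&
             all(nzchar(names(value)))) {
    mat_struct_body(mat_struct_array(list(value)), array_dims = FALSE)
  } else if (is.list(value)) {
    mat_cell_body(value)
  } else if (is.character(value) && length(value) == 1L) {
    mat_char_body(value)
  } else if (is.character(value)) {
    mat_cell_body(as.list(value))
  } else if (is.complex(value) || is.numeric(value) || is.logical(value)) {
    mat_numeric_body(value)
  } else {
    stop("cannot serialize object of class ", paste(class(value), collapse = "/"),
         call. = FALSE)
  }
  flags <- mat_u32(body$class + if (body$complex) 0x0800L else 0L)
  sub <- c(
    mat_element(MI_UINT32, c(flags, mat_u32(0L))),
    mat_element(MI_INT32, writeBin(as.integer(body$dims), raw(), size = 4L,
                                   endian = "little")),
    mat_element(MI_INT8, charToRaw(name)),
    body$data
  )
  mat_element(MI_MATRIX, sub)
}

mat_numeric_body <- function(value) {
  dims <- if (is.null(dim(value))) c(1L, length(value)) else dim(value)
  v <- as.vector(value)
  if (is.complex(v)) {
    data <- c(mat_element(MI_DOUBLE, mat_num_data(Re(v))),
              mat_element(MI_DOUBLE, mat_num_data(Im(v))))
    list(class = MX_DOUBLE, complex = TRUE, dims = dims, data = data)
  } else {
    list(class = MX_DOUBLE, complex = FALSE, dims = dims,
         data = mat_element(MI_DOUBLE, mat_num_data(as.double(v))))
  }
}

mat_char_body <- function(s) {
  codes <- utf8ToInt(s)
  list(class = MX_CHAR, complex = FALSE, dims = c(1L, length(codes)),
       data = mat_element(MI_UINT16,
                          writeBin(as.integer(codes), raw(), size = 2L,
                                   endian = "little")))
}

mat_cell_body <- function(value) {
  data <- do.call(c, c(list(raw(0)),
                       lapply(value, function(v) mat_matrix_raw("", v))))
  list(class = MX_CELL, complex = FALSE, dims = c(1L, length(value)),
       data = data)
}

mat_struct_body <- function(records, array_dims) {
  fields <- if (length(records)) names(records[[1]]) else character(0)
  maxlen <- 32L
  name_block <- raw(maxlen * length(fields))
  for (i in seq_along(fields)) {
    fn <- charToRaw(fields[i])
    if (length(fn) >= maxlen) stop("struct field name too long", call. = FALSE)
    name_block[(i - 1L) * maxlen + seq_along(fn)] <- fn
  }
  vals <- raw(0)
  for (rec in records) {             # element-major, fields within element
    for (f in fields) vals <- c(vals, mat_matrix_raw("", rec[[f]]))
  }
  dims <- if (array_dims) c(1L, length(records)) else c(1L, 1L)
  list(class = MX_STRUCT, complex = FALSE, dims = dims,
       data = c(mat_element(MI_INT32, writeBin(maxlen, raw(), size = 4L,
                                               endian = "little")),
                mat_element(MI_INT8, name_block),
                vals))
}

#' Write variables to a MATLAB level-5 file
#'
#' @param path Output file path.
#' @param vars Named list of variables.  Numeric/complex arrays keep their
#'   dimensions; a single string becomes a char row vector; a character
#'   vector becomes a cell array of strings; an unnamed list a cell array; a
#'   named list a scalar struct; a [mat_struct_array()] a `1 x N` struct
#'   array.
#' @return `path`, invisibly.
#' @seealso [read_mat()]
#' @export
write_mat <- function(path, vars) {
  if (is.null(names(vars)) || any(!nzchar(names(vars)))) {
    stop("`vars` must be a fully named list", call. = FALSE)
  }
  desc <- sprintf("MATLAB 5.0 MAT-file, written by eegtf")
  header <- charToRaw(desc)
  header <- c(header, rep(charToRaw(" "), 116L - length(header)))
  header <- c(header, raw(8L),
              writeBin(0x0100L, raw(), size = 2L, endian = "little"),
              charToRaw("IM"))
  body <- do.call(c, c(list(raw(0)), lapply(names(vars), function(nm) {
    mat_matrix_raw(nm, vars[[nm]])
  })))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

mat_read_u32 <- function(r, at) {
  x <- readBin(r[at + 0:3], "integer", size = 4L, endian = "little")
  if (x < 0) x + 2^32 else as.numeric(x)
}

# Read one data element at `at`; returns list(type, data, nxt).
mat_read_element <- function(r, at) {
  if (at + 3L > length(r)) stop("malformed MAT file: truncated element",
                                call. = FALSE)
  small <- r[at + 2L] != 0 || r[at + 3L] != 0
  if (small) {
    type <- readBin(r[at + 0:1], "integer", size = 2L, endian = "little")
    nb <- readBin(r[at + 2:3], "integer", size = 2L, endian = "little")
    list(type = type, data = r[at + 4L + seq_len(nb) - 1L], nxt = at + 8L)
  } else {
    type <- mat_read_u32(r, at)
    nb <- mat_read_u32(r, at + 4L)
    data <- if (nb > 0) r[at + 8L + seq_len(nb) - 1L] else raw(0)
    used <- 8L + nb
    pad <- if (type == MI_COMPRESSED) 0 else (8 - used %% 8) %% 8
    list(type = type, data = data, nxt = at + used + pad)
  }
}

mat_decode_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = as.double(readBin(data, "integer", n = length(data), size = 1L,
                            signed = TRUE)),
    "2" = as.double(readBin(data, "integer", n = length(data), size = 1L,
                            signed = FALSE)),
    "3" = as.double(readBin(data, "integer", n = length(data) / 2L, size = 2L,
                            signed = TRUE, endian = "little")),
    "4" = as.double(readBin(data, "integer", n = length(data) / 2L, size = 2L,
                            signed = FALSE, endian = "little")),
    "5" = as.double(readBin(data, "integer", n = length(data) / 4L, size = 4L,
                            endian = "little")),
    "6" = vapply(seq_len(length(data) / 4L),
                 function(i) mat_read_u32(data, (i - 1L) * 4L + 1L), 0),
    "7" = readBin(data, "double", n = length(data) / 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(data, "double", n = length(data) / 8L, size = 8L,
                  endian = "little"),
    "12" = as.double(readBin(data, "double", n = length(data) / 8L, size = 8L,
                             endian = "little")),  # int64, approximate
    stop("unsupported MAT data type: ", type, call. = FALSE))
}

mat_parse_matrix <- function(data) {
  el <- mat_read_element(data, 1L)
  flags <- mat_read_u32(el$data, 1L)
  klass <- as.integer(flags %% 256)
  is_complex <- bitwAnd(as.integer(flags %/% 256), 8L) > 0L
  el2 <- mat_read_element(data, el$nxt)
  dims <- readBin(el2$data, "integer", n = length(el2$data) / 4L, size = 4L,
                  endian = "little")
  el3 <- mat_read_element(data, el2$nxt)
  name <- rawToChar(el3$data[el3$data != as.raw(0)])
  at <- el3$nxt
  value <- NULL
  if (klass %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                   MX_UINT16, MX_INT32, MX_UINT32)) {
    pr <- mat_read_element(data, at)
    v <- mat_decode_numeric(pr$type, pr$data)
    at <- pr$nxt
    if (is_complex) {
      pi_el <- mat_read_element(data, at)
      v <- complex(real = v, imaginary = mat_decode_numeric(pi_el$type,
                                                            pi_el$data))
    }
    value <- if (length(dims) > 2L || (length(dims) == 2L && all(dims > 1L))) {
      array(v, dims)
    } else v
  } else if (klass == MX_CHAR) {
    ch <- mat_read_element(data, at)
    codes <- if (ch$type == MI_UTF8) {
      utf8ToInt(rawToChar(ch$data))
    } else mat_decode_numeric(ch$type, ch$data)
    if (length(dims) == 2L && dims[1] > 1L) {
      m <- matrix(as.integer(codes), dims[1], dims[2])
      value <- apply(m, 1L, function(row) trimws(intToUtf8(row), "right"))
    } else {
      value <- intToUtf8(as.integer(codes))
    }
  } else if (klass == MX_CELL) {
    n <- prod(dims)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- mat_read_element(data, at)
      out[[i]] <- mat_parse_matrix(sub$data)$value
      at <- sub$nxt
    }
    if (n > 0 && all(vapply(out, function(x)
      is.character(x) && length(x) == 1L, TRUE))) {
      out <- unlist(out)
    }
    value <- out
  } else if (klass == MX_STRUCT) {
    fl <- mat_read_element(data, at)
    maxlen <- readBin(fl$data, "integer", size = 4L, endian = "little")
    fn <- mat_read_element(data, fl$nxt)
    nfields <- length(fn$data) %/% maxlen
    fields <- vapply(seq_len(nfields), function(i) {
      chunk <- fn$data[(i - 1L) * maxlen + seq_len(maxlen)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, "")
    at <- fn$nxt
    n <- prod(dims)
    records <- vector("list", n)
    for (e in seq_len(n)) {
      rec <- stats::setNames(vector("list", nfields), fields)
      for (f in seq_len(nfields)) {
        sub <- mat_read_element(data, at)
        rec[[f]] <- mat_parse_matrix(sub$data)$value
        at <- sub$nxt
      }
      records[[e]] <- rec
    }
    value <- if (n == 1L) records[[1]] else mat_struct_array(records)
  } else {
    stop("unsupported MAT array class: ", klass, call. = FALSE)
  }
  list(name = name, value = value)
}

#' Read a MATLAB level-5 file
#'
#' Reads the subset of the MAT-v5 format this package writes, plus
#' zlib-compressed elements and integer/single numeric storage produced by
#' other writers.
#'
#' @param path File path.
#' @return Named list of variables; structs become named lists, `1 x N`
#'   struct arrays become [mat_struct_array()] lists, cell arrays of strings
#'   become character vectors.
#' @seealso [write_mat()]
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 128L) stop("malformed MAT file: too short", call. = FALSE)
  endian <- rawToChar(r[127:128])
  if (endian != "IM") {
    stop("unsupported MAT file (big-endian or not a level-5 file)",
         call. = FALSE)
  }
  at <- 129L
  out <- list()
  while (at <= length(r)) {
    el <- mat_read_element(r, at)
    if (el$type == MI_COMPRESSED) {
      inflated <- memDecompress(el$data, type = "gzip")
      inner <- mat_read_element(inflated, 1L)
      if (inner$type != MI_MATRIX) {
        stop("malformed MAT file: unexpected compressed content",
             call. = FALSE)
      }
      parsed <- mat_parse_matrix(inner$data)
    } else if (el$type == MI_MATRIX) {
      parsed <- mat_parse_matrix(el$data)
    } else {
      at <- el$nxt
      next
    }
    out[[parsed$name]] <- parsed$value
    at <- el$nxt
  }
  out
}
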