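#' Read a weighted edge list
#'
#' TSV with 2 or 3 columns (source, target, weight); `#` starts a comment;
#' a missing weight column defaults to 1.
#' @param path file path
#' @param sym_tol symmetrization tolerance, see [weighted_graph()]
#' @return a `weighted_graph`
#' @export
read_edge_list <- function(path, sym_tol = 1e-8) {
  edges <- utils::read.table(path, header = FALSE, sep = "",
                             comment.char = "#",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  if (ncol(edges) >= 3L) edges[[3L]] <- as.numeric(edges[[3L]])
  graph_from_edges(edges, sym_tol = sym_tol)
}

#' Read a dense matrix from CSV
#'
#' Detects an optional header row and label column (first cell empty or
#' non-numeric).  `kind` controls the conversion to a graph:
#' `"weight"` uses entries as edge weights, `"distance"` applies the
#' Gaussian affinity of [affinity_from_distance()], `"similarity"` uses
#' entries directly as weights with the diagonal zeroed.
#'
#' @param path CSV path
#' @param kind one of `"weight"`, `"distance"`, `"similarity"`
#' @param ... passed to [affinity_from_distance()] for `kind = "distance"`
#' @return a `weighted_graph`
#' @export
read_dense_graph <- function(path, kind = c("weight", "distance", "similarity"),
                             ...) {
  kind <- match.arg(kind)
  M <- read_matrix_csv(path)
  switch(kind,
         weight = graph_from_dense(M),
         distance = affinity_from_distance(M, ...),
         similarity = affinity_from_similarity(M))
}

#' Read a numeric matrix from CSV (optional header row / label column)
#' @param path CSV path
#' @return numeric matrix, with dimnames when labels are present
#' @export
read_matrix_csv <- function(path) {
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, ",", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells))) ||
    cells[1L] == ""
  df <- utils::read.csv(path, header = has_header, check.names = FALSE,
                        stringsAsFactors = FALSE)
  first_col_labels <- anyNA(suppressWarnings(as.numeric(df[[1L]]))) ||
    (has_header && (colnames(df)[1L] %in% c("", "label", "X")))
  if (first_col_labels) {
    labs <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
    rownames(M) <- labs
  } else {
    M <- as.matrix(df)
    rownames(M) <- if (has_header) colnames(M) else NULL
  }
  storage.mode(M) <- "double"
  M
}

#' Write a numeric matrix as CSV with labels
#' @param M matrix
#' @param path output path
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(label = if (!is.null(rownames(M))) rownames(M) else
    as.character(seq_len(nrow(M))), M, check.names = FALSE)
  colnames(df) <- c("label", if (!is.null(colnames(M))) colnames(M) else
    as.character(seq_len(ncol(M))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read an MRC image stack (mode 2, 32-bit float)
#'
#' Minimal reader for the standard MRC2014 layout: 1024-byte header, then
#' `nx * ny * nz` little-endian floats.  Only mode 2 is supported.
#' @param path MRC file
#' @return list of `nz` matrices of dimension `nx x ny`
#' @export
read_mrc_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported, got mode ", mode)
  seek(con, 1024)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  lapply(seq_len(nz), function(k)
    matrix(vals[((k - 1) * nx * ny + 1):(k * nx * ny)], nx, ny))
}

#' Write a list of images as an MRC stack (mode 2)
#' @param images list of equal-size numeric matrices
#' @param path output path
#' @export
write_mrc_stack <- function(images, path) {
  nx <- nrow(images[[1L]]); ny <- ncol(images[[1L]]); nz <- length(images)
  con <- file(path, "wb")
  on.exit(close(con))
  all_vals <- unlist(lapply(images, as.vector))
  hdr_int <- integer(256)
  hdr_int[1:4] <- c(nx, ny, nz, 2L)
  hdr_int[8:10] <- c(nx, ny, nz)   # mx, my, mz
  writeBin(hdr_int[1:10], con, size = 4, endian = "little")
  # cell dims as floats
  writeBin(as.numeric(c(nx, ny, nz, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(all_vals), max(all_vals), mean(all_vals))), con,
           size = 4, endian = "little")
  writeBin(integer(256 - 22), con, size = 4, endian = "little")
  writeBin(all_vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read projection images from an MRC stack or a directory of CSV grids
#' @param path `.mrc` file or a directory containing `*.csv` grids (one
#'   image per file, plain numeric CSV, no header)
#' @return list of matrices
#' @export
read_image_set <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no .csv images in ", path)
    lapply(files, function(f)
      as.matrix(utils::read.csv(f, header = FALSE)))
  } else if (grepl("\\.mrc$", path, ignore.case = TRUE)) {
    read_mrc_stack(path)
  } else stop("expected an .mrc stack or a directory of .csv grids: ", path)
}
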