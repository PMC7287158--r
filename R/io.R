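# File I/O: NPY arrays (v1.0, little-endian), CSV matrices, JSON results.
# The NPY reader/writer is implemented here directly (it is a small fixed
# binary layout: magic, version, Python-dict header, raw data in
# Fortran/C order).

#' Read / write NumPy .npy arrays
#'
#' Minimal NPY v1.0 support for the numeric dtypes used by this package:
#' little-endian float64/float32 and integer arrays, C or Fortran order.
#' Round-trips are lossless for double-precision data.
#'
#' @param path file path.
#' @return \code{readNpy}: a numeric array (R dimension order matches the
#'   NumPy shape).
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stopf("'%s' is not an NPY file", path)
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else readBin(con, "integer", 1L, size = 2L, signed = FALSE,
               endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  getField <- function(name) {
    m <- regmatches(header, regexpr(paste0("'", name, "':\\s*[^,}]+(\\([^)]*\\))?"),
                                    header))
    sub(paste0("'", name, "':\\s*"), "", m)
  }
  descr <- gsub("'", "", getField("descr"))
  fortran <- grepl("True", getField("fortran_order"))
  shapeStr <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shape <- as.integer(strsplit(gsub("[^0-9,]", "", shapeStr), ",")[[1]])
  shape <- shape[!is.na(shape)]
  nElem <- prod(shape)
  code <- substr(descr, nchar(descr) - 1L, nchar(descr))
  vals <- switch(code,
    f8 = readBin(con, "double", nElem, size = 8L, endian = "little"),
    f4 = readBin(con, "double", nElem, size = 4L, endian = "little"),
    i8 = readBin(con, "double", nElem, size = 8L, endian = "little"),
    i4 = readBin(con, "integer", nElem, size = 4L, endian = "little"),
    i2 = readBin(con, "integer", nElem, size = 2L, endian = "little"),
    stopf("unsupported NPY dtype '%s'", descr))
  if (length(shape) <= 1L) return(as.numeric(vals))
  if (fortran) array(vals, dim = shape)
  else aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
}

#' @rdname readNpy
#' @param x numeric vector, matrix, or array.
#' @export
writeNpy <- function(x, path) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%s), }",
                    if (length(shape) == 1L) paste0(shape, ",")
                    else paste(shape, collapse = ", "))
  # pad so that magic(6)+version(2)+len(2)+header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a data array from CSV (2-D) or NPY (N-D)
#'
#' CSV files are parsed with a period decimal separator regardless of
#' locale; a non-numeric first row is used as feature names. Dimension
#' roles default to samples on axis 1, features on axis 2, search on any
#' further axes, and can be overridden.
#'
#' @param path path to a .csv or .npy file.
#' @param dimRoles optional dimension roles for the resulting
#'   \linkS4class{DecodingData}.
#' @return a \linkS4class{DecodingData}.
#' @export
loadArray <- function(path, dimRoles = NULL) {
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    arr <- readNpy(path)
    return(DecodingData(as.array(arr), dimRoles = dimRoles))
  }
  first <- readLines(path, n = 1L)
  hasHeader <- suppressWarnings(
    any(is.na(as.numeric(strsplit(first, ",")[[1]]))))
  tab <- utils::read.csv(path, header = hasHeader, dec = ".",
                         colClasses = "numeric")
  X <- as.matrix(tab)
  d <- DecodingData(X, dimRoles = dimRoles)
  if (hasHeader) d@dimCoords[[2L]] <- colnames(tab)
  d
}

#' @rdname loadArray
#' @return \code{loadTargets}: numeric vector read from a single-column
#'   CSV (header optional).
#' @export
loadTargets <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- suppressWarnings(is.na(as.numeric(trimws(first))))
  drop(as.matrix(utils::read.csv(path, header = hasHeader,
                                 colClasses = "numeric")))
}

#' Save decoding or test results to files
#'
#' Writes a \linkS4class{DecodingResult} as one NPY array per metric with
#' a JSON sidecar (configuration echo, dimensions, coordinates) and a CSV
#' summary; or a \linkS4class{StatTestResult} as a JSON report (p-values,
#' clusters, parameters) plus NPY mask/statistic arrays.
#'
#' @param x a \code{DecodingResult} or \code{StatTestResult}.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the vector of files written.
#' @export
saveResults <- function(x, prefix) {
  written <- character(0)
  if (is(x, "DecodingResult")) {
    for (nm in names(x@metrics)) {
      val <- x@metrics[[nm]]
      if (is.numeric(val)) {
        f <- paste0(prefix, "_", nm, ".npy")
        writeNpy(val, f)
        written <- c(written, f)
      }
    }
    side <- list(metrics = names(x@metrics), dims = x@dims,
                 coords = x@coords,
                 cfg = x@cfg[setdiff(names(x@cfg), "foldPlan")])
    f <- paste0(prefix, "_result.json")
    jsonlite::write_json(side, f, auto_unbox = TRUE, null = "null",
                         digits = NA, force = TRUE)
    written <- c(written, f)
    sumf <- paste0(prefix, "_summary.csv")
    scalars <- Filter(function(nm) is.numeric(x@metrics[[nm]]),
                      names(x@metrics))
    rows <- do.call(rbind, lapply(scalars, function(nm) {
      v <- x@metrics[[nm]]
      data.frame(metric = nm, element = seq_along(v),
                 value = as.numeric(v))
    }))
    utils::write.csv(rows, sumf, row.names = FALSE)
    written <- c(written, sumf)
  } else if (is(x, "StatTestResult")) {
    rep <- list(method = x@method, alpha = x@alpha,
                nPermutations = x@nPermutations,
                p = as.numeric(x@p),
                statistic = as.numeric(x@statistic),
                clusters = lapply(x@clusters, function(cl)
                  list(members = cl$members, statistic = cl$statistic,
                       p = cl$p)))
    f <- paste0(prefix, "_stats.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
    fm <- paste0(prefix, "_mask.npy")
    writeNpy(as.numeric(x@mask), fm)
    written <- c(written, fm)
  } else stopf("cannot save object of class %s", class(x)[1L])
  invisible(written)
}

#' Export a volumetric metric map as NIfTI
#'
#' Writes a 3-D searchlight metric map (e.g. a voxel-wise AUC map) to a
#' NIfTI file for viewing in standard neuroimaging tools. Requires the
#' suggested RNifti package.
#'
#' @param map 3-D numeric array of metric values on the voxel grid.
#' @param path output path (.nii or .nii.gz).
#' @param voxelSize numeric length-3 voxel dimensions in mm.
#' @return invisibly, the path written.
#' @export
exportNifti <- function(map, path, voxelSize = c(1, 1, 1)) {
  if (length(dim(map)) != 3L) stopf("expected a 3-D voxel-grid map")
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("NIfTI export requires the RNifti package")
  img <- RNifti::asNifti(map, pixdim = voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}
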