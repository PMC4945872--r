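# Plain-text formats: rasters as CSV(0/1) or PGM (P2, maxval 1) with a
# JSON sidecar, result tables as TSV, images via PNG/TIFF readers.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(raster, path, provenance = list()) {
  meta <- c(list(cell_size_um = raster@cellSizeUm,
                 n_rows = nrow(raster@occupancy),
                 n_cols = ncol(raster@occupancy)),
            provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar_cell <- function(path, cellSizeUm) {
  if (!is.null(cellSizeUm)) return(cellSizeUm)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp)
    if (!is.null(meta$cell_size_um)) return(as.numeric(meta$cell_size_um))
  }
  18.4
}

#' Read and write raster maps
#'
#' Rasters travel as plain text: either CSV of 0/1 values (one row per
#' grid row, no header) or PGM "P2" images with maxval 1.  A JSON sidecar
#' (`<path>.json`) carries the physical cell size and any provenance the
#' caller supplies (threshold, bin factor, geometry); reading picks the
#' cell size up from the sidecar when present.
#'
#' @param raster a [RasterMap-class].
#' @param path file path; format inferred from the `.csv` / `.pgm`
#'   extension unless `format` is given.
#' @param format `"auto"`, `"csv"` or `"pgm"`.
#' @param sidecar write the JSON sidecar? (default `TRUE`).
#' @param provenance named list stored in the sidecar.
#' @param cellSizeUm override for the physical cell size when reading.
#' @return `readRasterMap` returns a [RasterMap-class];
#'   `writeRasterMap` returns `path` invisibly.
#' @export
writeRasterMap <- function(raster, path, format = c("auto", "csv", "pgm"),
                           sidecar = TRUE, provenance = list()) {
  stopifnot(is(raster, "RasterMap"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pgm$", path, ignore.case = TRUE)) "pgm" else "csv"
  }
  occ <- raster@occupancy * 1L
  if (format == "csv") {
    write.table(occ, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    lines <- c("P2",
               sprintf("# coralPCF raster, cell_size_um=%.17g", raster@cellSizeUm),
               sprintf("%d %d", ncol(occ), nrow(occ)),
               "1",
               apply(occ, 1, paste, collapse = " "))
    writeLines(lines, path)
  }
  if (sidecar) write_sidecar(raster, path, provenance)
  invisible(path)
}

#' @rdname writeRasterMap
#' @export
readRasterMap <- function(path, format = c("auto", "csv", "pgm"),
                          cellSizeUm = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pgm$", path, ignore.case = TRUE)) "pgm" else "csv"
  }
  if (format == "csv") {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    parsed <- lapply(seq_along(rows), function(i) {
      v <- strsplit(rows[i], ",", fixed = TRUE)[[1]]
      x <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(x) | !(x %in% c(0, 1)))
      if (length(bad)) {
        stop(sprintf("parse error in %s: line %d, field %d is not 0/1",
                     path, i, bad[1]), call. = FALSE)
      }
      x
    })
    if (length(unique(lengths(parsed))) != 1L) {
      stop(sprintf("parse error in %s: ragged rows", path), call. = FALSE)
    }
    occ <- do.call(rbind, parsed) == 1
  } else {
    tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (length(tok) < 4L || tok[1] != "P2") {
      stop(sprintf("parse error in %s: expected plain PGM magic 'P2'", path),
           call. = FALSE)
    }
    nc <- as.integer(tok[2]); nr <- as.integer(tok[3]); maxval <- as.integer(tok[4])
    if (is.na(maxval) || maxval != 1L) {
      stop(sprintf("parse error in %s: PGM maxval must be 1 (got '%s')",
                   path, tok[4]), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok[-(1:4)]))
    if (length(vals) != nr * nc || anyNA(vals) || !all(vals %in% c(0, 1))) {
      stop(sprintf("parse error in %s: expected %d 0/1 samples", path, nr * nc),
           call. = FALSE)
    }
    occ <- matrix(vals == 1, nr, nc, byrow = TRUE)
  }
  RasterMap(occ, cellSizeUm = read_sidecar_cell(path, cellSizeUm))
}

#' Read and write g(r) tables
#'
#' [PcfResult-class] objects are stored as TSV with the columns
#' `r_cells`, `r_um`, `g`, `n_focal`, `n_pairs`, `valid`, preceded by
#' `#`-comment metadata lines holding the estimator settings, so
#' write-then-read is lossless.
#'
#' @param pcf a [PcfResult-class].
#' @param path file path.
#' @return `readPcfTable` returns a [PcfResult-class]; `writePcfTable`
#'   returns `path` invisibly.
#' @export
writePcfTable <- function(pcf, path) {
  stopifnot(is(pcf, "PcfResult"))
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    "# coralPCF PcfResult",
    paste0("# overall_density: ", num(pcf@overallDensity)),
    paste0("# annulus_width_cells: ", num(pcf@annulusWidthCells)),
    paste0("# min_focal_cells: ", pcf@minFocalCells),
    paste0("# cell_size_um: ", num(pcf@cellSizeUm)),
    paste0("# ring_cells: ", paste(pcf@ringCells, collapse = " "))
  )
  tb <- pcf@table
  body <- c(paste(names(tb), collapse = "\t"),
            vapply(seq_len(nrow(tb)), function(i) {
              paste(c(num(tb$r_cells[i]), num(tb$r_um[i]), num(tb$g[i]),
                      tb$n_focal[i], num(tb$n_pairs[i]),
                      ifelse(tb$valid[i], "TRUE", "FALSE")),
                    collapse = "\t")
            }, character(1)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writePcfTable
#' @export
readPcfTable <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(lines, "#")]
  meta_of <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), com, value = TRUE)
    if (!length(hit)) stop(sprintf("parse error in %s: missing '%s' header",
                                   path, key), call. = FALSE)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  tb <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  need <- c("r_cells", "r_um", "g", "n_focal", "n_pairs", "valid")
  if (!all(need %in% names(tb))) {
    stop(sprintf("parse error in %s: missing columns", path), call. = FALSE)
  }
  tb <- tb[need]
  tb$n_focal <- as.integer(tb$n_focal)
  tb$valid <- as.logical(tb$valid)
  new("PcfResult", table = tb,
      ringCells = as.integer(strsplit(meta_of("ring_cells"), " ")[[1]]),
      overallDensity = as.numeric(meta_of("overall_density")),
      annulusWidthCells = as.numeric(meta_of("annulus_width_cells")),
      minFocalCells = as.integer(meta_of("min_focal_cells")),
      cellSizeUm = as.numeric(meta_of("cell_size_um")))
}

#' Write a classified g(r) curve as TSV
#'
#' Columns: `r_um`, `g`, `ci_lo`, `ci_hi`, `n_focal`, `classification`.
#'
#' @param ci a [CiResult-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCiTable <- function(ci, path) {
  stopifnot(is(ci, "CiResult"))
  tb <- ci@pcf@table
  out <- data.frame(r_um = tb$r_um, g = tb$g, ci_lo = ci@ciLo, ci_hi = ci@ciHi,
                    n_focal = tb$n_focal, classification = ci@classification)
  write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a critical-scale summary as JSON
#'
#' @param scales a [ScaleSummary-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeScaleSummary <- function(scales, path) {
  stopifnot(is(scales, "ScaleSummary"))
  jsonlite::write_json(
    list(aggregation_extent_um = scales@aggregationExtentUm,
         dip_radius_um = scales@dipRadiusUm,
         dip_g = scales@dipG,
         return_radius_um = scales@returnRadiusUm,
         homogeneous = scales@homogeneous),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an RGB image from PNG or TIFF
#'
#' 8- or 16-bit images are returned as numeric arrays with intensities in
#' \[0,1\]; an alpha channel, if present, is dropped.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return numeric array (height, width, 3).
#' @export
readImageRGB <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop(sprintf("%s is not an RGB image", path), call. = FALSE)
  }
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB image or a binary mask as PNG
#'
#' @param image numeric RGB array or logical mask matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  if (is.logical(image)) image <- image * 1
  png::writePNG(clamp01(image), path)
  invisible(path)
}
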