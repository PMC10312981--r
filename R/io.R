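#' Read a multichannel marker image from a (multipage) TIFF
#'
#' One 2D plane per listed marker, in file order. Intensities are loaded as
#' floating point; values are exact at the precision of the on-disk sample
#' type (integer bit depths round-trip exactly, 32-bit float at float32
#' precision).
#'
#' @param path TIFF file, one page per channel.
#' @param channelNames marker name for each page, in order.
#' @param pixelSize micrometres per pixel.
#' @param modality `"fluorescence"` or `"imc"`.
#' @param scale factor recovering raw intensities from the TIFF's
#'   `[0, 1]`-normalized samples. `NULL` (default) picks `2^bits - 1` for
#'   8/16-bit pages and 65536 for 32-bit pages, matching the conventions of
#'   [writeMarkerImage()].
#' @return a [MarkerImage-class]
#' @export
readMarkerImage <- function(path, channelNames, pixelSize = 1,
                            modality = c("fluorescence", "imc"),
                            scale = NULL) {
  modality <- match.arg(modality)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channelNames))
    stop("channel count mismatch: file has ", length(pages),
         " plane(s), ", length(channelNames), " name(s) given")
  channels <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    s <- if (!is.null(scale)) scale
         else if (!is.null(bits) && bits < 32L) 2^bits - 1
         else 65536
    m <- if (length(dim(p)) == 3L) p[, , 1L] else p
    m <- matrix(as.numeric(m) * s, nrow(m), ncol(m))
    m
  })
  if (any(vapply(channels, function(m) any(m < 0), logical(1L))))
    stop("negative pixel values are not allowed in a MarkerImage")
  names(channels) <- channelNames
  MarkerImage(channels, pixelSize = pixelSize, modality = modality)
}

#' Write a MarkerImage as a multipage TIFF
#'
#' Integer-valued images (raw detector counts) are stored as 16-bit samples
#' and round-trip bit-exactly. Images with fractional intensities are
#' stored as 32-bit samples scaled by 1/65536, quantized at 2^-32 of full
#' scale (absolute error below 1.6e-5); [readMarkerImage()] undoes the
#' scaling by default.
#'
#' @param image a [MarkerImage-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeMarkerImage <- function(image, path) {
  ch <- unname(image@channels)
  mx <- max(vapply(ch, max, numeric(1L)))
  if (mx >= 65536)
    stop("intensities must be below 65536 for the TIFF contract")
  integral <- all(vapply(ch, function(m) all(m == round(m)), logical(1L)))
  if (integral && mx <= 65535) {
    tiff::writeTIFF(lapply(ch, function(m) m / 65535), path,
                    bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(lapply(ch, function(m) m / 65536), path,
                    bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Read / write an integer cell label mask
#'
#' 16- or 32-bit integer TIFF, or 16-bit PNG; 0 is background.
#'
#' @param path mask file (.tif/.tiff/.png).
#' @return a [LabelMask-class]
#' @export
readLabelMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    ## readPNG normalizes to [0,1]; recover the scale from the IHDR bit depth
    bits <- as.integer(readBin(path, "raw", 25L)[25L])
    lab <- round(m * (2^bits - 1))
  } else {
    m <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(m, "bits.per.sample")
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    lab <- round(m * (2^(if (is.null(bits)) 16L else bits) - 1))
  }
  LabelMask(matrix(as.integer(lab), nrow(lab), ncol(lab)))
}

#' @rdname readLabelMask
#' @param mask a [LabelMask-class]
#' @export
writeLabelMask <- function(mask, path) {
  lab <- labelMatrix(mask)
  if (max(lab) > 65535L)
    stop("label masks support up to 65535 cell instances (16-bit contract)")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    ## writePNG emits 8-bit samples; larger label ranges use the TIFF path
    if (max(lab) > 255L)
      stop("PNG masks support up to 255 cell instances; use TIFF")
    png::writePNG(lab / 255, path)
  } else {
    tiff::writeTIFF(matrix(lab / 65535, nrow(lab), ncol(lab)), path,
                    bits.per.sample = 16L)
  }
  invisible(path)
}

#' log2(x + 1) preprocessing of raw IMC channels
#'
#' Mitigates the bias of isolated strong pixels in imaging mass cytometry by
#' log-transforming every channel in place. Low-intensity pixels are kept:
#' no noise floor is subtracted or thresholded, since the synapse score
#' compares contact against non-contact membrane and handles background
#' implicitly.
#'
#' @param image a [MarkerImage-class] with `modality == "imc"`
#' @return the transformed [MarkerImage-class] (flagged so a second
#'   application errors)
#' @examples
#' img <- MarkerImage(list(CD3 = matrix(c(0, 1, 7, 3), 2, 2)),
#'                    modality = "imc")
#' getChannel(imcPreprocess(img), "CD3")  # 0 -> 0, 1 -> 1, 7 -> 3
#' @export
imcPreprocess <- function(image) {
  if (modality(image) != "imc")
    stop("imcPreprocess applies to IMC images only")
  if (image@logTransformed)
    stop("image is already log2(x+1) transformed")
  image@channels <- lapply(image@channels, function(m) log2(m + 1))
  image@logTransformed <- TRUE
  image
}

#' Build a cell table from a mask (and optionally an image)
#'
#' Computes per-cell area, centroid (micrometres; x = column * pixel size,
#' y = row * pixel size, 0-based pixel grid) and, when an image is given,
#' mean intensity per channel over the whole cell area.
#'
#' @param mask a [LabelMask-class]
#' @param image optional [MarkerImage-class] for channel means
#' @param pixelSize um per pixel; taken from `image` when supplied
#' @return data.frame with columns `id`, `x_um`, `y_um`, `area_px`, `types`
#'   (";"-joined labels, empty when unannotated), `region`, and
#'   `mean_<marker>` columns
#' @export
makeCellTable <- function(mask, image = NULL, pixelSize = 1) {
  lab <- labelMatrix(mask)
  if (!is.null(image)) {
    if (!identical(dim(lab), dim(image)))
      stop("mask and image shapes differ")
    pixelSize <- pixelSize(image)
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  nr <- nrow(lab)
  row0 <- (idx - 1L) %% nr
  col0 <- (idx - 1L) %/% nr
  tab <- data.frame(
    id = sort(unique(ids)),
    x_um = as.vector(tapply(col0, ids, mean)) * pixelSize,
    y_um = as.vector(tapply(row0, ids, mean)) * pixelSize,
    area_px = as.vector(tapply(ids, ids, length)),
    types = "",
    region = "none",
    stringsAsFactors = FALSE
  )
  if (!is.null(image)) {
    for (ch in channelNames(image)) {
      v <- getChannel(image, ch)[idx]
      tab[[paste0("mean_", ch)]] <- as.vector(tapply(v, ids, mean))
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Read / validate a cell annotation table
#'
#' Expected CSV headers: `id` (positive integer), `x_um`, `y_um`, `types`
#' (";"-joined labels; multi-label cells such as CD3+CD14+ undersegmentation
#' artifacts are retained with all labels), optional `region`, `ki67`,
#' `loaded` and `mean_<marker>` columns.
#'
#' @param path CSV file
#' @param mask optional [LabelMask-class] to validate ids against
#' @return validated data.frame
#' @export
readCellTable <- function(path, mask = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCellTable(tab, mask)
}

#' @rdname readCellTable
#' @param cellTable a cell table data.frame
#' @export
validateCellTable <- function(cellTable, mask = NULL) {
  if (!"id" %in% names(cellTable)) stop("cell table needs an 'id' column")
  if (anyDuplicated(cellTable$id))
    stop("duplicate cell ids: ",
         paste(unique(cellTable$id[duplicated(cellTable$id)]), collapse = ", "))
  if (any(cellTable$id <= 0)) stop("cell ids must be positive")
  if (!is.null(mask)) {
    missing <- setdiff(cellTable$id, cellIds(mask))
    if (length(missing))
      stop("ids absent from mask: ", paste(missing, collapse = ", "))
  }
  mu <- grep("^mean_", names(cellTable), value = TRUE)
  for (col in mu)
    if (any(cellTable[[col]] < 0, na.rm = TRUE))
      stop("channel means must be >= 0 (", col, ")")
  if (is.null(cellTable$types)) cellTable$types <- ""
  cellTable$types[is.na(cellTable$types)] <- ""
  if (is.null(cellTable$region)) cellTable$region <- "none"
  cellTable
}

#' @rdname readCellTable
#' @export
writeCellTable <- function(cellTable, path) {
  utils::write.csv(cellTable, path, row.names = FALSE)
  invisible(path)
}

#' Write a result table with a JSON run-metadata sidecar
#'
#' Writes `records` as flat CSV at full precision (one row per cell-pair and
#' marker, or per aggregate) plus `<path>.meta.json` recording the
#' configuration, seed and package version.
#'
#' @param records data.frame of results
#' @param path output CSV
#' @param config optional [AnalysisConfig-class] snapshot for the sidecar
#' @param extra named list merged into the sidecar
#' @return `path`, invisibly
#' @export
writeResults <- function(records, path, config = NULL, extra = list()) {
  drop <- vapply(records, is.list, logical(1L))
  utils::write.csv(records[, !drop, drop = FALSE], path, row.names = FALSE)
  meta <- c(list(
    package = "cisa",
    version = as.character(utils::packageVersion("cisa")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  if (!is.null(config)) meta$config <- configAsList(config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

configAsList <- function(config) {
  sn <- slotNames(class(config))
  stats::setNames(lapply(sn, function(s) slot(config, s)), sn)
}

#' Read an AnalysisConfig from a YAML file
#'
#' Field names mirror the [cisaConfig()] arguments.
#' @param path YAML file
#' @return an [AnalysisConfig-class]
#' @export
readCisaConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cisaConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(cisaConfig, vals)
}
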