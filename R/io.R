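## Readers and writers. Conventions, enforced everywhere: CSV is
## comma-separated UTF-8 with a mandatory header and "." decimal; mosaics are
## single-plane grayscale TIFF; transforms and probability vectors are JSON;
## depths are micrometres from the apical surface, increasing basally.

#' Read a grayscale mosaic TIFF
#'
#' Loads a single-plane grayscale TIFF. Multi-channel input is reduced to its
#' first channel with a warning.
#'
#' @param path TIFF file path.
#' @param pixelSize micrometres per pixel.
#' @param modality,frameId passed to [mosaicImage()]; \code{frameId} defaults
#'   to the file name without extension.
#' @return a [MosaicImage-class].
#' @export
readMosaic <- function(path, pixelSize = 1,
                       modality = c("live-brightfield",
                                    "fixed-fluorescence-tile-scan"),
                       frameId = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("mosaic file not found: ", path)
  px <- tryCatch(tiff::readTIFF(path),
                 error = function(e) stop("cannot read TIFF '", path, "': ",
                                          conditionMessage(e)))
  if (length(dim(px)) == 3L) {
    warning("multi-channel TIFF '", path, "': using first channel")
    px <- px[, , 1]
  }
  if (length(px) == 0) stop("zero-sized image: ", path)
  if (is.null(frameId)) frameId <- sub("\\.[^.]*$", "", basename(path))
  mosaicImage(px, pixelSize, modality, frameId)
}

#' @rdname readMosaic
#' @param img a [MosaicImage-class] or numeric matrix in [0, 1].
#' @export
writeMosaic <- function(img, path) {
  px <- if (is(img, "MosaicImage")) img@pixels else img
  tiff::writeTIFF(px, path, bits.per.sample = 8L)
  invisible(path)
}

.MARKER_COLS <- c("d1_sox2", "d1_eomes", "d1_neun",
                  "d2_sox2", "d2_eomes", "d2_neun")
.FLAG_COLS <- c("d1_process_inherited", "d1_hes1_detected",
                "d2_process_inherited", "d2_hes1_detected")
.DIV_MANDATORY <- c("division_id", "stage", "depth_um", .MARKER_COLS,
                    .FLAG_COLS, "mst")

#' Read or write a division-record table
#'
#' CSV with one row per division. Mandatory columns: \code{division_id},
#' \code{stage}, \code{depth_um}, marker columns \code{d1_sox2} ...
#' \code{d2_neun} (tokens \code{pos}/\code{neg}/\code{na}), logical flag
#' columns \code{d*_process_inherited}, \code{d*_hes1_detected}, and
#' \code{mst}. Unknown columns are preserved. Row-level validation errors are
#' collected and reported together with line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of division records.
#' @export
readDivisionTable <- function(path) {
  if (!file.exists(path)) stop("division table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DIV_MANDATORY, names(df))
  if (length(missing))
    stop("division table schema error; missing column(s) ",
         paste(missing, collapse = ", "), ". Expected header: ",
         paste(.DIV_MANDATORY, collapse = ","))
  errs <- character()
  for (col in .MARKER_COLS) {
    bad <- which(!df[[col]] %in% c("pos", "neg", "na"))
    if (length(bad))
      errs <- c(errs, sprintf(
        "line %d: %s = '%s' (allowed tokens: pos|neg|na)",
        bad + 1L, col, df[[col]][bad]))
  }
  for (col in .FLAG_COLS) {
    v <- df[[col]]
    if (!is.logical(v)) {
      parsed <- toupper(as.character(v)) %in% c("TRUE", "T", "1")
      known <- toupper(as.character(v)) %in%
        c("TRUE", "T", "1", "FALSE", "F", "0")
      bad <- which(!known)
      if (length(bad))
        errs <- c(errs, sprintf("line %d: %s = '%s' (expected TRUE/FALSE)",
                                bad + 1L, col, as.character(v)[bad]))
      df[[col]] <- parsed
    }
  }
  if (length(errs))
    stop("invalid division table '", path, "':\n  ",
         paste(errs, collapse = "\n  "))
  df$depth_um <- as.numeric(df$depth_um)
  df
}

#' @rdname readDivisionTable
#' @param records data.frame of division records.
#' @export
writeDivisionTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a fate-probability vector as JSON
#'
#' JSON object with keys \code{p_AA}, \code{p_AB}, \code{p_AC}, \code{p_BB},
#' \code{p_CC}.
#'
#' @param path JSON file path.
#' @return a [FateProbabilities-class].
#' @export
readFateProbabilities <- function(path) {
  if (!file.exists(path)) stop("probabilities file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("p_AA", "p_AB", "p_AC", "p_BB", "p_CC")
  if (!all(need %in% names(j)))
    stop("probabilities JSON must have keys ", paste(need, collapse = ", "))
  fateProbabilities(j$p_AA, j$p_AB, j$p_AC, j$p_BB, j$p_CC)
}

#' @rdname readFateProbabilities
#' @param p a [FateProbabilities-class].
#' @export
writeFateProbabilities <- function(p, path) {
  stopifnot(is(p, "FateProbabilities"))
  v <- probVector(p)
  jsonlite::write_json(as.list(setNames(v, paste0("p_", names(v)))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a transform as JSON
#'
#' JSON object with keys \code{rotation_deg}, \code{scale}, \code{tx},
#' \code{ty}, \code{mirror}, \code{residual_rms}.
#'
#' @param path JSON file path.
#' @return a [Transform2D-class].
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform2D(j$rotation_deg, j$scale, j$tx, j$ty, j$mirror,
              j$residual_rms %||% NA_real_)
}

#' @rdname readTransform
#' @param t a [Transform2D-class].
#' @export
writeTransform <- function(t, path) {
  stopifnot(is(t, "Transform2D"))
  jsonlite::write_json(list(rotation_deg = t@rotation, scale = t@scale,
                            tx = t@tx, ty = t@ty, mirror = t@mirror,
                            residual_rms = t@residualRMS),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.polyToWkt <- function(poly) {
  ring <- rbind(poly, poly[1, ])
  sprintf("POLYGON((%s))",
          paste(sprintf("%.4f %.4f", ring[, 1], ring[, 2]), collapse = ", "))
}

.wktToPoly <- function(wkt) {
  inner <- sub("^POLYGON\\(\\(", "", sub("\\)\\)$", "", wkt))
  parts <- strsplit(strsplit(inner, ",\\s*")[[1]], "\\s+")
  poly <- do.call(rbind, lapply(parts, as.numeric))
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  colnames(poly) <- c("x", "y")
  poly
}

#' Read or write slice contours as CSV
#'
#' Columns: \code{slice_id}, \code{source}, \code{area_um2},
#' \code{centroid_x}, \code{centroid_y}, \code{pixel_size_um},
#' \code{polygon} (well-known-text string) and descriptor components
#' \code{d1} ... \code{d7}.
#'
#' @param path CSV file path.
#' @return list of [SliceContour-class].
#' @export
readContours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(k) {
    poly <- .wktToPoly(df$polygon[k])
    new("SliceContour", sliceId = df$slice_id[k], source = df$source[k],
        polygon = poly, pixelSize = df$pixel_size_um[k],
        area = df$area_um2[k],
        centroid = c(df$centroid_x[k], df$centroid_y[k]),
        descriptor = as.numeric(df[k, sprintf("d%d", 1:7)]))
  })
}

#' @rdname readContours
#' @param contours list of [SliceContour-class].
#' @export
writeContours <- function(contours, path) {
  rows <- lapply(contours, function(ct) {
    d <- as.list(setNames(ct@descriptor, sprintf("d%d", 1:7)))
    cbind(data.frame(slice_id = ct@sliceId, source = ct@source,
                     area_um2 = ct@area, centroid_x = ct@centroid[1],
                     centroid_y = ct@centroid[2],
                     pixel_size_um = ct@pixelSize,
                     polygon = .polyToWkt(ct@polygon),
                     stringsAsFactors = FALSE),
          as.data.frame(d))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname readContours
#' @param pairing a [SlicePairing-class].
#' @export
writePairing <- function(pairing, path) {
  stopifnot(is(pairing, "SlicePairing"))
  utils::write.csv(pairing@pairs, path, row.names = FALSE)
  invisible(path)
}
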