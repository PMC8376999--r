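# File-based image input and the directory-level ROI stage.

#' Read a fish photograph
#'
#' Reads a PNG/TIFF/JPEG image into the structure the pipeline consumes.
#'
#' @param path Image file.
#' @param fish_id,session Optional labels (e.g. from a manifest).
#' @return A `fish_image` (without ground-truth metadata).
#' @export
read_fish_image <- function(path, fish_id = NA, session = NA) {
  img <- EBImage::readImage(path)
  d <- dim(EBImage::imageData(img))
  if (length(d) == 2) {
    g <- EBImage::imageData(img)
    arr <- array(g, c(d[1], d[2], 3))
  } else {
    arr <- EBImage::imageData(img)[, , 1:3, drop = FALSE]
  }
  structure(list(img = arr, fish_id = fish_id, session = session,
                 scene = NULL, truth = NULL, path = path),
            class = "fish_image")
}

#' Extract ROIs for a directory of images
#'
#' Runs the full ROI pipeline on every image of a directory (or of a
#' `manifest.csv` with an `image_path` column) and writes, per image, the
#' normalized ROI as PNG plus a JSON sidecar with the landmarks, ROI offset
#' and scale.
#'
#' @param input_dir Directory of PNG/TIFF/JPEG images (a `manifest.csv`
#'   inside is used when present).
#' @param output_dir Output directory, created if missing.
#' @param config [roi_config()].
#' @return Data frame listing input, ROI path and landmark coordinates
#'   (invisibly).
#' @export
extract_roi_dir <- function(input_dir, output_dir, config = roi_config()) {
  man_file <- file.path(input_dir, "manifest.csv")
  files <- if (file.exists(man_file)) {
    man <- read.csv(man_file)
    file.path(dirname(man_file), basename(man$image_path))
  } else {
    list.files(input_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
               ignore.case = TRUE, full.names = TRUE)
  }
  if (length(files) == 0) stop("no images found in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(files, function(f) {
    roi <- extract_normalized_roi(read_fish_image(f), config)
    base <- sub("\\.[^.]+$", "", basename(f))
    roi_path <- file.path(output_dir, paste0(base, "_roi.png"))
    EBImage::writeImage(EBImage::Image(roi$image), roi_path)
    lmk <- roi$landmarks
    jsonlite::write_json(
      list(source = f, scale = roi$scale, offset = as.list(roi$offset),
           landmarks = lapply(lmk, function(p) unname(as.numeric(p)))),
      file.path(output_dir, paste0(base, "_roi.json")),
      auto_unbox = TRUE, digits = NA)
    data.frame(image_path = f, roi_path = roi_path,
               EP_x = lmk$EP[1], EP_y = lmk$EP[2],
               UP_x = lmk$UP[1], UP_y = lmk$UP[2],
               BP_x = lmk$BP[1], BP_y = lmk$BP[2])
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(output_dir, "roi_manifest.csv"), row.names = FALSE)
  invisible(out)
}
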