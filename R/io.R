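## File-format glue: PNG frame stacks, 0/255 mask PNGs, scribble JSON,
## semen CSV tables and report writers. All coordinates in scribble files
## are 1-based (row, col), matching R indexing; this convention is stated
## in the JSON sidecar of every file the package writes.

#' Write video frames as a zero-padded grayscale PNG stack
#'
#' @param frames List of intensity matrices in `[0, 1]`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths (`frame_00001.png`, ...).
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%05d.png", i))
    png::writePNG(pmin(pmax(frames[[i]], 0), 1), p)
    p
  }, "")
  invisible(paths)
}

#' Read a PNG frame stack as intensity matrices
#'
#' Files matching `frame_*.png` are read in lexicographic order, which must
#' agree with their numeric order. RGB frames are converted to luminance
#' (`0.299 R + 0.587 G + 0.114 B`).
#'
#' @param dir Directory containing the stack.
#' @return List of numeric matrices in `[0, 1]`.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop_pulseroi("no frame_*.png files in ", dir)
  nums <- suppressWarnings(
    as.integer(sub("^frame_0*([0-9]+)\\.png$", "\\1", basename(files))))
  if (anyNA(nums) || is.unsorted(nums, strictly = TRUE))
    stop_pulseroi("frame numbering in ", dir,
                  " is not strictly increasing in lexicographic order")
  lapply(files, function(f) as_luminance(png::readPNG(f)))
}

as_luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  if (length(dim(img)) == 3L && dim(img)[3L] >= 3L)
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  if (length(dim(img)) == 3L) return(img[, , 1L])
  stop_pulseroi("unsupported image layout")
}

#' Write / read a binary mask as a 0/255 PNG
#'
#' On read, any pixel value above one half (127 of 255) is foreground, so
#' the round trip is exact.
#'
#' @param mask Logical mask matrix.
#' @param path PNG file path.
#' @return `write_mask`: invisibly, the path. `read_mask`: logical matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- check_mask(mask)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_pulseroi("mask file not found: ", path)
  as_luminance(png::readPNG(path)) > 0.5
}

#' Write / read scribbles as JSON
#'
#' Format: `{"index_base": 1, "foreground": [[row, col], ...],
#' "background": [[row, col], ...]}`.
#'
#' @param seeds A [scribble_set()].
#' @param path JSON file path.
#' @return `write_scribbles`: invisibly, the path. `read_scribbles`: a
#'   [scribble_set()].
#' @export
write_scribbles <- function(seeds, path) {
  stopifnot(inherits(seeds, "scribble_set"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(index_base = 1L,
         foreground = unname(apply(seeds$foreground, 1L, identity,
                                   simplify = FALSE)),
         background = unname(apply(seeds$background, 1L, identity,
                                   simplify = FALSE))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scribbles
#' @export
read_scribbles <- function(path) {
  if (!file.exists(path)) stop_pulseroi("scribble file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  shift <- if (!is.null(js$index_base) && js$index_base == 0L) 1L else 0L
  scribble_set(foreground = matrix(as.integer(js$foreground), ncol = 2L) + shift,
               background = matrix(as.integer(js$background), ncol = 2L) + shift)
}

#' Read a per-ejaculate semen-variable table
#'
#' Expects a header row, UTF-8, `.` decimal separator, a `boar_id` column
#' and unique (boar, ejaculate) keys when an `ejaculate_id` column is
#' present.
#'
#' @param path CSV file path.
#' @return Data frame with `boar_id` as a factor.
#' @export
read_semen_table <- function(path) {
  if (!file.exists(path)) stop_pulseroi("semen table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"boar_id" %in% names(tab))
    stop_pulseroi("semen table must have a 'boar_id' column")
  for (col in setdiff(names(tab), c("boar_id", "ejaculate_id"))) {
    v <- tab[[col]]
    if (is.character(v)) {
      bad <- grepl("^[0-9]+,[0-9]+$", v)
      if (any(bad))
        stop_pulseroi("column '", col, "' row ", which(bad)[1L],
                      ": comma decimal separator ('", v[which(bad)[1L]],
                      "'); use '.'")
      stop_pulseroi("column '", col, "' is not numeric")
    }
  }
  if ("ejaculate_id" %in% names(tab)) {
    key <- paste(tab$boar_id, tab$ejaculate_id)
    if (anyDuplicated(key))
      stop_pulseroi("duplicate (boar_id, ejaculate_id) key: ",
                    key[anyDuplicated(key)])
  }
  tab$boar_id <- factor(tab$boar_id)
  tab
}

#' Write a data frame as CSV (UTF-8, '.' decimal, no row names)
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
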