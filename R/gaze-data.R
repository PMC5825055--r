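#' Fixation tables
#'
#' A fixation table holds per-observer, per-image fixation records together
#' with the pixel dimensions of every referenced image. Coordinates are
#' 0-based: `x` is the column, `y` the row, origin at the top-left corner,
#' valid range `[0, width) x [0, height)`.
#'
#' @param records A data frame with columns `observer`, `group`, `image`,
#'   `x`, `y` and optionally `duration_ms` and `index`.
#' @param dims A data frame with columns `image`, `width`, `height`.
#' @param groups Optional character vector of allowed group labels; defaults
#'   to the labels present in `records`.
#' @return An object of class `fixation_table`.
#' @seealso [load_fixation_table()], [build_fixation_map()]
#' @export
fixation_table <- function(records, dims, groups = NULL) {
  req <- c("observer", "group", "image", "x", "y")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c("image", "width", "height") %in% names(dims)))
    stop("dims needs columns image, width, height", call. = FALSE)
  records <- as.data.frame(records)
  dims <- as.data.frame(dims)
  if (is.null(groups)) groups <- sort(unique(as.character(records$group)))
  bad <- setdiff(unique(as.character(records$group)), groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  nodim <- setdiff(unique(as.character(records$image)), dims$image)
  if (length(nodim))
    stop("no registered dims for image(s): ", paste(nodim, collapse = ", "),
         call. = FALSE)
  # drop out-of-bounds rows (half-open range) with a logged count
  wh <- dims[match(records$image, dims$image), c("width", "height")]
  ok <- records$x >= 0 & records$x < wh$width &
        records$y >= 0 & records$y < wh$height
  if (any(!ok)) {
    warning(sum(!ok), " fixation(s) outside image bounds dropped")
    records <- records[ok, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(records = records, dims = dims, groups = groups),
            class = "fixation_table")
}

#' @export
print.fixation_table <- function(x, ...) {
  cat("<fixation_table> ", nrow(x$records), " fixations, ",
      length(unique(x$records$observer)), " observers, ",
      length(x$groups), " group(s) [", paste(x$groups, collapse = ", "),
      "], ", nrow(x$dims), " image(s)\n", sep = "")
  invisible(x)
}

#' Read / write a fixation table from delimited text
#'
#' The file must be CSV or TSV with a header containing at least
#' `observer,group,image,x,y` (optional: `duration_ms,index`). Image
#' dimensions come either from a sidecar CSV (`image,width,height`), a data
#' frame of the same shape, or a named list of images/dims. Rows outside the
#' image bounds are dropped with a warning giving the count.
#'
#' @param path Fixation CSV/TSV path.
#' @param dims Sidecar CSV path, a data frame `image,width,height`, or a
#'   named list mapping image id to `c(width, height)`.
#' @param groups Optional vector of allowed group labels.
#' @param sep Field separator; guessed from the file extension by default.
#' @return A [fixation_table].
#' @export
load_fixation_table <- function(path, dims, groups = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (is.character(dims) && length(dims) == 1)
    dims <- utils::read.csv(dims, stringsAsFactors = FALSE)
  if (is.list(dims) && !is.data.frame(dims))
    dims <- data.frame(image = names(dims),
                       width = vapply(dims, `[`, numeric(1), 1),
                       height = vapply(dims, `[`, numeric(1), 2))
  fixation_table(rec, dims, groups = groups)
}

#' @rdname load_fixation_table
#' @param table A [fixation_table] to write.
#' @export
write_fixation_table <- function(table, path) {
  stopifnot(inherits(table, "fixation_table"))
  utils::write.csv(table$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# select records for one (group, image); internal
select_fixations <- function(table, group, image_id) {
  r <- table$records
  r[r$group == group & r$image == image_id, , drop = FALSE]
}

#' Binary human fixation map
#'
#' Pools the fixations of all observers of `group` on `image_id` into a
#' binary raster: `grid[round(y), round(x)] = 1` (round-half-away-from-zero
#' per axis; duplicate pixels collapse to a single 1).
#'
#' @param table A [fixation_table].
#' @param group Group label.
#' @param image_id Image id.
#' @return An object of class `fixation_map` with elements `grid`
#'   (height x width 0/1 matrix), `image_id`, `group`, `n_fixations`.
#' @export
build_fixation_map <- function(table, group, image_id) {
  stopifnot(inherits(table, "fixation_table"))
  rec <- select_fixations(table, group, image_id)
  if (nrow(rec) == 0)
    stop("no fixations for group '", group, "' on image '", image_id, "'",
         call. = FALSE)
  d <- table$dims[table$dims$image == image_id, ]
  h <- d$height[1]; w <- d$width[1]
  grid <- matrix(0L, h, w)
  row <- pmin(pmax(round_half_away(rec$y), 0), h - 1) + 1L
  col <- pmin(pmax(round_half_away(rec$x), 0), w - 1) + 1L
  grid[cbind(row, col)] <- 1L
  structure(list(grid = grid, image_id = image_id, group = group,
                 n_fixations = nrow(rec)),
            class = "fixation_map")
}

#' @export
print.fixation_map <- function(x, ...) {
  cat("<fixation_map> ", x$group, "/", x$image_id, ": ",
      sum(x$grid), " fixated pixel(s) on ", nrow(x$grid), "x", ncol(x$grid),
      "\n", sep = "")
  invisible(x)
}

#' Saliency map container
#'
#' A non-negative 2-D raster plus bookkeeping: which image it belongs to,
#' whether it is a human (gaze-derived) or model map, and its normalization
#' state.
#'
#' @param grid Numeric matrix, all values `>= 0`.
#' @param image_id Image id (may be `NA`).
#' @param source One of `"human"`, `"model_S"`, `"model_SIC"`, `"model_P"`,
#'   `"center_map"`.
#' @param normalization `"raw"` or `"minmax01"`.
#' @export
saliency_map <- function(grid, image_id = NA_character_,
                         source = c("human", "model_S", "model_SIC",
                                    "model_P", "center_map"),
                         normalization = c("raw", "minmax01")) {
  source <- match.arg(source)
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(grid))
  if (any(grid < 0)) stop("saliency values must be >= 0", call. = FALSE)
  structure(list(grid = grid, image_id = image_id, source = source,
                 normalization = normalization),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map> ", x$source, ", ", nrow(x$grid), "x", ncol(x$grid),
      ", range [", format(min(x$grid), digits = 4), ", ",
      format(max(x$grid), digits = 4), "], ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Gaussian-smoothed human saliency map
#'
#' Convolves an isotropic Gaussian across the binary fixation map and
#' min-max normalizes the result to `[0, 1]` — the empirical attention
#' density of a group on one image. The blur uses zero padding, so
#' fixations hugging the border lose some mass.
#'
#' @param fmap A `fixation_map` (or a 0/1 matrix).
#' @param sigma Gaussian standard deviation in pixels. Default: 25 px per
#'   1024 px of image width (about 1 degree of visual angle at a typical
#'   60 cm viewing distance), scaled proportionally to the actual width.
#' @return A [saliency_map] with `source = "human"`.
#' @export
build_human_saliency_map <- function(fmap, sigma = NULL) {
  grid <- if (inherits(fmap, "fixation_map")) fmap$grid else fmap
  if (is.null(sigma)) sigma <- 25 * ncol(grid) / 1024
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  sm <- gaussian_blur(grid, sigma)
  saliency_map(minmax01(sm),
               image_id = if (inherits(fmap, "fixation_map")) fmap$image_id
                          else NA_character_,
               source = "human", normalization = "minmax01")
}

# default smoothing sigma for a given image width; shared by analysis code
default_sigma <- function(width) 25 * width / 1024
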