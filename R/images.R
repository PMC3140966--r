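#' Read registered embryo images with their metadata
#'
#' Loads grayscale PNG or TIFF rasters of registered, background-free
#' embryos, rescales intensities linearly to `[0, 1]`, and attaches the
#' image/gene metadata. Images are returned sorted by `image_id` so that
#' downstream feature matrices are deterministic regardless of file order.
#'
#' Images are stored with the convention that stronger staining has the
#' higher value; set `invert = TRUE` for dark-on-light stains.
#'
#' @param meta Data frame with columns `image_id`, `gene_id`, `file`, and
#'   optionally `orientation` (`"lateral"`, `"dorsal_ventral"`, `"unknown"`).
#' @param dir Directory that `meta$file` paths are relative to (`""` for
#'   absolute paths).
#' @param invert Logical; if `TRUE`, intensities are flipped (`1 - x`) so
#'   that stronger staining maps to higher values.
#' @return A list of `spexfa_image` objects, each a list with `image_id`,
#'   `gene_id`, `orientation` and a numeric `pixels` matrix in `[0, 1]`.
#' @export
read_expression_images <- function(meta, dir = "", invert = FALSE) {
  meta <- tibble::as_tibble(meta)
  abort_if(!all(c("image_id", "gene_id", "file") %in% names(meta)),
           "metadata must have columns image_id, gene_id, file")
  if (nrow(meta) == 0L) return(list())
  abort_if(anyNA(meta$image_id) | anyNA(meta$gene_id),
           "metadata has missing image_id or gene_id")
  meta <- dplyr::arrange(meta, .data$image_id)
  orientation <- if ("orientation" %in% names(meta)) meta$orientation else
    rep("unknown", nrow(meta))
  purrr::pmap(
    list(meta$image_id, meta$gene_id, meta$file, orientation),
    function(id, gene, file, orient) {
      path <- if (nzchar(dir)) file.path(dir, file) else file
      abort_if(!file.exists(path), paste0("cannot read image file: ", path))
      px <- read_gray_raster(path)
      if (invert) px <- 1 - px
      new_spexfa_image(px, id, gene, orient)
    }
  )
}

new_spexfa_image <- function(pixels, image_id, gene_id,
                             orientation = "unknown") {
  abort_if(length(pixels) == 0L, "image has no pixels")
  abort_if(!all(is.finite(pixels)) || any(pixels < 0) || any(pixels > 1),
           "pixel intensities must be finite and within [0, 1]")
  structure(
    list(image_id = as.character(image_id), gene_id = as.character(gene_id),
         orientation = orientation, pixels = pixels),
    class = "spexfa_image"
  )
}

#' @export
print.spexfa_image <- function(x, ...) {
  cat(sprintf("<spexfa_image %s (gene %s), %d x %d px, %s view>\n",
              x$image_id, x$gene_id, nrow(x$pixels), ncol(x$pixels),
              x$orientation))
  invisible(x)
}

# Decode a PNG/TIFF to a grayscale matrix rescaled to [0, 1].
# Multi-channel rasters are averaged across channels; an alpha channel,
# if present, is dropped.
read_gray_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format (need png/tiff): ", path, call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3]
    if (nc %in% c(2L, 4L)) nc <- nc - 1L    # drop alpha
    px <- apply(px[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  rng <- range(px)
  if (rng[2] > rng[1]) px <- (px - rng[1]) / (rng[2] - rng[1])
  px
}

#' Bilinear image rescale
#'
#' Resamples a grayscale intensity matrix to the requested size with
#' bilinear interpolation under the align-corners convention: the corner
#' pixel centres of the input map exactly onto the corner pixel centres of
#' the output, so a 1-D ramp upsamples to a longer linear ramp and constant
#' images are preserved exactly.
#'
#' @param x Numeric matrix (height x width) or a `spexfa_image`.
#' @param width,height Positive integer target dimensions.
#' @return Object of the same type as `x` with `height x width` pixels.
#' @export
resize_bilinear <- function(x, width, height) {
  if (inherits(x, "spexfa_image")) {
    out <- x
    out$pixels <- resize_bilinear(x$pixels, width, height)
    return(out)
  }
  abort_if(width < 1 || height < 1, "target dimensions must be >= 1")
  src_h <- nrow(x); src_w <- ncol(x)
  if (src_h == height && src_w == width) return(x)
  # fractional source coordinates of each output pixel centre
  coord <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(1, n_out) else
      seq(1, n_in, length.out = n_out)
  }
  ry <- coord(height, src_h)
  rx <- coord(width, src_w)
  y0 <- pmin(floor(ry), src_h - (src_h > 1)); y1 <- pmin(y0 + 1, src_h)
  x0 <- pmin(floor(rx), src_w - (src_w > 1)); x1 <- pmin(x0 + 1, src_w)
  wy <- ry - y0; wx <- rx - x0
  top    <- x[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
            x[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  bottom <- x[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
            x[y1, x1, drop = FALSE] * outer(wy, wx)
  out <- top + bottom
  # clamp tiny interpolation overshoot so intensities stay in range
  pmin(pmax(out, min(x)), max(x))
}

#' Grid-patch mean-intensity features
#'
#' Splits the image into an `n_rows x n_cols` grid of equal rectangular
#' patches and returns the mean pixel value of each patch, stacked
#' row-major (top-left patch first) into a vector of length
#' `n_rows * n_cols`.
#'
#' @param x Numeric intensity matrix or `spexfa_image`.
#' @param n_rows,n_cols Grid dimensions; image height/width must be exact
#'   multiples (rescale first with [resize_bilinear()] otherwise).
#' @return Numeric feature vector of length `n_rows * n_cols`.
#' @export
grid_features <- function(x, n_rows, n_cols) {
  if (inherits(x, "spexfa_image")) x <- x$pixels
  abort_if(n_rows < 1 || n_cols < 1, "grid dimensions must be >= 1")
  abort_if(nrow(x) %% n_rows != 0 || ncol(x) %% n_cols != 0,
           "image dimensions not divisible by grid; rescale the image first")
  ph <- nrow(x) / n_rows
  pw <- ncol(x) / n_cols
  row_block <- (seq_len(nrow(x)) - 1L) %/% ph
  col_block <- (seq_len(ncol(x)) - 1L) %/% pw
  # patch sums via two grouped matrix products, then divide by patch area
  Rm <- outer(0:(n_rows - 1L), row_block, "==") * 1
  Cm <- outer(col_block, 0:(n_cols - 1L), "==") * 1
  sums <- Rm %*% x %*% Cm
  as.vector(t(sums / (ph * pw)))   # row-major stacking
}

#' Assemble the image-by-feature matrix
#'
#' Applies [grid_features()] to every image and stacks the vectors into an
#' `N x P` matrix with one row per image, optionally centering each row
#' (gene pattern) to zero mean as the factor model assumes.
#'
#' @param images List of `spexfa_image` objects with identical dimensions.
#' @param n_rows,n_cols Grid dimensions (default the high-resolution
#'   80-column by 40-row grid).
#' @param center Logical; center each row to mean zero.
#' @return A `spexfa_features` object: list with the `N x P` matrix `X`,
#'   a `meta` tibble (`image_id`, `gene_id`), `grid = c(n_rows, n_cols)`
#'   and the `centered` flag.
#' @export
feature_matrix <- function(images, n_rows = 40, n_cols = 80, center = TRUE) {
  abort_if(length(images) == 0L, "need at least one image")
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  abort_if(any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]),
           "images have differing dimensions; rescale to a common size first")
  X <- t(vapply(images, grid_features, numeric(n_rows * n_cols),
                n_rows = n_rows, n_cols = n_cols))
  meta <- tibble::tibble(
    image_id = vapply(images, `[[`, character(1), "image_id"),
    gene_id  = vapply(images, `[[`, character(1), "gene_id")
  )
  fm <- new_spexfa_features(X, meta, c(n_rows, n_cols), centered = FALSE)
  if (center) fm <- center_patterns(fm) else fm
}

new_spexfa_features <- function(X, meta, grid, centered) {
  X <- as.matrix(X)
  abort_if(nrow(X) != nrow(meta), "row count of X must match metadata")
  rownames(X) <- meta$image_id
  structure(
    list(X = X, meta = tibble::as_tibble(meta),
         grid = as.integer(grid), centered = isTRUE(centered)),
    class = "spexfa_features"
  )
}

#' Center each gene pattern to zero mean
#'
#' @param fm A `spexfa_features` object.
#' @return The same object with every row of `X` shifted to mean zero and
#'   `centered = TRUE`. Centering an already-centered matrix is a no-op.
#' @export
center_patterns <- function(fm) {
  abort_if(!inherits(fm, "spexfa_features"), "fm must be a spexfa_features")
  fm$X <- fm$X - rowMeans(fm$X)
  fm$centered <- TRUE
  fm
}

#' @export
print.spexfa_features <- function(x, ...) {
  cat(sprintf(
    "<spexfa_features: %d images x %d features (grid %d rows x %d cols), %s>\n",
    nrow(x$X), ncol(x$X), x$grid[1], x$grid[2],
    if (x$centered) "centered" else "raw"))
  invisible(x)
}

#' @describeIn feature_matrix Long-format view of the feature matrix.
#' @param x A `spexfa_features` object.
#' @param ... Unused.
#' @importFrom tibble as_tibble
#' @method as_tibble spexfa_features
#' @export
as_tibble.spexfa_features <- function(x, ...) {
  P <- ncol(x$X)
  tibble::tibble(
    image_id = rep(x$meta$image_id, each = P),
    gene_id  = rep(x$meta$gene_id, each = P),
    feature  = rep(seq_len(P), times = nrow(x$X)),
    value    = as.vector(t(x$X))
  )
}

#' Write / read a feature matrix as TSV
#'
#' The file starts with a comment line recording the grid and centering
#' flag, followed by a header `image_id gene_id f_0001 ... f_P` and one row
#' per image. Features are stacked row-major over the grid.
#'
#' @param fm A `spexfa_features` object.
#' @param path Output file path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the reconstructed `spexfa_features`.
#' @export
write_features <- function(fm, path) {
  P <- ncol(fm$X)
  hdr <- sprintf("# spexfa features grid_rows=%d grid_cols=%d centered=%s",
                 fm$grid[1], fm$grid[2], fm$centered)
  df <- data.frame(image_id = fm$meta$image_id, gene_id = fm$meta$gene_id,
                   fm$X, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("f_%04d", seq_len(P))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 1L)
  abort_if(!startsWith(hdr, "# spexfa features"),
           "not a spexfa feature file (missing header line)")
  parse_kv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m)
  }
  grid <- c(as.integer(parse_kv("grid_rows")), as.integer(parse_kv("grid_cols")))
  centered <- identical(parse_kv("centered"), "TRUE")
  df <- read.delim(path, skip = 1L, check.names = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  new_spexfa_features(X, df[, 1:2], grid, centered)
}
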