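#' AIO layout configuration
#'
#' Describes the image layout an ordered gene list is mapped onto: height,
#' width and number of channels (1 = grayscale).  The two layouts used with
#' 16,384 genes are `aio_config(128, 128, 1)` and `aio_config(64, 64, 4)`.
#'
#' @param height,width,channels Positive integer image dimensions.
#' @param pad_policy What to do when the gene list is shorter than the
#'   pixel capacity: `"zero"` leaves trailing pixels at intensity 0,
#'   `"error"` refuses.
#' @return An `aio_config` with capacity `height * width * channels`.
#' @export
aio_config <- function(height, width, channels = 1,
                       pad_policy = c("zero", "error")) {
  pad_policy <- match.arg(pad_policy)
  height <- as.integer(height); width <- as.integer(width)
  channels <- as.integer(channels)
  stopifnot(height >= 1, width >= 1, channels >= 1)
  structure(list(height = height, width = width, channels = channels,
                 capacity = height * width * channels,
                 pad_policy = pad_policy),
            class = "aio_config")
}

#' @export
print.aio_config <- function(x, ...) {
  cat(sprintf("aio_config: %d x %d x %d (capacity %d, pad=%s)\n",
              x$height, x$width, x$channels, x$capacity, x$pad_policy))
  invisible(x)
}

#' Deterministic gene-to-pixel map
#'
#' Assigns the gene at 0-based position i of the order to
#' `channel = i div (H*W)`, then row-major within the channel:
#' `row = (i mod H*W) div W`, `col = i mod W` (all 0-based).  So for a
#' 128x128 grayscale layout the first 128 genes form the first row and the
#' next 128 the second; for 64x64x4 the first 4096 genes form the first
#' channel and the second 4096 the second.  The same gene therefore
#' occupies the same coordinates for every sample, and the map is
#' invertible ([gene_at()]).
#'
#' @param order A `gene_order` (or character vector of unique gene
#'   symbols).
#' @param config An [aio_config()]; the order must not exceed its capacity,
#'   and must equal it when `pad_policy = "error"`.
#' @return A `pixel_map`: data frame (`gene`, `channel`, `row`, `col`,
#'   0-based) with the configuration attached.
#' @export
make_pixel_map <- function(order, config) {
  stopifnot(inherits(config, "aio_config"))
  order <- as.character(order)
  if (anyDuplicated(order)) stop("gene order contains duplicates")
  n <- length(order)
  if (n > config$capacity)
    stop(sprintf("gene order (%d genes) exceeds pixel capacity (%d)",
                 n, config$capacity))
  if (n < config$capacity && config$pad_policy == "error")
    stop(sprintf(paste0("gene order (%d genes) underfills capacity (%d) ",
                        "and pad_policy is 'error'"), n, config$capacity))
  i <- seq_len(n) - 1L
  hw <- config$height * config$width
  map <- data.frame(gene = order,
                    channel = i %/% hw,
                    row = (i %% hw) %/% config$width,
                    col = i %% config$width,
                    stringsAsFactors = FALSE)
  structure(list(map = map, config = config,
                 index = stats::setNames(seq_len(n), order)),
            class = "pixel_map")
}

#' @export
print.pixel_map <- function(x, ...) {
  cat(sprintf("pixel_map: %d genes on a %d x %d x %d grid\n",
              nrow(x$map), x$config$height, x$config$width,
              x$config$channels))
  invisible(x)
}

#' Look up the pixel of a gene, or the gene at a pixel
#'
#' `pixel_of()` returns the 0-based `(channel, row, col)` of a mapped gene;
#' `gene_at()` inverts the map, returning the gene symbol at a coordinate
#' or `NA` for a padded (unmapped) pixel.
#'
#' @param pmap A [make_pixel_map()] result.
#' @param gene Gene symbol.
#' @param coord Integer `c(channel, row, col)`, 0-based, within the
#'   configuration bounds.
#' @return `pixel_of()`: named integer vector; `gene_at()`: gene symbol or
#'   `NA_character_`.
#' @export
gene_at <- function(pmap, coord) {
  stopifnot(inherits(pmap, "pixel_map"), length(coord) == 3L)
  cfg <- pmap$config
  ch <- coord[1L]; row <- coord[2L]; col <- coord[3L]
  if (ch < 0 || ch >= cfg$channels || row < 0 || row >= cfg$height ||
      col < 0 || col >= cfg$width)
    stop(sprintf("coordinate (%d,%d,%d) out of bounds for %dx%dx%d",
                 ch, row, col, cfg$height, cfg$width, cfg$channels))
  i <- ch * cfg$height * cfg$width + row * cfg$width + col + 1
  if (i > nrow(pmap$map)) NA_character_ else pmap$map$gene[i]
}

#' @rdname gene_at
#' @export
pixel_of <- function(pmap, gene) {
  stopifnot(inherits(pmap, "pixel_map"))
  i <- pmap$index[gene]
  if (is.na(i)) stop("gene '", gene, "' is not mapped")
  c(channel = pmap$map$channel[i], row = pmap$map$row[i],
    col = pmap$map$col[i])
}

#' Materialize one sample's AIO tensor
#'
#' Places the sample's scaled intensity for each mapped gene at its pixel;
#' padded pixels carry 0.
#'
#' @param sample_row Named integer vector of 0..255 intensities covering
#'   every mapped gene, or a single-row `scaled_matrix`.
#' @param pmap A [make_pixel_map()] result.
#' @return An `aio_tensor`: integer array `(channels, height, width)`.
#' @export
build_aio <- function(sample_row, pmap) {
  stopifnot(inherits(pmap, "pixel_map"))
  if (inherits(sample_row, "scaled_matrix")) {
    stopifnot(nrow(sample_row$values) == 1L)
    sample_row <- sample_row$values[1L, ]
  }
  genes <- pmap$map$gene
  miss <- setdiff(genes, names(sample_row))
  if (length(miss))
    stop("missing value(s) for mapped gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  v <- sample_row[genes]
  if (any(v < 0 | v > 255)) stop("intensities must lie in 0..255")
  cfg <- pmap$config
  a <- array(0L, dim = c(cfg$channels, cfg$height, cfg$width))
  a[cbind(pmap$map$channel + 1L, pmap$map$row + 1L, pmap$map$col + 1L)] <-
    as.integer(v)
  structure(a, class = "aio_tensor")
}

#' Build AIO tensors for a whole cohort
#'
#' Vectorized construction of one AIO per sample from a `scaled_matrix`
#' whose column order matches the pixel map's gene order.
#'
#' @param scaled A `scaled_matrix` from [rescale_per_gene()].
#' @param pmap A [make_pixel_map()] result built on the same gene order.
#' @return An `aio_stack`: list with `tensors`, a `(N, height, width,
#'   channels)` integer array, `sample_ids`, and the `pixel_map`.
#' @export
build_aios <- function(scaled, pmap) {
  stopifnot(inherits(scaled, "scaled_matrix"), inherits(pmap, "pixel_map"))
  if (!identical(as.character(scaled$order), pmap$map$gene))
    stop("scaled matrix column order does not match the pixel map gene order")
  cfg <- pmap$config
  n <- nrow(scaled$values)
  # Column i of the scaled matrix is pixel i in (channel, row-major) order;
  # pad with zero columns up to capacity, then permute to (N, H, W, C).
  v <- scaled$values
  if (ncol(v) < cfg$capacity)
    v <- cbind(v, matrix(0L, n, cfg$capacity - ncol(v)))
  a <- array(t(v), dim = c(cfg$width, cfg$height, cfg$channels, n))
  a <- aperm(a, c(4L, 2L, 1L, 3L))    # -> (N, H, W, C)
  structure(list(tensors = a, sample_ids = rownames(scaled$values),
                 pixel_map = pmap), class = "aio_stack")
}

#' @export
print.aio_stack <- function(x, ...) {
  d <- dim(x$tensors)
  cat(sprintf("aio_stack: %d AIOs of %d x %d x %d\n", d[1L], d[2L], d[3L],
              d[4L]))
  invisible(x)
}

# Tensor of one sample from a stack, as (C, H, W) like build_aio().
stack_tensor <- function(stack, i) {
  a <- stack$tensors[i, , , , drop = TRUE]
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  structure(aperm(a, c(3L, 1L, 2L)), class = "aio_tensor")
}

#' Export / import AIO tensors
#'
#' `format = "rds"` writes a lossless array container (tensors +
#' sample ids) with a delimited-text pixel-map companion
#' (`<path>.pixelmap.tsv`).  `format = "png"` writes one PNG per sample;
#' channel counts map to PNG color types purely for storage (1 ->
#' grayscale, 3 -> RGB, 4 -> RGBA; channel semantics are positional, not
#' chromatic), so 2-channel tensors are refused.  Both round-trip the
#' integer intensities bit-exactly.
#'
#' @param stack An `aio_stack`.
#' @param path Output file (`"rds"`) or directory (`"png"`).
#' @param format `"rds"` or `"png"`.
#' @return `export_aio()` returns the written path(s) invisibly;
#'   `import_aio()` returns an `aio_stack` (without pixel map for PNG
#'   directories read back with `sample_ids` from file names).
#' @export
export_aio <- function(stack, path, format = c("rds", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "aio_stack"))
  d <- dim(stack$tensors)
  if (format == "rds") {
    saveRDS(list(tensors = stack$tensors, sample_ids = stack$sample_ids),
            path)
    pm <- stack$pixel_map$map
    utils::write.table(pm, paste0(path, ".pixelmap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ch <- d[4L]
  if (!ch %in% c(1L, 3L, 4L))
    stop("png export supports 1 (grayscale), 3 (RGB) or 4 (RGBA) channels; ",
         "got ", ch)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(d[1L])
  for (i in seq_len(d[1L])) {
    img <- stack$tensors[i, , , , drop = TRUE] / 255
    if (ch == 1L) dim(img) <- d[2:3]
    files[i] <- file.path(path, paste0(stack$sample_ids[i], ".png"))
    png::writePNG(img, files[i])
  }
  invisible(files)
}

#' @rdname export_aio
#' @export
import_aio <- function(path, format = c("rds", "png")) {
  format <- match.arg(format)
  if (format == "rds") {
    obj <- readRDS(path)
    return(structure(list(tensors = obj$tensors,
                          sample_ids = obj$sample_ids, pixel_map = NULL),
                     class = "aio_stack"))
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no png files under ", path)
  imgs <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    img
  })
  d <- dim(imgs[[1L]])
  a <- array(0L, dim = c(length(imgs), d))
  for (i in seq_along(imgs)) a[i, , , ] <- as.integer(round(imgs[[i]] * 255))
  structure(list(tensors = a,
                 sample_ids = sub("\\.png$", "", basename(files)),
                 pixel_map = NULL),
            class = "aio_stack")
}
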