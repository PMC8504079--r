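#' Expression matrix container
#'
#' A samples x genes matrix of gene-level expression with unique sample and
#' gene identifiers and an explicit scale marker: `"fpkm"` for raw
#' non-negative FPKM values, `"log2"` after log transformation.
#'
#' @param values Numeric samples x genes matrix with rownames (sample ids)
#'   and colnames (gene symbols).
#' @param scale `"fpkm"` or `"log2"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, scale = c("fpkm", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs rownames (sample ids) and colnames (gene symbols)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate sample identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate gene identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', gene '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (scale == "fpkm" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative FPKM value at sample '%s', gene '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression matrix whose first column holds identifiers.
#' Orientation is normalized to samples x genes.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples_x_genes"` (rows are samples) or
#'   `"genes_x_samples"` (rows are genes; the matrix is transposed on read).
#' @param scale Scale marker of the stored values (see
#'   [expression_matrix()]).
#' @param sep Field delimiter; `"auto"` lets the reader sniff it.
#' @return An `expression_matrix`.
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_x_genes",
                                                  "genes_x_samples"),
                                  scale = "fpkm", sep = "auto") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  ids <- as.character(dt[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate identifier(s) in first column: ",
                        paste(unique(dup), collapse = ", "))
  cn <- names(dt)[-1L]
  m <- as.matrix(dt[, -1L, drop = FALSE])
  colnames(m) <- cn                 # keep duplicates visible to validation
  rownames(m) <- ids
  if (orientation == "genes_x_samples") m <- t(m)
  expression_matrix(m, scale = scale)
}

#' Log2-transform an FPKM matrix
#'
#' Replaces every value x by `log2(x + pseudocount)` and flips the scale
#' marker to `"log2"`.  FPKM contains exact zeros, so the default
#' pseudocount of 1 keeps zero expression at intensity zero.
#'
#' @param mat An `expression_matrix` on the `"fpkm"` scale.
#' @param pseudocount Positive offset added before taking log2.
#' @return An `expression_matrix` on the `"log2"` scale.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$scale != "fpkm")
    stop("matrix is already on the log2 scale; log2_transform() expects ",
         "an 'fpkm'-scale matrix")
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  expression_matrix(log2(mat$values + pseudocount), scale = "log2")
}

#' Gene annotation table
#'
#' One row per gene symbol with its chromosome and transcription start site
#' (TSS), used to order genes along the genome.
#'
#' @param symbol Character gene symbols (unique).
#' @param chromosome Chromosome names: `1..22`, `X`, `Y`, `MT`, or other
#'   contig names.
#' @param tss Non-negative integer transcription start positions.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(symbol, chromosome, tss) {
  symbol <- as.character(symbol)
  dup <- symbol[duplicated(symbol)]
  if (length(dup)) stop("duplicate gene symbol(s) in annotation: ",
                        paste(unique(dup), collapse = ", "))
  tss <- as.numeric(tss)
  if (any(is.na(tss)) || any(tss < 0)) stop("`tss` must be non-negative")
  structure(data.frame(symbol = symbol,
                       chromosome = as.character(chromosome),
                       tss = tss, stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

# Total order over contig names: autosomes 1..22 numerically, then X, Y,
# MT, then any other contigs alphabetically.
chromosome_rank <- function(chromosome) {
  chr <- sub("^chr", "", as.character(chromosome), ignore.case = TRUE)
  n <- suppressWarnings(as.integer(chr))
  rank <- ifelse(!is.na(n), n,
                 ifelse(toupper(chr) == "X", 23L,
                        ifelse(toupper(chr) == "Y", 24L,
                               ifelse(toupper(chr) %in% c("MT", "M"), 25L,
                                      NA_integer_))))
  other <- is.na(rank)
  if (any(other)) {
    lev <- sort(unique(chr[other]))
    rank[other] <- 25L + match(chr[other], lev)
  }
  rank
}

#' Genome-ordered shared gene list
#'
#' Intersects the gene sets of several datasets, sorts the shared genes by
#' (chromosome rank, TSS, symbol) -- chromosomes ordered numerically, then
#' X, Y, MT, then other contigs alphabetically -- and keeps the first
#' `n_selected` genes.  This is the canonical gene order that fills the AIO
#' pixel grid.
#'
#' @param annotation A [gene_annotation()] covering (at least) the shared
#'   genes.
#' @param gene_lists List of character vectors, one gene set per dataset.
#' @param n_selected Number of genes to keep (must not exceed the
#'   intersection size); e.g. 16384 fills a 128x128 or 64x64x4 image.
#' @return A `gene_order` character vector of length `n_selected`.
#' @export
shared_gene_order <- function(annotation, gene_lists, n_selected) {
  stopifnot(inherits(annotation, "gene_annotation"), length(gene_lists) >= 1)
  shared <- Reduce(intersect, lapply(gene_lists, as.character))
  if (length(shared) < n_selected)
    stop(sprintf(paste0("shared gene set too small: intersection has %d ",
                        "genes but n_selected = %d"),
                 length(shared), n_selected))
  ann <- annotation[annotation$symbol %in% shared, , drop = FALSE]
  miss <- setdiff(shared, ann$symbol)
  if (length(miss))
    stop("shared gene(s) missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ord <- order(chromosome_rank(ann$chromosome), ann$tss, ann$symbol)
  out <- ann$symbol[ord][seq_len(n_selected)]
  structure(out, class = "gene_order")
}

#' Per-gene min-max rescaling to 0..255
#'
#' Rescales log2 expression gene by gene into the 1-byte intensity range of
#' a digital image: `round(255 * (x - min) / (max - min))` with half-even
#' rounding.  When `scaler` is absent the per-gene min/max are fit on
#' `mat` (the training cohort); a prefit scaler applies the training range
#' and clips out-of-range values to \[0, 255\].  Constant genes
#' (max == min) map to 0.
#'
#' @param mat An `expression_matrix` on the `"log2"` scale.
#' @param order A `gene_order` (all its genes must be columns of `mat`);
#'   output columns follow this order.
#' @param scaler Optional prefit `scaler_params` from an earlier call.
#' @return A list with `scaled` (a `scaled_matrix`: integer matrix in
#'   0..255 plus the order and scaler that produced it) and `scaler` (the
#'   `scaler_params` used).
#' @export
rescale_per_gene <- function(mat, order, scaler = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$scale != "log2")
    stop("rescale_per_gene() expects a log2-scale matrix; ",
         "run log2_transform() first")
  order <- as.character(order)
  miss <- setdiff(order, colnames(mat$values))
  if (length(miss))
    stop("gene(s) in order missing from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  x <- mat$values[, order, drop = FALSE]
  if (is.null(scaler)) {
    mins <- apply(x, 2L, min)
    maxs <- apply(x, 2L, max)
    scaler <- structure(list(gene = order, min = unname(mins),
                             max = unname(maxs)), class = "scaler_params")
  } else {
    stopifnot(inherits(scaler, "scaler_params"))
    if (!identical(as.character(scaler$gene), order))
      stop("prefit scaler does not cover the requested gene order")
    mins <- scaler$min
    maxs <- scaler$max
  }
  rng <- maxs - mins
  z <- sweep(x, 2L, mins, "-")
  z <- sweep(z, 2L, ifelse(rng > 0, rng, 1), "/")
  z[, rng == 0] <- 0
  z <- pmin(pmax(z, 0), 1)      # clip for prefit out-of-range values
  v <- round(255 * z)           # round() is half-even in R
  storage.mode(v) <- "integer"
  scaled <- structure(list(values = v, order = structure(order,
                                                         class = "gene_order"),
                           scaler = scaler), class = "scaled_matrix")
  list(scaled = scaled, scaler = scaler)
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled_matrix: %d samples x %d genes, intensities 0..255\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Persist / restore per-gene scaler parameters
#'
#' The scaler is stored as a three-column TSV (gene, min, max) so that a
#' training-cohort fit can be applied unchanged to external test cohorts.
#'
#' @param scaler A `scaler_params` object.
#' @param path TSV file path.
#' @return `write_scaler()` returns `path` invisibly; `read_scaler()`
#'   returns the `scaler_params`.
#' @export
write_scaler <- function(scaler, path) {
  stopifnot(inherits(scaler, "scaler_params"))
  utils::write.table(data.frame(gene = scaler$gene, min = scaler$min,
                                max = scaler$max),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(df$min > df$max)) stop("invalid scaler: min > max for some gene")
  structure(list(gene = as.character(df$gene), min = df$min, max = df$max),
            class = "scaler_params")
}

parse_nhg <- function(v) {
  raw <- trimws(toupper(sub("^\\s*GRADE\\s*", "", as.character(v),
                            ignore.case = TRUE)))
  out <- rep(NA_integer_, length(raw))
  roman <- c("I" = 0L, "II" = 1L, "III" = 2L)
  isr <- raw %in% names(roman)
  out[isr] <- roman[raw[isr]]
  num <- suppressWarnings(as.integer(raw))
  isn <- !isr & !is.na(num)
  # Numeric coding is ambiguous between grades 1..3 and codes 0..2; the
  # presence of a 0 (resp. 3) disambiguates, otherwise codes are assumed.
  if (any(isn)) {
    vals <- unique(num[isn])
    if (any(vals == 0L) && any(vals == 3L))
      stop("NHG column mixes 0-based codes and 1-based grades")
    offset <- if (any(vals == 3L)) 1L else 0L
    conv <- num[isn] - offset
    if (any(conv < 0L | conv > 2L))
      stop("invalid NHG value(s): ",
           paste(unique(raw[isn][conv < 0L | conv > 2L]), collapse = ", "))
    out[isn] <- conv
  }
  bad <- !isr & is.na(num) & !is.na(raw) & raw != "" & raw != "NA"
  if (any(bad))
    stop("invalid NHG value(s): ", paste(unique(raw[bad]), collapse = ", "))
  out
}

#' Read a sample label table
#'
#' Reads per-sample labels: binary Ki67 status, 3-class NHG (Nottingham
#' histologic grade), and optional survival time/event.  A raw Ki67
#' staining percentage column, when present, is dichotomized at the
#' clinical 20% cutoff: `<= 20` percent stained cells is class 0 (Ki67-),
#' `> 20` is class 1 (Ki67+).  NHG values `I/II/III` (or `Grade I` etc.)
#' map to codes 0/1/2; numeric columns may carry either 1-based grades or
#' 0-based codes and are disambiguated by their value range.  Missing
#' entries stay missing.
#'
#' @param path Delimited text file with a sample id column.
#' @param id_col,ki67_col,ki67_percent_col,nhg_col,time_col,event_col
#'   Column names; set to `NULL` to skip.  `ki67_percent_col` takes
#'   precedence over `ki67_col`.
#' @param ki67_cutoff Dichotomization cutoff on the staining percentage.
#' @return A `label_set` data frame with columns `sample_id`, `ki67`,
#'   `nhg`, and optionally `survival_days`, `event`.
#' @export
read_labels <- function(path, id_col = "sample_id",
                        ki67_col = "ki67", ki67_percent_col = "ki67_percent",
                        nhg_col = "nhg", time_col = "survival_days",
                        event_col = "event", ki67_cutoff = 20) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  if (!id_col %in% names(df)) stop("sample id column '", id_col, "' not found")
  out <- data.frame(sample_id = as.character(df[[id_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample identifier(s) in label table")
  if (!is.null(ki67_percent_col) && ki67_percent_col %in% names(df)) {
    pct <- as.numeric(df[[ki67_percent_col]])
    out$ki67 <- ifelse(is.na(pct), NA_integer_,
                       as.integer(pct > ki67_cutoff))
  } else if (!is.null(ki67_col) && ki67_col %in% names(df)) {
    v <- suppressWarnings(as.integer(df[[ki67_col]]))
    if (any(!v %in% c(0L, 1L) & !is.na(v)))
      stop("ki67 labels must be 0/1 (or provide a percentage column)")
    out$ki67 <- v
  } else out$ki67 <- NA_integer_
  out$nhg <- if (!is.null(nhg_col) && nhg_col %in% names(df))
    parse_nhg(df[[nhg_col]]) else NA_integer_
  has_time <- !is.null(time_col) && time_col %in% names(df)
  has_event <- !is.null(event_col) && event_col %in% names(df)
  if (has_time != has_event)
    stop("survival_days and event columns must be present together")
  if (has_time) {
    out$survival_days <- as.numeric(df[[time_col]])
    if (any(out$survival_days < 0, na.rm = TRUE))
      stop("survival_days must be >= 0")
    ev <- as.integer(df[[event_col]])
    if (any(!ev %in% c(0L, 1L) & !is.na(ev)))
      stop("event must be 0 (censored) or 1 (event)")
    out$event <- ev
  }
  structure(out, class = c("label_set", "data.frame"))
}
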