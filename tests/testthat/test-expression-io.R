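test_that("delimited expression tables parse with validation", {
  mat <- toy_expression()
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = rownames(mat$values), mat$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_expression_table(path)
  expect_equal(dim(got$values), dim(mat$values))
  expect_equal(rownames(got$values), rownames(mat$values))
  expect_equal(colnames(got$values), colnames(mat$values))
  expect_equal(got$values, mat$values)

  # genes-in-rows orientation transposes back to samples x genes
  patht <- withr::local_tempfile(fileext = ".tsv")
  dft <- data.frame(gene = colnames(mat$values), t(mat$values),
                    check.names = FALSE)
  write.table(dft, patht, sep = "\t", quote = FALSE, row.names = FALSE)
  gott <- read_expression_table(patht, orientation = "genes_x_samples")
  expect_equal(gott$values, mat$values)
})

test_that("duplicate identifiers and negative FPKM are named in errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tTP53\tTP53", "S1\t1\t2", "S2\t3\t4"), path)
  expect_error(read_expression_table(path), "TP53")

  m <- matrix(c(1, 2, -2, 4), 2, 2,
              dimnames = list(c("S1", "S2"), c("GA", "GB")))
  err <- tryCatch(expression_matrix(m, "fpkm"), error = conditionMessage)
  expect_match(err, "negative")
  expect_match(err, "S1")
  expect_match(err, "GB")
})

test_that("log2 transform matches log2(x + pseudocount) and round-trips", {
  m <- expression_matrix(matrix(c(0, 1, 3, 7), 1, 4,
                                dimnames = list("S1", paste0("G", 1:4))),
                         "fpkm")
  lg <- log2_transform(m)
  expect_equal(unname(lg$values[1, ]), c(0, 1, 2, 3))
  expect_identical(lg$scale, "log2")
  expect_error(log2_transform(lg), "already")

  set.seed(1)
  x <- matrix(rexp(50, 1 / 5), 5, 10,
              dimnames = list(paste0("S", 1:5), paste0("G", 1:10)))
  lg2 <- log2_transform(expression_matrix(x, "fpkm"), pseudocount = 1)
  expect_equal(2^lg2$values - 1, x, tolerance = 1e-9)
})

test_that("shared gene order sorts by chromosome rank, TSS, then symbol", {
  ann <- toy_annotation()
  ord <- shared_gene_order(ann, list(c("GA", "GB", "GC"),
                                     c("GB", "GC", "GD", "GA")), 3)
  # chr2 (GB tss 100 < GA tss 500) before chr10 (GC) before X (GD)
  expect_equal(as.character(ord), c("GB", "GA", "GC"))

  # numeric, not lexicographic, chromosome ordering: chr2 < chr10
  ann2 <- gene_annotation(c("A2", "B2", "A10", "B10"),
                          c("2", "2", "10", "10"), c(10, 20, 1, 2))
  ord2 <- shared_gene_order(ann2, list(c("A2", "B2", "A10", "B10")), 4)
  expect_equal(as.character(ord2), c("A2", "B2", "A10", "B10"))

  # ties on (chromosome, tss) break by symbol
  ann3 <- gene_annotation(c("ZZ", "AA"), c("1", "1"), c(5, 5))
  expect_equal(as.character(shared_gene_order(ann3, list(c("ZZ", "AA")), 2)),
               c("AA", "ZZ"))

  expect_error(shared_gene_order(ann, list(c("GA", "GB"), c("GC")), 1),
               "intersection has 0")
  err <- tryCatch(shared_gene_order(ann, list(c("GA", "GB")), 5),
                  error = conditionMessage)
  expect_match(err, "2")
  expect_match(err, "5")
})

test_that("shared gene order is invariant to dataset and row permutations", {
  set.seed(3)
  ann <- gene_annotation(sprintf("G%02d", 1:20),
                         rep(c("1", "2", "X"), length.out = 20),
                         sample(1e5, 20))
  lists <- list(sprintf("G%02d", 1:18), sprintf("G%02d", 3:20),
                sprintf("G%02d", 2:19))
  ref <- shared_gene_order(ann, lists, 10)
  for (i in 1:5) {
    perm_ann <- ann[sample(nrow(ann)), ]
    class(perm_ann) <- class(ann)
    got <- shared_gene_order(perm_ann, sample(lists),
                             10)
    expect_equal(as.character(got), as.character(ref))
  }
})

test_that("per-gene rescaling hits endpoints, handles constants, clips", {
  m <- expression_matrix(matrix(c(2, 4, 6, 5, 5, 5), 3, 2,
                                dimnames = list(paste0("S", 1:3),
                                                c("GA", "GB"))),
                         "log2")
  ord <- structure(c("GA", "GB"), class = "gene_order")
  rs <- rescale_per_gene(m, ord)
  expect_equal(unname(rs$scaled$values[, "GA"]), c(0L, 128L, 255L))
  expect_equal(unname(rs$scaled$values[, "GB"]), c(0L, 0L, 0L))

  # prefit scaler clips out-of-range test values
  m2 <- expression_matrix(matrix(c(8, 1), 2, 1,
                                 dimnames = list(c("T1", "T2"), "GA")),
                          "log2")
  expect_error(rescale_per_gene(m2, ord, rs$scaler), "GB")
  ord_a <- structure("GA", class = "gene_order")
  sc_a <- structure(list(gene = "GA", min = 2, max = 6),
                    class = "scaler_params")
  rs2 <- rescale_per_gene(m2, ord_a, sc_a)
  expect_equal(unname(rs2$scaled$values[, 1]), c(255L, 0L))

  expect_error(rescale_per_gene(m, structure("GZ", class = "gene_order")),
               "GZ")
})

test_that("rescaling keeps all outputs in 0..255 and maps extrema exactly", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:20, 1)
    g <- sample(3:12, 1)
    x <- matrix(rnorm(n * g, 5, 3), n, g,
                dimnames = list(paste0("S", 1:n), paste0("G", 1:g)))
    m <- expression_matrix(x, "log2")
    ord <- structure(paste0("G", 1:g), class = "gene_order")
    v <- rescale_per_gene(m, ord)$scaled$values
    expect_true(all(v >= 0L & v <= 255L))
    for (j in 1:g) {
      expect_equal(v[which.min(x[, j]), j], 0L)
      expect_equal(v[which.max(x[, j]), j], 255L)
    }
  }
})

test_that("scaler parameters persist as TSV and round-trip", {
  sc <- structure(list(gene = c("GA", "GB"), min = c(0.5, 1),
                       max = c(7.25, 9)), class = "scaler_params")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scaler(sc, path)
  got <- read_scaler(path)
  expect_equal(got$gene, sc$gene)
  expect_equal(got$min, sc$min)
  expect_equal(got$max, sc$max)
})

test_that("label reading dichotomizes Ki67 at 20% and codes NHG 0/1/2", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,ki67_percent,nhg,survival_days,event",
               "S1,20,Grade III,100,1",
               "S2,20.1,I,250,0",
               "S3,NA,II,300,1",
               "S4,55,,50,0"), path)
  lab <- read_labels(path)
  expect_equal(lab$ki67, c(0L, 1L, NA, 1L))
  expect_equal(lab$nhg, c(2L, 0L, 1L, NA))
  expect_equal(lab$survival_days, c(100, 250, 300, 50))

  # 1-based numeric grades disambiguated by presence of a 3
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,nhg", "S1,1", "S2,3", "S3,2"), path2)
  expect_equal(read_labels(path2)$nhg, c(0L, 2L, 1L))

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,nhg", "S1,IV"), path3)
  expect_error(read_labels(path3), "invalid NHG")
})
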