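test_that("expression TSV round-trips value-identically, with rows preserved", {
  x <- toy_expression(n_genes = 12, samples = c("a", "b", "c"))
  # shuffle rows: loading must preserve them as given, ordering is deferred
  perm <- sample(nrow(x$values))
  shuffled <- expression_data(x$values[perm, ], x$annotation, x$scale)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(shuffled, path)
  back <- read_expression(path, scale = "log2cpm")
  expect_identical(rownames(back$values), rownames(shuffled$values))
  expect_equal(back$values, shuffled$values)
  expect_equal(as.character(back$annotation$chromosome),
               as.character(shuffled$annotation[
                 match(rownames(shuffled$values), shuffled$annotation$gene_id),
                 "chromosome"]))
})

test_that("malformed expression input is rejected", {
  x <- toy_expression(n_genes = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  tab <- read.delim(path, check.names = FALSE)
  # duplicated gene row
  dup <- rbind(tab, tab[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(path), "duplicate gene ids")
  # non-numeric cell
  bad <- tab; bad$s1 <- as.character(bad$s1); bad$s1[2] <- "oops"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(path), "non-numeric")
  # unknown chromosome
  bad2 <- tab; bad2$chromosome[1] <- "MT"
  write.table(bad2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(path), "chromosome")
  # NA cell
  expect_error(expression_data(matrix(c(1, NA), 1, 2,
                                      dimnames = list("g1", c("a", "b"))),
                               x$annotation[1, ], "counts"),
               "missing")
})

test_that("pairing forms the full intra x extra cross product per patient", {
  expect_equal(nrow(build_pairs(toy_sheet(c(A = 1)))), 1L)
  p6 <- build_pairs(toy_sheet(c(A = 3)))
  # add a second intracranial sample: 2 x 3 = 6
  sheet <- toy_sheet(c(A = 3))
  sheet <- rbind(sheet, data.frame(sample_id = "A_i2", patient_id = "A",
                                   compartment = "intracranial",
                                   tissue = "brain"))
  p <- build_pairs(sheet)
  expect_equal(nrow(p), 6L)
  # brute-force enumeration oracle
  expected <- sort(as.vector(outer(c("A_i", "A_i2"),
                                   c("A_e1", "A_e2", "A_e3"),
                                   function(i, e) paste0("PA_", i, "-", e))))
  expect_setequal(p$pair_id, expected)
})

test_that("pair counts match the analytic cross-product sum on random sheets", {
  set.seed(7)
  for (rep in 1:10) {
    n_pat <- sample(2:6, 1)
    counts <- sample(0:3, n_pat, replace = TRUE)
    intra <- sample(1:2, n_pat, replace = TRUE)
    sheet <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      pt <- paste0("pt", i)
      rbind(
        if (intra[i] > 0)
          data.frame(sample_id = sprintf("%s_i%d", pt, seq_len(intra[i])),
                     patient_id = pt, compartment = "intracranial",
                     tissue = "brain"),
        if (counts[i] > 0)
          data.frame(sample_id = sprintf("%s_e%d", pt, seq_len(counts[i])),
                     patient_id = pt, compartment = "extracranial",
                     tissue = "lung"))
    }))
    pairs <- suppressWarnings(build_pairs(sheet))
    expect_equal(nrow(pairs), sum(intra * counts * (counts > 0)))
    expect_false(anyDuplicated(pairs$pair_id) > 0)
  }
})

test_that("patients lacking one compartment are skipped with a warning", {
  sheet <- toy_sheet(c(A = 1))
  sheet <- rbind(sheet, data.frame(sample_id = "B_i", patient_id = "B",
                                   compartment = "intracranial",
                                   tissue = "brain"))
  expect_warning(p <- build_pairs(sheet), "lacks samples")
  expect_equal(p$patient_id, "A")
})

test_that("gene ordering sorts by chromosome then start, stably and idempotently", {
  ann <- gene_annotation(c("a", "b", "c"), c("2", "1", "1"), c(100, 500, 200))
  expect_equal(order_genes(ann), c("c", "b", "a"))
  # idempotence: ordering the ordered annotation is the identity
  ord <- order_genes(ann)
  ann2 <- ann[match(ord, ann$gene_id), ]
  expect_equal(order_genes(ann2), ord)
  # oracle: lexicographic key sort on 50 shuffled genes, X/Y after autosomes
  set.seed(3)
  ann3 <- gene_annotation(
    sprintf("g%02d", 1:50),
    sample(c(as.character(1:22), "X", "Y"), 50, replace = TRUE),
    sample(1:1e6, 50))
  key <- sprintf("%02d_%09d",
                 match(as.character(ann3$chromosome), c(as.character(1:22), "X", "Y")),
                 ann3$start)
  expect_equal(order_genes(ann3), ann3$gene_id[order(key)])
  # bijection
  expect_setequal(order_genes(ann3), ann3$gene_id)
})

test_that("the study cohort sheet reproduces the published composition", {
  sheet <- study_sample_sheet()
  expect_equal(nrow(sheet), 37L)
  expect_equal(sum(sheet$compartment == "intracranial"), 16L)
  expect_equal(length(unique(sheet$patient_id)), 16L)
})
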