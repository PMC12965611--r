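# Loading, alignment, filtering and scaling of omics and response data.

write_omics_fixture <- function(dir, cells = sprintf("c%02d", 1:6),
                                drop_cell_from = NULL) {
  genes <- list(expression = paste0("G", 1:12),
                mutation = paste0("G", 1:10),
                methylation = paste0("G", 1:8),
                pathway = paste0("P", 1:5))
  paths <- list()
  set.seed(1)
  for (name in names(genes)) {
    rows <- cells
    if (identical(drop_cell_from, name)) rows <- cells[-1]
    m <- matrix(round(rnorm(length(rows) * length(genes[[name]])), 3),
                length(rows), length(genes[[name]]),
                dimnames = list(rows, genes[[name]]))
    if (name == "mutation") m <- (m > 0) * 1
    df <- data.frame(cell_id = rows, m, check.names = FALSE)
    paths[[name]] <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, paths[[name]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}

test_that("load_omics_set applies the gene whitelist in whitelist order", {
  dir <- withr::local_tempdir()
  p <- write_omics_fixture(dir)
  wl <- file.path(dir, "genes.txt")
  writeLines(c("G5", "G2", "G9", "ZZZ_ABSENT"), wl)
  om <- load_omics_set(p$expression, p$mutation, p$methylation,
                       p$pathway, gene_whitelist = wl)
  expect_identical(colnames(om$expression), c("G5", "G2", "G9"))
  expect_identical(colnames(om$mutation), c("G5", "G2", "G9"))
  expect_identical(colnames(om$methylation), c("G5", "G2"))  # G9 absent
  expect_identical(ncol(om$pathway), 5L)  # pathway never filtered
  expect_identical(om$cell_ids, sort(om$cell_ids))
})

test_that("cells missing from one file are dropped with a warning", {
  dir <- withr::local_tempdir()
  p <- write_omics_fixture(dir, drop_cell_from = "methylation")
  expect_warning(
    om <- load_omics_set(p$expression, p$mutation, p$methylation,
                         p$pathway),
    "dropped cells")
  expect_identical(length(om$cell_ids), 5L)
  for (name in c("expression", "mutation", "methylation", "pathway"))
    expect_identical(rownames(om[[name]]), om$cell_ids)
})

test_that("mutation aggregation is presence/absence and idempotent", {
  rec <- data.frame(
    cell_id = c("c1", "c1", "c1", "c2", "c2"),
    gene = c("TP53", "TP53", "TP53", "TP53", "KRAS"),
    mutation_type = c("missense", "nonsense", "frameshift",
                      "missense", "splice"))
  m <- aggregate_mutations(rec)
  expect_identical(unname(m["c1", "TP53"]), 1L)  # 3 types -> one bit
  expect_identical(unname(m["c2", "KRAS"]), 1L)
  expect_identical(unname(m["c1", "KRAS"]), 0L)  # no record -> 0
  expect_true(all(m %in% c(0L, 1L)))
  # idempotence: re-aggregating the binarized records changes nothing
  rec2 <- subset(data.frame(cell_id = rep(rownames(m), ncol(m)),
                            gene = rep(colnames(m), each = nrow(m)),
                            present = as.vector(m)), present == 1)
  expect_identical(aggregate_mutations(rec2[1:2]), m)
})

test_that("scaler standardizes training columns and freezes parameters", {
  set.seed(3)
  train <- cbind(matrix(rnorm(40, 5, 2), 20, 2), 7)  # constant 3rd col
  test <- cbind(matrix(rnorm(10, 9, 2), 5, 2), 7)
  sc <- fit_scaler(train)
  st <- apply_scaler(sc, train)
  expect_equal(unname(colMeans(st[, 1:2])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(st[, 1:2], 2, sd)), c(1, 1),
               tolerance = 1e-12)
  expect_true(all(st[, 3] == 0))  # constant column -> zeros
  # round-trip is bit-stable
  expect_identical(apply_scaler(sc, train), st)
  # test columns scaled with train parameters are not re-centred
  stest <- apply_scaler(sc, test)
  expect_gt(abs(mean(stest[, 1])), 0.5)
  expect_error(apply_scaler(sc, test[, 1:2]), class = "drp_shape_error")
})

test_that("response loading drops bad rows and reports them", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "resp.tsv")
  writeLines(c("drug_id\tcell_id\tln_ic50",
               "d1\tc1\t1.5",
               "d1\tc2\t",          # missing response
               "d2\tc1\t2.5",
               "dX\tc1\t0.5",       # unknown drug
               "d2\tc1\t9.9",       # duplicate pair
               "d2\tc2\t-1.0"), f)
  expect_warning(
    pd <- load_response_table(f, drug_ids = c("d1", "d2"),
                              cell_ids = c("c1", "c2")),
    "dropped")
  expect_identical(nrow(pd), 3L)
  expect_identical(pd$ln_ic50[pd$drug_id == "d2" & pd$cell_id == "c1"],
                   2.5)  # first occurrence kept
  expect_true(all(pd$split == "none"))
  # all rows unusable -> data error
  writeLines(c("drug_id\tcell_id\tln_ic50", "dX\tc1\t1"), f)
  expect_error(
    suppressWarnings(load_response_table(f, drug_ids = "d1",
                                         cell_ids = "c1")),
    class = "drp_data_error")
})

test_that("row order of input files does not change the loaded set", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_omics_fixture(dir1)
  # rewrite with permuted rows
  for (name in names(p1)) {
    tab <- utils::read.delim(p1[[name]], check.names = FALSE)
    set.seed(9)
    tab <- tab[sample(nrow(tab)), ]
    utils::write.table(tab, file.path(dir2, basename(p1[[name]])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  om1 <- load_omics_set(p1$expression, p1$mutation, p1$methylation,
                        p1$pathway)
  om2 <- load_omics_set(file.path(dir2, "expression.tsv"),
                        file.path(dir2, "mutation.tsv"),
                        file.path(dir2, "methylation.tsv"),
                        file.path(dir2, "pathway.tsv"))
  expect_identical(om1$expression, om2$expression)
  expect_identical(om1$mutation, om2$mutation)
})
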