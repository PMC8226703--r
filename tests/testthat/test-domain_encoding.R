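test_that("parse_annotations deduplicates accessions and keeps first-appearance order", {
  lines <- c("P1\tIPR001304", "P1\tIPR000436", "P1\tIPR001304", "P2\t")
  ann <- parse_annotations(lines, dialect = "tsv2")
  expect_length(ann, 2L)
  expect_equal(ann[[1]]$protein_id, "P1")
  expect_equal(ann[[1]]$domains, c("IPR001304", "IPR000436"))
  expect_equal(ann[[2]]$protein_id, "P2")
  expect_length(ann[[2]]$domains, 0L)

  # bare one-field line also records a protein with no accession
  ann2 <- parse_annotations(c("P9"), dialect = "tsv2")
  expect_length(ann2[[1]]$domains, 0L)

  expect_equal(parse_annotations(character(), "tsv2"), list())
  expect_error(parse_annotations("P1\ta\tb", "tsv2"), "line 1")
})

test_that("parse_annotations reads the InterProScan TSV dialect", {
  ipr_line <- function(id, acc) {
    paste(c(id, "md5", "100", "Pfam", "PF00001", "desc", "1", "90",
            "1e-10", "T", "25-04-2021", acc, "name"), collapse = "\t")
  }
  lines <- c(ipr_line("P1", "IPR001304"),
             ipr_line("P1", "-"),
             ipr_line("P2", "IPR000436"),
             # 11-column line: no InterPro column at all
             paste(rep("x", 11), collapse = "\t"))
  ann <- parse_annotations(lines, dialect = "interproscan")
  expect_equal(vapply(ann, `[[`, "", "protein_id"), c("P1", "P2", "x"))
  expect_equal(ann[[1]]$domains, "IPR001304")
  expect_length(ann[[3]]$domains, 0L)
  expect_error(parse_annotations("P1\tonly\tthree", "interproscan"), "line 1")
})

test_that("a six-protein fixture parses to the hand-built expectation table", {
  lines <- c("A\tIPR000001", "B\tIPR000001", "B\tIPR000002", "C\t",
             "D\tIPR000003", "D\tIPR000004", "D\tIPR000001",
             "E\tIPR000002", "F\tIPR000004", "A\tIPR000002")
  ann <- parse_annotations(lines, "tsv2")
  expected <- list(A = c("IPR000001", "IPR000002"),
                   B = c("IPR000001", "IPR000002"),
                   C = character(),
                   D = c("IPR000003", "IPR000004", "IPR000001"),
                   E = "IPR000002", F = "IPR000004")
  expect_equal(vapply(ann, `[[`, "", "protein_id"), names(expected))
  for (i in seq_along(ann)) {
    expect_equal(ann[[i]]$domains, expected[[i]], ignore_attr = TRUE)
  }
})

test_that("build_domain_matrix matches hand enumeration and counts removals per class", {
  lines <- c("A\tD1", "A\tD2", "B\tD2", "C\t", "D\tD3", "E\tD1", "E\tD3")
  labels <- c(A = 1L, B = 2L, C = 1L, D = 2L, E = 2L)
  dm <- build_domain_matrix(parse_annotations(lines, "tsv2"), labels)
  expect_equal(rownames(dm$incidence), c("A", "B", "D", "E"))
  expect_equal(colnames(dm$incidence), c("D1", "D2", "D3"))
  expect_equal(as.matrix(dm$incidence),
               matrix(c(1, 0, 0, 1,
                        1, 1, 0, 0,
                        0, 0, 1, 1), 4, 3,
                      dimnames = list(c("A", "B", "D", "E"), c("D1", "D2", "D3"))))
  expect_equal(dm$labels, c(1L, 2L, 2L, 2L))
  expect_equal(dm$removed, c(pos = 1L, neg = 0L))
})

test_that("unannotated and label-only proteins are removed and counted", {
  ann <- parse_annotations(c("A\tD1", "B\t"), "tsv2")
  labels <- c(A = 1L, B = 2L, Z = 2L)  # Z labelled but never annotated
  dm <- build_domain_matrix(ann, labels)
  expect_equal(rownames(dm$incidence), "A")
  expect_equal(dm$removed, c(pos = 0L, neg = 2L))
  # kept + removed = labelled input count, per class
  expect_equal(sum(dm$labels == 1L) + dm$removed[["pos"]], sum(labels == 1L))
  expect_equal(sum(dm$labels == 2L) + dm$removed[["neg"]], sum(labels == 2L))
})

test_that("build_domain_matrix enforces label and uniqueness contracts", {
  ann <- parse_annotations(c("A\tD1", "B\tD2"), "tsv2")
  expect_error(build_domain_matrix(ann, c(A = 1L)), "B")
  dup <- c(ann, ann[1])
  expect_error(build_domain_matrix(dup, c(A = 1L, B = 2L)), "duplicate")
})

test_that("matrix construction invariants hold on random annotation inputs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    doms <- sprintf("IPR%06d", 1:8)
    ann <- lapply(seq_len(n), function(i) {
      list(protein_id = sprintf("P%02d", i),
           domains = sample(doms, sample(0:4, 1)))
    })
    labels <- stats::setNames(sample(c(1L, 2L), n, replace = TRUE),
                              sprintf("P%02d", seq_len(n)))
    dm <- build_domain_matrix(ann, labels)
    expect_true(all(Matrix::rowSums(dm$incidence) > 0))
    expect_equal(nrow(dm$incidence) + sum(dm$removed), n)
    union_doms <- unique(unlist(lapply(ann, `[[`, "domains")))
    expect_equal(ncol(dm$incidence), length(union_doms))
    # determinism: identical inputs give identical matrices
    dm2 <- build_domain_matrix(ann, labels)
    expect_identical(as.matrix(dm$incidence), as.matrix(dm2$incidence))
    expect_identical(dm$labels, dm2$labels)
  }
})

test_that("triplet and MatrixMarket round-trips are the identity", {
  dm <- random_dm(20, 15, density = 0.25, seed = 11)
  for (ext in c("mat.tsv", "mat.mtx")) {
    path <- file.path(withr::local_tempdir(), ext)
    write_domain_matrix(dm, path)
    back <- read_domain_matrix(path)
    expect_identical(rownames(back$incidence), rownames(dm$incidence))
    expect_identical(colnames(back$incidence), colnames(dm$incidence))
    expect_equal(as.matrix(back$incidence), as.matrix(dm$incidence))
    expect_identical(back$labels, dm$labels)
  }
})

test_that("matrix files with foreign values or labels are rejected", {
  path <- withr::local_tempfile()
  writeLines(c("#rows\tP1\tP2", "#cols\tD1", "#labels\t1\t2",
               "P1\tD1\t2"), path)
  expect_error(read_domain_matrix(path), "value must be 1")
  writeLines(c("#rows\tP1", "#cols\tD1", "#labels\t3", "P1\tD1\t1"), path)
  expect_error(read_domain_matrix(path), "labels must be 1 or 2")
  writeLines(c("#rows\tP1", "#cols\tD1", "#labels\t1", "P9\tD1\t1"), path)
  expect_error(read_domain_matrix(path), "absent from headers")
})

test_that("an empty (0-row) matrix survives a round-trip and is flagged downstream", {
  dm <- domain_matrix(Matrix::Matrix(0, 0, 0, sparse = TRUE), integer())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_matrix(dm, path)
  back <- read_domain_matrix(path)
  expect_equal(dim(back), c(0L, 0L))
  expect_error(mrmr_rank(back, 1), ">= 1 row")
})

test_that("label files are validated", {
  path <- withr::local_tempfile()
  writeLines(c("A\t1", "B\t2"), path)
  expect_equal(read_labels(path), c(A = 1L, B = 2L))
  writeLines(c("A\t1", "A\t2"), path)
  expect_error(read_labels(path), "duplicate")
  writeLines("A\t3", path)
  expect_error(read_labels(path), "class must be 1")
})
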