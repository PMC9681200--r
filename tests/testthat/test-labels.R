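test_that("cell-essential calls are strictly above the threshold", {
  dm <- dep_long(matrix(c(0.66, 0.65, 0.0, 1.0), nrow = 2, ncol = 2,
                        dimnames = list(c("g1", "g2"), c("c1", "c2"))))
  ls <- call_cell_essential(dm, threshold = 0.65)
  lookup <- function(g, c) ls$label[ls$gene_id == g & ls$cell_line_id == c]
  expect_equal(lookup("g1", "c1"), 1L)  # 0.66
  expect_equal(lookup("g2", "c1"), 0L)  # 0.65 exactly: strict
  expect_equal(lookup("g1", "c2"), 0L)  # 0.00
  expect_equal(lookup("g2", "c2"), 1L)  # 1.00
  expect_error(call_cell_essential(dm, threshold = 0),
               class = "depnet_argument_error")
})

test_that("strictness is symmetric: t and 1-(1-t) give identical calls", {
  withr::local_seed(14)
  dm <- dep_long(matrix(runif(200), 20, 10,
                        dimnames = list(paste0("g", 1:20), paste0("c", 1:10))))
  t <- 0.65
  expect_equal(call_cell_essential(dm, t)$label,
               call_cell_essential(dm, 1 - (1 - t))$label)
})

test_that("pan-essential genes are essential in every line", {
  dm <- dep_long(matrix(c(0.9, 0.9, 0.9,   # pan
                          0.9, 0.9, 0.1,   # 2/3
                          0.1, 0.1, 0.1),  # never
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("pan", "some", "none"),
                                        c("c1", "c2", "c3"))))
  ls <- call_cell_essential(dm)
  expect_equal(pan_essential_set(ls), "pan")
  expect_equal(pan_essential_set(ls[0, ]), character(0))
})

test_that("the variation filter honours the chosen dispersion statistic", {
  flat <- rep(0.9, 10)
  alternating <- rep(c(0, 1), 5)
  dm <- dep_long(rbind(flat = flat, alt = alternating) |>
                   `colnames<-`(paste0("c", 1:10)))
  # alternating 0/1: sample variance 0.2778, sd 0.527, range 1
  expect_equal(var(alternating), 0.2777778, tolerance = 1e-6)
  for (stat in c("variance", "sd", "range")) {
    kept <- variance_filter(dm, 0.1, stat)
    expect_false("flat" %in% kept)
    expect_true("alt" %in% kept)
  }
  expect_setequal(variance_filter(dm, 0), c("flat", "alt"))
})

test_that("balanced splits downsample, stratify 60/20/20 and reproduce", {
  withr::local_seed(31)
  probs <- c(runif(100, 0.7, 1), runif(300, 0, 0.6))
  dm <- dep_long(matrix(probs, ncol = 1,
                        dimnames = list(paste0("g", 1:400), "c1")))
  ls <- call_cell_essential(dm)
  sp <- balanced_split(ls, "c1", seed = 5)
  pool <- c(sp$train, sp$validation, sp$test)
  expect_equal(length(pool), 200L)  # 100 positives + 100 downsampled negatives
  expect_equal(length(sp$test), 40L)
  expect_equal(length(sp$validation), 40L)
  expect_equal(length(sp$train), 120L)
  # disjoint partitions covering the pool
  expect_equal(anyDuplicated(pool), 0L)
  # class balance within +/- 1 in every partition
  for (part in list(sp$train, sp$validation, sp$test)) {
    expect_lte(abs(sum(sp$labels[part] == 1) - sum(sp$labels[part] == 0)), 1L)
  }
  sp2 <- balanced_split(ls, "c1", seed = 5)
  expect_identical(sp[c("train", "validation", "test")],
                   sp2[c("train", "validation", "test")])
  sp3 <- balanced_split(ls, "c1", seed = 6)
  expect_false(identical(sp$train, sp3$train))
})

test_that("a too-small minority class is refused with the cell line named", {
  dm <- dep_long(matrix(c(rep(0.9, 3), rep(0.1, 50)), ncol = 1,
                        dimnames = list(paste0("g", 1:53), "tiny_line")))
  ls <- call_cell_essential(dm)
  expect_error(balanced_split(ls, "tiny_line", seed = 1),
               class = "depnet_argument_error")
  expect_error(balanced_split(ls, "tiny_line", seed = 1), "tiny_line")
})

test_that("rarity strata bin by essentiality count and nest properly", {
  withr::local_seed(77)
  n_lines <- 39
  counts <- c(a = 39, b = 29, c = 19, d = 5, e = 1, f = 0)
  mat <- t(sapply(counts, function(k) {
    c(rep(0.9, k), rep(0.1, n_lines - k))
  }))
  colnames(mat) <- paste0("c", 1:n_lines)
  ls <- call_cell_essential(dep_long(mat))
  strata <- rarity_strata(ls, bounds = c(30, 20, 10))
  expect_equal(strata$all, "a")
  expect_setequal(strata[["<30"]], c("b", "c", "d", "e"))
  expect_setequal(strata[["<20"]], c("c", "d", "e"))
  expect_setequal(strata[["<10"]], c("d", "e"))
  expect_equal(strata[["1"]], "e")
  # nesting of the bounded strata
  expect_true(all(strata[["<10"]] %in% strata[["<20"]]))
  expect_true(all(strata[["<20"]] %in% strata[["<30"]]))
  # never-essential genes belong to no stratum
  expect_false("f" %in% unlist(strata))
})

test_that("per-count strata partition the cell-essential gene set", {
  withr::local_seed(50)
  dm <- dep_long(matrix(runif(600), 60, 10,
                        dimnames = list(paste0("g", 1:60), paste0("c", 1:10))))
  ls <- call_cell_essential(dm)
  counts <- ls |>
    dplyr::distinct(.data$gene_id, .data$essential_in) |>
    dplyr::filter(.data$essential_in > 0)
  by_count <- table(counts$essential_in)
  expect_equal(sum(by_count), nrow(counts))
})

test_that("DepMap-style gene headers are stripped on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "TP53 (7157),0.9,0.2", "BRCA1 (672),0.1,0.8"),
             path)
  dm <- read_dependency_matrix(path)
  expect_setequal(unique(dm$gene_id), c("TP53", "BRCA1"))
  expect_equal(nrow(dm), 4L)
})
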