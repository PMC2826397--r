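# Readers, writers and validation for every domain type.

test_that("prediction lists read in file order and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ranked edges",
               "G85\tG1\t1.00", "G85\tG10\t0.99",
               "G10\tG85\t0.73", "G99\tG52\t0.44"), f)
  pl <- read_prediction_list(f, universe = 100)
  expect_s3_class(pl, "prediction_list")
  expect_equal(nrow(pl), 4)
  expect_equal(pl$source[1], "G85")
  expect_equal(pl$target[1], "G1")
  expect_equal(pl$confidence, c(1, 0.99, 0.73, 0.44))
  expect_length(attr(pl, "nodes"), 100)

  # order is authoritative even with tied confidences
  writeLines(c("b\ta\t0.5", "a\tb\t0.5", "c\ta\t0.5"), f)
  pl2 <- read_prediction_list(f)
  expect_equal(pl2$source, c("b", "a", "c"))
})

test_that("malformed prediction lists raise typed errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(read_prediction_list(f), "no edges",
               class = "dreambench_validation_error")

  writeLines("G1\tG1\t0.5", f)
  expect_error(read_prediction_list(f), "self-edge",
               class = "dreambench_validation_error")

  writeLines(c("G1\tG2\t0.5", "G1\tG2\t0.4"), f)
  expect_error(read_prediction_list(f), "duplicate",
               class = "dreambench_validation_error")

  writeLines(c("G1\tG2\t0.5", "G2\tG1\t0.9"), f)
  expect_error(read_prediction_list(f), "row 2",
               class = "dreambench_validation_error")
})

test_that("gold networks accept explicit-negative style and reject conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t1", "B\tC\t1", "A\tC\t0"), f)
  g <- read_gold_network(f)
  expect_equal(g$n_positives, 2)
  expect_equal(g$n_candidates, 6)

  writeLines(c("A\tB\t1", "A\tB\t0"), f)
  expect_error(read_gold_network(f), "both",
               class = "dreambench_validation_error")
  writeLines(c("A\tA\t1"), f)
  expect_error(read_gold_network(f), "self-edge",
               class = "dreambench_validation_error")
})

test_that("measurement tables mask NA cells and reject bad values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("condition\takt\terk", "c1\t100\tNA", "c2\t200\t300"), f)
  mt <- read_measurement_table(f)
  expect_equal(sum(mt$mask), 1)
  expect_true(mt$mask[1, "erk"])
  expect_equal(mt$values[2, "akt"], 200)

  writeLines(c("condition\takt", "c1\t100", "c2\t200"), f)
  expect_equal(sum(read_measurement_table(f)$mask), 0)

  writeLines(c("condition\takt", "c1\t-5"), f)
  expect_error(read_measurement_table(f), "negative",
               class = "dreambench_validation_error")

  # empty-string and NaN spellings of NA also mask
  writeLines(c("condition\takt\terk", "c1\tNaN\t", "c2\t1\t2"), f)
  expect_equal(sum(read_measurement_table(f)$mask), 2)
})

test_that("rank matrices enforce the column-permutation invariant", {
  m <- rank_matrix(cbind(t1 = 1:3, t2 = c(3, 1, 2)))
  expect_s3_class(m, "rank_matrix")
  expect_error(rank_matrix(cbind(t1 = c(1, 1, 3))), "permutation",
               class = "dreambench_validation_error")
})

test_that("assignment tables are injective and total", {
  sp <- paste0("s", 1:7)
  at <- assignment_table(c(x1 = "s1", x2 = "s2"), species = sp)
  expect_equal(length(at$measurements), 2)
  expect_error(assignment_table(c(x1 = "s1", x2 = "s1"), species = sp),
               "injective", class = "dreambench_validation_error")
  expect_error(assignment_table(stats::setNames(paste0("s", 1:4), paste0("x", 1:4)),
                                species = paste0("s", 1:3)),
               class = "dreambench_validation_error")
})

test_that("every type round-trips through its writer and reader", {
  dir <- withr::local_tempdir()

  pl <- prediction_list(c("a", "b", "c"), c("b", "c", "a"),
                        confidence = c(0.9, 0.5, 0.5), universe = 3)
  f <- file.path(dir, "pred.tsv")
  write_prediction_list(pl, f)
  pl2 <- read_prediction_list(f, universe = 3)
  expect_equal(as.data.frame(pl2), as.data.frame(pl))

  g <- gold_network(c("a", "b", "c"),
                    data.frame(source = c("a", "b"), target = c("b", "c")))
  f <- file.path(dir, "gold.tsv")
  write_gold_network(g, f)
  g2 <- read_gold_network(f, nodes = g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$nodes, g$nodes)

  mt <- make_response_fixture()$train
  f <- file.path(dir, "meas.tsv")
  write_measurement_table(mt, f)
  mt2 <- read_measurement_table(f)
  expect_equal(unname(mt2$mask), unname(mt$mask))
  expect_equal(unname(mt2$values[!mt2$mask]), unname(mt$values[!mt$mask]),
               tolerance = 1e-12)

  rm_ <- rank_matrix(matrix(c(1:5, c(2, 1, 4, 5, 3)), 5, 2,
                            dimnames = list(paste0("g", 1:5), c("t0", "t1"))))
  f <- file.path(dir, "ranks.tsv")
  write_rank_matrix(rm_, f)
  expect_equal(unclass(read_rank_matrix(f)), unclass(rm_))

  at <- assignment_table(c(x1 = "s3", x2 = "s1"), species = paste0("s", 1:5))
  f <- file.path(dir, "assign.tsv")
  write_assignment_table(at, f)
  at2 <- read_assignment_table(f, species = at$species)
  expect_equal(at2$mapping, at$mapping)
})

test_that("a simulator 50x8 rank fixture round-trips with G=50, T=8", {
  set.seed(42)
  m <- rank_matrix(matrix(unlist(lapply(1:8, function(i) sample(50))), 50, 8,
                          dimnames = list(sprintf("g%02d", 1:50),
                                          sprintf("t%d", 1:8))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rank_matrix(m, f)
  m2 <- read_rank_matrix(f)
  expect_equal(dim(m2), c(50L, 8L))
  expect_equal(unclass(m2), unclass(m))
})
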