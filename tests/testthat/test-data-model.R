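test_that("CSV ingestion validates structure and reports dimensions", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(toy_table(), path, row.names = FALSE)
  ds <- read_metabolite_table(path, toy_schema(), quiet = TRUE)
  expect_s3_class(ds, "metabo_dataset")
  expect_equal(c(ds$N, ds$T_max, ds$M, ds$L), c(2L, 4L, 2L, 3L))

  # duplicate (individual, time point)
  bad <- toy_table()
  bad$timepoint[2L] <- 1L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_metabolite_table(path, toy_schema(), quiet = TRUE),
               "duplicate.*A, t=1")

  # incomplete series are legal
  incomplete <- toy_table()[-7L, ] # drop B's timepoint 3
  ds2 <- metabo_dataset(incomplete, toy_schema())
  expect_equal(ds2$N, 2L)
  expect_equal(sum(ds2$data$id == "B"), 3L)

  # non-numeric metabolite cell
  bad <- toy_table()
  bad$met1 <- as.character(bad$met1)
  bad$met1[3L] <- "oops"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_metabolite_table(path, toy_schema(), quiet = TRUE),
               "non-numeric metabolite.*met1")

  # schema referencing an absent column
  sch <- metabo_schema("id", "timepoint", "age", c("met1", "nope"))
  expect_error(metabo_dataset(toy_table(), sch), "absent.*nope")
})

test_that("design matrices: intercept-led X, complete-case filter, total row index", {
  ds <- toy_dataset()
  design <- build_design(ds)
  expect_equal(dim(design$X), c(8L, 4L))
  expect_equal(dim(design$Y), c(8L, 2L))
  expect_true(all(design$X[, 1L] == 1))
  expect_equal(colnames(design$X), c("(Intercept)", "age", "bmi", "sex"))

  # every Y row maps back to its dataset cell exactly
  for (r in seq_len(nrow(design$Y))) {
    ri <- design$row_index[r, ]
    cell <- ds$data[ds$data$id == ri$individual &
                      ds$data$timepoint == ri$timepoint, ]
    expect_identical(unname(design$Y[r, ]), c(cell$met1, cell$met2))
  }

  # a missing metabolite value drops only its own row
  tab <- toy_table()
  tab$met2[2L] <- NA
  dsm <- metabo_dataset(tab, toy_schema())
  dm <- build_design(dsm)
  expect_equal(nrow(dm$Y), 7L)
  expect_equal(sum(dm$row_index$individual == "A"), 3L)
  expect_false(anyNA(dm$Y))
  # surviving rows unchanged
  expect_identical(dm$Y[dm$row_index$individual == "B", ],
                   build_design(ds)$Y[5:8, ])
  # unfiltered matrices still cover all rows
  expect_equal(nrow(dm$X_all), 8L)

  # determinism: same input, bitwise-identical matrices
  expect_identical(build_design(toy_dataset()), build_design(toy_dataset()))

  # all rows missing -> hard error
  tab$met2 <- NA_real_
  expect_error(build_design(metabo_dataset(tab, toy_schema())),
               "complete_case = FALSE|no usable rows")

  # zero-variance covariate warns but is kept
  tab2 <- toy_table()
  tab2$sex <- 1
  expect_warning(d2 <- build_design(metabo_dataset(tab2, toy_schema())),
                 "zero variance")
  expect_equal(ncol(d2$X), 4L)
})

test_that("per-timepoint correlations are Pearson across individuals", {
  set.seed(1)
  N <- 12L
  d <- data.frame(id = sprintf("i%02d", rep(1:N, each = 2L)),
                  timepoint = rep(1:2, N),
                  met1 = rnorm(2L * N), met2 = NA_real_, met3 = rnorm(2L * N))
  d$met2 <- ifelse(d$timepoint == 1L, 2 * d$met1, rnorm(2L * N))
  ds <- metabo_dataset(d, metabo_schema("id", "timepoint", character(),
                                        c("met1", "met2", "met3")))
  cors <- correlation_by_timepoint(ds)
  expect_length(cors, 2L)
  expect_equal(cors[[1L]]["met1", "met2"], 1.0)
  for (C in cors) {
    expect_equal(diag(C), setNames(rep(1, 3L), colnames(C)))
    expect_equal(C, t(C))
    expect_true(all(abs(C) <= 1 + 1e-12, na.rm = TRUE))
  }
  # identical inputs give MAD 0 downstream
  expect_equal(mad_correlation(cors[[1L]], cors[[1L]]), 0)

  # large-sample null: independent metabolites have near-zero correlation
  set.seed(2)
  Nbig <- 10000L
  db <- data.frame(id = sprintf("i%05d", 1:Nbig), timepoint = 1L,
                   met1 = rnorm(Nbig), met2 = rnorm(Nbig),
                   met3 = rnorm(Nbig))
  dsb <- metabo_dataset(db, metabo_schema("id", "timepoint", character(),
                                          c("met1", "met2", "met3")))
  Cb <- correlation_by_timepoint(dsb)[[1L]]
  expect_true(all(abs(Cb[upper.tri(Cb)]) < 0.05))

  # constant metabolite warns and yields NA correlations
  d$met3[d$timepoint == 1L] <- 7
  dsc <- metabo_dataset(d, metabo_schema("id", "timepoint", character(),
                                         c("met1", "met2", "met3")))
  expect_warning(Cc <- correlation_by_timepoint(dsc), "constant at time point 1")
  expect_true(is.na(Cc[[1L]]["met1", "met3"]))
})

test_that("observed sign matrix follows the pooled correlation with +1 ties", {
  # monotone increasing / decreasing relations make the signs unambiguous
  d <- data.frame(id = sprintf("i%d", 1:6), timepoint = 1L,
                  met1 = c(1, 2, 3, 4, 5, 6),
                  met2 = c(6, 5, 4, 3, 2, 1),       # anti-correlated
                  met3 = c(1.1, 2.2, 2.9, 4.2, 4.8, 6.1)) # correlated
  ds <- metabo_dataset(d, metabo_schema("id", "timepoint", character(),
                                        c("met1", "met2", "met3")))
  S <- observed_sign_matrix(ds)
  expect_equal(S["met1", "met2"], -1)
  expect_equal(S["met1", "met3"], 1)
  expect_equal(S["met2", "met3"], -1)
  expect_equal(diag(S), setNames(rep(1, 3L), colnames(S)))

  # exactly-zero correlation maps to +1 (documented convention)
  dz <- data.frame(id = sprintf("i%d", 1:4), timepoint = 1L,
                   met1 = c(-1, 0, 0, 1), met2 = c(0, -1, 1, 0))
  dsz <- metabo_dataset(dz, metabo_schema("id", "timepoint", character(),
                                          c("met1", "met2")))
  expect_equal(observed_sign_matrix(dsz)["met1", "met2"], 1)

  # M = 1 degenerates to [ +1 ]
  ds1 <- metabo_dataset(d[, c("id", "timepoint", "met1")],
                        metabo_schema("id", "timepoint", character(), "met1"))
  expect_equal(unname(observed_sign_matrix(ds1)), matrix(1, 1, 1))
})
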