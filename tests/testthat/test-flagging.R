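test_that("HPD interval is the shortest window with the documented tie rule", {
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  # near-1 level: window spans everything, interval is (min, max)
  expect_equal(hpd_interval(1:100, 0.999), c(lower = 1, upper = 100))
  # skewed sample: HPD hugs the mode, narrower than equal-tail
  set.seed(6)
  x <- rexp(5000L)
  h <- hpd_interval(x, 0.9)
  q <- equal_tail_interval(x, 0.9)
  expect_lt(h[["upper"]] - h[["lower"]], q[["upper"]] - q[["lower"]])
  expect_lt(h[["lower"]], q[["lower"]])
  expect_error(hpd_interval(1:50, 0.95), "at least 100")
})

test_that("predictive draws reduce to fitted means in the zero-noise limit", {
  ds <- toy_dataset()
  design <- build_design(ds)
  beta <- matrix(c(10, 0.01, 0.02, 0.1, 5, 0.005, 0.01, 0.05), 4L, 2L)
  u <- matrix(c(0.5, -0.5, 0.2, -0.2), 2L, 2L)
  fit <- fake_mv_draws(design, beta, u, G = diag(2L),
                       R = diag(1e-18, 2L), S = 120L)
  pred <- predictive_draws(fit, design, seed = 4L)
  mu <- design$X_all %*% beta + u[match(design$row_index_all$individual,
                                        design$individuals), ]
  for (ci in seq_len(nrow(pred$cells)))
    expect_equal(unname(pred$draws[60L, ci, ]), unname(mu[ci, ]),
                 tolerance = 1e-6)

  # beta = 0 with a large random intercept: cells centred at u_i
  fit0 <- fake_mv_draws(design, matrix(0, 4L, 2L),
                        u = matrix(c(50, 0, 50, 0), 2L, 2L),
                        G = diag(2L), R = diag(2L) * 0.01, S = 150L)
  p0 <- predictive_draws(fit0, design, seed = 9L)
  a_cells <- which(p0$cells$individual == "A")
  b_cells <- which(p0$cells$individual == "B")
  expect_equal(mean(p0$draws[, a_cells, 1L]), 50, tolerance = 0.1)
  expect_equal(mean(p0$draws[, b_cells, 1L]), 0, tolerance = 0.1)

  # unknown individuals are refused
  expect_error(predictive_draws(fit, design,
                                targets = data.frame(individual = "Z",
                                                     timepoint = 1L)),
               "unknown individual")
})

test_that("flag decisions bracket the observed value correctly", {
  ds <- toy_dataset()
  design <- build_design(ds)
  set.seed(12)
  beta <- matrix(0, 4L, 2L)
  fit <- fake_mv_draws(design, beta, matrix(0, 2L, 2L), diag(2L), diag(2L),
                       S = 400L)
  # overwrite the point-mass chains with genuine spread so intervals exist
  fit$chains[[1L]]$beta[, 1L, ] <- rnorm(800L, 10, 0.2)
  pred <- predictive_draws(fit, design, seed = 3L)

  ds2 <- ds
  med <- median(pred$draws[, 1L, 1L])
  hi <- max(pred$draws[, 1L, 1L]) + 10
  ds2$data$met1[1L] <- med
  ds2$data$met2[1L] <- hi
  fl <- suppressMessages(flag_individuals(ds2, pred))
  cell1 <- fl[fl$individual == "A" & fl$timepoint == 1L, ]
  expect_false(any(cell1$flagged[cell1$metabolite == "met1"]))
  expect_true(all(cell1$flagged[cell1$metabolite == "met2"]))
  expect_true(all(fl$lower < fl$upper))
  expect_true(all((fl$observed < fl$lower | fl$observed > fl$upper) ==
                    fl$flagged, na.rm = TRUE))

  # a missing observed value keeps its intervals with an absent flag
  ds3 <- ds
  ds3$data$met1[2L] <- NA
  fl3 <- suppressMessages(flag_individuals(ds3, predictive_draws(fit, design,
                                                                 seed = 3L)))
  r <- fl3[fl3$individual == "A" & fl3$timepoint == 2L &
             fl3$metabolite == "met1", ]
  expect_true(all(is.na(r$flagged)))
  expect_true(all(is.finite(r$lower)))
})

test_that("flag summaries implement the single-timepoint threshold rule", {
  inds <- sprintf("i%02d", 1:10)
  mets <- sprintf("m%d", 1:5)
  # 3 individuals with 4 metabolites flagged at one time point
  cells <- expand.grid(individual = inds[1:3], timepoint = 2L,
                       metabolite = mets[1:4], stringsAsFactors = FALSE)
  fl <- fake_flag_table(inds, 1:3, mets, c(0.95, 0.975), cells)
  s <- summarize_flags(fl, min_metabolites = 4L)
  expect_equal(s$summary$proportion, c(0.3, 0.3))
  expect_equal(s$summary$n_flagged, c(3L, 3L))

  # threshold 1 saturates when everyone has a flag
  cells_all <- data.frame(individual = inds, timepoint = 1L,
                          metabolite = mets[1L], stringsAsFactors = FALSE)
  expect_equal(summarize_flags(fake_flag_table(inds, 1:2, mets, 0.95,
                                               cells_all),
                               1L)$summary$proportion, 1)

  # 3 + 1 flags split over two time points never reach a threshold of 4
  cells_split <- rbind(
    expand.grid(individual = inds[1L], timepoint = 1L,
                metabolite = mets[1:3], stringsAsFactors = FALSE),
    data.frame(individual = inds[1L], timepoint = 2L, metabolite = mets[4L]))
  s_split <- summarize_flags(fake_flag_table(inds, 1:3, mets, 0.95,
                                             cells_split), 4L)
  expect_equal(s_split$summary$n_flagged, 0L)

  expect_error(summarize_flags(fl, 6L), "exceeds")
})

test_that("pair counts enumerate same-timepoint co-flags symmetrically", {
  inds <- sprintf("i%02d", 1:6)
  mets <- c("A", "B", "C", "D")
  cells <- data.frame(individual = "i01", timepoint = 2L,
                      metabolite = c("A", "B", "C"), stringsAsFactors = FALSE)
  fl <- fake_flag_table(inds, 1:3, mets, 0.95, cells)
  pc <- pair_flag_counts(fl, min_metabolites = 3L, level = 0.95)
  expect_equal(pc["A", "B"], 1L)
  expect_equal(pc["A", "C"], 1L)
  expect_equal(pc["B", "C"], 1L)
  expect_equal(pc["A", "D"], 0L)
  expect_equal(diag(pc), c(A = 1L, B = 1L, C = 1L, D = 0L))

  # empty restricted set: all-zero matrix
  expect_true(all(pair_flag_counts(fl, 4L, 0.95) == 0L))

  # symmetry on random constructed tables
  set.seed(77)
  for (k in 1:5) {
    rc <- data.frame(individual = sample(inds, 12L, TRUE),
                     timepoint = sample(1:3, 12L, TRUE),
                     metabolite = sample(mets, 12L, TRUE),
                     stringsAsFactors = FALSE)
    rc <- rc[!duplicated(rc), ]
    m <- pair_flag_counts(fake_flag_table(inds, 1:3, mets, 0.95, rc),
                          2L, 0.95)
    expect_identical(m, t(m))
  }
})

test_that("replicate datasets conserve shape and the fitted-mean limit", {
  ds <- toy_dataset()
  design <- build_design(ds)
  beta <- matrix(c(10, 0.01, 0.02, 0.1, 5, 0.005, 0.01, 0.05), 4L, 2L)
  u <- matrix(c(0.5, -0.5, 0.2, -0.2), 2L, 2L)
  fit <- fake_mv_draws(design, beta, u, diag(2L), diag(1e-18, 2L), S = 150L)
  reps <- replicate_datasets(fit, design, n_rep = 3L, seed = 8L)
  expect_length(reps, 3L)
  mu <- design$X %*% beta + u[design$id_index, ]
  for (Yr in reps) {
    expect_equal(dim(Yr), dim(design$Y))
    expect_identical(attr(Yr, "row_index"), design$row_index)
    expect_equal(as.vector(Yr), as.vector(mu), tolerance = 1e-6)
  }
  expect_error(replicate_datasets(fit, design, n_rep = 151L), "exceeds")

  # Monte-Carlo consistency: replicate cell means track the predictive mean
  set.seed(30)
  fit2 <- fake_mv_draws(design, beta, u, diag(2L), diag(0.25, 2L), S = 150L)
  reps2 <- replicate_datasets(fit2, design, n_rep = 100L, seed = 5L)
  cellmeans <- Reduce(`+`, reps2) / length(reps2)
  se <- sqrt(0.25 / length(reps2))
  expect_true(all(abs(cellmeans - mu) < 4 * se))
})
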