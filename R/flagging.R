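#' Individual-level posterior-predictive draws
#'
#' For every retained posterior draw `s` and every requested
#' (individual, time point) cell, computes the predictive mean
#' `beta^(s)' x_it + u_i^(s)` and adds M-variate residual noise
#' `N(0, R^(s))` (for the independent model, independent per-metabolite
#' noise `N(0, sigma2_e^(s))`). Cells are available for every observed
#' (individual, time point) pair, including rows dropped from the
#' likelihood for missing metabolite values, since their covariates are
#' known.
#'
#' @param fit A `posterior_draws` (multivariate) or `independent_fit`.
#' @param design The [build_design()] result the model was fitted to.
#' @param targets Optional data.frame with columns `individual` and
#'   `timepoint`; defaults to every observed (individual, time point) pair.
#' @param seed Seed for the predictive noise.
#' @return A `predictive_samples` object: array `draws`
#'   (S_total × cells × M) plus the cell map.
#' @export
predictive_draws <- function(fit, design, targets = NULL, seed = 1L) {
  UseMethod("predictive_draws")
}

resolve_targets <- function(design, targets) {
  if (is.null(targets))
    targets <- design$row_index_all[, c("individual", "timepoint")]
  stopifnot(is.data.frame(targets),
            all(c("individual", "timepoint") %in% names(targets)))
  targets$individual <- as.character(targets$individual)
  unknown <- setdiff(targets$individual, design$individuals)
  if (length(unknown))
    stop("unknown individual(s): ", paste(head(unknown, 5L), collapse = ", "),
         "; out-of-sample individuals are not supported", call. = FALSE)
  key_all <- paste(design$row_index_all$individual,
                   design$row_index_all$timepoint)
  idx <- match(paste(targets$individual, targets$timepoint), key_all)
  if (anyNA(idx))
    stop("no covariate row available for target(s): ",
         paste(head(paste0(targets$individual[is.na(idx)], ", t=",
                           targets$timepoint[is.na(idx)]), 5L),
               collapse = "; "), call. = FALSE)
  list(targets = targets, X = design$X_all[idx, , drop = FALSE],
       uid = match(targets$individual, design$individuals))
}

#' @rdname predictive_draws
#' @export
predictive_draws.posterior_draws <- function(fit, design, targets = NULL,
                                             seed = 1L) {
  tg <- resolve_targets(design, targets)
  pooled <- pool_draws(fit)
  S <- dim(pooled$beta)[1L]
  n <- nrow(tg$X); M <- length(fit$metabolites)
  pred <- array(NA_real_, c(S, n, M),
                dimnames = list(NULL, NULL, fit$metabolites))
  set.seed(seed)
  for (s in seq_len(S)) {
    mu <- tg$X %*% pooled$beta[s, , ] + pooled$u[s, tg$uid, , drop = FALSE][1, , ]
    if (M == 1L) dim(mu) <- c(n, 1L)
    Rs <- matrix(pooled$R[s, , ], M, M)
    pred[s, , ] <- mu + rmvn0(n, Rs)
  }
  structure(list(draws = pred, cells = tg$targets,
                 metabolites = fit$metabolites),
            class = "predictive_samples")
}

#' @rdname predictive_draws
#' @export
predictive_draws.independent_fit <- function(fit, design, targets = NULL,
                                             seed = 1L) {
  tg <- resolve_targets(design, targets)
  S <- nrow(fit$fits[[1L]]$beta_draws)
  n <- nrow(tg$X); M <- length(fit$metabolites)
  pred <- array(NA_real_, c(S, n, M),
                dimnames = list(NULL, NULL, fit$metabolites))
  set.seed(seed)
  for (m in seq_len(M)) {
    f <- fit$fits[[m]]
    mu <- tg$X %*% t(f$beta_draws) + t(f$u_draws)[tg$uid, , drop = FALSE]
    noise <- matrix(rnorm(n * S, 0, rep(sqrt(f$sigma2_e_draws), each = n)),
                    n, S)
    pred[, , m] <- t(mu + noise)
  }
  structure(list(draws = pred, cells = tg$targets,
                 metabolites = fit$metabolites),
            class = "predictive_samples")
}

#' Highest-posterior-density interval of a sample
#'
#' Shortest-window estimator on the sorted draws: among all windows of
#' `ceiling(level * S)` consecutive order statistics the narrowest is
#' returned, ties broken toward the lower start index.
#'
#' @param samples Numeric vector of at least 100 draws.
#' @param level Coverage level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  stopifnot(is.numeric(samples), level > 0, level < 1)
  samples <- samples[!is.na(samples)]
  S <- length(samples)
  if (S < 100L) stop("need at least 100 draws for an HPD interval",
                     call. = FALSE)
  w <- ceiling(level * S)
  if (w > S) stop("window exceeds the number of draws", call. = FALSE)
  s <- sort(samples)
  widths <- s[w:S] - s[seq_len(S - w + 1L)]
  i <- which.min(widths) # ties resolve to the lowest start index
  c(lower = s[i], upper = s[i + w - 1L])
}

#' Equal-tail interval of a sample (comparison alternative to the HPD)
#'
#' @inheritParams hpd_interval
#' @return Named numeric vector `c(lower, upper)`.
#' @export
equal_tail_interval <- function(samples, level = 0.95) {
  stopifnot(level > 0, level < 1)
  q <- quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, na.rm = TRUE)
  c(lower = q[1L], upper = q[2L])
}

#' Flag observations outside their predictive HPD intervals
#'
#' For every (individual, time point, metabolite) cell and every requested
#' level, computes the HPD prediction interval from the predictive draws
#' and flags the observation when it falls outside. Cells without an
#' observed value keep their intervals with `flagged = NA`. Observed HPD
#' nesting violations across levels (possible with finite samples) are
#' reported via a message, never silently ignored.
#'
#' @param dataset The observed [metabo_dataset()].
#' @param predictive A [predictive_draws()] result covering every observed
#'   (individual, time point).
#' @param levels HPD coverage levels (default 0.95, 0.975, 0.99).
#' @param interval `"hpd"` (default) or `"equal_tail"`.
#' @return A `flag_table` data.frame with columns individual, timepoint,
#'   metabolite, level, lower, upper, observed, flagged.
#' @export
flag_individuals <- function(dataset, predictive,
                             levels = c(0.95, 0.975, 0.99),
                             interval = c("hpd", "equal_tail")) {
  stopifnot(inherits(dataset, "metabo_dataset"),
            inherits(predictive, "predictive_samples"),
            all(levels > 0), all(levels < 1))
  interval <- match.arg(interval)
  ifun <- if (interval == "hpd") hpd_interval else equal_tail_interval
  sc <- dataset$schema
  obs_key <- paste(as.character(dataset$data[[sc$id]]),
                   dataset$data[[sc$time]])
  cell_key <- paste(predictive$cells$individual, predictive$cells$timepoint)
  miss <- setdiff(obs_key, cell_key)
  if (length(miss))
    stop("observed (individual, time point) pair(s) without predictive draws: ",
         paste(head(miss, 5L), collapse = "; "), call. = FALSE)

  levels <- sort(levels)
  M <- length(predictive$metabolites)
  n_cells <- nrow(predictive$cells)
  obs_row <- match(cell_key, obs_key)
  out <- vector("list", n_cells * M)
  nesting_violations <- 0L
  k <- 0L
  for (ci in seq_len(n_cells)) {
    for (m in seq_len(M)) {
      draws_cm <- predictive$draws[, ci, m]
      ints <- vapply(levels, function(l) ifun(draws_cm, l), numeric(2L))
      # wider levels should contain narrower ones; count observed violations
      if (length(levels) > 1L)
        nesting_violations <- nesting_violations +
          sum(diff(ints[1L, ]) > 1e-12 | diff(ints[2L, ]) < -1e-12)
      observed <- if (is.na(obs_row[ci])) NA_real_ else
        dataset$data[[predictive$metabolites[m]]][obs_row[ci]]
      k <- k + 1L
      out[[k]] <- data.frame(
        individual = predictive$cells$individual[ci],
        timepoint = predictive$cells$timepoint[ci],
        metabolite = predictive$metabolites[m],
        level = levels, lower = ints[1L, ], upper = ints[2L, ],
        observed = observed,
        flagged = if (is.na(observed)) NA else
          observed < ints[1L, ] | observed > ints[2L, ],
        stringsAsFactors = FALSE)
    }
  }
  if (nesting_violations > 0L)
    message(sprintf("%d empirical HPD nesting violation(s) across levels",
                    nesting_violations))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("flag_table", "data.frame")
  res
}

#' Summarise flags into per-level individual proportions
#'
#' An individual counts, at a given level, when at least `min_metabolites`
#' of their metabolites are flagged at one single time point (flags spread
#' over several time points do not accumulate).
#'
#' @param flags A [flag_individuals()] result.
#' @param min_metabolites Threshold number of metabolites flagged within a
#'   time point.
#' @return A `flag_summary`: `summary` data.frame (level, n_individuals,
#'   n_flagged, proportion) and `detail` (per individual × level, the
#'   maximum number of metabolites flagged at any single time point).
#' @export
summarize_flags <- function(flags, min_metabolites = 1L) {
  stopifnot(inherits(flags, "flag_table"), nrow(flags) > 0L)
  M <- length(unique(flags$metabolite))
  if (min_metabolites > M)
    stop(sprintf("min_metabolites = %d exceeds the %d metabolites present",
                 min_metabolites, M), call. = FALSE)
  counts <- aggregate(flagged ~ individual + timepoint + level, data = flags,
                      FUN = function(z) sum(z, na.rm = TRUE))
  detail <- aggregate(flagged ~ individual + level, data = counts, FUN = max)
  names(detail)[names(detail) == "flagged"] <- "max_flags_single_timepoint"
  detail$qualifies <- detail$max_flags_single_timepoint >= min_metabolites
  individuals <- unique(flags$individual)
  summ <- do.call(rbind, lapply(sort(unique(flags$level)), function(l) {
    d <- detail[detail$level == l, ]
    data.frame(level = l, min_metabolites = min_metabolites,
               n_individuals = length(individuals),
               n_flagged = sum(d$qualifies),
               proportion = sum(d$qualifies) / length(individuals))
  }))
  structure(list(summary = summ,
                 detail = detail[order(detail$level, detail$individual), ]),
            class = "flag_summary")
}

#' @export
print.flag_summary <- function(x, ...) {
  cat("<flag_summary> proportion of individuals with >=",
      x$summary$min_metabolites[1L], "metabolites flagged in a time point:\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %5.1f%% HPD: %5.1f%% (%d of %d)\n",
                100 * x$summary$level[i], 100 * x$summary$proportion[i],
                x$summary$n_flagged[i], x$summary$n_individuals[i]))
  invisible(x)
}

#' Metabolite-pair co-flagging counts
#'
#' Restricted to individuals reaching `min_metabolites` flags at some time
#' point, entry (m, m') counts the individuals with both metabolites
#' flagged at the same time point; the diagonal counts individuals with
#' metabolite m flagged at all (within the restricted set).
#'
#' @param flags A [flag_individuals()] result.
#' @param min_metabolites Restriction threshold.
#' @param level The HPD level to evaluate (must be present in `flags`).
#' @return A symmetric M×M integer matrix with metabolite dimnames.
#' @export
pair_flag_counts <- function(flags, min_metabolites = 1L, level = 0.975) {
  stopifnot(inherits(flags, "flag_table"))
  if (!any(abs(flags$level - level) < 1e-12))
    stop(sprintf("level %g not present in the flag table", level),
         call. = FALSE)
  metabolites <- unique(flags$metabolite)
  M <- length(metabolites)
  if (min_metabolites > M)
    stop("min_metabolites exceeds the number of metabolites", call. = FALSE)
  fl <- flags[abs(flags$level - level) < 1e-12 & !is.na(flags$flagged) &
                flags$flagged, ]
  counts <- matrix(0L, M, M, dimnames = list(metabolites, metabolites))
  if (!nrow(fl)) return(counts)

  per_it <- split(fl$metabolite, paste(fl$individual, fl$timepoint, sep = "\r"))
  qual_ind <- unique(sub("\r.*", "",
                         names(per_it)[lengths(per_it) >= min_metabolites]))
  if (!length(qual_ind)) return(counts)

  pair_seen <- list(); diag_seen <- list()
  for (key in names(per_it)) {
    ind <- sub("\r.*", "", key)
    if (!ind %in% qual_ind) next
    mets <- unique(per_it[[key]])
    diag_seen[[ind]] <- union(diag_seen[[ind]], mets)
    if (length(mets) >= 2L) {
      prs <- combn(sort(match(mets, metabolites)), 2L)
      pair_seen[[ind]] <- union(pair_seen[[ind]],
                                paste(prs[1L, ], prs[2L, ]))
    }
  }
  for (ind in names(diag_seen)) {
    mi <- match(diag_seen[[ind]], metabolites)
    counts[cbind(mi, mi)] <- counts[cbind(mi, mi)] + 1L
  }
  for (ind in names(pair_seen)) {
    ij <- do.call(rbind, lapply(strsplit(pair_seen[[ind]], " "), as.integer))
    counts[ij] <- counts[ij] + 1L
    counts[ij[, 2:1, drop = FALSE]] <- counts[ij[, 2:1, drop = FALSE]] + 1L
  }
  counts
}

#' Posterior-predictive replicate datasets
#'
#' Draws `n_rep` full synthetic response matrices from the fitted model,
#' each based on one systematically spaced retained draw (not randomly
#' chosen, for reproducibility): replicate rows are
#' `beta' x + u_i + N(0, R)` (independent model: per-metabolite
#' `N(0, sigma2_e)`), in the row order of the fitted design.
#'
#' @param fit A `posterior_draws` or `independent_fit`.
#' @param design The fitted [build_design()] result.
#' @param n_rep Number of replicates (at most the retained draw count).
#' @param seed Seed for the replicate noise.
#' @return A list of `n_rep` matrices with a `row_index` attribute matching
#'   the design.
#' @export
replicate_datasets <- function(fit, design, n_rep = 100L, seed = 1L) {
  UseMethod("replicate_datasets")
}

spaced_indices <- function(S, n_rep) {
  if (n_rep > S)
    stop(sprintf("n_rep = %d exceeds the %d retained draws", n_rep, S),
         call. = FALSE)
  unique(floor(seq(1L, S, length.out = n_rep)))
}

#' @rdname replicate_datasets
#' @export
replicate_datasets.posterior_draws <- function(fit, design, n_rep = 100L,
                                               seed = 1L) {
  pooled <- pool_draws(fit)
  idx <- spaced_indices(dim(pooled$beta)[1L], n_rep)
  n <- nrow(design$X); M <- length(fit$metabolites)
  set.seed(seed)
  lapply(idx, function(s) {
    mu <- design$X %*% pooled$beta[s, , ] +
      pooled$u[s, design$id_index, , drop = FALSE][1, , ]
    if (M == 1L) dim(mu) <- c(n, 1L)
    Yr <- mu + rmvn0(n, matrix(pooled$R[s, , ], M, M))
    colnames(Yr) <- fit$metabolites
    attr(Yr, "row_index") <- design$row_index
    Yr
  })
}

#' @rdname replicate_datasets
#' @export
replicate_datasets.independent_fit <- function(fit, design, n_rep = 100L,
                                               seed = 1L) {
  S <- nrow(fit$fits[[1L]]$beta_draws)
  idx <- spaced_indices(S, n_rep)
  n <- nrow(design$X); M <- length(fit$metabolites)
  set.seed(seed)
  lapply(idx, function(s) {
    Yr <- matrix(NA_real_, n, M, dimnames = list(NULL, fit$metabolites))
    for (m in seq_len(M)) {
      f <- fit$fits[[m]]
      Yr[, m] <- design$X %*% f$beta_draws[s, ] +
        f$u_draws[s, design$id_index] +
        rnorm(n, 0, sqrt(f$sigma2_e_draws[s]))
    }
    attr(Yr, "row_index") <- design$row_index
    Yr
  })
}
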