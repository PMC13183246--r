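#' Declare column roles for a repeated-measures metabolite table
#'
#' A schema maps columns of a CSV file onto the roles the model needs:
#' the individual identifier, the time point, the covariates entering the
#' fixed-effect design, and the metabolite concentrations.
#'
#' @param id Name of the individual-identifier column.
#' @param time Name of the integer time-point column (1-based, consecutive).
#' @param covariates Character vector of covariate column names (may be
#'   empty). Covariates enter the design untransformed; any standardisation
#'   is the caller's responsibility.
#' @param metabolites Character vector of metabolite column names.
#' @return An object of class `metabo_schema`.
#' @seealso [read_metabolite_table()], [read_metabo_schema()]
#' @export
metabo_schema <- function(id, time, covariates = character(), metabolites) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(time), length(time) == 1L,
            is.character(covariates), is.character(metabolites),
            length(metabolites) >= 1L)
  if (anyDuplicated(metabolites))
    stop("metabolite names must be unique", call. = FALSE)
  structure(list(id = id, time = time, covariates = covariates,
                 metabolites = metabolites),
            class = "metabo_schema")
}

#' Read a column-role schema from a YAML file
#'
#' The file must contain scalar fields `id` and `time` and sequences
#' `covariates` and `metabolites`.
#'
#' @param path Path to a YAML schema file.
#' @return A `metabo_schema`.
#' @export
read_metabo_schema <- function(path) {
  s <- yaml::read_yaml(path)
  known <- c("id", "time", "covariates", "metabolites")
  extra <- setdiff(names(s), known)
  if (length(extra))
    stop("unknown schema field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  metabo_schema(id = s$id, time = s$time,
                covariates = as.character(s$covariates %||% character()),
                metabolites = as.character(s$metabolites))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct and validate a repeated-measures metabolite dataset
#'
#' @param data A data.frame with one row per (individual, time point).
#' @param schema A [metabo_schema()] naming the roles of its columns.
#' @return A `metabo_dataset` with dimensions `N` (individuals), `T_max`
#'   (largest observed time point), `M` (metabolites) and `L` (covariates).
#'   Individuals keep their order of first appearance; rows are sorted by
#'   (individual, time point). Missing metabolite values are permitted;
#'   incomplete time series (fewer than `T_max` rows for an individual) are
#'   legal.
#' @export
metabo_dataset <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "metabo_schema"))
  data <- as.data.frame(data)
  needed <- c(schema$id, schema$time, schema$covariates, schema$metabolites)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("schema names column(s) absent from the data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  tp <- data[[schema$time]]
  if (!is.numeric(tp) || any(is.na(tp)) || any(tp != round(tp)) || any(tp < 1))
    stop("time points must be positive integers", call. = FALSE)
  data[[schema$time]] <- as.integer(tp)

  for (mcol in schema$metabolites) {
    v <- data[[mcol]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))
      stop(sprintf("non-numeric metabolite value in column '%s' (row %s)",
                   mcol, paste(head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  for (ccol in schema$covariates) {
    v <- data[[ccol]]
    if (is.logical(v)) data[[ccol]] <- as.numeric(v)
    else if (!is.numeric(v))
      stop(sprintf("covariate column '%s' must be numeric or logical", ccol),
           call. = FALSE)
    if (anyNA(data[[ccol]]))
      stop(sprintf("covariate column '%s' contains missing values", ccol),
           call. = FALSE)
  }

  ids <- as.character(data[[schema$id]])
  key <- paste(ids, data[[schema$time]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (individual, time point) pair(s): ",
         paste(gsub("\r", ", t=", head(dup, 5L)), collapse = "; "),
         call. = FALSE)
  }

  individuals <- unique(ids)
  T_max <- max(data[[schema$time]])
  n_per <- table(ids)
  if (any(n_per > T_max))
    stop("an individual has more rows than observed time points",
         call. = FALSE)

  ord <- order(match(ids, individuals), data[[schema$time]])
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  structure(list(
    data = data, schema = schema, individuals = individuals,
    N = length(individuals), T_max = T_max,
    M = length(schema$metabolites), L = length(schema$covariates)
  ), class = "metabo_dataset")
}

#' @export
print.metabo_dataset <- function(x, ...) {
  Ymat <- as.matrix(x$data[x$schema$metabolites])
  cat(sprintf(paste0("<metabo_dataset> %d individuals, time points 1..%d, ",
                     "%d metabolites, %d covariates, %d rows, ",
                     "%d missing metabolite cells\n"),
              x$N, x$T_max, x$M, x$L, nrow(x$data), sum(is.na(Ymat))))
  invisible(x)
}

#' Read a repeated-measures metabolite table from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [metabo_schema()] or the path to a YAML schema file.
#' @param quiet Suppress the ingestion summary message.
#' @return A validated [metabo_dataset()].
#' @export
read_metabolite_table <- function(path, schema, quiet = FALSE) {
  if (is.character(schema)) schema <- read_metabo_schema(schema)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ds <- metabo_dataset(raw, schema)
  if (!quiet) {
    Ymat <- as.matrix(ds$data[schema$metabolites])
    message(sprintf(
      "read %d rows: %d individuals, time points 1..%d, %d metabolites, %d covariates, %d missing metabolite cells",
      nrow(ds$data), ds$N, ds$T_max, ds$M, ds$L, sum(is.na(Ymat))))
  }
  ds
}

#' Build the model design matrices from a dataset
#'
#' Constructs the response matrix `Y`, the fixed-effect design `X` (leading
#' intercept column, then covariates in schema order) and the per-row
#' individual index standing in for the sparse random-effect indicator
#' matrix. Rows are kept in dataset order (individual, time point).
#'
#' @param dataset A [metabo_dataset()].
#' @param complete_case Drop rows with any missing metabolite value from
#'   the likelihood (default). The full, unfiltered matrices are retained in
#'   `X_all` / `row_index_all` so posterior predictions can cover dropped
#'   rows too.
#' @return A `design_matrices` object with elements `Y` (rows × M), `X`
#'   (rows × (L+1)), `id_index` (1-based individual index per row),
#'   `row_index` (data.frame mapping each Y row to (individual, timepoint)),
#'   plus the unfiltered counterparts.
#' @export
build_design <- function(dataset, complete_case = TRUE) {
  stopifnot(inherits(dataset, "metabo_dataset"))
  sc <- dataset$schema
  d <- dataset$data
  Y <- as.matrix(d[sc$metabolites])
  storage.mode(Y) <- "double"
  X <- cbind("(Intercept)" = 1,
             as.matrix(if (dataset$L) d[sc$covariates] else
               d[, 0, drop = FALSE]))
  storage.mode(X) <- "double"
  id_index <- match(as.character(d[[sc$id]]), dataset$individuals)
  row_index <- data.frame(row = seq_len(nrow(d)),
                          individual = as.character(d[[sc$id]]),
                          timepoint = d[[sc$time]],
                          stringsAsFactors = FALSE)

  for (j in seq_len(ncol(X))[-1])
    if (var(X[, j]) == 0)
      warning(sprintf("covariate '%s' has zero variance (kept)",
                      colnames(X)[j]), call. = FALSE)

  keep <- if (complete_case) !apply(is.na(Y), 1L, any) else rep(TRUE, nrow(Y))
  if (!any(keep)) stop("no usable rows after complete-case filtering",
                       call. = FALSE)
  if (anyNA(Y[keep, , drop = FALSE]))
    stop("missing metabolite values present with complete_case = FALSE; the sampler requires complete rows",
         call. = FALSE)

  ri <- row_index[keep, , drop = FALSE]
  ri$row <- seq_len(nrow(ri))
  structure(list(
    Y = Y[keep, , drop = FALSE], X = X[keep, , drop = FALSE],
    id_index = id_index[keep], row_index = ri,
    Y_all = Y, X_all = X, id_index_all = id_index,
    row_index_all = row_index,
    individuals = dataset$individuals, metabolites = sc$metabolites,
    covariates = sc$covariates, N = dataset$N, T_max = dataset$T_max,
    M = dataset$M, L = dataset$L
  ), class = "design_matrices")
}

#' Per-timepoint Pearson correlation matrices
#'
#' Computes, at each time point, the M×M Pearson correlation of metabolite
#' levels across individuals (pairwise-complete over missing cells). A
#' metabolite constant at a time point yields `NA` correlations (with a
#' warning); downstream mean-absolute-difference comparisons exclude `NA`
#' entries pairwise.
#'
#' @param dataset A [metabo_dataset()].
#' @return A list of `T_max` symmetric M×M matrices with unit diagonal.
#' @export
correlation_by_timepoint <- function(dataset) {
  stopifnot(inherits(dataset, "metabo_dataset"))
  sc <- dataset$schema
  lapply(seq_len(dataset$T_max), function(t) {
    sub <- dataset$data[dataset$data[[sc$time]] == t, sc$metabolites,
                        drop = FALSE]
    if (nrow(sub) < 3L)
      stop(sprintf("fewer than 3 individuals observed at time point %d", t),
           call. = FALSE)
    sds <- vapply(sub, function(v) sd(v, na.rm = TRUE), 0)
    if (any(!is.na(sds) & sds == 0))
      warning(sprintf(
        "metabolite(s) %s constant at time point %d; correlations undefined",
        paste(sc$metabolites[!is.na(sds) & sds == 0], collapse = ", "), t),
        call. = FALSE)
    C <- suppressWarnings(cor(as.matrix(sub), use = "pairwise.complete.obs"))
    diag(C) <- 1
    C
  })
}

#' Sign matrix of the pooled observed correlation
#'
#' Signs of the Pearson correlation matrix of the observed response pooled
#' over all rows; used to orient the off-diagonal entries of the
#' inverse-Wishart scale matrices. By convention the diagonal is +1 and an
#' exactly zero correlation maps to +1.
#'
#' @param dataset A [metabo_dataset()].
#' @return An M×M matrix with entries in `{-1, +1}`.
#' @export
observed_sign_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "metabo_dataset"))
  sc <- dataset$schema
  Ymat <- as.matrix(dataset$data[sc$metabolites])
  if (dataset$M == 1L)
    return(matrix(1, 1, 1, dimnames = list(sc$metabolites, sc$metabolites)))
  C <- suppressWarnings(cor(Ymat, use = "pairwise.complete.obs"))
  if (anyNA(C)) {
    warning("undefined pooled correlations (constant metabolite?); their signs default to +1",
            call. = FALSE)
    C[is.na(C)] <- 0
  }
  S <- sign(C)
  S[S == 0] <- 1
  diag(S) <- 1
  dimnames(S) <- list(sc$metabolites, sc$metabolites)
  S
}
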