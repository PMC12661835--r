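#' @keywords internal
"_PACKAGE"

MISSING_LEVEL <- "(missing)"

#' Declare a variable of a mixed-type tabular schema
#'
#' A schema variable is either numeric or categorical. Categorical variables
#' carry their full set of admissible levels so that data files can be
#' validated at load time and generative models know the level universe.
#'
#' @param name Variable name (must match the CSV header).
#' @param kind `"numeric"` or `"categorical"`.
#' @param levels Character vector of admissible levels (categorical only,
#'   at least two).
#' @param role `"predictor"` or `"outcome"`. The outcome must be categorical
#'   with exactly two levels; the second level is treated as the positive
#'   class.
#' @return An object of class `tabaug_variable`.
#' @export
var_spec <- function(name, kind = c("numeric", "categorical"),
                     levels = character(), role = c("predictor", "outcome")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    levels <- as.character(levels)
    if (length(unique(levels)) < 2L)
      stop("categorical variable '", name, "' needs >= 2 distinct levels")
    if (anyDuplicated(levels))
      stop("duplicate levels in variable '", name, "'")
  } else if (length(levels) > 0L) {
    stop("numeric variable '", name, "' must not declare levels")
  }
  structure(list(name = name, kind = kind, levels = levels, role = role),
            class = "tabaug_variable")
}

#' Assemble a schema from variable declarations
#'
#' @param ... `tabaug_variable` objects (or a single list of them).
#' @return An object of class `tabaug_schema`.
#' @export
schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1L]]) &&
      !inherits(vars[[1L]], "tabaug_variable"))
    vars <- vars[[1L]]
  if (!all(vapply(vars, inherits, logical(1L), "tabaug_variable")))
    stop("all arguments must be created by var_spec()")
  nms <- vapply(vars, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("variable names must be unique")
  roles <- vapply(vars, `[[`, character(1L), "role")
  if (sum(roles == "outcome") != 1L)
    stop("schema must declare exactly one outcome variable")
  out <- vars[[which(roles == "outcome")]]
  if (out$kind != "categorical" || length(out$levels) != 2L)
    stop("outcome must be categorical with exactly 2 levels")
  names(vars) <- nms
  structure(list(variables = vars), class = "tabaug_schema")
}

#' @export
print.tabaug_schema <- function(x, ...) {
  cat("<tabaug_schema> with", length(x$variables), "variables\n")
  for (v in x$variables) {
    lv <- if (v$kind == "categorical")
      paste0(" {", paste(utils::head(v$levels, 6L), collapse = ","),
             if (length(v$levels) > 6L) ",..." else "", "}") else ""
    cat(sprintf("  %-20s %-11s %s%s\n", v$name, v$kind, v$role, lv))
  }
  invisible(x)
}

schema_names <- function(schema) names(schema$variables)

#' @rdname schema
#' @param x A schema.
#' @export
outcome_name <- function(x) {
  roles <- vapply(x$variables, `[[`, character(1L), "role")
  names(x$variables)[roles == "outcome"]
}

#' @rdname schema
#' @export
predictor_names <- function(x) {
  roles <- vapply(x$variables, `[[`, character(1L), "role")
  names(x$variables)[roles == "predictor"]
}

var_kind <- function(schema, name) schema$variables[[name]]$kind
var_levels <- function(schema, name) schema$variables[[name]]$levels

#' Construct a schema-typed dataset
#'
#' Wraps a data frame together with its schema. Categorical cells are stored
#' as factors over the declared levels (plus an explicit `"(missing)"` level
#' when missing predictor cells are present); numeric cells are doubles.
#' Rows with a missing outcome are dropped.
#'
#' @param data A data frame whose columns match the schema variables.
#' @param schema A `tabaug_schema`.
#' @param id Dataset label used in result tables.
#' @return An object of class `tabaug_dataset`.
#' @export
dataset <- function(data, schema, id = "dataset") {
  stopifnot(inherits(schema, "tabaug_schema"), is.data.frame(data))
  need <- schema_names(schema)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing schema columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[need]
  out_nm <- outcome_name(schema)
  drop <- is.na(data[[out_nm]]) |
    (is.character(data[[out_nm]]) & data[[out_nm]] == "")
  if (any(drop)) data <- data[!drop, , drop = FALSE]
  for (nm in need) {
    v <- schema$variables[[nm]]
    col <- data[[nm]]
    if (v$kind == "numeric") {
      if (is.factor(col)) col <- as.character(col)
      if (is.character(col)) {
        col[col == ""] <- NA_character_
        num <- suppressWarnings(as.numeric(col))
        if (any(is.na(num) & !is.na(col)))
          stop("unparseable numeric cell in column '", nm, "'")
        col <- num
      }
      data[[nm]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      col[is.na(col) | col == ""] <- if (nm == out_nm) NA_character_ else MISSING_LEVEL
      levs <- v$levels
      bad <- setdiff(unique(col[!is.na(col)]), c(levs, MISSING_LEVEL))
      if (length(bad))
        stop("unknown level(s) in column '", nm, "': ",
             paste(utils::head(bad, 5L), collapse = ", "))
      if (MISSING_LEVEL %in% col) levs <- c(levs, MISSING_LEVEL)
      data[[nm]] <- factor(col, levels = levs)
    }
  }
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, id = id),
            class = "tabaug_dataset")
}

#' @export
print.tabaug_dataset <- function(x, ...) {
  cat(sprintf("<tabaug_dataset> '%s': %d rows, %d predictors, outcome '%s'\n",
              x$id, nrow(x$data), length(predictor_names(x$schema)),
              outcome_name(x$schema)))
  invisible(x)
}

#' @export
dim.tabaug_dataset <- function(x) dim(x$data)

#' @export
as.data.frame.tabaug_dataset <- function(x, ...) x$data

n_rows <- function(ds) nrow(ds$data)

#' Outcome as a 0/1 vector
#'
#' The second declared outcome level is the positive class.
#'
#' @param ds A `tabaug_dataset`.
#' @return Integer vector of 0/1.
#' @export
outcome01 <- function(ds) {
  nm <- outcome_name(ds$schema)
  pos <- var_levels(ds$schema, nm)[2L]
  as.integer(as.character(ds$data[[nm]]) == pos)
}

subset_rows <- function(ds, idx, id = ds$id) {
  structure(list(data = ds$data[idx, , drop = FALSE], schema = ds$schema,
                 id = id), class = "tabaug_dataset")
}

bind_datasets <- function(a, b, id = a$id) {
  stopifnot(identical(schema_names(a$schema), schema_names(b$schema)))
  d <- rbind(a$data, b$data)
  rownames(d) <- NULL
  structure(list(data = d, schema = a$schema, id = id),
            class = "tabaug_dataset")
}

# ---- schema sidecar (YAML) --------------------------------------------------

#' Read / write a schema sidecar
#'
#' The sidecar is a YAML list with one entry per variable giving `name`,
#' `kind`, `role` and (for categoricals) `levels`.
#'
#' @param path File path.
#' @return `read_schema` returns a `tabaug_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$variables)) raw <- raw$variables
  vars <- lapply(raw, function(v)
    var_spec(v$name, v$kind, levels = as.character(v$levels %||% character()),
             role = v$role %||% "predictor"))
  schema(vars)
}

#' @rdname read_schema
#' @param schema A `tabaug_schema`.
#' @export
write_schema <- function(schema, path) {
  vars <- lapply(schema$variables, function(v) {
    out <- list(name = v$name, kind = v$kind, role = v$role)
    if (v$kind == "categorical") out$levels <- as.list(v$levels)
    out
  })
  yaml::write_yaml(list(variables = unname(vars)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- dataset I/O ------------------------------------------------------------

#' Read a dataset from CSV plus schema sidecar
#'
#' @param path CSV path (comma-separated, UTF-8, header required).
#' @param schema_path YAML sidecar path, or a `tabaug_schema` object.
#' @param id Dataset label; defaults to the file stem.
#' @return A `tabaug_dataset`.
#' @export
read_dataset <- function(path, schema_path,
                         id = tools::file_path_sans_ext(basename(path))) {
  sch <- if (inherits(schema_path, "tabaug_schema")) schema_path
         else read_schema(schema_path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(schema_names(sch), names(df))
  if (outcome_name(sch) %in% miss)
    stop("missing outcome column '", outcome_name(sch), "'")
  if (length(miss))
    stop("CSV is missing columns: ", paste(miss, collapse = ", "))
  dataset(df, sch, id = id)
}

#' Write a dataset to CSV (optionally with its schema sidecar)
#'
#' Numerics are written with 15 significant digits so that a read/write
#' round-trip preserves values to at least 12 significant digits.
#'
#' @param ds A `tabaug_dataset`.
#' @param path Output CSV path.
#' @param schema_path Optional YAML sidecar path.
#' @export
write_dataset <- function(ds, path, schema_path = NULL) {
  df <- ds$data
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "",
                         formatC(df[[nm]], digits = 15, format = "g"))
    } else {
      x <- as.character(df[[nm]])
      x[is.na(x)] <- ""
      df[[nm]] <- x
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  if (!is.null(schema_path)) write_schema(ds$schema, schema_path)
  invisible(path)
}

# ---- stratified splitting ---------------------------------------------------

#' Outcome-stratified train/test split
#'
#' Splits a population into disjoint train and test partitions, stratified by
#' the binary outcome so that both partitions preserve prevalence.
#'
#' @param pop A `tabaug_dataset`.
#' @param train_fraction Fraction of rows assigned to the training partition.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `train` and `test` (both `tabaug_dataset`).
#' @export
split_population <- function(pop, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- outcome01(pop)
  if (min(table(y)) < 2L)
    stop("each outcome class needs >= 2 rows to split")
  rng <- local_rng(seed)
  idx_train <- integer(0)
  for (cl in c(0L, 1L)) {
    rows <- which(y == cl)
    k <- round(train_fraction * length(rows))
    k <- max(1L, min(length(rows) - 1L, k))
    idx_train <- c(idx_train, sample(rows, k))
  }
  idx_train <- sort(idx_train)
  list(train = subset_rows(pop, idx_train, id = paste0(pop$id, "_train")),
       test = subset_rows(pop, setdiff(seq_len(nrow(pop$data)), idx_train),
                          id = paste0(pop$id, "_test")))
}

# Run `expr`-style RNG work under a private, restorable stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(old)
}

# ---- target encoding --------------------------------------------------------

#' Fit an outcome-mean (target) encoder on training data
#'
#' Each categorical level is mapped to a smoothed positive-outcome rate,
#' `(n_level * mean_level + smoothing * global_mean) / (n_level + smoothing)`.
#' Numerics pass through unchanged; unseen levels at apply time map to the
#' global mean. The encoder only ever sees the training outcome, so applying
#' it to held-out data cannot leak held-out labels.
#'
#' @param train A `tabaug_dataset` used to fit the encoder.
#' @param smoothing Non-negative shrinkage weight (default 10).
#' @return An object of class `tabaug_encoder` with a `predict` method that
#'   returns a numeric matrix over the predictors.
#' @export
target_encoder <- function(train, smoothing = 10) {
  stopifnot(smoothing >= 0)
  y <- outcome01(train)
  gm <- mean(y)
  maps <- list()
  for (nm in predictor_names(train$schema)) {
    if (var_kind(train$schema, nm) != "categorical") next
    col <- as.character(train$data[[nm]])
    lev_mean <- tapply(y, col, mean)
    lev_n <- tapply(rep(1L, length(col)), col, sum)
    enc <- (lev_n * lev_mean + smoothing * gm) / (lev_n + smoothing)
    maps[[nm]] <- enc
  }
  structure(list(maps = maps, global_mean = gm, smoothing = smoothing,
                 schema = train$schema),
            class = "tabaug_encoder")
}

#' @export
predict.tabaug_encoder <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "tabaug_dataset"))
  preds <- predictor_names(object$schema)
  out <- matrix(NA_real_, nrow(newdata$data), length(preds),
                dimnames = list(NULL, preds))
  for (nm in preds) {
    if (var_kind(object$schema, nm) == "numeric") {
      out[, nm] <- as.numeric(newdata$data[[nm]])
    } else {
      col <- as.character(newdata$data[[nm]])
      enc <- object$maps[[nm]]
      vals <- unname(enc[col])
      vals[is.na(vals)] <- object$global_mean
      out[, nm] <- vals
    }
  }
  out
}

#' One-shot target encoding of an apply set using training statistics
#'
#' @param train Training `tabaug_dataset` (fits the encoder).
#' @param apply_to Dataset to encode (defaults to `train`).
#' @param smoothing Shrinkage weight, see [target_encoder()].
#' @return Numeric matrix with the fitted encoder attached as attribute
#'   `"encoder"`.
#' @export
target_encode <- function(train, apply_to = train, smoothing = 10) {
  enc <- target_encoder(train, smoothing = smoothing)
  m <- predict(enc, apply_to)
  attr(m, "encoder") <- enc
  m
}
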