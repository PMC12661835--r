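# Generative models for tabular synthesis. Each fit_* function returns a
# classed generator sharing the sample_synth()/augment() contract; sampled
# categoricals only ever emit levels observed in the training data.

#' Sample synthetic records from a fitted generator
#'
#' @param model A fitted generator (`fit_bootstrap()`, `fit_seq_trees()`,
#'   `fit_bayes_net()`, `fit_adapter()`).
#' @param m Number of records to draw (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `tabaug_dataset` with exactly `m` rows conforming to the
#'   training schema.
#' @export
sample_synth <- function(model, m, seed = 1L) {
  if (!inherits(model, "tabaug_generator")) stop("not a fitted generator")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  UseMethod("sample_synth")
}

#' @export
print.tabaug_generator <- function(x, ...) {
  cat(sprintf("<tabaug_generator> method '%s' fitted on %d rows\n",
              x$method, x$n_train))
  invisible(x)
}

#' Augment a base dataset with synthetic records
#'
#' Concatenates the base rows (verbatim, in order) with `n_prime` records
#' sampled from the generator, so the augmented dataset has
#' `nrow(base) + n_prime` rows.
#'
#' @param base The base `tabaug_dataset`.
#' @param model A generator fitted on `base` (or on a superset fold).
#' @param n_prime Number of synthetic records (>= 1; use the base directly
#'   for n_prime = 0).
#' @param seed Integer seed for sampling.
#' @return A `tabaug_dataset`.
#' @export
augment <- function(base, model, n_prime, seed = 1L) {
  stopifnot(inherits(base, "tabaug_dataset"))
  if (n_prime < 1L) stop("n_prime must be >= 1; use the base dataset directly")
  if (!identical(schema_names(base$schema), schema_names(model$schema)))
    stop("generator schema does not match base dataset")
  syn <- sample_synth(model, n_prime, seed = seed)
  bind_datasets(base, syn, id = paste0(base$id, "_aug"))
}

# ---- bootstrap --------------------------------------------------------------

#' Fit the bootstrap (resampling) generator
#'
#' Sampling draws whole rows uniformly with replacement from the base data.
#' This is the null augmentation method: it increases sample size without
#' adding new records, so its diversity is expected to be minimal.
#'
#' @param base A non-empty `tabaug_dataset`.
#' @return A `tabaug_generator` of method `"bootstrap"`.
#' @export
fit_bootstrap <- function(base) {
  stopifnot(inherits(base, "tabaug_dataset"))
  if (nrow(base$data) < 1L) stop("base dataset is empty")
  structure(list(method = "bootstrap", schema = base$schema,
                 rows = base$data, n_train = nrow(base$data)),
            class = c("tabaug_bootstrap", "tabaug_generator"))
}

#' @export
sample_synth.tabaug_bootstrap <- function(model, m, seed = 1L) {
  local_rng(seed)
  idx <- sample.int(nrow(model$rows), m, replace = TRUE)
  d <- model$rows[idx, , drop = FALSE]
  rownames(d) <- NULL
  structure(list(data = d, schema = model$schema, id = "bootstrap_sample"),
            class = "tabaug_dataset")
}

# ---- sequential decision trees ---------------------------------------------

# Leaf node ids for new data from a fitted rpart tree (row numbers of
# fit$frame, as fit$where uses). rpart has no exported leaf-membership
# predictor; pred.rpart is the routine predict.rpart itself routes through.
rpart_leaf <- function(fit, newdata) {
  if (nrow(fit$frame) == 1L) return(rep(1L, nrow(newdata)))
  Terms <- stats::delete.response(fit$terms)
  nd <- stats::model.frame(Terms, newdata, na.action = stats::na.pass,
                           xlev = attr(fit, "xlevels"))
  rpart:::pred.rpart(fit, rpart:::rpart.matrix(nd))
}

#' Fit the sequential decision-tree generator
#'
#' Variables are synthesized one at a time in a fixed order: the first from
#' its empirical marginal, each later variable from a CART tree
#' (classification for categoricals, regression for numerics) fitted on the
#' variables earlier in the order. Sampling walks each synthetic row's
#' prefix down variable j's tree and draws from the reached leaf —
#' class frequencies for categoricals, the leaf's pool of observed values
#' for numerics — so synthetic cells never leave the observed support.
#'
#' @param base A `tabaug_dataset` with at least `2 * min_leaf` rows.
#' @param min_leaf Minimum records per tree leaf (default 5).
#' @param max_depth Maximum tree depth (default 12).
#' @param order Optional character vector permuting the schema variables;
#'   default is schema order.
#' @return A `tabaug_generator` of method `"seq_trees"`.
#' @export
fit_seq_trees <- function(base, min_leaf = 5L, max_depth = 12L, order = NULL,
                          max_split_levels = 10L) {
  stopifnot(inherits(base, "tabaug_dataset"))
  nms <- schema_names(base$schema)
  if (nrow(base$data) < 2L * min_leaf)
    stop("base dataset smaller than 2 * min_leaf")
  if (is.null(order)) order <- nms
  stopifnot(setequal(order, nms))
  dat <- base$data
  # High-cardinality factor predictors are frequency-rank encoded for split
  # search (an exhaustive level-subset search would be exponential for
  # multi-level responses); responses and leaf pools stay on raw values.
  enc_maps <- list()
  for (nm in nms) {
    col <- dat[[nm]]
    if (is.factor(col) && nlevels(droplevels(col)) > max_split_levels) {
      f <- table(as.character(col))
      codes <- rank(-as.numeric(f), ties.method = "first")
      enc_maps[[nm]] <- stats::setNames(as.numeric(codes), names(f))
    }
  }
  encode_pred <- function(df) {
    for (nm in intersect(names(enc_maps), names(df))) {
      v <- unname(enc_maps[[nm]][as.character(df[[nm]])])
      v[is.na(v)] <- max(enc_maps[[nm]]) + 1
      df[[nm]] <- v
    }
    df
  }
  dat_enc <- encode_pred(dat)
  models <- vector("list", length(order))
  names(models) <- order
  ctrl <- rpart::rpart.control(minsplit = max(2L, 2L * min_leaf),
                               minbucket = min_leaf, cp = 0, xval = 0,
                               maxdepth = min(30L, max_depth),
                               maxcompete = 0, maxsurrogate = 0)
  for (j in seq_along(order)) {
    nm <- order[j]
    y <- dat[[nm]]
    if (is.factor(y)) y <- droplevels(y)
    if (j == 1L || is_constant(y)) {
      models[[nm]] <- list(type = "marginal", pool = y)
      next
    }
    preds <- order[seq_len(j - 1L)]
    fml <- stats::as.formula(paste0("`", nm, "` ~ ",
                                    paste0("`", preds, "`", collapse = " + ")))
    fitdat <- dat_enc[c(nm, preds)]
    fitdat[[nm]] <- y
    method <- if (is.factor(y)) "class" else "anova"
    fit <- rpart::rpart(fml, data = fitdat, method = method, control = ctrl)
    models[[nm]] <- list(type = "tree", fit = fit, preds = preds,
                         pools = split(y, fit$where),  # keyed by frame row
                         is_factor = is.factor(y),
                         levels = if (is.factor(y)) levels(y) else NULL)
  }
  structure(list(method = "seq_trees", schema = base$schema, order = order,
                 models = models, enc_maps = enc_maps,
                 n_train = nrow(base$data)),
            class = c("tabaug_seq_trees", "tabaug_generator"))
}

is_constant <- function(x) length(unique(x[!is.na(x)])) <= 1L && !anyNA(x) ||
  length(unique(x)) <= 1L

#' @export
sample_synth.tabaug_seq_trees <- function(model, m, seed = 1L) {
  local_rng(seed)
  cols <- stats::setNames(vector("list", length(model$order)), model$order)
  df <- NULL
  for (nm in model$order) {
    mod <- model$models[[nm]]
    if (mod$type == "marginal") {
      col <- mod$pool[sample.int(length(mod$pool), m, replace = TRUE)]
    } else {
      df_enc <- df
      for (pn in intersect(names(model$enc_maps), names(df_enc))) {
        v <- unname(model$enc_maps[[pn]][as.character(df_enc[[pn]])])
        v[is.na(v)] <- max(model$enc_maps[[pn]]) + 1
        df_enc[[pn]] <- v
      }
      leaf <- rpart_leaf(mod$fit, df_enc)  # frame row index per synthetic row
      col <- if (mod$is_factor) factor(rep(NA_character_, m), levels = mod$levels)
             else numeric(m)
      for (lf in unique(leaf)) {
        rows <- which(leaf == lf)
        pool <- mod$pools[[as.character(lf)]]
        if (is.null(pool) || length(pool) == 0L)
          pool <- unlist(mod$pools, use.names = FALSE)
        col[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
      }
    }
    cols[[nm]] <- col
    filled <- !vapply(cols, is.null, logical(1L))
    df <- as.data.frame(cols[filled], stringsAsFactors = FALSE, optional = TRUE)
    names(df) <- names(cols)[filled]
  }
  d <- df[schema_names(model$schema)]
  for (nm in names(d)) if (is.factor(d[[nm]])) d[[nm]] <- as.character(d[[nm]])
  dataset(d, model$schema, id = "seq_trees_sample")
}

# ---- Bayesian network -------------------------------------------------------

#' Fit the Bayesian-network generator
#'
#' Numerics are discretized into equal-frequency bins; a network structure
#' over the discretized variables is learned by greedy hill climbing
#' (add/remove/reverse arc moves) maximizing the decomposable BIC score from
#' an empty graph, subject to acyclicity and a parent limit. Conditional
#' probability tables use Dirichlet additive smoothing over the observed
#' level universe. Sampling is ancestral in topological order; numeric cells
#' are back-transformed by a uniform draw within the sampled bin.
#'
#' @param base A `tabaug_dataset` with >= 10 rows and >= 2 variables.
#' @param max_parents Maximum parents per node (default 3).
#' @param prior_strength Symmetric Dirichlet pseudo-count per cell
#'   (default 1).
#' @param n_bins Equal-frequency bins per numeric variable (default 5).
#' @return A `tabaug_generator` of method `"bayes_net"` whose `state` holds
#'   the DAG, CPTs and discretization edges.
#' @export
fit_bayes_net <- function(base, max_parents = 3L, prior_strength = 1,
                          n_bins = 5L) {
  stopifnot(inherits(base, "tabaug_dataset"), prior_strength > 0)
  nms <- schema_names(base$schema)
  if (length(nms) < 2L) stop("Bayesian network needs >= 2 variables")
  n <- nrow(base$data)
  if (n < 10L) stop("base dataset needs >= 10 rows")

  disc <- list()
  D <- list()
  for (nm in nms) {
    col <- base$data[[nm]]
    if (is.numeric(col)) {
      edges <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1L),
                                      na.rm = TRUE, names = FALSE, type = 7))
      if (length(edges) < 2L) edges <- c(edges, edges + 1e-9)
      binned <- cut(col, breaks = edges, include.lowest = TRUE, labels = FALSE)
      binned[is.na(binned)] <- 1L  # missing numerics fall in the first bin
      disc[[nm]] <- edges
      D[[nm]] <- factor(binned, levels = seq_len(length(edges) - 1L))
    } else {
      D[[nm]] <- droplevels(col)
    }
  }
  D <- as.data.frame(D, optional = TRUE)
  names(D) <- nms

  dag <- hill_climb_bic(D, max_parents = max_parents)
  cpts <- lapply(nms, function(nm)
    fit_cpt(D, nm, dag$parents[[nm]], prior_strength))
  names(cpts) <- nms

  structure(list(method = "bayes_net", schema = base$schema,
                 state = list(dag = dag, cpts = cpts, discretization = disc,
                              var_names = nms,
                              levels = lapply(D, levels)),
                 n_train = n),
            class = c("tabaug_bayes_net", "tabaug_generator"))
}

# Family log-likelihood and BIC penalty for one node given parents.
node_bic <- function(D, node, parents) {
  n <- nrow(D)
  y <- D[[node]]
  r <- nlevels(y)
  if (length(parents) == 0L) {
    cnt <- table(y)
    ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
    q <- 1L
  } else {
    pa <- interaction(D[parents], drop = TRUE, lex.order = TRUE)
    tab <- table(pa, y)
    rs <- rowSums(tab)
    nz <- tab > 0
    ll <- sum(tab[nz] * log(tab[nz] / rs[row(tab)[nz]]))
    q <- prod(vapply(D[parents], nlevels, integer(1L)))
  }
  ll - 0.5 * log(n) * q * (r - 1L)
}

# Greedy hill climb over add/remove/reverse arc moves maximizing total BIC.
hill_climb_bic <- function(D, max_parents = 3L) {
  nms <- names(D)
  p <- length(nms)
  parents <- stats::setNames(rep(list(character()), p), nms)
  score <- vapply(nms, function(nm) node_bic(D, nm, character()), numeric(1L))
  names(score) <- nms

  creates_cycle <- function(parents, from, to) {
    # does adding from -> to create a cycle? (is `to` an ancestor of `from`?)
    stack <- from
    seen <- character()
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, parents[[v]])
    }
    FALSE
  }

  repeat {
    best <- list(delta = 1e-9, action = NULL)
    for (to in nms) for (from in nms) {
      if (from == to) next
      has_arc <- from %in% parents[[to]]
      if (!has_arc) {
        if (length(parents[[to]]) >= max_parents) next
        if (creates_cycle(parents, from, to)) next
        new_s <- node_bic(D, to, c(parents[[to]], from))
        delta <- new_s - score[[to]]
        if (delta > best$delta)
          best <- list(delta = delta, action = "add", from = from, to = to,
                       new_to = new_s)
      } else {
        # remove
        new_s <- node_bic(D, to, setdiff(parents[[to]], from))
        delta <- new_s - score[[to]]
        if (delta > best$delta)
          best <- list(delta = delta, action = "remove", from = from, to = to,
                       new_to = new_s)
        # reverse (remove from->to, add to->from)
        if (length(parents[[from]]) < max_parents) {
          p2 <- parents
          p2[[to]] <- setdiff(p2[[to]], from)
          if (!creates_cycle(p2, to, from)) {
            s_to <- node_bic(D, to, setdiff(parents[[to]], from))
            s_from <- node_bic(D, from, c(parents[[from]], to))
            delta <- (s_to - score[[to]]) + (s_from - score[[from]])
            if (delta > best$delta)
              best <- list(delta = delta, action = "reverse", from = from,
                           to = to, new_to = s_to, new_from = s_from)
          }
        }
      }
    }
    if (is.null(best$action)) break
    if (best$action == "add") {
      parents[[best$to]] <- c(parents[[best$to]], best$from)
      score[[best$to]] <- best$new_to
    } else if (best$action == "remove") {
      parents[[best$to]] <- setdiff(parents[[best$to]], best$from)
      score[[best$to]] <- best$new_to
    } else {
      parents[[best$to]] <- setdiff(parents[[best$to]], best$from)
      parents[[best$from]] <- c(parents[[best$from]], best$to)
      score[[best$to]] <- best$new_to
      score[[best$from]] <- best$new_from
    }
  }
  list(parents = parents, score = sum(score))
}

# CPT with additive Dirichlet smoothing; rows indexed by parent config.
fit_cpt <- function(D, node, parents, a) {
  y <- D[[node]]
  k <- nlevels(y)
  if (length(parents) == 0L) {
    cnt <- as.numeric(table(y))
    probs <- matrix((cnt + a) / (sum(cnt) + k * a), nrow = 1L)
    colnames(probs) <- levels(y)
    return(list(parents = character(), probs = probs, config = NULL))
  }
  pa_levels <- lapply(D[parents], levels)
  config <- expand.grid(pa_levels, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  names(config) <- parents
  key <- do.call(paste, c(lapply(parents, function(p) as.character(D[[p]])),
                          sep = "\r"))
  cfg_key <- do.call(paste, c(lapply(config, as.character), sep = "\r"))
  tab <- table(factor(key, levels = cfg_key), y)
  probs <- (unclass(tab) + a) / (rowSums(tab) + k * a)
  colnames(probs) <- levels(y)
  list(parents = parents, probs = probs, config_key = cfg_key)
}

topological_order <- function(parents) {
  nms <- names(parents)
  order <- character()
  remaining <- nms
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      all(parents[[v]] %in% order), logical(1L))]
    if (!length(ready)) stop("graph has a cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' @export
sample_synth.tabaug_bayes_net <- function(model, m, seed = 1L) {
  local_rng(seed)
  st <- model$state
  ord <- topological_order(st$dag$parents)
  cells <- stats::setNames(vector("list", length(ord)), ord)
  for (nm in ord) {
    cpt <- st$cpts[[nm]]
    levs <- st$levels[[nm]]
    k <- length(levs)
    if (length(cpt$parents) == 0L) {
      draw <- sample.int(k, m, replace = TRUE, prob = cpt$probs[1L, ])
    } else {
      key <- do.call(paste, c(lapply(cpt$parents, function(p)
        as.character(cells[[p]])), sep = "\r"))
      row_idx <- match(key, cpt$config_key)
      draw <- integer(m)
      for (r in unique(row_idx)) {
        rows <- which(row_idx == r)
        draw[rows] <- sample.int(k, length(rows), replace = TRUE,
                                 prob = cpt$probs[r, ])
      }
    }
    cells[[nm]] <- factor(levs[draw], levels = levs)
  }
  # back-transform discretized numerics
  out <- list()
  for (nm in st$var_names) {
    if (nm %in% names(st$discretization)) {
      edges <- st$discretization[[nm]]
      bin <- as.integer(as.character(cells[[nm]]))
      lo <- edges[bin]; hi <- edges[bin + 1L]
      out[[nm]] <- stats::runif(m, lo, hi)
    } else {
      out[[nm]] <- as.character(cells[[nm]])
    }
  }
  dataset(as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE),
          model$schema, id = "bayes_net_sample")
}

# ---- external adapter -------------------------------------------------------

#' Wrap an external generator behind the fit/sample contract
#'
#' The adapter invokes an external command as
#' `command train.csv schema.yaml m seed out.csv`; the command must write a
#' schema-conformant CSV with `m` rows to `out.csv`. This is the integration
#' point for third-party deep tabular synthesizers, whose internals are out
#' of this package's scope.
#'
#' @param base Training `tabaug_dataset` (written to a temp CSV at fit time).
#' @param command Character vector: the executable and any leading arguments.
#' @return A `tabaug_generator` of method `"adapter"`.
#' @export
fit_adapter <- function(base, command) {
  stopifnot(inherits(base, "tabaug_dataset"), is.character(command))
  dir <- tempfile("tabaug_adapter_")
  dir.create(dir)
  train_csv <- file.path(dir, "train.csv")
  schema_yaml <- file.path(dir, "schema.yaml")
  write_dataset(base, train_csv, schema_path = schema_yaml)
  structure(list(method = "adapter", schema = base$schema, command = command,
                 train_csv = train_csv, schema_yaml = schema_yaml,
                 n_train = nrow(base$data)),
            class = c("tabaug_adapter", "tabaug_generator"))
}

#' @export
sample_synth.tabaug_adapter <- function(model, m, seed = 1L) {
  out_csv <- tempfile(fileext = ".csv")
  args <- c(model$command[-1L], model$train_csv, model$schema_yaml,
            as.character(m), as.character(seed), out_csv)
  status <- system2(model$command[[1L]], shQuote(args))
  if (!identical(status, 0L)) stop("adapter command failed with status ", status)
  syn <- read_dataset(out_csv, model$schema, id = "adapter_sample")
  if (nrow(syn$data) != m) stop("adapter returned ", nrow(syn$data),
                                " rows, expected ", m)
  syn
}
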