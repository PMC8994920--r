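#' Control parameters of the CART imputation machinery
#'
#' @param min_leaf minimum number of donors in a terminal node (rpart
#'   `minbucket`); at least 2, so every routed case has a non-trivial donor
#'   pool.
#' @param complexity minimum complexity-parameter decrease to split (rpart
#'   `cp`).
#' @param max_depth maximum tree depth (rpart caps at 30).
#' @param n_chained_iters sweeps of the chained-equations loop over the
#'   incomplete variables.
#' @return an object of class `cart_params`.
#' @export
cart_params <- function(min_leaf = 5, complexity = 1e-4, max_depth = 30,
                        n_chained_iters = 5) {
  if (min_leaf < 2) stopf("min_leaf must be at least 2")
  if (n_chained_iters < 1) stopf("n_chained_iters must be at least 1")
  structure(list(min_leaf = as.integer(min_leaf), complexity = complexity,
                 max_depth = as.integer(min(max_depth, 30L)),
                 n_chained_iters = as.integer(n_chained_iters)),
            class = "cart_params")
}

#' Imputation model specification
#'
#' Records, for one target variable, the candidate predictors offered to the
#' selection tree, the subset it selected (variables appearing in at least
#' one split), and the predictors forced into every model (age, sex and
#' education at the anchor wave in the standard pipeline). The final design
#' of the imputation model is `union(forced, selected)`.
#'
#' @param target target variable name (wave-qualified).
#' @param candidates candidate predictor names.
#' @param selected predictors chosen by the selection tree.
#' @param forced predictors always included.
#' @return an object of class `imputation_spec`.
#' @export
imputation_spec <- function(target, candidates = character(),
                            selected = character(), forced = character()) {
  selected <- setdiff(selected, target)
  structure(list(target = target, candidates = setdiff(candidates, target),
                 selected = selected, forced = setdiff(forced, target)),
            class = "imputation_spec")
}

#' @export
print.imputation_spec <- function(x, ...) {
  cat("<imputation_spec> target:", x$target, "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat("  forced:  ", paste(x$forced, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise imputation specs to JSON
#'
#' @param specs a list of [imputation_spec()] objects.
#' @param path file path; if `NULL` the JSON string is returned.
#' @export
specs_to_json <- function(specs, path = NULL) {
  payload <- lapply(specs, function(s)
    list(target = jsonlite::unbox(s$target),
         selected = s$selected, forced = s$forced))
  js <- jsonlite::toJSON(payload, auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# classification for factors/characters/binaries, regression otherwise
target_method <- function(y) {
  if (is.factor(y) || is.character(y) || is.logical(y)) return("class")
  if (length(unique(y[!is.na(y)])) <= 2) return("class")
  "anova"
}

rpart_ctrl <- function(params) {
  rpart::rpart.control(minbucket = params$min_leaf, cp = params$complexity,
                       maxdepth = params$max_depth, xval = 0)
}

# Route rows of `newdata` to terminal nodes of a fitted rpart tree.
# rpart's predict looks up frame$yval at the reached node for type = "vector",
# so overwriting yval with the frame row index returns the node itself.
route_to_node <- function(fit, newdata) {
  fit$frame$yval <- seq_len(nrow(fit$frame))
  as.integer(predict(fit, newdata = newdata, type = "vector"))
}

#' Select predictors for one imputation model with a CART
#'
#' Fits a single tree of the target on the candidate predictors over the
#' rows where the target is observed and returns the variables appearing in
#' at least one split, merged with the forced predictors. During selection
#' (and only then) missing candidate values are handled by a "missing as its
#' own category" level for categorical candidates and a median fill for
#' numeric ones, so selection never leaks imputed values.
#'
#' @param data a data.frame.
#' @param target target variable name; must have at least one observed value.
#' @param candidates candidate predictor names (the target is excluded).
#' @param forced predictors forced into the final model.
#' @param params a [cart_params()].
#' @return an [imputation_spec()].
#' @export
select_predictors <- function(data, target, candidates, forced = character(),
                              params = cart_params()) {
  candidates <- setdiff(candidates, target)
  y <- data[[target]]
  if (is.null(y)) stopf("unknown target '%s'", target)
  obs <- which(!is.na(y))
  if (!length(obs)) stopf("target '%s' is fully missing; cannot select predictors", target)
  if (!length(candidates) || length(unique(y[obs])) < 2)
    return(imputation_spec(target, candidates, character(), forced))
  X <- data[obs, candidates, drop = FALSE]
  for (j in seq_along(X)) {
    cl <- X[[j]]
    if (is.numeric(cl)) {
      cl[is.na(cl)] <- stats::median(cl, na.rm = TRUE)
    } else {
      cl <- as.character(cl)
      cl[is.na(cl)] <- "(missing)"
      cl <- factor(cl)
    }
    X[[j]] <- cl
  }
  method <- target_method(y)
  yfit <- if (method == "class") factor(y[obs]) else y[obs]
  df <- cbind(.target = yfit, X)
  fit <- rpart::rpart(.target ~ ., data = df, method = method,
                      control = rpart_ctrl(params))
  sel <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
  imputation_spec(target, candidates, sel, forced)
}

#' Impute one variable by CART donor draws
#'
#' Grows a tree of the target on the spec's predictor set
#' (`union(forced, selected)`) over the rows with an observed target, routes
#' each row to be imputed to its terminal node, and draws one observed donor
#' value uniformly from that node. Imputed values are therefore always
#' observed donor values (donor closure); with no predictors the donor pool
#' is the whole observed marginal.
#'
#' @param data a data.frame.
#' @param spec an [imputation_spec()].
#' @param params a [cart_params()].
#' @param rows row indices to impute; defaults to all rows with a missing
#'   target.
#' @param seed optional seed; if `NULL` the current RNG stream is used (as in
#'   the chained loop).
#' @return `data` with the target completed on `rows`.
#' @export
impute_variable <- function(data, spec, params = cart_params(), rows = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "impute", spec$target))
  y <- data[[spec$target]]
  if (is.null(y)) stopf("unknown target '%s'", spec$target)
  if (is.null(rows)) rows <- which(is.na(y))
  if (!length(rows)) return(data)
  yfit <- y
  yfit[rows] <- NA # never treat previously imputed cells as observed
  obs <- which(!is.na(yfit))
  if (!length(obs)) stopf("target '%s' has no observed donors", spec$target)
  yobs <- y[obs]
  # one uniform per row to impute, drawn up-front: imputations of rows whose
  # donor pool is unchanged are invariant to changes elsewhere (this is what
  # couples scenario copies run under the same stream)
  u <- runif(length(rows))
  draw_from <- function(pool_vals, uu) pool_vals[floor(uu * length(pool_vals)) + 1L]

  predictors <- union(spec$forced, spec$selected)
  if (length(unique(yobs)) < 2 || !length(predictors)) {
    data[[spec$target]][rows] <- draw_from(yobs, u)
    return(data)
  }
  method <- target_method(y)
  yy <- if (method == "class") factor(yobs) else yobs
  # factor levels must come from the full data so routing never meets a new level
  X <- data[, predictors, drop = FALSE]
  for (j in seq_along(X)) if (is.character(X[[j]])) X[[j]] <- factor(X[[j]])
  df_obs <- cbind(.target = yy, X[obs, , drop = FALSE])
  fit <- try(rpart::rpart(.target ~ ., data = df_obs, method = method,
                          control = rpart_ctrl(params)), silent = TRUE)
  if (inherits(fit, "try-error") || nrow(fit$frame) == 1) {
    data[[spec$target]][rows] <- draw_from(yobs, u)
    return(data)
  }
  pools <- split(yobs, fit$where)
  nodes <- route_to_node(fit, X[rows, , drop = FALSE])
  imp <- yobs[rep.int(1L, length(rows))] # placeholder with the target's type
  for (i in seq_along(rows)) {
    pool <- pools[[as.character(nodes[i])]]
    if (is.null(pool)) pool <- yobs # routed to a pruned/internal node
    imp[i] <- draw_from(pool, u[i])
  }
  data[[spec$target]][rows] <- imp
  data
}

# Deterministic completion of vital-status columns: death is absorbing
# downward, participation implies being alive. Returns the data with the
# implied cells filled; remaining NAs (if any) are left for model imputation.
resolve_vital_bounds <- function(data, years) {
  if (length(years) < 1 ||
      !any(wave_col("alive", years) %in% names(data))) return(data)
  for (w in seq_along(years)) {
    cl <- wave_col("alive", years[w])
    if (!cl %in% names(data)) next
    a <- data[[cl]]
    if (w > 1) {
      prev <- data[[wave_col("alive", years[w - 1])]]
      a[is.na(a) & !is.na(prev) & prev == 0] <- 0L
    }
    sub <- data[, intersect(wave_col(.substantive_vars, years[w]),
                            names(data)), drop = FALSE]
    if (ncol(sub)) a[is.na(a) & rowSums(!is.na(sub)) > 0] <- 1L
    data[[cl]] <- a
  }
  # alive later implies alive now
  if (length(years) < 2) return(data)
  for (w in rev(seq_len(length(years) - 1))) {
    cl <- wave_col("alive", years[w])
    nxt <- wave_col("alive", years[w + 1])
    if (!all(c(cl, nxt) %in% names(data))) next
    a <- data[[cl]]
    a[is.na(a) & !is.na(data[[nxt]]) & data[[nxt]] == 1] <- 1L
    data[[cl]] <- a
  }
  data
}

# Cells eligible for imputation for one variable: missing, and not masked by
# death (substantive variables stay missing at waves where the individual is
# dead).
imputable_rows <- function(data, col) {
  y <- data[[col]]
  rows <- which(is.na(y))
  info <- parse_col(col)
  if (!is.na(info$year) && info$var %in% c(.substantive_vars, .score_vars)) {
    alive <- data[[wave_col("alive", info$year)]]
    if (!is.null(alive)) rows <- rows[!is.na(alive[rows]) & alive[rows] == 1]
  }
  rows
}

#' Chained-equations imputation with CART conditional models
#'
#' Completes a dataset by iterative conditional draws: missing cells are
#' initialised by uniform draws from each variable's observed marginal, then
#' `params$n_chained_iters` sweeps visit the incomplete variables in order of
#' increasing missingness fraction (ties broken by column order),
#' re-imputing each target from the current completed data with
#' [impute_variable()]. Vital-status columns are first completed
#' deterministically where implied (death is absorbing; observed survey
#' content implies being alive) and any remainder is imputed like other
#' variables, in wave order; substantive cells at waves where the individual
#' is dead are never imputed.
#'
#' This returns a single completed dataset: in the projection pipeline the
#' "multiple" of multiple imputation comes from the bootstrap replicates.
#'
#' @param data a data.frame.
#' @param specs named list of [imputation_spec()], one per incomplete
#'   variable (a variable with imputable missingness but no spec is an
#'   error).
#' @param params a [cart_params()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param visit explicit visit order (character vector of targets) overriding
#'   the missingness-fraction order; used by the projection engine to impose
#'   the two-phase scenario order.
#' @param n_iters optional override of `params$n_chained_iters`.
#' @return the completed data.frame.
#' @export
chained_impute <- function(data, specs, params = cart_params(), seed = NULL,
                           visit = NULL, n_iters = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "chain"))
  n_iters <- n_iters %||% params$n_chained_iters
  years <- sort(unique(parse_col(names(data))$year))
  years <- years[!is.na(years)]
  data <- resolve_vital_bounds(data, years)

  # alive columns are resolved first, in wave order, so the death masks that
  # define every other variable's imputable cells are fixed before the loop
  for (year in years) {
    cl <- wave_col("alive", year)
    if (!cl %in% names(data) || !anyNA(data[[cl]])) next
    sp <- specs[[cl]]
    if (is.null(sp))
      stopf("variable '%s' has missing values but no imputation spec", cl)
    data <- impute_variable(data, sp, params, rows = which(is.na(data[[cl]])))
    data <- resolve_vital_bounds(data, years)
  }

  todo <- list()
  for (cl in setdiff(names(data), c(.id_vars, grep("^alive_", names(data), value = TRUE)))) {
    rows <- imputable_rows(data, cl)
    if (length(rows)) todo[[cl]] <- rows
  }
  if (!length(todo)) return(data)
  missing_no_spec <- setdiff(names(todo), names(specs))
  if (length(missing_no_spec))
    stopf("variable '%s' has missing values but no imputation spec",
          missing_no_spec[1])
  frac <- vapply(todo, length, 1L) / nrow(data)
  order_cols <- if (is.null(visit)) {
    names(todo)[order(frac, match(names(todo), names(data)))]
  } else {
    intersect(visit, names(todo))
  }
  # initialisation: uniform draws from each observed marginal
  for (cl in order_cols) {
    y <- data[[cl]]
    obs <- y[setdiff(seq_along(y), todo[[cl]])]
    obs <- obs[!is.na(obs)]
    if (!length(obs)) stopf("variable '%s' has no observed values", cl)
    data[[cl]][todo[[cl]]] <- obs[floor(runif(length(todo[[cl]])) * length(obs)) + 1L]
  }
  for (it in seq_len(n_iters)) {
    for (cl in order_cols)
      data <- impute_variable(data, specs[[cl]], params, rows = todo[[cl]])
  }
  data
}
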