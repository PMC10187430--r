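#' Preprocess marker scores for panel modelling
#'
#' Optionally subtracts the per-subject background (negative-control channel)
#' from every marker, floors the result at a small positive value, and takes
#' logarithms. The floor defaults to half the smallest positive
#' post-subtraction value in the table, so subjects at or below background
#' get a finite, minimal log score rather than -Inf.
#'
#' @param table a [marker_score_table()].
#' @param subtract_background subtract the table's background column first.
#' @param log_base base of the logarithm (default 10; fluorescence readouts
#'   span decades).
#' @param floor positive lower bound applied before the log.
#' @return A [marker_score_table()] of log-scale scores; the applied
#'   transform is recorded in attribute `"transform"`.
#' @export
preprocess_scores <- function(table, subtract_background = FALSE,
                              log_base = 10, floor = NULL) {
  v <- table$values
  if (subtract_background) {
    if (is.null(table$background)) {
      stop("table has no background column", call. = FALSE)
    }
    v <- sweep(v, 1, table$background, "-")
  }
  if (is.null(floor)) {
    pos <- v[v > 0]
    if (length(pos) == 0L) stop("no positive values to set a floor from",
                                call. = FALSE)
    floor <- min(pos) / 2
  }
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  v <- log(pmax(v, floor), base = log_base)
  out <- marker_score_table(table$subjects, v, table$background)
  attr(out, "transform") <- list(subtract_background = subtract_background,
                                 log_base = log_base, floor = floor)
  out
}

logistic_loglik <- function(beta, X1, y) {
  eta <- drop(X1 %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Newton solver for ridge-penalised logistic regression (intercept
# unpenalised); used only when ML fitting hits separation.
ridge_logistic <- function(X1, y, lambda, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% beta
    hess <- crossprod(X1 * w, X1) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Maximum-likelihood logistic fit for a marker subset
#'
#' Fits `label ~ markers` with an intercept by ML (via [stats::glm()]).
#' When the fit hits complete or quasi-complete separation (fitted
#' probabilities numerically 0/1, divergent coefficients), the model is refit
#' with a small L2 penalty on the slopes (default 1e-4, intercept
#' unpenalised) so that finite coefficients and an AIC comparable across
#' subsets are still reported; such fits are flagged with
#' `separation = TRUE`. The reported log-likelihood is always the
#' unpenalised binomial log-likelihood at the returned coefficients, and
#' `aic = 2k - 2 logL` with `k = length(markers) + 1`.
#'
#' @param X numeric matrix, subjects x markers, with marker colnames.
#' @param y binary outcome: 0/1, logical, or a character/factor with levels
#'   `"control"`/`"case"` (case = 1).
#' @param markers marker names (default: all columns of `X`).
#' @param ridge L2 penalty used by the separation fallback.
#' @param transform optional preprocessing description carried along.
#' @return Object of class `panel_model` with `markers`, `coefficients`
#'   (named slope vector), `intercept`, `log_likelihood`, `aic`, `k`,
#'   `converged`, `separation`, `transform`.
#' @export
fit_logistic <- function(X, y, markers = colnames(X), ridge = 1e-4,
                         transform = NULL) {
  X <- as.matrix(X)
  if (is.character(y) || is.factor(y)) {
    y <- as.integer(as.character(y) == "case")
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  Xs <- X[, markers, drop = FALSE]
  if (any(apply(Xs, 2, stats::sd) == 0)) {
    stop("constant (zero-variance) marker column", call. = FALSE)
  }
  sep <- FALSE
  conv <- TRUE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, Xs), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  if (!fit$converged || any(abs(beta) > 1e3)) sep <- TRUE
  if (sep) {
    beta <- ridge_logistic(cbind(1, Xs), y, ridge)
    conv <- FALSE
  }
  ll <- logistic_loglik(beta, cbind(1, Xs), y)
  k <- length(markers) + 1L
  structure(
    list(markers = markers,
         coefficients = stats::setNames(beta[-1], markers),
         intercept = unname(beta[1]),
         log_likelihood = ll, aic = 2 * k - 2 * ll, k = k,
         converged = conv, separation = sep, transform = transform),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic panel model:", panel_equation(x), "\n")
  cat(sprintf("  logL = %.4f, AIC = %.4f, k = %d%s\n", x$log_likelihood,
              x$aic, x$k,
              if (x$separation) " (separation; ridge-stabilised)" else ""))
  invisible(x)
}

#' Human-readable linear combination equation of a panel model
#' @param model a `panel_model`.
#' @param digits coefficient digits.
#' @return A string like `"11.299 x log(IGSF8) + 14.935 x log(ITGA5)"`.
#' @export
panel_equation <- function(model, digits = 3) {
  terms <- sprintf("%s x log(%s)", format(round(model$coefficients, digits),
                                          trim = TRUE), model$markers)
  paste(terms, collapse = " + ")
}

#' Exhaustive best-subset panel search by AIC
#'
#' Fits a logistic model for every marker subset of the requested sizes
#' (default 2 markers, 3 markers, ..., up to the full panel) and ranks the
#' models by AIC, lower being better; ties break lexicographically on the
#' marker subset for determinism.
#'
#' @param table a preprocessed [marker_score_table()].
#' @param subset_sizes integer vector of subset sizes (default `2:m`).
#' @param max_markers guard against combinatorial blowup (default 20).
#' @param ridge separation-fallback penalty, see [fit_logistic()].
#' @return Object of class `panel_search` with `all_models` (every fitted
#'   `panel_model`), `best` (minimal AIC) and `ranking` (models sorted by
#'   AIC).
#' @export
exhaustive_search <- function(table, subset_sizes = NULL, max_markers = 20L,
                              ridge = 1e-4) {
  m <- length(table$markers)
  if (m > max_markers) {
    stop(m, " markers exceed the subset-search guard (", max_markers,
         "); pass an explicit marker list", call. = FALSE)
  }
  if (is.null(subset_sizes)) subset_sizes <- seq(2L, m)
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  if (any(subset_sizes < 1L | subset_sizes > m)) {
    stop("subset sizes must lie in 1..", m, call. = FALSE)
  }
  y <- table$subjects$label
  transform <- attr(table, "transform")
  models <- list()
  for (s in subset_sizes) {
    combos <- utils::combn(table$markers, s, simplify = FALSE)
    for (cc in combos) {
      models[[length(models) + 1L]] <-
        fit_logistic(table$values, y, markers = cc, ridge = ridge,
                     transform = transform)
    }
  }
  aics <- vapply(models, `[[`, 0, "aic")
  keys <- vapply(models, function(mod) paste(mod$markers, collapse = "|"), "")
  ord <- order(aics, keys)
  structure(list(all_models = models, best = models[[ord[1]]],
                 ranking = models[ord]),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat("Exhaustive panel search:", length(x$all_models), "models\n")
  top <- utils::head(x$ranking, 5L)
  for (mod in top) {
    cat(sprintf("  AIC %8.3f  {%s}\n", mod$aic,
                paste(mod$markers, collapse = ", ")))
  }
  invisible(x)
}

#' Linear combination score of a panel model
#'
#' The linear term of the logistic model, `sum_j beta_j * x_j`, with the
#' intercept excluded: ROC analysis of the score is invariant to the omitted
#' constant, and classification thresholds absorb it.
#'
#' @param model a `panel_model`.
#' @param X numeric matrix whose columns cover `model$markers` (already
#'   preprocessed consistently with `model$transform`).
#' @return Numeric score vector, one value per row of `X`.
#' @export
linear_score <- function(model, X) {
  X <- as.matrix(X)
  missing_m <- setdiff(model$markers, colnames(X))
  if (length(missing_m) > 0L) {
    stop("score matrix lacks marker column(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  drop(X[, model$markers, drop = FALSE] %*% model$coefficients)
}

#' Evaluate a panel model's diagnostic performance
#'
#' Computes the linear combination score for every subject and reports the
#' same statistics as a single-marker analysis: AUC with DeLong SE/CI and
#' one-tailed p, sensitivity at a fixed specificity, specificity at a fixed
#' sensitivity, and the Youden-optimal point.
#'
#' @param model a `panel_model`.
#' @param table a [marker_score_table()] preprocessed consistently with the
#'   model.
#' @param spec_target,sens_target,ci_level see [marker_report()].
#' @return A [marker_report()]-style list, plus `scores` (named per-subject
#'   score vector) and `model`.
#' @export
evaluate_panel <- function(model, table, spec_target = 0.998,
                           sens_target = 0.95, ci_level = 0.95) {
  scores <- linear_score(model, table$values)
  ctrl <- scores[table$subjects$label == "control"]
  case <- scores[table$subjects$label == "case"]
  rep <- marker_report(unname(ctrl), unname(case), spec_target, sens_target,
                       ci_level)
  rep$scores <- stats::setNames(scores, table$subjects$subject_id)
  rep$model <- model
  rep
}
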