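#' Transform occurrence predictors
#'
#' Applies the study's predictor transformation to a presence/absence
#' table: each spatial trait is \code{ln(x+1)} transformed and then
#' centered/scaled to mean 0, SD 1 over the combined presence+absence set.
#' The transform parameters are stored so that new records can be mapped
#' onto the training scale for prediction.
#'
#' @param records data.frame with a \code{presence} column (0/1) and the
#'   five non-negative predictor columns \code{slope, aspect, elevation,
#'   radiation, hotspot_distance} (polygon means).
#' @return data.frame of class \code{occurrence_design} with transformed
#'   predictors and attributes \code{centers}, \code{scales}.
#' @export
transform_predictors <- function(records) {
  records <- as.data.frame(records)
  vars <- c("slope", "aspect", "elevation", "radiation", "hotspot_distance")
  miss <- setdiff(c("presence", vars), names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$presence %in% c(0, 1)))
    stop("presence must be 0/1")
  out <- records[, c("presence", vars)]
  centers <- scales <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    x <- records[[v]]
    if (any(!is.finite(x))) stop("non-finite predictor: ", v)
    if (any(x < 0)) stop("negative predictor (ln(x+1) undefined): ", v)
    lx <- log1p(x)
    centers[v] <- mean(lx)
    scales[v] <- stats::sd(lx)
    if (scales[v] == 0) scales[v] <- 1
    out[[v]] <- (lx - centers[v]) / scales[v]
  }
  structure(out, centers = centers, scales = scales,
            class = c("occurrence_design", "data.frame"))
}

# Apply a stored transform to new raw records.
apply_transform <- function(design, newdata) {
  centers <- attr(design, "centers")
  scales <- attr(design, "scales")
  newdata <- as.data.frame(newdata)
  for (v in names(centers)) {
    if (is.null(newdata[[v]])) next
    x <- newdata[[v]]
    lx <- log1p(x)
    z <- (lx - centers[v]) / scales[v]
    rng <- range(design[[v]])
    if (any(z < rng[1] - 1e-9 | z > rng[2] + 1e-9))
      warning("extrapolating beyond the training range of ", v)
    newdata[[v]] <- z
  }
  newdata
}

# Model formula for a term subset. Slope and aspect enter as thin-plate
# regression spline smoothers; the rest are linear on the logit scale.
.occurrence_formula <- function(terms, k = 10) {
  smooth_terms <- c(slope = sprintf("s(slope, bs = \"tp\", k = %d)", k),
                    aspect = sprintf("s(aspect, bs = \"tp\", k = %d)", k))
  rhs <- vapply(terms, function(t)
    if (t %in% names(smooth_terms)) smooth_terms[[t]] else t, character(1))
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste("presence ~", paste(rhs, collapse = " + ")))
}

#' Fit one additive logistic occurrence model
#'
#' Penalized-likelihood fit of a binary (logit link) additive model for
#' colony presence: slope and aspect as thin-plate regression spline
#' smoothers, solar radiation, elevation and hotspot distance linear on the
#' logit scale. Smoothing parameters are selected by the configured
#' criterion; AIC counts effective degrees of freedom.
#'
#' @param design an \code{\link{transform_predictors}} result.
#' @param terms character subset of \code{c("slope", "aspect", "elevation",
#'   "radiation", "hotspot_distance")}; empty for the null model.
#' @param k smoother basis dimension (default 10).
#' @param method smoothing-parameter selection criterion passed to
#'   \code{mgcv::gam} (default \code{"REML"}).
#' @param sp optional fixed smoothing parameters (e.g. \code{0} to disable
#'   penalization).
#' @return object of class \code{occurrence_model}: list with the
#'   \code{mgcv} fit, \code{terms}, \code{aic}, \code{edf} (named, per
#'   smoother), \code{deviance_explained}, \code{term_estimates} (linear
#'   terms: estimate, SE, Z, p).
#' @export
fit_occurrence_model <- function(design, terms = character(0), k = 10,
                                 method = "REML", sp = NULL) {
  stopifnot(inherits(design, "occurrence_design"))
  if (nrow(design) < 20) stop("need at least 20 records")
  if (length(unique(design$presence)) < 2)
    stop("single-class response: both presences and absences required")
  fml <- .occurrence_formula(terms, k = k)
  fit <- mgcv::gam(fml, family = stats::binomial(), data = design,
                   method = method, sp = sp)
  if (!fit$converged)
    stop("occurrence model did not converge (possible complete separation)")
  sm <- summary(fit)
  edf <- if (length(fit$smooth))
    stats::setNames(sm$edf, vapply(fit$smooth, function(s) s$term,
                                   character(1)))
  else stats::setNames(numeric(0), character(0))
  est <- as.data.frame(sm$p.table)
  names(est) <- c("estimate", "se", "z", "p")
  structure(list(fit = fit, terms = terms, aic = stats::AIC(fit),
                 edf = edf, deviance_explained = sm$dev.expl,
                 term_estimates = est,
                 design = design),
            class = "occurrence_model")
}

#' @export
print.occurrence_model <- function(x, ...) {
  cat(sprintf("occurrence model [%s]: AIC %.2f, deviance explained %.1f%%\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "null",
              x$aic, 100 * x$deviance_explained))
  invisible(x)
}

#' All-subsets occurrence model set
#'
#' Fits every subset of the candidate terms (2^k models including the
#' null), ranks by AIC and attaches Akaike weights
#' \code{w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)}. With the study's
#' five candidates this is 32 models. Models that fail to fit are flagged,
#' excluded from the weights and reported with a warning.
#'
#' @param design an \code{\link{transform_predictors}} result.
#' @param candidates candidate term names (default all five).
#' @param ... passed to \code{\link{fit_occurrence_model}}.
#' @return object of class \code{occurrence_model_set}: list with
#'   \code{table} (terms, aic, delta_aic, weight, deviance_explained,
#'   ranked ascending by AIC) and \code{models} (in table order).
#' @export
all_subsets <- function(design,
                        candidates = c("slope", "aspect", "elevation",
                                       "radiation", "hotspot_distance"),
                        ...) {
  if (length(candidates) == 0) stop("candidate list is empty")
  k <- length(candidates)
  subsets <- lapply(seq_len(2^k) - 1, function(m)
    candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  fits <- vector("list", length(subsets))
  ok <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(fit_occurrence_model(design, subsets[[i]], ...),
                          error = function(e) e)
    ok[i] <- inherits(fits[[i]], "occurrence_model")
  }
  if (!all(ok))
    warning(sum(!ok), " model(s) failed to fit and were excluded from weights")
  fits <- fits[ok]
  subsets <- subsets[ok]
  if (length(fits) == 0) stop("no model could be fitted")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aic)
  fits <- fits[ord]; subsets <- subsets[ord]; aic <- aic[ord]
  delta <- aic - aic[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(null)", character(1)),
    n_terms = vapply(subsets, length, integer(1)),
    aic = aic, delta_aic = delta, weight = w,
    deviance_explained = vapply(fits, function(f) f$deviance_explained,
                                numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(table = tab, models = fits, subsets = subsets,
                 candidates = candidates),
            class = "occurrence_model_set")
}

#' @export
print.occurrence_model_set <- function(x, ...) {
  cat(sprintf("%d occurrence models over {%s}\n", nrow(x$table),
              paste(x$candidates, collapse = ", ")))
  print(utils::head(x$table, 8), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Relative variable importance
#'
#' RVI of a candidate term is the sum of the Akaike weights of all models
#' in which the term occurs; a term present in every model has RVI 1.
#'
#' @param model_set an \code{\link{all_subsets}} result.
#' @return named numeric vector of RVIs, sorted decreasing.
#' @export
relative_variable_importance <- function(model_set) {
  stopifnot(inherits(model_set, "occurrence_model_set"))
  if (length(model_set$models) == 0) stop("empty model set")
  rvi <- vapply(model_set$candidates, function(term)
    sum(model_set$table$weight[vapply(model_set$subsets,
                                      function(s) term %in% s, logical(1))]),
    numeric(1))
  sort(rvi, decreasing = TRUE)
}

#' Deviance explained relative to a null model
#'
#' \code{1 - deviance(model) / deviance(null)}, the binomial-model analogue
#' of variance explained.
#'
#' @param model,null_model \code{\link{fit_occurrence_model}} results
#'   fitted to the same records.
#' @return fraction in [0, 1].
#' @export
deviance_explained <- function(model, null_model) {
  stopifnot(inherits(model, "occurrence_model"),
            inherits(null_model, "occurrence_model"))
  if (!isTRUE(all.equal(as.data.frame(model$design),
                        as.data.frame(null_model$design))))
    stop("models were fitted to different record sets")
  1 - stats::deviance(model$fit) / stats::deviance(null_model$fit)
}

#' Predict colony-occurrence probability
#'
#' Maps raw (untransformed) predictor values through the stored
#' \code{ln(x+1)}-and-scale transform and returns the inverse-logit of the
#' fitted linear predictor. Queries outside the training range raise an
#' extrapolation warning.
#'
#' @param model an \code{\link{fit_occurrence_model}} result.
#' @param newdata data.frame of raw predictor values.
#' @param transformed set TRUE if \code{newdata} is already on the
#'   transformed scale.
#' @return vector of probabilities in (0, 1).
#' @export
predict_occurrence <- function(model, newdata, transformed = FALSE) {
  stopifnot(inherits(model, "occurrence_model"))
  nd <- if (transformed) as.data.frame(newdata)
  else apply_transform(model$design, newdata)
  as.numeric(stats::predict(model$fit, newdata = nd, type = "response"))
}
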