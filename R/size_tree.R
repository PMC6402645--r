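# --- Conditional inference tree for colony size -------------------------
#
# Recursive binary partitioning in which each split must first pass a
# permutation test of association between the response and a predictor,
# Bonferroni-adjusted over the predictors tested at the node. Splitting
# stops when no adjusted p-value falls below alpha, so tree depth is
# governed by significance, not pruning.

# Monte-Carlo permutation p-values of the linear association statistic for
# a list of predictors against one response, sharing one set of
# permutations. Numeric predictors use |sum(x_c * y_c)|; categorical
# predictors use the maximum over level indicators of the statistic
# standardized by its permutation moments. Constant predictors get p = 1.
.assoc_pvals <- function(y, predictors, n_perm, seed) {
  n <- length(y)
  yc <- y - mean(y)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  YP <- matrix(yc[perm_idx], n, n_perm)
  vapply(predictors, function(x) {
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      x <- droplevels(x)
      if (nlevels(x) < 2) return(1)
      I <- stats::model.matrix(~ 0 + x)
      t_obs <- as.numeric(crossprod(I, yc))
      t_perm <- crossprod(I, YP)
      mu <- rowMeans(t_perm)
      sd <- sqrt(pmax(apply(t_perm, 1, stats::var), .Machine$double.eps))
      z_obs <- max(abs((t_obs - mu) / sd))
      z_perm <- apply(abs((t_perm - mu) / sd), 2, max)
      eps <- 1e-8 * (abs(z_obs) + 1)
      (1 + sum(z_perm >= z_obs - eps)) / (n_perm + 1)
    } else {
      if (stats::var(x) == 0) return(1)
      xc <- x - mean(x)
      s_obs <- abs(sum(xc * yc))
      s_perm <- abs(as.numeric(crossprod(xc, YP)))
      eps <- 1e-8 * (s_obs + 1)
      (1 + sum(s_perm >= s_obs - eps)) / (n_perm + 1)
    }
  }, numeric(1))
}

#' Permutation test of association
#'
#' Monte-Carlo permutation p-value of the linear association statistic
#' between a response and one predictor (covariance statistic for numeric
#' predictors; maximum standardized indicator statistic over levels for
#' categorical ones). The smallest attainable p-value is
#' \code{1/(n_perm+1)}; a constant predictor returns 1 by convention.
#'
#' @param response numeric response values (>= 2 distinct).
#' @param predictor numeric vector, or factor/character for categorical.
#' @param n_perm number of Monte-Carlo permutations (>= 999).
#' @param seed integer seed; the p-value is deterministic given it.
#' @return p-value in (0, 1].
#' @export
association_test <- function(response, predictor, n_perm = 9999, seed = 1L) {
  if (length(unique(response)) < 2)
    stop("need at least 2 distinct response values")
  if (n_perm < 999) stop("n_perm must be at least 999")
  if (length(predictor) != length(response))
    stop("response and predictor lengths differ")
  as.numeric(.assoc_pvals(response, list(predictor), n_perm, seed))
}

# Best binary split of a numeric predictor by between-group sum of squares.
# Returns list(threshold, between_ss) or NULL if no split satisfies
# minbucket.
.best_numeric_split <- function(x, y, minbucket) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(y)
  csum <- cumsum(ys)
  tot <- csum[n]
  nl <- seq_len(n - 1)
  # candidate cuts between distinct consecutive values only
  distinct <- xs[nl] < xs[nl + 1]
  valid <- distinct & nl >= minbucket & (n - nl) >= minbucket
  if (!any(valid)) return(NULL)
  ml <- csum[nl] / nl
  mr <- (tot - csum[nl]) / (n - nl)
  gm <- tot / n
  bss <- nl * (ml - gm)^2 + (n - nl) * (mr - gm)^2
  bss[!valid] <- -Inf
  k <- which.max(bss)
  list(threshold = (xs[k] + xs[k + 1]) / 2, between_ss = bss[k])
}

# Best level-subset split of a categorical predictor: exhaustive search of
# the 2^(L-1)-1 bipartitions of observed levels. Returns
# list(levels = left-side level set, between_ss) or NULL.
.best_categorical_split <- function(x, y, minbucket) {
  x <- droplevels(factor(x))
  levs <- levels(x)
  L <- length(levs)
  if (L < 2) return(NULL)
  n <- length(y)
  gm <- mean(y)
  best <- NULL; best_ss <- -Inf
  for (mask in seq_len(2^(L - 1) - 1)) {
    left_levs <- levs[bitwAnd(mask, 2^(seq_len(L) - 1)) > 0]
    left <- x %in% left_levs
    nl <- sum(left)
    if (nl < minbucket || (n - nl) < minbucket) next
    ss <- nl * (mean(y[left]) - gm)^2 + (n - nl) * (mean(y[!left]) - gm)^2
    if (ss > best_ss) { best_ss <- ss; best <- left_levs }
  }
  if (is.null(best)) return(NULL)
  # normalize: report the smaller side (lexicographic tie-break)
  other <- setdiff(levs, best)
  pick <- if (length(other) < length(best) ||
              (length(other) == length(best) &&
               paste(sort(other), collapse = ",") <
               paste(sort(best), collapse = ","))) other else best
  list(levels = sort(pick), between_ss = best_ss)
}

#' Select the splitting variable and split point at a node
#'
#' Computes per-predictor permutation p-values of association with the
#' response, Bonferroni-adjusts them over the predictors tested, and stops
#' if the smallest adjusted p exceeds \code{alpha}. Otherwise the most
#' significant predictor is split at the binary cutpoint (threshold for
#' numeric, level subset for categorical) maximizing the between-group sum
#' of squares of the response. Ties in p are resolved by predictor
#' declaration order.
#'
#' @param records data.frame holding the response and predictors.
#' @param response name of the response column.
#' @param predictors names of predictor columns.
#' @param alpha significance level for splitting (default 0.05).
#' @param n_perm Monte-Carlo permutations.
#' @param seed integer seed.
#' @param minbucket minimum records on each side of a split.
#' @return NULL (stop) or list \code{variable, p_adjusted, threshold} /
#'   \code{levels} describing the split (left child: \code{x <= threshold}
#'   or \code{x \%in\% levels}).
#' @export
select_split <- function(records, response, predictors, alpha = 0.05,
                         n_perm = 9999, seed = 1L, minbucket = 7L) {
  y <- records[[response]]
  if (length(unique(y)) < 2) return(NULL)
  preds <- lapply(predictors, function(p) records[[p]])
  constant <- vapply(preds, function(x) length(unique(x)) < 2, logical(1))
  if (all(constant)) return(NULL)
  pvals <- rep(1, length(preds))
  pvals[!constant] <- .assoc_pvals(y, preds[!constant], n_perm, seed)
  k <- sum(!constant)
  p_adj <- pmin(1, pvals * k)
  if (min(p_adj) > alpha) return(NULL)
  best <- which.min(p_adj)  # first index wins ties: declaration order
  x <- preds[[best]]
  split <- if (is.numeric(x)) .best_numeric_split(x, y, minbucket)
  else .best_categorical_split(x, y, minbucket)
  if (is.null(split)) return(NULL)
  c(list(variable = predictors[best], p_adjusted = p_adj[best]), split)
}

#' Fit a conditional inference tree for colony size
#'
#' Recursive significance-based binary partitioning of colony size on
#' terrain and geology predictors: at each node, predictors are tested for
#' association with the response by Monte-Carlo permutation tests,
#' Bonferroni-adjusted; the node splits on the most significant predictor
#' only if its adjusted p-value is below \code{alpha}, so no pruning is
#' needed. Categorical predictors (rock type) are split by exhaustive
#' level-subset search.
#'
#' @param records data.frame with the response and predictor columns.
#' @param response response column name (default \code{"colony_size"}).
#' @param predictors predictor column names (default: all other columns).
#' @param alpha split significance level (default 0.05).
#' @param minsplit minimum records in a node to attempt a split (default 20).
#' @param minbucket minimum records in a child (default 7).
#' @param n_perm Monte-Carlo permutations per test (default 9999).
#' @param seed integer seed; the tree is deterministic given it.
#' @return object of class \code{cit_tree}.
#' @export
cit_fit <- function(records, response = "colony_size",
                    predictors = setdiff(names(records), response),
                    alpha = 0.05, minsplit = 20L, minbucket = 7L,
                    n_perm = 9999, seed = 1L) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("empty input")
  if (!response %in% names(records)) stop("response column not found")
  for (p in predictors) {
    if (is.character(records[[p]])) records[[p]] <- factor(records[[p]])
  }
  next_id <- 0L
  build <- function(rows) {
    next_id <<- next_id + 1L
    id <- next_id
    node <- list(node_id = id, n = length(rows),
                 node_mean = mean(records[[response]][rows]),
                 split_variable = NULL, p_adjusted = NA_real_,
                 threshold = NULL, levels = NULL,
                 left = NULL, right = NULL)
    if (length(rows) >= minsplit) {
      sp <- select_split(records[rows, , drop = FALSE], response,
                         predictors, alpha = alpha, n_perm = n_perm,
                         seed = seed + id * 101L, minbucket = minbucket)
      if (!is.null(sp)) {
        x <- records[[sp$variable]][rows]
        goes_left <- if (!is.null(sp$threshold)) x <= sp$threshold
        else x %in% sp$levels
        node$split_variable <- sp$variable
        node$p_adjusted <- sp$p_adjusted
        node$threshold <- sp$threshold
        node$levels <- sp$levels
        node$left <- build(rows[goes_left])
        node$right <- build(rows[!goes_left])
      }
    }
    node
  }
  root <- build(seq_len(nrow(records)))
  structure(list(root = root, response = response, predictors = predictors,
                 alpha = alpha, n = nrow(records), seed = seed),
            class = "cit_tree")
}

#' @export
print.cit_tree <- function(x, ...) {
  cat(sprintf("conditional inference tree: %d records, alpha = %g\n",
              x$n, x$alpha))
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split_variable)) {
      cat(sprintf("%s[%d] terminal: n = %d, mean = %.1f\n",
                  pad, node$node_id, node$n, node$node_mean))
    } else {
      rule <- if (!is.null(node$threshold))
        sprintf("%s <= %.4g", node$split_variable, node$threshold)
      else sprintf("%s in {%s}", node$split_variable,
                   paste(node$levels, collapse = ", "))
      cat(sprintf("%s[%d] %s (p_adj = %.4g, n = %d)\n",
                  pad, node$node_id, rule, node$p_adjusted, node$n))
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  rec(x$root, 0)
  invisible(x)
}

# All terminal nodes of a tree, in node_id order.
cit_terminal_nodes <- function(tree) {
  out <- list()
  rec <- function(node) {
    if (is.null(node$split_variable)) out[[length(out) + 1]] <<- node
    else { rec(node$left); rec(node$right) }
  }
  rec(tree$root)
  out
}

#' Tree depth (number of split levels)
#' @param tree a \code{\link{cit_fit}} result.
#' @return 0 for a single-node tree.
#' @export
cit_depth <- function(tree) {
  rec <- function(node) {
    if (is.null(node$split_variable)) 0L
    else 1L + max(rec(node$left), rec(node$right))
  }
  rec(tree$root)
}

#' Predict colony size from a conditional inference tree
#'
#' Routes each record through the split rules to a terminal node and
#' returns the node mean and node id.
#'
#' @param tree a \code{\link{cit_fit}} result.
#' @param newdata data.frame with the predictors used by the tree.
#' @return data.frame with \code{predicted} (terminal node mean) and
#'   \code{node_id}.
#' @export
cit_predict <- function(tree, newdata) {
  newdata <- as.data.frame(newdata)
  route <- function(node, row) {
    if (is.null(node$split_variable)) return(node)
    x <- row[[node$split_variable]]
    if (is.null(x) || length(x) == 0 || is.na(x))
      stop("missing predictor value for ", node$split_variable,
           " (no surrogate splits)")
    left <- if (!is.null(node$threshold)) x <= node$threshold
    else as.character(x) %in% node$levels
    route(if (left) node$left else node$right, row)
  }
  res <- lapply(seq_len(nrow(newdata)), function(i)
    route(tree$root, newdata[i, , drop = FALSE]))
  data.frame(predicted = vapply(res, function(n) n$node_mean, numeric(1)),
             node_id = vapply(res, function(n) n$node_id, integer(1)))
}
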