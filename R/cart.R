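#' Gini impurity of a label multiset
#'
#' \eqn{1 - \sum_k p_k^2} over the observed class proportions: 0 for a pure
#' node, 0.5 for a balanced two-class node.
#'
#' @param labels non-empty vector of class labels.
#' @return impurity in [0, 1).
#' @examples
#' gini(c("a", "a", "b", "b"))  # 0.5
#' @export
gini <- function(labels) {
  if (length(labels) == 0) stop("gini of an empty label set is undefined")
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

giniFromCounts <- function(counts) {
  n <- sum(counts)
  1 - sum((counts / n)^2)
}

#' Exhaustive best binary split
#'
#' Searches every candidate threshold (midpoints between consecutive sorted
#' distinct values) of every candidate variable and returns the split that
#' maximizes the weighted Gini impurity decrease. Ties are broken by
#' variable declaration order, then by the lower threshold. Splits are of
#' the form \code{x <= threshold} (left) vs \code{x > threshold} (right).
#'
#' @param x data.frame of numeric predictors.
#' @param y vector of class labels, same length as \code{nrow(x)}.
#' @param vars candidate variables (default: all columns of \code{x}).
#' @param minLeaf smallest admissible child size.
#' @return a list \code{(var, threshold, decrease)}, or NULL when no valid
#'   split exists (pure node, or no threshold separates the data).
#' @examples
#' bestSplit(data.frame(x = c(1, 2, 10, 11)), c("A", "A", "B", "B"))
#' @export
bestSplit <- function(x, y, vars = names(x), minLeaf = 1) {
  n <- length(y)
  if (n < 2 || length(unique(y)) < 2) return(NULL)
  classes <- sort(unique(as.character(y)))
  g0 <- giniFromCounts(table(factor(y, levels = classes)))
  best <- NULL
  for (v in vars) {
    xv <- x[[v]]
    ord <- order(xv)
    xs <- xv[ord]
    ys <- as.character(y)[ord]
    cum <- vapply(classes, function(cl) cumsum(ys == cl),
                  numeric(n))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    tot <- cum[n, ]
    i <- which(xs[-n] < xs[-1])            # valid split positions
    i <- i[i >= minLeaf & (n - i) >= minLeaf]
    if (!length(i)) next
    nl <- i; nr <- n - i
    sl <- rowSums(cum[i, , drop = FALSE]^2)
    sr <- rowSums((rep(tot, each = length(i)) -
                   cum[i, , drop = FALSE])^2)
    wimp <- (nl * (1 - sl / nl^2) + nr * (1 - sr / nr^2)) / n
    dec <- g0 - wimp
    k <- which(dec >= max(dec) - 1e-12)[1]  # lower threshold on ties
    cand <- list(var = v, threshold = (xs[i[k]] + xs[i[k] + 1]) / 2,
                 decrease = dec[k])
    if (is.null(best) || cand$decrease > best$decrease + 1e-12)
      best <- cand                           # declaration order on ties
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

nodeCounts <- function(y, classes) {
  as.integer(table(factor(y, levels = classes)))
}

majorityClass <- function(counts, classes) {
  classes[which.max(counts)]                 # first class on ties
}

#' Grow a classification tree (CART)
#'
#' Binary recursive partitioning with Gini impurity splits, grown until
#' node purity, the minimum leaf size or the maximum depth is reached.
#' Deterministic: the split search and all tie-breaks are order-independent
#' given the data. Defaults (\code{minLeaf = 5}, \code{maxDepth = 10}) are
#' chosen so trees expressing the three-rule floodplain partition — which
#' needs depth up to eight on the soil branch — remain reachable.
#'
#' @param x data.frame of numeric predictors (ordinal soil classes are
#'   split as numeric).
#' @param y class labels, length \code{nrow(x)}.
#' @param minLeaf minimum samples per leaf.
#' @param maxDepth maximum tree depth (root = depth 0).
#' @return an object of class \code{palmCART} with the fitted tree;
#'   supports [predict.palmCART()], [extractRules()], [pruneTreeCV()].
#' @export
growTree <- function(x, y, minLeaf = 5, maxDepth = 10) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  y <- as.character(y)
  classes <- sort(unique(y))
  build <- function(idx, depth) {
    counts <- nodeCounts(y[idx], classes)
    node <- list(n = length(idx), counts = counts,
                 class = majorityClass(counts, classes), depth = depth,
                 leaf = TRUE)
    if (sum(counts > 0) < 2 || depth >= maxDepth ||
        length(idx) < 2 * minLeaf)
      return(node)
    s <- bestSplit(x[idx, , drop = FALSE], y[idx], minLeaf = minLeaf)
    if (is.null(s)) return(node)
    go <- x[[s$var]][idx] <= s$threshold
    node$leaf <- FALSE
    node$var <- s$var
    node$threshold <- s$threshold
    node$left <- build(idx[go], depth + 1)
    node$right <- build(idx[!go], depth + 1)
    node
  }
  structure(list(root = build(seq_along(y), 0), vars = names(x),
                 classes = classes, n = length(y), minLeaf = minLeaf,
                 maxDepth = maxDepth),
            class = "palmCART")
}

#' @export
print.palmCART <- function(x, ...) {
  cat(sprintf("palmCART tree: %d leaves, %d training samples, classes: %s\n",
              countLeaves(x$root), x$n, paste(x$classes, collapse = ", ")))
  if (!is.null(x$cv))
    cat(sprintf("  CV-pruned: alpha = %.4g, CV accuracy = %.3f\n",
                x$cv$alpha, x$cv$accuracy))
  invisible(x)
}

countLeaves <- function(node) {
  if (node$leaf) 1L else countLeaves(node$left) + countLeaves(node$right)
}

#' Predict classes from a fitted tree
#'
#' @param object a \code{palmCART} tree.
#' @param newdata data.frame containing the tree's predictor columns.
#' @param ... ignored.
#' @return character vector of predicted class labels.
#' @export
predict.palmCART <- function(object, newdata, ...) {
  out <- character(nrow(newdata))
  walk <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (node$leaf) {
      out[idx] <<- node$class
      return(invisible(NULL))
    }
    go <- newdata[[node$var]][idx] <= node$threshold
    walk(node$left, idx[go])
    walk(node$right, idx[!go])
  }
  walk(object$root, seq_len(nrow(newdata)))
  out
}

# misclassification count of a node treated as a leaf
leafError <- function(node) node$n - max(node$counts)

# bottom-up weakest-link collapse: prune every internal node whose
# per-leaf cost-complexity improvement g(t) <= alpha (g normalised by the
# training size so alpha is on the error-rate scale)
pruneAtAlpha <- function(node, alpha, nTotal) {
  if (node$leaf) return(node)
  node$left <- pruneAtAlpha(node$left, alpha, nTotal)
  node$right <- pruneAtAlpha(node$right, alpha, nTotal)
  sub <- subtreeStats(node)
  g <- (leafError(node) - sub$err) / nTotal / (sub$leaves - 1)
  if (g <= alpha + 1e-12) {
    node$leaf <- TRUE
    node[c("var", "threshold", "left", "right")] <- NULL
  }
  node
}

subtreeStats <- function(node) {
  if (node$leaf) return(list(err = leafError(node), leaves = 1L))
  l <- subtreeStats(node$left); r <- subtreeStats(node$right)
  list(err = l$err + r$err, leaves = l$leaves + r$leaves)
}

# increasing sequence of critical cost-complexity values of a tree
alphaSequence <- function(root, nTotal) {
  alphas <- numeric(0)
  repeat {
    gs <- numeric(0)
    collect <- function(node) {
      if (node$leaf) return(invisible(NULL))
      sub <- subtreeStats(node)
      gs <<- c(gs, (leafError(node) - sub$err) / nTotal / (sub$leaves - 1))
      collect(node$left); collect(node$right)
    }
    collect(root)
    if (!length(gs)) break
    a <- min(gs)
    alphas <- c(alphas, a)
    root <- pruneAtAlpha(root, a, nTotal)
  }
  sort(unique(alphas))
}

#' Cost-complexity pruning with 10-fold cross-validation
#'
#' Computes the tree's cost-complexity sequence, estimates the
#' misclassification rate of each complexity value by stratified k-fold
#' cross-validation (re-growing the tree on each training fold), selects
#' the complexity by the one-standard-error rule (the most heavily pruned
#' tree whose CV error is within one SE of the minimum), and returns the
#' full tree pruned at that complexity. Fold assignment is stratified by
#' class and driven entirely by \code{seed}, so the result is
#' deterministic.
#'
#' @param tree a \code{palmCART} from [growTree()].
#' @param x,y the training data the tree was grown on.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return the pruned \code{palmCART}; its \code{$cv} element records the
#'   chosen alpha, the CV accuracy at that alpha and the full CV profile.
#' @export
pruneTreeCV <- function(tree, x, y, folds = 10, seed = 1) {
  stopifnot(folds >= 2)
  y <- as.character(y)
  n <- length(y)
  alphas <- alphaSequence(tree$root, tree$n)
  if (!length(alphas)) {                  # already a single leaf
    tree$cv <- list(alpha = 0, accuracy = 1 - leafError(tree$root) / n,
                    profile = NULL)
    return(tree)
  }
  # representative alpha for each interval between critical values
  cand <- c(0, alphas)
  reps <- c(0, sqrt(cand[-1] * cand[-length(cand)]),
            alphas[length(alphas)] * 2)
  reps <- sort(unique(reps))

  fold <- integer(n)
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  miss <- numeric(length(reps))
  for (f in seq_len(folds)) {
    tr <- fold != f
    ft <- growTree(x[tr, , drop = FALSE], y[tr],
                   minLeaf = tree$minLeaf, maxDepth = tree$maxDepth)
    for (k in seq_along(reps)) {
      pr <- ft
      pr$root <- pruneAtAlpha(pr$root, reps[k], pr$n)
      pred <- predict(pr, x[!tr, , drop = FALSE])
      miss[k] <- miss[k] + sum(pred != y[!tr])
    }
  }
  cvErr <- miss / n
  se <- sqrt(cvErr * (1 - cvErr) / n)
  kmin <- which.min(cvErr)
  chosen <- max(which(cvErr <= cvErr[kmin] + se[kmin]))  # 1-SE rule
  tree$root <- pruneAtAlpha(tree$root, reps[chosen], tree$n)
  tree$cv <- list(alpha = reps[chosen], accuracy = 1 - cvErr[chosen],
                  profile = data.frame(alpha = reps, cvError = cvErr,
                                       se = se))
  tree
}

#' Extract interval rules from a fitted tree
#'
#' Reads the tree's leaves of the minority (non-default) class back into an
#' explicit \code{RuleSet}: one rule per such leaf, as a conjunction of
#' interval conditions accumulated along the root-to-leaf path; the default
#' class is the majority class at the root. Soil, an ordinal predictor
#' split as numeric, is reported as the matched set of class codes rather
#' than an interval. The extracted rules reproduce the tree's predictions
#' exactly on every input.
#'
#' @param tree a \code{palmCART}.
#' @return a \code{RuleSet}.
#' @export
extractRules <- function(tree) {
  default <- tree$root$class
  rules <- list()
  descend <- function(node, lower, upper) {
    if (node$leaf) {
      if (node$class != default) {
        conds <- list()
        for (v in tree$vars) {
          if (v == "soil") {
            codes <- 1:4
            codes <- codes[codes > lower[[v]] & codes <= upper[[v]]]
            if (length(codes) < 4)
              conds[[length(conds) + 1]] <-
                list(var = v, op = "in", value = codes)
          } else {
            if (is.finite(lower[[v]]))
              conds[[length(conds) + 1]] <-
                list(var = v, op = "gt", value = lower[[v]])
            if (is.finite(upper[[v]]))
              conds[[length(conds) + 1]] <-
                list(var = v, op = "le", value = upper[[v]])
          }
        }
        rules[[length(rules) + 1]] <<- list(class = node$class,
                                            conditions = conds)
      }
      return(invisible(NULL))
    }
    ul <- upper; ul[[node$var]] <- min(upper[[node$var]], node$threshold)
    descend(node$left, lower, ul)
    ll <- lower; ll[[node$var]] <- max(lower[[node$var]], node$threshold)
    descend(node$right, ll, upper)
  }
  inf <- stats::setNames(as.list(rep(-Inf, length(tree$vars))), tree$vars)
  sup <- stats::setNames(as.list(rep(Inf, length(tree$vars))), tree$vars)
  descend(tree$root, inf, sup)
  newRuleset(rules, default = default)
}

#' Collect the split thresholds of a tree by variable
#'
#' @param tree a \code{palmCART}.
#' @return named list of numeric threshold vectors, one per split variable.
#' @export
treeThresholds <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (node$leaf) return(invisible(NULL))
    out[[node$var]] <<- c(out[[node$var]], node$threshold)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  out
}
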