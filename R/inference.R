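#' Response transformations used by the comparison models
#'
#' Three transforms: `log` (natural log); `logit_capped`, the logit of
#' `x / cap` for responses with a known ceiling (locus counts, with a
#' default assumed maximum of 30,000 loci per library); and `logit_offset`,
#' `logit(x + offset)` for proportions that can be exactly zero (default
#' offset 0.001).
#'
#' @param x numeric vector.
#' @param kind `"log"`, `"logit_capped"` or `"logit_offset"`.
#' @param cap ceiling for `logit_capped` (default 30000).
#' @param offset offset for `logit_offset` (default 0.001).
#' @return transformed numeric vector.
#' @export
transform_response <- function(x, kind = c("log", "logit_capped",
                                           "logit_offset"),
                               cap = 30000, offset = 0.001) {
  kind <- match.arg(kind)
  stopifnot(cap > 0, offset > 0)
  logit <- function(q) log(q / (1 - q))
  switch(kind,
    log = {
      if (any(x <= 0)) .stopf("log transform needs x > 0 (got %g)", min(x))
      log(x)
    },
    logit_capped = {
      if (any(x <= 0 | x >= cap))
        .stopf("logit_capped needs 0 < x < cap = %g (got %g)", cap,
               x[which(x <= 0 | x >= cap)[1L]])
      logit(x / cap)
    },
    logit_offset = {
      if (any(x < 0 | x > 1))
        .stopf("logit_offset needs 0 <= x <= 1 (got %g)",
               x[which(x < 0 | x > 1)[1L]])
      logit(x + offset)
    })
}

# fixed-effect terms that may be dropped: those not marginal to any retained
# higher-order term
.eliminable_terms <- function(formula_fixed) {
  tt <- terms(formula_fixed)
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0L) return(character(0))
  vars <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
  keep <- vapply(seq_along(labels), function(i) {
    !any(vapply(seq_along(labels), function(j) {
      j != i && all(vars[[i]] %in% vars[[j]])
    }, logical(1)))
  }, logical(1))
  labels[keep]
}

.fixed_formula <- function(formula) {
  lme4::nobars(formula)
}

#' Linear mixed model with stepwise backward elimination
#'
#' Fits a REML linear mixed model (random intercepts given in the formula
#' with `(1 | group)` syntax) and simplifies it by backward elimination:
#' at each step the least-significant eliminable fixed effect (interactions
#' before their main effects) whose F-test p-value exceeds `alpha` is
#' dropped and the model refit, until every remaining eliminable term is
#' significant.  F-tests use Satterthwaite denominator degrees of freedom;
#' a formula without random effects falls back to ordinary least squares
#' with marginal F-tests (`drop1`).
#'
#' @param formula model formula, e.g.
#'   `y ~ log(n_reads) * method + (1 | pool) + (1 | taxon)`.
#' @param data `data.frame` with all model variables (e.g. from
#'   [library_stats()]).
#' @param alpha significance level for elimination (default 0.05); `alpha =
#'   1` keeps the full model.
#' @param reml fit by REML (default `TRUE`).
#' @return object of class `rad_mixed`: final `fit`, `formula`, elimination
#'   `trail` (`data.frame`: step, dropped, p), term table `anova`,
#'   `coefficients`, and `singular` flag.
#' @export
fit_mixed <- function(formula, data, alpha = 0.05, reml = TRUE) {
  has_ranef <- length(lme4::findbars(formula)) > 0L
  trail <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  refit <- function(f) {
    if (has_ranef) {
      suppressMessages(lmerTest::lmer(f, data = data, REML = reml))
    } else {
      lm(f, data = data)
    }
  }
  term_pvals <- function(fit, f) {
    elim <- .eliminable_terms(.fixed_formula(f))
    if (length(elim) == 0L) return(numeric(0))
    if (has_ranef) {
      an <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
      p <- an[elim, "Pr(>F)"]
    } else {
      an <- drop1(fit, test = "F")
      p <- an[elim, "Pr(>F)"]
    }
    setNames(p, elim)
  }
  f <- formula
  fit <- refit(f)
  step_i <- 0L
  repeat {
    p <- term_pvals(fit, f)
    p <- p[!is.na(p)]
    if (length(p) == 0L || max(p) <= alpha) break
    drop_term <- names(p)[which.max(p)]
    step_i <- step_i + 1L
    trail <- rbind(trail, data.frame(step = step_i, dropped = drop_term,
                                     p = unname(max(p)),
                                     stringsAsFactors = FALSE))
    f <- update(as.formula(f), paste(". ~ . -", drop_term))
    environment(f) <- environment(formula)
    fit <- refit(f)
  }
  singular <- has_ranef && lme4::isSingular(fit)
  if (singular)
    .warnf("final mixed-model fit is singular")
  an_final <- if (has_ranef) {
    suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  } else {
    tryCatch(drop1(fit, test = "F"), error = function(e) NULL)
  }
  coefs <- if (has_ranef) lme4::fixef(fit) else coef(fit)
  structure(list(fit = fit, formula = f, trail = trail, anova = an_final,
                 coefficients = coefs, singular = singular, alpha = alpha),
            class = "rad_mixed")
}

#' @export
print.rad_mixed <- function(x, ...) {
  cat("Linear", if (length(lme4::findbars(x$formula)) > 0L) "mixed", "model",
      "after backward elimination\n")
  cat("  formula:", deparse1(x$formula), "\n")
  if (nrow(x$trail) > 0L) {
    cat("  dropped:", paste(sprintf("%s (p=%.3g)", x$trail$dropped,
                                    x$trail$p), collapse = ", "), "\n")
  } else {
    cat("  dropped: none\n")
  }
  cat("  fixed effects:\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.rad_mixed <- function(object, ...) object$coefficients

#' @export
summary.rad_mixed <- function(object, ...) summary(object$fit, ...)

#' Multivariate distance matrix regression (MDMR)
#'
#' Regression of a dissimilarity matrix on a table of predictors.  The
#' squared dissimilarities are Gower-centered into an inner-product matrix
#' `G = -1/2 C A C` (`A_ij = d_ij^2`, `C` the centering matrix); the design
#' hat matrix `H` (with intercept) yields the omnibus pseudo-R-squared
#' `tr(HGH) / tr(G)`.  Per-predictor effects are marginal (drop-one):
#' `(tr(HGH) - tr(H_-j G H_-j)) / tr(G)` where `H_-j` omits that predictor's
#' columns.  Negative eigenvalue mass of `G` (non-Euclidean
#' dissimilarities) is retained in the traces.  p-values come from jointly
#' permuting rows and columns of the dissimilarity matrix:
#' `p = (1 + #(perm >= observed)) / (1 + n_permutations)`.
#'
#' @param dm a [rad_dist()], `dist`, or complete symmetric matrix.
#' @param predictors `data.frame` of predictors, rows aligned to the
#'   distance labels (categorical columns are expanded to indicator
#'   contrasts).
#' @param n_permutations number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return object of class `mdmr`: `data.frame` `effects` (predictor,
#'   pseudo_r2, p) with the omnibus effect first, plus `n`,
#'   `n_permutations`, `seed`.
#' @export
mdmr <- function(dm, predictors, n_permutations = 999L, seed = NULL) {
  m <- if (inherits(dm, "rad_dist")) dm$values else as.matrix(dm)
  n <- nrow(m)
  if (anyNA(m)) .stopf("mdmr needs a complete distance matrix")
  if (!is.null(rownames(m)) && !is.null(rownames(predictors)) &&
      all(rownames(m) %in% rownames(predictors)))
    predictors <- predictors[rownames(m), , drop = FALSE]
  if (nrow(predictors) != n)
    .stopf("predictors (%d rows) do not match distance labels (%d)",
           nrow(predictors), n)
  pred_df <- as.data.frame(predictors)
  for (j in seq_along(pred_df))
    if (is.character(pred_df[[j]])) pred_df[[j]] <- factor(pred_df[[j]])
  X <- model.matrix(~ ., data = pred_df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    .stopf("rank-deficient design; aliased columns: %s",
           paste(aliased, collapse = ", "))
  }
  groups <- attr(X, "assign")
  pred_names <- colnames(pred_df)
  A <- m^2
  rm_ <- rowMeans(A)
  G <- -0.5 * (A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A))
  trG <- sum(diag(G))
  if (trG <= 0) .stopf("degenerate dissimilarity matrix (tr(G) <= 0)")
  hat_of <- function(Xs) {
    Xs %*% solve(crossprod(Xs), t(Xs))
  }
  H <- hat_of(X)
  H_minus <- lapply(seq_along(pred_names), function(j) {
    hat_of(X[, groups != j, drop = FALSE])
  })
  stat_all <- function(Gp) {
    full <- sum(H * Gp)
    c(full, vapply(H_minus, function(Hm) full - sum(Hm * Gp), numeric(1))) / trG
  }
  obs <- stat_all(G)
  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(obs))
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    exceed <- exceed + (stat_all(G[p, p]) >= obs - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_permutations)
  effects <- data.frame(
    predictor = c("(omnibus)", pred_names),
    pseudo_r2 = obs, p = pvals, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(effects = effects, n = n,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "mdmr")
}

#' @export
print.mdmr <- function(x, ...) {
  cat(sprintf("Multivariate distance matrix regression (n = %d, %d permutations)\n",
              x$n, x$n_permutations))
  eff <- x$effects
  eff$pseudo_r2 <- round(eff$pseudo_r2, 4)
  print(eff, row.names = FALSE)
  invisible(x)
}
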