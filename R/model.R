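# Group comparison, logistic risk models, ROC/AUC with DeLong variance,
# likelihood ratios at fixed specificity, and LOOCV evaluation.

#' Mann-Whitney U comparison of two groups
#'
#' Tie-corrected normal-approximation two-sided p-value, plus the AUC
#' equivalent `U / (nA nB)` — identical to the empirical ROC area when
#' group B is taken as the positive class.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return tibble: `U`, `p`, `auc_equivalent`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  # U counts pairs where b > a (+0.5 per tie), so U/(na nb) is the AUC
  # of a score that ranks group b as the positive class
  U <- sum(r[na + seq_len(nb)]) - nb * (nb + 1) / 2
  auc_b <- U / (na * nb)
  N <- na + nb
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (U - na * nb / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(U = U, p = min(p, 1), auc_equivalent = auc_b)
}

#' Closed-form AUC for two normal score distributions
#'
#' \deqn{AUC = \Phi\left(\frac{|\mu_b - \mu_a|}{\sqrt{\sigma_a^2 +
#'   \sigma_b^2}}\right)}
#' Links printed group summary statistics (mean, SD per group) to the
#' AUC a univariate score with those distributions would achieve.
#'
#' @param mean_a,sd_a,mean_b,sd_b group means and SDs (`sd > 0`).
#' @return scalar AUC in \[0.5, 1\].
#' @export
#' @examples
#' binormal_auc(25.0, 3.9, 29.0, 4.6) # about 0.746
binormal_auc <- function(mean_a, sd_a, mean_b, sd_b) {
  check_number(sd_a, "sd_a", lower = 0, strict_lower = TRUE)
  check_number(sd_b, "sd_b", lower = 0, strict_lower = TRUE)
  stats::pnorm(abs(mean_b - mean_a) / sqrt(sd_a^2 + sd_b^2))
}

# DeLong placements: for each positive, the fraction of negatives it
# beats (ties count half), and vice versa.
.delong_placements <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x)
    (sum(x > ys) + 0.5 * sum(x == ys)) / n, numeric(1))
  v01 <- vapply(ys, function(y)
    (sum(xs > y) + 0.5 * sum(xs == y)) / m, numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Empirical ROC curve with DeLong standard error and CI
#'
#' The ROC is swept over all observed score thresholds (predicted
#' positive when score >= threshold); the AUC equals the Mann-Whitney
#' U statistic divided by the number of case-control pairs, and its
#' variance comes from the DeLong structural components. The Wald CI is
#' truncated to \[0, 1\].
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels 0/1 outcome, both classes present.
#' @param conf_level confidence level (0.95 gives z = 1.96; the
#'   5th-95th percentile span of some reports corresponds to 0.90).
#' @return object of class `roc_delong`: list with `curve` (tibble of
#'   `threshold`, `fpr`, `tpr`, `specificity`, `sensitivity`), `auc`,
#'   `se`, `ci`, and counts.
#' @export
roc_with_delong <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  pl <- .delong_placements(scores, labels)
  s10 <- if (pl$m > 1) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1) stats::var(pl$v01) else 0
  se <- sqrt(s10 / pl$m + s01 / pl$n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(xs >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(ys >= t), numeric(1))
  )
  curve$sensitivity <- curve$tpr
  curve$specificity <- 1 - curve$fpr
  out <- list(curve = curve, auc = pl$auc, se = se, ci = ci,
              n_cases = pl$m, n_controls = pl$n,
              conf_level = conf_level)
  class(out) <- "roc_delong"
  out
}

#' @export
print.roc_delong <- function(x, ...) {
  cat(sprintf("<roc_delong> AUC %.3f (%.0f%% CI %.3f, %.3f), SE %.4f; %d cases / %d controls\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2], x$se,
              x$n_cases, x$n_controls))
  invisible(x)
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of two models scored on the same subjects; the
#' covariance between the two AUCs is estimated from the paired
#' structural components.
#'
#' @param scores_a,scores_b risk scores of the two models on identical
#'   subjects, in the same order.
#' @param labels shared 0/1 outcome.
#' @return tibble: `auc_a`, `auc_b`, `delta`, `z`, `p` (two-sided).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores and labels must cover the same subjects", call. = FALSE)
  labels <- as.integer(labels)
  pa <- .delong_placements(scores_a, labels)
  pb <- .delong_placements(scores_b, labels)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- (if (pa$m > 1) stats::var(d10) else 0) / pa$m +
    (if (pa$n > 1) stats::var(d01) else 0) / pa$n
  delta <- pa$auc - pb$auc
  if (v < 1e-14) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 z = z, p = p)
}

#' Positive likelihood ratio at a target specificity
#'
#' Picks the ROC operating point with the smallest specificity at or
#' above the target and reports `LR+ = sensitivity / (1 - target)`
#' together with the score threshold realizing it. With the target at
#' 75%, a perfect classifier gives LR+ = 1 / 0.25 = 4.
#'
#' @param roc a [roc_with_delong()] object.
#' @param specificity target specificity (default 0.75).
#' @return tibble: `lr_plus`, `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
lr_at_specificity <- function(roc, specificity = 0.75) {
  cv <- roc$curve[roc$curve$specificity >= specificity, ]
  cv <- cv[which.min(cv$specificity), ]
  denom <- 1 - specificity
  tibble::tibble(lr_plus = cv$sensitivity / denom,
                 threshold = cv$threshold,
                 sensitivity = cv$sensitivity,
                 specificity = cv$specificity)
}

# Firth-penalized logistic regression (Jeffreys prior): stabilizes the
# MLE under (quasi-)separation, which is routine in cohorts of n ~ 27
# with strong predictors.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome on one or
#' two predictors (with intercept). Predictors are z-scored internally
#' for numerical stability; ROC quantities are rank-invariant to this.
#' If the fit separates (non-finite or exploding coefficients, fitted
#' probabilities at 0/1), the model is refitted with Firth's penalized
#' likelihood and flagged.
#'
#' @param data data frame with the outcome and predictor columns.
#' @param outcome name of the 0/1 outcome column.
#' @param predictors character vector of 1-2 predictor column names.
#' @param lr_specificity specificity at which LR+ is reported.
#' @param conf_level CI level for the DeLong interval.
#' @return object of class `ivh_model`: coefficients (original scale),
#'   per-subject probabilities, `roc` ([roc_with_delong()]), `auc`,
#'   `ci`, `lr` row, and `method` (`"mle"` or `"firth"`). Has `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @export
fit_logistic <- function(data, outcome = "label", predictors,
                         lr_specificity = 0.75, conf_level = 0.95) {
  stopifnot(length(predictors) >= 1, length(predictors) <= 2)
  df <- tibble::as_tibble(data)
  y <- as.integer(df[[outcome]])
  if (min(table(y)) < 2)
    stop("need at least 2 subjects per class", call. = FALSE)
  Xraw <- as.matrix(df[predictors])
  if (anyNA(Xraw) || anyNA(y))
    stop("missing values in predictors or outcome", call. = FALSE)
  ctr <- colMeans(Xraw)
  scl <- apply(Xraw, 2, stats::sd)
  scl[scl == 0] <- 1
  Xz <- scale(Xraw, center = ctr, scale = scl)
  X <- cbind(`(Intercept)` = 1, Xz)
  method <- "mle"
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  beta <- fit$coefficients
  sep <- !fit$converged || any(!is.finite(beta)) ||
    max(abs(beta[-1])) > 15 ||
    any(fit$fitted.values > 1 - 1e-8 & y == 0) ||
    any(fit$fitted.values < 1e-8 & y == 1) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (sep) {
    method <- "firth"
    beta <- .firth_logistic(X, y)
  }
  prob <- stats::plogis(drop(X %*% beta))
  roc <- roc_with_delong(prob, y, conf_level = conf_level)
  # map coefficients back to the original predictor scale
  b_orig <- beta[-1] / scl
  b0_orig <- beta[1] - sum(beta[-1] * ctr / scl)
  out <- list(
    predictors = predictors,
    coefficients = c(`(Intercept)` = unname(b0_orig),
                     stats::setNames(b_orig, predictors)),
    probabilities = prob,
    labels = y,
    roc = roc,
    auc = roc$auc, ci = roc$ci, se = roc$se,
    lr = lr_at_specificity(roc, lr_specificity),
    method = method,
    scaling = list(center = ctr, scale = scl),
    data = df[c(outcome, predictors)],
    outcome = outcome
  )
  class(out) <- "ivh_model"
  out
}

#' @export
print.ivh_model <- function(x, ...) {
  cat(sprintf("<ivh_model> %s ~ %s  [%s]\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$method))
  cat(sprintf("  AUC %.3f (CI %.3f, %.3f); LR+ %.2f at spec %.2f\n",
              x$auc, x$ci[1], x$ci[2], x$lr$lr_plus, x$lr$specificity))
  if (!is.null(x$loocv))
    cat(sprintf("  LOOCV AUC %.3f (CI %.3f, %.3f)\n",
                x$loocv$auc, x$loocv$ci[1], x$loocv$ci[2]))
  invisible(x)
}

#' Predict IVH probability for new subjects
#'
#' @param object an `ivh_model`.
#' @param newdata data frame containing the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.ivh_model <- function(object, newdata, ...) {
  X <- as.matrix(tibble::as_tibble(newdata)[object$predictors])
  eta <- object$coefficients[1] +
    drop(X %*% object$coefficients[-1])
  stats::plogis(eta)
}

#' Screen candidate predictor pairs for collinearity
#'
#' A pair is excluded when its Spearman rank correlation is significant
#' at `alpha` (two-sided), mirroring the exclusion of significantly
#' correlated predictor combinations from bivariate models. Pearson is
#' available for sensitivity checks.
#'
#' @param pairs data frame (or 2-column matrix) of candidate predictor
#'   name pairs.
#' @param features per-subject feature tibble.
#' @param alpha significance level for exclusion.
#' @param method correlation type.
#' @return tibble: `feature_1`, `feature_2`, `rho`, `p`, `allowed`.
#' @export
collinearity_screen <- function(pairs, features, alpha = 0.05,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pairs <- as.data.frame(pairs)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    f1 <- as.character(pairs[i, 1]); f2 <- as.character(pairs[i, 2])
    ct <- suppressWarnings(
      stats::cor.test(features[[f1]], features[[f2]], method = method,
                      exact = FALSE)
    )
    tibble::tibble(feature_1 = f1, feature_2 = f2,
                   rho = unname(ct$estimate), p = ct$p.value,
                   allowed = ct$p.value >= alpha)
  })
}

#' Leave-one-out cross-validation of a logistic risk model
#'
#' Each subject is held out in turn, the model is refitted on the
#' remaining n - 1, and the held-out predicted probability recorded;
#' the compiled probabilities form a single pooled ROC evaluated with
#' the DeLong machinery. A training fold that loses one class entirely
#' is flagged and its probability taken from an intercept-only fit.
#'
#' @inheritParams fit_logistic
#' @return an `ivh_model` (apparent fit on all data) whose `loocv`
#'   element holds `probabilities`, `roc`, `auc`, `ci` and any flagged
#'   folds.
#' @export
loocv_evaluate <- function(data, outcome = "label", predictors,
                           lr_specificity = 0.75, conf_level = 0.95) {
  df <- tibble::as_tibble(data)
  n <- nrow(df)
  stopifnot(n >= 4)
  y <- as.integer(df[[outcome]])
  stopifnot(min(table(y)) >= 2)
  probs <- numeric(n)
  flagged <- integer()
  for (i in seq_len(n)) {
    train <- df[-i, ]
    if (length(unique(train[[outcome]])) < 2) {
      flagged <- c(flagged, i)
      probs[i] <- mean(as.integer(train[[outcome]]))
      next
    }
    m <- fit_logistic(train, outcome = outcome, predictors = predictors,
                      lr_specificity = lr_specificity,
                      conf_level = conf_level)
    probs[i] <- predict(m, df[i, ])
  }
  full <- fit_logistic(df, outcome = outcome, predictors = predictors,
                       lr_specificity = lr_specificity,
                       conf_level = conf_level)
  roc <- roc_with_delong(probs, y, conf_level = conf_level)
  full$loocv <- list(probabilities = probs, roc = roc, auc = roc$auc,
                     ci = roc$ci, flagged_folds = flagged)
  full
}
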