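#' Remove the spatial component from a SAR fit
#'
#' Builds the adjusted response used for hierarchical partitioning:
#' with `method = "whitened_residuals"` (default)
#' `y_adj = X beta + (I - lambda W)(y* - X beta)`, i.e. the fitted trend
#' plus the whitened residual, so the spatially dependent part
#' `lambda W u` of the error is removed while the independent innovation
#' is kept; with `method = "trend"` only the fitted trend `X beta` is
#' returned. When `lambda = 0` the default is exactly `y*`.
#'
#' @param fit a [fit_sar_error()] object.
#' @param method `"whitened_residuals"` or `"trend"`.
#' @return numeric vector of length `fit$n` with attribute `method`.
#' @export
despatialize <- function(fit, method = c("whitened_residuals", "trend")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "sar_fit"))
  out <- switch(method,
                whitened_residuals = fit$fitted_trend + fit$whitened_residuals,
                trend = fit$fitted_trend)
  structure(out, method = method)
}

# R2 of the least-squares fit of y on (intercept + X[, cols])
.r2 <- function(y, X, cols) {
  M <- cbind(1, X[, cols, drop = FALSE])
  rss <- sum(stats::lm.fit(M, y)$residuals^2)
  1 - rss / sum((y - mean(y))^2)
}

#' LMG (Shapley) decomposition of explained variance
#'
#' Partitions the full-model least-squares R2 among predictors as the
#' average, over all orderings of the predictors, of each predictor's
#' incremental R2 -- equivalently the Shapley value
#' `share(x) = sum over subsets S not containing x of
#' [R2(S + x) - R2(S)] * |S|! (p - |S| - 1)! / p!`. Exact enumeration,
#' so at most 10 predictors. Shares are non-negative up to numerical
#' error and sum exactly to the full-model R2. Protected terms (e.g. the
#' effort covariate) participate in the decomposition like any other
#' predictor but are reported separately and excluded from
#' `total_r2_excluding_protected`.
#'
#' @param y response vector (typically a [despatialize()]d response).
#' @param X predictor matrix (no intercept column; one is added to every
#'   subset fit).
#' @param protected character vector of protected column names.
#' @return object of class `lmg_partition`: `shares` (data.frame with
#'   `term`, `share` as an R2 fraction, `share_pct`, `protected`),
#'   `r2_full`, `total_r2_excluding_protected` (fraction).
#' @export
lmg_shares <- function(y, X, protected = character()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- X[, !apply(X, 2L, function(col) all(col == 1)), drop = FALSE]
  p <- ncol(X)
  if (p < 1L) stop_("no predictors")
  if (p > 10L) stop_("exact LMG enumeration limited to 10 predictors (got %d)", p)
  if (qr(cbind(1, X))$rank < p + 1L) {
    stop_("rank-deficient design; check columns: %s",
          paste(colnames(X), collapse = ", "))
  }
  bad <- setdiff(protected, colnames(X))
  if (length(bad)) stop_("protected term(s) not in design: %s",
                         paste(bad, collapse = ", "))
  n_sub <- 2L^p
  r2 <- numeric(n_sub) # indexed by bitmask + 1
  for (mask in seq_len(n_sub - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    r2[mask + 1L] <- .r2(y, X, cols)
  }
  wt <- function(s) exp(lfactorial(s) + lfactorial(p - s - 1L) - lfactorial(p))
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(n_sub - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      shares[j] <- shares[j] + wt(s) * (r2[bitwOr(mask, bit) + 1L] - r2[mask + 1L])
    }
  }
  is_prot <- colnames(X) %in% protected
  out <- data.frame(term = colnames(X), share = shares,
                    share_pct = 100 * shares, protected = is_prot)
  structure(list(shares = out, r2_full = r2[n_sub],
                 total_r2_excluding_protected = sum(shares[!is_prot])),
            class = "lmg_partition")
}

#' @export
print.lmg_partition <- function(x, ...) {
  cat(sprintf("LMG partition: full R2 = %.3f, total excl. protected = %.3f\n",
              x$r2_full, x$total_r2_excluding_protected))
  print(x$shares, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare habitat vs functional-diversity model types
#'
#' Assembles the per-response comparison table: for each fitted model type
#' the retained terms' coefficients and Z statistics, the LMG R2 share of
#' each predictor (percent), the SAR AIC and the total R2 excluding
#' protected terms; winner flags by lower AIC and by higher total R2 are
#' reported separately (they can disagree).
#'
#' @param fits list of entries, each a list with elements `response`
#'   (character), `model_type` (`"habitat"` or `"functional_diversity"`),
#'   `fit` (a [fit_sar_error()]) and `partition` (a [lmg_shares()]).
#'   Both model types must be present for every response.
#' @return object of class `model_comparison`: `table` (term-level rows:
#'   response, model_type, term, beta, z, r2_pct), `summary` (per
#'   response x model_type: aic, total_r2_pct, winner_aic, winner_r2).
#' @export
compare_model_types <- function(fits) {
  stopifnot(length(fits) >= 2L)
  meta <- data.frame(
    response = vapply(fits, `[[`, "", "response"),
    model_type = vapply(fits, `[[`, "", "model_type"))
  if (!all(meta$model_type %in% c("habitat", "functional_diversity")))
    stop_("model_type must be 'habitat' or 'functional_diversity'")
  for (resp in unique(meta$response)) {
    have <- meta$model_type[meta$response == resp]
    if (!all(c("habitat", "functional_diversity") %in% have))
      stop_("response '%s' lacks one model type", resp)
  }
  term_rows <- do.call(rbind, lapply(fits, function(f) {
    co <- f$fit$coefficients
    co <- co[co$term != "(Intercept)", , drop = FALSE]
    sh <- f$partition$shares
    data.frame(response = f$response, model_type = f$model_type,
               term = co$term, beta = co$beta, z = co$z,
               r2_pct = sh$share_pct[match(co$term, sh$term)])
  }))
  summ <- do.call(rbind, lapply(fits, function(f)
    data.frame(response = f$response, model_type = f$model_type,
               aic = f$fit$aic,
               total_r2_pct = 100 * f$partition$total_r2_excluding_protected)))
  summ$winner_aic <- FALSE
  summ$winner_r2 <- FALSE
  for (resp in unique(summ$response)) {
    i <- which(summ$response == resp)
    best_aic <- i[summ$aic[i] == min(summ$aic[i])]
    best_r2 <- i[summ$total_r2_pct[i] == max(summ$total_r2_pct[i])]
    summ$winner_aic[best_aic] <- TRUE
    summ$winner_r2[best_r2] <- TRUE
  }
  structure(list(table = term_rows, summary = summ),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (per response: habitat vs functional_diversity)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
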