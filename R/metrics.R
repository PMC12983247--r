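# Prediction metrics and the closed-form ridge baseline (the linear oracle
# used to demonstrate nonlinearity capture).

#' Prediction metrics for genomic prediction
#'
#' Computes R2, Pearson correlation (PCC), mean absolute error (MAE, trait
#' units), normalized mean square error (NMSE = MSE / Var(y)), relative root
#' mean square error (RRMSE = RMSE / mean(y)) and mean absolute percentage
#' error (MAPE, %, samples with `y = 0` excluded). Two R2 conventions are
#' exposed: `"pearson"` (default) is the squared Pearson correlation between
#' predicted and observed — the proportion of phenotypic variance explained
#' by the predictions, invariant to affine transforms of the predictions;
#' `"ss"` is the coefficient of determination `1 - SSres/SStot`, which is
#' not. When either vector is constant the PCC is undefined and reported as
#' 0 with a warning.
#'
#' @param y observed values (length >= 2, finite).
#' @param yhat predicted values, same length.
#' @param r2Method `"pearson"` or `"ss"`.
#' @return one-row `data.frame(R2, PCC, MAE, NMSE, RRMSE, MAPE)`.
#' @examples
#' computeMetrics(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5))
#' @export
computeMetrics <- function(y, yhat, r2Method = c("pearson", "ss")) {
  r2Method <- match.arg(r2Method)
  if (length(y) != length(yhat)) stopf("length mismatch")
  if (length(y) < 2L) stopf("need at least 2 observations")
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stopf("non-finite values in y or yhat")
  }
  pcc <- if (sd(y) == 0 || sd(yhat) == 0) {
    warnf("constant vector: PCC undefined, reported as 0")
    0
  } else {
    cor(y, yhat)
  }
  mse <- mean((y - yhat)^2)
  r2 <- if (r2Method == "pearson") pcc^2 else 1 - mse * length(y) /
    sum((y - mean(y))^2)
  nz <- y != 0
  mape <- if (any(nz)) mean(abs((y - yhat)[nz] / y[nz])) * 100 else NA_real_
  data.frame(
    R2 = r2, PCC = pcc, MAE = mean(abs(y - yhat)),
    NMSE = mse / var(y), RRMSE = sqrt(mse) / mean(y), MAPE = mape
  )
}

#' Closed-form ridge-regression baseline
#'
#' Ridge regression on the signed genotype codes with an unpenalised
#' intercept (markers and response centred on the training set), solved in
#' closed form through the singular value decomposition. With
#' `lambda = NULL` the penalty is chosen by generalised cross-validation
#' over a log-spaced grid. This is the linear oracle: its test R2 is the
#' additive benchmark a nonlinear model has to beat.
#'
#' @param Gtrain,Gtest training/test genotypes ([GenotypeData] or
#'   samples-x-markers matrices).
#' @param ytrain training phenotypes.
#' @param lambda ridge penalty (>= 0), or `NULL` for GCV selection.
#' @return predicted test values, with attributes `coefficients`,
#'   `intercept` and `lambda`.
#' @export
ridgeBaseline <- function(Gtrain, ytrain, Gtest, lambda = NULL) {
  X <- if (is(Gtrain, "GenotypeData")) genoMatrix(Gtrain) else
    as.matrix(Gtrain)
  Xt <- if (is(Gtest, "GenotypeData")) genoMatrix(Gtest) else
    as.matrix(Gtest)
  stopifnot(nrow(X) == length(ytrain), ncol(X) == ncol(Xt))
  if (!is.null(lambda) && lambda < 0) stopf("lambda must be >= 0")
  if (!is.null(lambda) && lambda == 0 && ncol(X) > nrow(X)) {
    stopf("singular system: lambda = 0 with more markers than samples")
  }
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  ym <- mean(ytrain)
  yc <- ytrain - ym
  sv <- svd(Xc)
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  if (is.null(lambda)) {
    grid <- 10^seq(-3, 5, length.out = 40)
    n <- nrow(X)
    gcv <- vapply(grid, function(l) {
      shrink <- d^2 / (d^2 + l)
      fit <- sv$u %*% (shrink * uty)
      df <- sum(shrink)
      n * sum((yc - fit)^2) / (n - df)^2
    }, numeric(1))
    lambda <- grid[which.min(gcv)]
  }
  if (lambda == 0 && any(d < max(d) * 1e-10)) {
    stopf("singular system at lambda = 0")
  }
  beta <- sv$v %*% (d / (d^2 + lambda) * uty)
  pred <- as.vector(sweep(Xt, 2, xm) %*% beta) + ym
  attr(pred, "coefficients") <- as.vector(beta)
  attr(pred, "intercept") <- ym - sum(xm * beta)
  attr(pred, "lambda") <- lambda
  pred
}
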