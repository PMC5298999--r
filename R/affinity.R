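# Dissociation free energies and k-nearest-neighbor affinity regression in
# (IVW-IPL, NIS_charged) space, with a constant null model and the
# d_i / sigma_i reliability diagnostics.

#' Convert a dissociation constant to dissociation free energy
#'
#' `-dG = -RT ln(Kd / c0)` at standard state `c0 = 1 M`, with
#' `R = 1.9872e-3 kcal / (mol K)`.
#'
#' @param Kd dissociation constant in mol/L (> 0)
#' @param T temperature in kelvin
#' @return `minus_dG` in kcal/mol
#' @export
kd_to_dG <- function(Kd, T = 298) {
  if (any(!is.finite(Kd)) || any(Kd <= 0)) stop("Kd must be positive")
  stopifnot(all(T > 0))
  -.R_KCAL * T * log(Kd)
}

#' Convert a free-energy error to a Kd fold-ratio
#'
#' @param err_kcal absolute error in kcal/mol
#' @param T temperature in kelvin
#' @return the corresponding multiplicative factor on Kd, `exp(err / RT)`
#' @export
dG_to_kd_ratio <- function(err_kcal, T = 298) {
  exp(err_kcal / (.R_KCAL * T))
}

#' Free-energy width of m orders of magnitude in Kd
#'
#' @param m number of orders of magnitude
#' @param T temperature in kelvin
#' @return `m * RT * ln 10` in kcal/mol (about 1.4 per order at 298 K)
#' @export
orders_threshold <- function(m, T = 298) {
  m * .R_KCAL * T * log(10)
}

#' Build an affinity table from Kd measurements
#'
#' @param df data frame with columns `complex_id`, `Kd` and optionally `T`
#'   (kelvin, default 298) and `is_ig_ag`
#' @return the data frame with a `minus_dG` column added
#' @export
affinity_table <- function(df) {
  stopifnot(all(c("complex_id", "Kd") %in% names(df)))
  if (is.null(df$T)) df$T <- 298
  df$minus_dG <- kd_to_dG(df$Kd, df$T)
  df
}

#' Fit a k-nearest-neighbor affinity regressor
#'
#' Stores the training point cloud in (IVW-IPL, NIS_charged) space, z-scored
#' by training statistics by default, with the `minus_dG` responses.
#'
#' @param training data frame with the feature and response columns
#' @param features feature column names
#' @param response response column name
#' @param k number of neighbors (must be < number of training points)
#' @param scaling `"zscore"` (default) or `"none"`
#' @return object of class `igvor_knn`
#' @export
fit_knn <- function(training, features = c("ivw_ipl", "nis_charged"),
                    response = "minus_dG", k = 10,
                    scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(all(c(features, response) %in% names(training)))
  X <- as.matrix(training[, features, drop = FALSE])
  y <- training[[response]]
  stopifnot(all(is.finite(X)), all(is.finite(y)))
  if (k > nrow(X)) stop("k cannot exceed the number of training points")
  if (k == nrow(X)) {
    warning("k equals the training size: predictions reduce to the null model",
            call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1")
  if (scaling == "zscore") {
    mu <- colMeans(X)
    sg <- apply(X, 2, sd)
    sg[sg == 0] <- 1
  } else {
    mu <- rep(0, ncol(X)); sg <- rep(1, ncol(X))
  }
  structure(list(
    X = sweep(sweep(X, 2, mu), 2, sg, "/"),
    y = y,
    ids = if (!is.null(training$complex_id)) as.character(training$complex_id)
          else as.character(seq_len(nrow(X))),
    k = k, features = features, response = response,
    scaling = scaling, center = mu, scale = sg
  ), class = "igvor_knn")
}

#' @export
#' @describeIn fit_knn Predict affinities with per-query diagnostics:
#'   `d_i` (mean scaled distance to the k neighbors), `sigma_i` (SD of the
#'   neighbors' responses) and their ratio; ties at the k-th distance are
#'   broken by stable training order.
#' @param object an `igvor_knn`
#' @param newdata data frame of query points (and optionally the response
#'   column, reported as `truth` with `abs_error`)
#' @param ... unused
predict.igvor_knn <- function(object, newdata, ...) {
  Q <- as.matrix(newdata[, object$features, drop = FALSE])
  Q <- sweep(sweep(Q, 2, object$center), 2, object$scale, "/")
  n <- nrow(Q)
  out <- data.frame(
    complex_id = if (!is.null(newdata$complex_id))
      as.character(newdata$complex_id) else as.character(seq_len(n)),
    predicted = numeric(n), d_i = numeric(n), sigma_i = numeric(n),
    ratio = numeric(n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(object$X) - Q[i, ])^2))
    nb <- order(d)[seq_len(object$k)] # stable order breaks ties
    yn <- object$y[nb]
    out$predicted[i] <- mean(yn)
    out$d_i[i] <- mean(d[nb])
    out$sigma_i[i] <- if (object$k > 1) sd(yn) else 0
    out$ratio[i] <- if (out$sigma_i[i] > 0) out$d_i[i] / out$sigma_i[i]
                    else NA_real_
  }
  if (!is.null(newdata[[object$response]])) {
    out$truth <- newdata[[object$response]]
    out$abs_error <- abs(out$truth - out$predicted)
  }
  out
}

#' Affinity prediction metrics
#'
#' @param abs_error vector of absolute errors (kcal/mol)
#' @param T temperature used for the order-of-magnitude thresholds
#' @return list: median absolute error and the fractions of predictions
#'   within 1, 2, 3 orders of magnitude in Kd (boundary inclusive)
#' @export
affinity_metrics <- function(abs_error, T = 298) {
  list(
    median_abs_error = median(abs_error),
    frac_within_1 = mean(abs_error <= orders_threshold(1, T)),
    frac_within_2 = mean(abs_error <= orders_threshold(2, T)),
    frac_within_3 = mean(abs_error <= orders_threshold(3, T))
  )
}

#' Sweep the neighbor count k
#'
#' Refits the regressor for each `k` and evaluates it on the test set.
#'
#' @param training,test data frames with features and response
#' @param ks values of k (default 5..25)
#' @param T temperature for thresholds
#' @param ... passed to [fit_knn()]
#' @return data frame: one row per k with `median_abs_error` and the
#'   within-1/2/3-orders fractions
#' @export
k_sweep <- function(training, test, ks = 5:25, T = 298, ...) {
  rows <- lapply(ks, function(k) {
    model <- fit_knn(training, k = k, ...)
    pred <- predict(model, test)
    if (is.null(pred$abs_error)) stop("test set must include the response")
    m <- affinity_metrics(pred$abs_error, T)
    data.frame(k = k, median_abs_error = m$median_abs_error,
               frac_within_1 = m$frac_within_1,
               frac_within_2 = m$frac_within_2,
               frac_within_3 = m$frac_within_3)
  })
  do.call(rbind, rows)
}

#' Constant null model
#'
#' Predicts the training-mean `minus_dG` for every test complex and reports
#' the same metric suite as the knn model.
#'
#' @inheritParams k_sweep
#' @param response response column name
#' @return list with `prediction` (the constant), `predictions` data frame,
#'   and `metrics`
#' @export
null_model <- function(training, test, response = "minus_dG", T = 298) {
  const <- mean(training[[response]])
  abs_error <- abs(test[[response]] - const)
  list(
    prediction = const,
    predictions = data.frame(
      complex_id = if (!is.null(test$complex_id))
        as.character(test$complex_id) else as.character(seq_len(nrow(test))),
      predicted = const,
      truth = test[[response]],
      abs_error = abs_error,
      stringsAsFactors = FALSE
    ),
    metrics = affinity_metrics(abs_error, T)
  )
}

#' Reliability diagnostics of knn predictions
#'
#' Pearson correlations (with two-sided p-values) of the absolute prediction
#' error against the mean neighbor distance `d_i`, the neighbor-response
#' spread `sigma_i`, and their ratio `d_i / sigma_i`.
#'
#' @param diagnostics prediction data frame from [predict.igvor_knn()] with
#'   known truths (`abs_error` present)
#' @return data frame: one row per diagnostic with `r` and `p_value`
#' @export
reliability_analysis <- function(diagnostics) {
  stopifnot(!is.null(diagnostics$abs_error))
  if (nrow(diagnostics) < 3) stop("need >= 3 test points with known truth")
  vars <- c(d_i = "d_i", sigma_i = "sigma_i", ratio = "ratio")
  rows <- lapply(names(vars), function(v) {
    x <- diagnostics[[vars[[v]]]]
    if (anyNA(x)) {
      stop("diagnostic ", v, " is undefined (NA values, e.g. sigma_i = 0)")
    }
    if (sd(x) == 0 || sd(diagnostics$abs_error) == 0) {
      warning("correlation with ", v, " undefined (zero variance)",
              call. = FALSE)
      return(data.frame(diagnostic = v, r = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(diagnostics$abs_error, x, method = "pearson")
    data.frame(diagnostic = v, r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
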