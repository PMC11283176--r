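# percentile bounds at ranks ceiling(alpha/2 * B) and floor((1 - alpha/2) * B)
percentile_ci <- function(replicates, level = 0.95) {
  B <- nrow(replicates)
  alpha <- (1 - level) / 2
  # guard the rank arithmetic against floating-point drift (0.025 * 200 is
  # fractionally above 5 in double precision)
  lo_rank <- max(1L, as.integer(ceiling(alpha * B - 1e-9)))
  hi_rank <- min(B, as.integer(floor((1 - alpha) * B + 1e-9)))
  if (hi_rank <= lo_rank) {
    warn("too few bootstrap replicates for the requested level; interval collapses")
    hi_rank <- max(hi_rank, lo_rank)
  }
  lower <- apply(replicates, 2, function(v) sort(v)[lo_rank])
  upper <- apply(replicates, 2, function(v) sort(v)[hi_rank])
  list(lower = lower, upper = upper)
}

#' Cluster-bootstrap confidence intervals
#'
#' Resamples whole subjects (clusters) with replacement, preserving the
#' within-subject correlation, refits the model on each resample with the
#' knot count and settings of the original fit, and forms percentile
#' confidence intervals for every scalar parameter. The delete-one-component
#' parametrization keeps the first index component positive on every
#' replicate, so the index coefficients are sign-aligned by construction.
#'
#' @param fit A [bvsim()] fit.
#' @param B Number of bootstrap replications (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the resampling and refits are fully reproducible
#'   given it.
#' @return An object of class `bvsim_boot`: the matrix of converged replicate
#'   estimates, the point estimates, percentile bounds, the level and the
#'   number of failed replicates. More than 50% failures is an error.
#' @export
bvsim_bootstrap <- function(fit, B = 200, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "bvsim_fit"), B >= 2, level > 0, level < 1)
  data <- fit$data
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1, B))
  est <- param_vector(fit$params)
  reps <- matrix(NA_real_, B, length(est),
                 dimnames = list(NULL, names(est)))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- withr::with_seed(rep_seeds[b],
                            sample.int(data$n, data$n, replace = TRUE))
    boot_df <- purrr::map_dfr(seq_along(idx), function(k) {
      i <- idx[k]
      rows <- (data$start0[i] + 1):(data$start0[i] + data$m[i])
      out <- data$df[rows, , drop = FALSE]
      out$subject <- sprintf("boot_%04d", k) # relabel duplicated clusters
      out
    })
    res <- tryCatch(
      bvsim(boot_df, knots = fit$K, order = fit$order, control = fit$control),
      error = function(e) NULL
    )
    if (is.null(res)) failures <- failures + 1L
    else reps[b, ] <- param_vector(res$params)
  }
  if (failures > B / 2) {
    abort("more than half of the bootstrap refits failed; consider more data or fewer knots")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  ci <- percentile_ci(reps, level)
  structure(
    list(replicates = reps, estimate = est, lower = ci$lower,
         upper = ci$upper, level = level, failures = failures, B = B,
         seed = seed),
    class = "bvsim_boot"
  )
}

#' @export
print.bvsim_boot <- function(x, ...) {
  cat(sprintf(
    "Cluster bootstrap: %d replicates (%d failed), %.0f%% percentile intervals\n",
    x$B, x$failures, 100 * x$level))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Tidy a bootstrap result into a confidence-interval table
#'
#' @param x A `bvsim_boot`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy bvsim_boot
#' @export
tidy.bvsim_boot <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = as.numeric(x$estimate),
         conf.low = as.numeric(x$lower), conf.high = as.numeric(x$upper))
}

#' @rdname tidy.bvsim_boot
#' @method glance bvsim_boot
#' @export
glance.bvsim_boot <- function(x, ...) {
  tibble(B = x$B, converged = nrow(x$replicates), failures = x$failures,
         level = x$level)
}

#' Forest plot of bootstrap confidence intervals
#'
#' @param object A `bvsim_boot`.
#' @param terms Optional character vector restricting the plotted terms
#'   (default: index coefficients and skewness).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bvsim_boot
#' @export
autoplot.bvsim_boot <- function(object, terms = NULL, ...) {
  tbl <- tidy(object)
  if (is.null(terms)) {
    terms <- grep("^(beta|gamma)", tbl$term, value = TRUE)
  }
  tbl <- dplyr::filter(tbl, .data$term %in% terms)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::labs(x = "estimate", y = NULL)
}

#' Write a bootstrap confidence-interval table as delimited text
#'
#' @param boot A `bvsim_boot`.
#' @param file Output path.
#' @param delim Field delimiter.
#' @return The path, invisibly.
#' @export
write_ci_table <- function(boot, file, delim = ",") {
  readr::write_delim(tidy(boot), file, delim = delim)
  invisible(file)
}

#' Average absolute fitted and prediction errors
#'
#' AAFE is the mean absolute error of the conditional fitted values on the
#' training members (random effects at their posterior means
#' \eqn{E[b_i|y_i]}); AAPE is the mean absolute error of the marginal
#' predictions on test members from unseen subjects (random effects at their
#' prior mean zero). The error mean \eqn{\hat\gamma} is added to both when
#' `include_gamma = TRUE`. Test index values outside the training support
#' are clamped and counted.
#'
#' @param fit A [bvsim()] fit.
#' @param test Optional long-format test data for the prediction errors.
#' @param include_gamma Add \eqn{\hat\gamma} to fitted/predicted means?
#' @return A one-row tibble with `aafe1`, `aafe2` and (when `test` is given)
#'   `aape1`, `aape2` and the count of clamped test indices.
#' @export
prediction_errors <- function(fit, test = NULL, include_gamma = TRUE) {
  stopifnot(inherits(fit, "bvsim_fit"))
  f <- predict(fit, type = "conditional", include_gamma = include_gamma)
  out <- tibble(
    aafe1 = mean(abs(fit$data$y[, 1] - f[, 1])),
    aafe2 = mean(abs(fit$data$y[, 2] - f[, 2]))
  )
  if (!is.null(test)) {
    test <- as_bvsim_data(test)
    u1 <- as.numeric(test$X1 %*% fit$params$beta1)
    u2 <- as.numeric(test$X2 %*% fit$params$beta2)
    n_clamped <- sum(u1 < fit$bases$b1$support[1] |
                       u1 > fit$bases$b1$support[2]) +
      sum(u2 < fit$bases$b2$support[1] | u2 > fit$bases$b2$support[2])
    pr <- predict(fit, newdata = test, type = "marginal",
                  include_gamma = include_gamma)
    out$aape1 <- mean(abs(test$y[, 1] - pr[, 1]))
    out$aape2 <- mean(abs(test$y[, 2] - pr[, 2]))
    out$n_clamped <- n_clamped
  }
  out
}
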