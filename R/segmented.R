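#' One-breakpoint segmented (piecewise-linear) regression
#'
#' Fits `y = a + b1 * x + (b2 - b1) * (x - psi)+` by iterative
#' linearization: the working linear model is augmented with
#' `U = pmax(x - psi, 0)` and `V = -I(x > psi)`, and the breakpoint is
#' updated by `psi <- psi + gamma / beta` (coefficient of `V` over
#' coefficient of `U`) until the update is below `tol * range(x)` or
#' `max_iter` iterations.  If the iteration fails to converge or leaves the
#' interior of `x`, the fit falls back to an exhaustive residual
#' sum-of-squares grid search over interior `x` quantiles (ties broken
#' toward the smaller breakpoint); the `method` field records which route
#' produced the estimate.  The breakpoint standard error comes from the
#' delta method on `gamma / beta`.
#'
#' A fit is flagged degenerate (`converged = FALSE`) when the slope change
#' is negligible relative to the overall slope scale or the breakpoint sits
#' on the boundary — the no-breakpoint case.
#'
#' @param data A data frame containing the regressor and response, or
#'   `NULL` to pass `x`/`y` directly.
#' @param x,y Column names (strings) when `data` is given, otherwise
#'   numeric vectors.
#' @param psi0 Optional starting breakpoint; defaults to `median(x)`.
#' @param max_iter,tol Iteration controls.
#' @return An object of class `segmented_fit` with fields `psi`, `psi_se`,
#'   `intercept`, `slope_left`, `slope_right`, `rss`, `rss_linear`,
#'   `converged`, `iterations`, `method`, `n`.
#' @examples
#' d <- gen_response(n = 48, psi_true = 550, seed = 1)
#' fit <- segmented_fit(d, x = "dose", y = "response")
#' glance(fit)
#' @export
segmented_fit <- function(data = NULL, x = "x", y = "y", psi0 = NULL,
                          max_iter = 50, tol = 1e-6) {
  if (is.data.frame(data)) {
    xv <- data[[x]]; yv <- data[[y]]
  } else {
    xv <- x; yv <- y
  }
  keep <- complete.cases(xv, yv)
  xv <- as.numeric(xv[keep]); yv <- as.numeric(yv[keep])
  n <- length(xv)
  if (n < 6) abort("Segmented regression needs at least 6 points.")
  rng <- range(xv)
  if (diff(rng) == 0) abort("`x` is constant; no breakpoint is estimable.")

  fit_lin <- lm(yv ~ xv)
  rss_linear <- sum(fit_lin$residuals^2)
  interior <- sort(unique(xv))
  interior <- interior[interior > rng[1] & interior < rng[2]]

  psi <- psi0 %||% median(xv)
  psi <- min(max(psi, interior[1]), interior[length(interior)])
  converged <- FALSE
  method <- "iterative"
  it <- 0
  fit <- NULL
  for (it in seq_len(max_iter)) {
    U <- pmax(xv - psi, 0)
    V <- -as.numeric(xv > psi)
    fit <- lm(yv ~ xv + U + V)
    beta <- coef(fit)[["U"]]
    gamma <- coef(fit)[["V"]]
    if (!is.finite(beta) || abs(beta) < 1e-12) break
    step <- gamma / beta
    psi_new <- psi + step
    if (psi_new <= rng[1] || psi_new >= rng[2]) {
      psi <- NA_real_
      break
    }
    psi <- psi_new
    if (abs(step) < tol * diff(rng)) {
      converged <- TRUE
      break
    }
  }

  if (!converged || is.na(psi)) {
    method <- "grid"
    grid <- grid_search_psi(xv, yv, interior)
    psi <- grid$psi
    U <- pmax(xv - psi, 0)
    V <- -as.numeric(xv > psi)
    fit <- lm(yv ~ xv + U + V)
    converged <- TRUE
  }

  # final refit at the located breakpoint
  U <- pmax(xv - psi, 0)
  seg <- lm(yv ~ xv + U)
  rss <- sum(seg$residuals^2)
  b1 <- coef(seg)[["xv"]]
  b2 <- b1 + coef(seg)[["U"]]

  # delta-method SE of psi = -gamma/beta from the augmented working model
  psi_se <- NA_real_
  vc <- tryCatch(suppressWarnings(vcov(fit)), error = function(e) NULL)
  if (!is.null(vc) && all(c("U", "V") %in% rownames(vc))) {
    beta <- coef(fit)[["U"]]; gamma <- coef(fit)[["V"]]
    if (is.finite(beta) && abs(beta) > 1e-12) {
      g <- c(1 / beta, -gamma / beta^2)      # d(psi)/d(gamma), d(psi)/d(beta)
      psi_se <- sqrt(drop(t(g) %*% vc[c("V", "U"), c("V", "U")] %*% g))
    }
  }

  # degenerate when the slope change is negligible
  slope_scale <- max(abs(b1), abs(b2), sd(yv) / diff(rng))
  if (abs(b2 - b1) < 1e-8 * max(slope_scale, 1e-12)) converged <- FALSE

  structure(
    list(psi = psi, psi_se = psi_se, intercept = coef(seg)[["(Intercept)"]],
         slope_left = b1, slope_right = b2, rss = rss,
         rss_linear = rss_linear, converged = converged, iterations = it,
         method = method, n = n, x = xv, y = yv,
         x_name = if (is.data.frame(data)) x else "x",
         y_name = if (is.data.frame(data)) y else "y"),
    class = "segmented_fit"
  )
}

# exhaustive RSS search over candidate breakpoints; ties toward smaller psi
grid_search_psi <- function(xv, yv, candidates) {
  rss <- vapply(candidates, function(p) {
    sum(lm(yv ~ xv + pmax(xv - p, 0))$residuals^2)
  }, numeric(1))
  i <- which(rss <= min(rss) + 1e-12)[1]
  list(psi = candidates[i], rss = rss[i])
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "<segmented_fit> psi = %.4g (SE %.3g), slopes %.4g -> %.4g, %s%s, n = %d\n",
    x$psi, x$psi_se, x$slope_left, x$slope_right, x$method,
    if (x$converged) "" else " [degenerate]", x$n))
  invisible(x)
}

#' @method tidy segmented_fit
#' @export
tidy.segmented_fit <- function(x, ...) {
  tibble(term = c("psi", "intercept", "slope_left", "slope_right"),
         estimate = c(x$psi, x$intercept, x$slope_left, x$slope_right),
         std.error = c(x$psi_se, NA, NA, NA))
}

#' @method glance segmented_fit
#' @export
glance.segmented_fit <- function(x, ...) {
  tibble(psi = x$psi, psi_se = x$psi_se, slope_left = x$slope_left,
         slope_right = x$slope_right, rss = x$rss,
         rss_linear = x$rss_linear, converged = x$converged,
         iterations = x$iterations, method = x$method, n = x$n)
}

#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$x else {
    if (is.data.frame(newdata)) newdata[[object$x_name]] else newdata
  }
  object$intercept + object$slope_left * xv +
    (object$slope_right - object$slope_left) * pmax(xv - object$psi, 0)
}

#' Plot a segmented fit
#'
#' Scatter of the data with the two fitted segments and a dashed vertical
#' line at the breakpoint.
#'
#' @param object A `segmented_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot segmented_fit
#' @export
autoplot.segmented_fit <- function(object, ...) {
  d <- tibble(x = object$x, y = object$y)
  xs <- sort(c(seq(min(d$x), max(d$x), length.out = 101), object$psi))
  line <- tibble(x = xs, y = predict(object, xs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$psi, linetype = "dashed") +
    ggplot2::labs(x = object$x_name, y = object$y_name,
                  subtitle = sprintf("breakpoint = %.4g", object$psi)) +
    ggplot2::theme_minimal()
}
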