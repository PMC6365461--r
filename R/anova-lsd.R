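#' One-way ANOVA with Fisher's LSD compact letter display
#'
#' Runs a one-way ANOVA and groups treatment means with Fisher's least
#' significant difference: a pair of groups differs at level `alpha` when
#' `|mean_i - mean_j| > t(1 - alpha/2, df_error) * sqrt(MSE (1/n_i + 1/n_j))`.
#' Groups are assigned compact letters by the insert-and-absorb procedure,
#' so two groups share a letter exactly when their difference is not
#' significant.
#'
#' @param data A data frame, or `NULL` to pass vectors directly.
#' @param values,groups Column names (strings) when `data` is given, else a
#'   numeric vector and a matching label vector.
#' @param alpha Significance level for the LSD (default 0.05).
#' @return An object of class `anova_lsd`: `f_statistic`, `p_value`,
#'   degrees of freedom, `mse`, `lsd` (for the harmonic-mean group size),
#'   `alpha`, and a `groups` tibble (`group`, `n`, `mean`, `se`,
#'   `letters`) sorted by decreasing mean.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5),
#'                     y = rnorm(15, rep(c(0, 0, 5), each = 5)))
#' anova_lsd(d, "y", "g")
#' @export
anova_lsd <- function(data = NULL, values = "values", groups = "groups",
                      alpha = 0.05) {
  if (is.data.frame(data)) {
    v <- data[[values]]; g <- data[[groups]]
  } else {
    v <- values; g <- groups
  }
  keep <- complete.cases(v, g)
  v <- as.numeric(v[keep]); g <- as.character(g[keep])
  counts <- table(g)
  if (length(counts) < 2) abort("At least two groups are required.")
  if (any(counts < 2)) {
    abort(sprintf("Every group needs >= 2 observations (offending: %s).",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  fit <- lm(v ~ factor(g))
  an <- suppressWarnings(stats::anova(fit))   # degeneracy handled below
  df1 <- an$Df[1]; df2 <- an$Df[2]
  mse <- an$`Mean Sq`[2]
  means <- tapply(v, g, mean)
  ns <- as.numeric(counts[names(means)])
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; ns <- ns[ord]

  if (mse <= 1e-12 * max(mean(v^2), .Machine$double.eps)) {
    warn("Zero within-group variance; F and the LSD are undefined.")
    grp <- tibble(group = names(means), n = ns, mean = as.numeric(means),
                  se = 0,
                  letters = compact_letters(outer(means, means,
                                                  function(a, b) a != b)))
    return(new_anova_lsd(NA_real_, NA_real_, df1, df2, 0, NA_real_, alpha, grp))
  }

  tcrit <- qt(1 - alpha / 2, df2)
  k <- length(means)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lsd_ij <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd_ij
  }
  grp <- tibble(group = names(means), n = ns, mean = as.numeric(means),
                se = sqrt(mse / ns), letters = compact_letters(sig))
  lsd_harm <- tcrit * sqrt(mse * 2 / (k / sum(1 / ns)))
  new_anova_lsd(an$`F value`[1], an$`Pr(>F)`[1], df1, df2, mse, lsd_harm,
                alpha, grp)
}

new_anova_lsd <- function(f, p, df1, df2, mse, lsd, alpha, groups) {
  structure(
    list(f_statistic = f, p_value = p, df_between = df1, df_error = df2,
         mse = mse, lsd = lsd, alpha = alpha, groups = groups),
    class = "anova_lsd"
  )
}

# Insert-and-absorb compact letter display.  `sig` is a symmetric logical
# matrix over groups ALREADY sorted by decreasing mean; TRUE = pair differs.
# Returns one letter-string per group such that two groups share a letter
# iff their pair is not significantly different.
compact_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))           # each column = set of group indices
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (all(c(i, j) %in% col)) {
        cols[[ci]] <- setdiff(col, i)
        cols[[length(cols) + 1]] <- setdiff(col, j)
      }
    }
    # absorb columns that are subsets of another
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && !drop[b] && !drop[a] &&
          all(cols[[a]] %in% cols[[b]])) {
        drop[a] <- TRUE
        break
      }
    }
    cols <- cols[!drop]
  }
  # order columns by their smallest member so 'a' goes to the largest mean
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(col) i %in% col, logical(1)))],
          collapse = "")
  }, character(1))
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("<anova_lsd> F(%d, %d) = %.3f, p = %.4g, LSD(%.2f) = %.4g\n",
              x$df_between, x$df_error, x$f_statistic, x$p_value,
              x$alpha, x$lsd))
  print(x$groups)
  invisible(x)
}

#' @method tidy anova_lsd
#' @export
tidy.anova_lsd <- function(x, ...) x$groups

#' @method glance anova_lsd
#' @export
glance.anova_lsd <- function(x, ...) {
  tibble(statistic = x$f_statistic, p.value = x$p_value,
         df = x$df_between, df.residual = x$df_error, mse = x$mse,
         lsd = x$lsd, alpha = x$alpha)
}

#' Plot group means with LSD letters
#'
#' @param object An `anova_lsd`.
#' @param ... Unused.
#' @return A ggplot of means, standard-error bars and letter labels.
#' @method autoplot anova_lsd
#' @export
autoplot.anova_lsd <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = stats::reorder(.data$group, -.data$mean),
                                  y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + 1.5 * .data$se),
                       vjust = 0) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}
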