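# Nonparametric group comparison of the six pore parameters. The U statistic
# is computed from midrank-based rank sums; small tie-free samples get an
# exact p-value from the full permutation distribution (dynamic programming),
# larger or tied samples a normal approximation with tie and continuity
# corrections.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` is the smaller of the two group statistics
#' `U_x`, `U_y` computed from midranks. When `n1 * n2 <= 400` and there are no
#' ties the p-value is exact (full enumeration of the permutation distribution
#' via the standard counting recursion); otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return an object of class `lp_mwu`: list with `U`, `p_value`, `method`
#'   (`"exact"` or `"normal-approximation"`), `U_x`, `U_y`, `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  u <- min(ux, uy)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 * n2 <= 400) {
    p <- min(1, 2 * exact_u_cdf(u, n1, n2))
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_tab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (u - n1 * n2 / 2 + 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal-approximation"
  }
  structure(list(U = u, p_value = p, method = method,
                 U_x = ux, U_y = uy, n1 = n1, n2 = n2),
            class = "lp_mwu")
}

#' @export
print.lp_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

# P(U <= u) for the tie-free null distribution, by the standard counting
# recursion N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1), built layer by
# layer over n; row m of a layer depends on row m - 1 of the *same* layer.
exact_u_cdf <- function(u, n1, n2) {
  u <- floor(u + 1e-9)
  if (u < 0) return(0)
  umax <- n1 * n2
  if (u >= umax) return(1)
  counts <- matrix(0, n1 + 1, umax + 1)  # layer n = 0: only u = 0 possible
  counts[, 1] <- 1
  for (n in seq_len(n2)) {
    nxt <- matrix(0, n1 + 1, umax + 1)
    nxt[1, 1] <- 1
    for (m in seq_len(n1)) {
      shifted <- c(rep(0, n), nxt[m, seq_len(umax + 1 - n)])
      nxt[m + 1, ] <- counts[m + 1, ] + shifted
    }
    counts <- nxt
  }
  total <- choose(n1 + n2, n1)
  sum(counts[n1 + 1, seq_len(u + 1)]) / total
}

#' Compare the six pore parameters between groups
#'
#' One Mann-Whitney U comparison per parameter, at pore level by default
#' (each pore an observation, mirroring the unit of analysis of the reference
#' cohort). Pores within an eye are correlated; `by_eye = TRUE` aggregates to
#' eye means first (a conservative alternative, at a heavy cost in n). No
#' multiple-testing adjustment is applied by default; `bonferroni = TRUE`
#' adjusts the significance threshold across the compared parameters.
#'
#' @param metrics an `lp_metrics` table from [compute_cohort_metrics()].
#' @param parameters character vector of metric columns to compare.
#' @param alpha significance level (default 0.05).
#' @param by_eye aggregate pores to eye means before testing.
#' @param bonferroni divide `alpha` by the number of parameters.
#' @return a data.frame (class `lp_comparison`) with one row per parameter:
#'   group means and SDs, group sizes, `U`, `p_value`, `method`,
#'   `significant`.
#' @export
compare_groups <- function(metrics, parameters = lp_parameters(),
                           alpha = 0.05, by_eye = FALSE, bonferroni = FALSE) {
  stopifnot(is.data.frame(metrics), all(c("group", parameters) %in%
                                          colnames(metrics)))
  groups <- unique(metrics$group)
  if (length(groups) < 2L) {
    stop("metrics table contains a single group; nothing to compare")
  }
  g1 <- "normal"; g2 <- "glaucoma"
  if (!all(c(g1, g2) %in% groups)) { g1 <- groups[1]; g2 <- groups[2] }
  thr <- if (bonferroni) alpha / length(parameters) else alpha
  rows <- lapply(parameters, function(p) {
    d <- metrics
    if (by_eye) {
      agg <- stats::aggregate(d[[p]], by = list(eye_id = d$eye_id,
                                                group = d$group), FUN = mean)
      x <- agg$x[agg$group == g1]; y <- agg$x[agg$group == g2]
    } else {
      x <- d[[p]][d$group == g1]; y <- d[[p]][d$group == g2]
    }
    tst <- mann_whitney_u(x, y)
    data.frame(parameter = p,
               mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
               mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
               U = tst$U, p_value = tst$p_value, method = tst$method,
               significant = tst$p_value < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(g1, g2)
  attr(out, "alpha") <- thr
  attr(out, "by_eye") <- by_eye
  class(out) <- c("lp_comparison", "data.frame")
  out
}

#' @export
print.lp_comparison <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("Group comparison (%s vs %s, alpha = %g%s)\n", gr[1], gr[2],
              attr(x, "alpha"),
              if (isTRUE(attr(x, "by_eye"))) ", eye-level" else ""))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-20s %s%.4g +/- %.3g vs %.4g +/- %.3g, U = %g, p = %.3g\n",
                x$parameter[i], if (x$significant[i]) "* " else "  ",
                x$mean_1[i], x$sd_1[i], x$mean_2[i], x$sd_2[i], x$U[i],
                x$p_value[i]))
  }
  invisible(x)
}

#' Write a group comparison as CSV and Markdown
#'
#' @param comparison an `lp_comparison` from [compare_groups()].
#' @param csv_path,md_path output paths; `NULL` skips that format.
#' @return invisibly, the Markdown table as a character vector.
#' @export
write_comparison <- function(comparison, csv_path = NULL, md_path = NULL) {
  stopifnot(inherits(comparison, "lp_comparison"))
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(comparison), csv_path, row.names = FALSE)
  }
  gr <- attr(comparison, "groups")
  hdr <- sprintf("| parameter | %s (mean ± SD) | %s (mean ± SD) | U | p | significant |",
                 gr[1], gr[2])
  sep <- "|---|---|---|---|---|---|"
  body <- vapply(seq_len(nrow(comparison)), function(i) {
    sprintf("| %s | %.4g ± %.3g | %.4g ± %.3g | %g | %.3g | %s |",
            comparison$parameter[i], comparison$mean_1[i], comparison$sd_1[i],
            comparison$mean_2[i], comparison$sd_2[i], comparison$U[i],
            comparison$p_value[i],
            if (comparison$significant[i]) "yes" else "no")
  }, character(1))
  md <- c(hdr, sep, body)
  if (!is.null(md_path)) writeLines(md, md_path)
  invisible(md)
}
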