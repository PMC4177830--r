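#' @importFrom utils combn
NULL

new_htest <- function(method, statistic, p_value, exact, n) {
  structure(list(method = method, statistic = statistic,
                 p_value = min(max(p_value, 0), 1), exact = exact, n = n),
            class = "airspace_htest")
}

#' @export
print.airspace_htest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact" else "asymptotic",
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.airspace_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, exact = x$exact,
                 n = paste(x$n, collapse = ","))
}

check_sample <- function(x, name) {
  if (length(x) == 0 || !is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a non-empty finite numeric vector.", name),
          class = "airspace_error_validation")
  }
}

#' Two-sided Mann-Whitney U test
#'
#' The U statistic is reported as `min(U1, U2)`. For combined sample sizes
#' up to `exact_max` (default 16) the two-sided p-value is exact: the null
#' distribution of `min(U1, U2)` is enumerated over all
#' `choose(n1 + n2, n1)` assignments of the pooled (tie-averaged) ranks, and
#' `p = P(min(U1, U2) <= observed)`. Above the cutoff a normal approximation
#' with tie-corrected variance and a continuity correction of 0.5 is used.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact `NULL` (decide by size), `TRUE` or `FALSE`.
#' @param exact_max Combined-size cutoff for enumeration.
#' @return An `airspace_htest`.
#' @export
mann_whitney <- function(a, b, exact = NULL, exact_max = 16) {
  check_sample(a, "a"); check_sample(b, "b")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  do_exact <- exact %||% (n <= exact_max)
  if (do_exact) {
    subsets <- combn(n, n1)
    u1_null <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
    u_null <- pmin(u1_null, n1 * n2 - u1_null)
    p <- mean(u_null <= u + 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity correction: shrink |U - E[U]| by 0.5 before standardizing
      dev <- u1 - n1 * n2 / 2
      z <- sign(dev) * max(abs(dev) - 0.5, 0) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
  }
  new_htest("Mann-Whitney U", u, p, do_exact, c(n1, n2))
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p-value from the chi-square distribution
#' with `g - 1` degrees of freedom.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return An `airspace_htest`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("Need at least two groups.", class = "airspace_error_validation")
  }
  for (i in seq_along(groups)) check_sample(groups[[i]], paste0("groups[[", i, "]]"))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (correction > 0) h / correction else 0
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_htest("Kruskal-Wallis", h, p, FALSE, lengths(groups))
}

# Kolmogorov limit distribution: P(sup |B| > x)
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))))
}

ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|`. For combined sample sizes up to `exact_max`
#' (default 12) the p-value is exact by enumeration of all assignments of
#' the pooled values; otherwise the asymptotic Kolmogorov distribution on
#' `sqrt(n1 n2 / (n1 + n2)) * D` is used.
#'
#' @inheritParams mann_whitney
#' @export
ks_two_sample <- function(a, b, exact = NULL, exact_max = 12) {
  check_sample(a, "a"); check_sample(b, "b")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  d <- ks_statistic(a, b)
  do_exact <- exact %||% (n <= exact_max)
  if (do_exact) {
    pool <- c(a, b)
    subsets <- combn(n, n1)
    d_null <- apply(subsets, 2, function(ix) {
      ks_statistic(pool[ix], pool[-ix])
    })
    p <- mean(d_null >= d - 1e-9)
  } else {
    p <- if (d == 0) 1 else kolmogorov_sf(sqrt(n1 * n2 / n) * d)
  }
  new_htest("Kolmogorov-Smirnov", d, p, do_exact, c(n1, n2))
}

#' Compare per-image D-index values between genotype groups
#'
#' Runs the Kruskal-Wallis omnibus test across all groups, then two-sided
#' Mann-Whitney tests on every group pair. All raw p-values are reported;
#' no multiplicity correction is applied, and the report labels each test.
#'
#' @param data A data frame with one row per image.
#' @param value,group Columns holding the per-image value (default `d2_um`)
#'   and the group label (default `group`), given unquoted.
#' @param alpha Two-sided significance level recorded in the report.
#' @return A tibble with columns `test`, `groups`, `statistic`, `p_value`,
#'   `exact`, `significant`.
#' @export
compare_genotype_groups <- function(data, value = d2_um, group = group,
                                    alpha = 0.05) {
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  groups <- split(v, g)
  if (length(groups) < 2) {
    abort("Need at least two groups to compare.",
          class = "airspace_error_validation")
  }
  kw <- kruskal_wallis(groups)
  rows <- list(tibble::tibble(
    test = "Kruskal-Wallis", groups = paste(names(groups), collapse = " | "),
    statistic = kw$statistic, p_value = kw$p_value, exact = kw$exact))
  pairs <- combn(names(groups), 2)
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    mw <- mann_whitney(groups[[g1]], groups[[g2]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "Mann-Whitney U", groups = paste(g1, "vs", g2),
      statistic = mw$statistic, p_value = mw$p_value, exact = mw$exact)
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < alpha
  out
}
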