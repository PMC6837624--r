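# Categorical association machinery for parameter-phenotype screens:
# encoding continuous parameters as categories, Barnard's unconditional
# exact test for 2x2 tables, rank/t/Wilcoxon wrappers, and
# Benjamini-Hochberg false-discovery-rate control.

#' Encode continuous values as categories
#'
#' `sign` mode labels values `pos`/`neg` (zero counts as `pos`). `tertile`
#' mode labels the top third of the ranks `high`, the bottom third `low`,
#' and drops the middle third (`NA`); ties at a tertile boundary are broken
#' deterministically by original position (first-occurrence rank).
#'
#' @param values Numeric vector (at least 3 values for tertile mode).
#' @param mode `"sign"` or `"tertile"`.
#' @return Character vector with `NA` for dropped values.
#' @examples
#' categorize_values(c(-2, -1, 3), "sign")
#' categorize_values(1:9, "tertile")
#' @export
categorize_values <- function(values, mode = c("sign", "tertile")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values))
  if (mode == "sign") {
    return(ifelse(values >= 0, "pos", "neg"))
  }
  n <- length(values)
  if (n < 3) stop("tertile mode needs at least 3 values", call. = FALSE)
  if (diff(range(values)) == 0) {
    warning("all values equal; every value dropped in tertile mode")
    return(rep(NA_character_, n))
  }
  k <- as.integer(round(n / 3))
  r <- rank(values, ties.method = "first")
  out <- rep(NA_character_, n)
  out[r <= k] <- "low"
  out[r > n - k] <- "high"
  out
}

# pooled two-proportion Wald z over all tables with column sizes n1, n2;
# zero or full pooled proportion gives an undefined statistic, scored 0
wald_z_matrix <- function(n1, n2) {
  x <- 0:n1
  y <- 0:n2
  xs <- matrix(x, n1 + 1, n2 + 1)
  ys <- matrix(y, n1 + 1, n2 + 1, byrow = TRUE)
  pp <- (xs + ys) / (n1 + n2)
  den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (xs / n1 - ys / n2) / den
  z[!is.finite(z)] <- 0
  z
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' The two columns are treated as independent binomial samples with fixed
#' sizes and a common success probability under the null; only the column
#' totals are fixed, so row totals are free to vary (the property that gives
#' the test its power advantage over conditional exact tests). The test
#' statistic is the pooled (Wald) two-proportion z score, two-sided by
#' absolute value, and the p-value is the maximum over a grid of nuisance
#' probabilities of the null probability of a statistic at least as extreme
#' as observed.
#'
#' @param x 2x2 matrix of non-negative integer counts (rows: outcome,
#'   columns: group).
#' @param grid_step Nuisance-grid resolution on (0, 1).
#' @return A one-row tibble: `statistic` (observed |z|), `p_value`,
#'   `pi_max` (nuisance probability attaining the maximum), `degenerate`
#'   (flag: statistic undefined, p forced to 1).
#' @examples
#' barnard_test(matrix(c(5, 0, 0, 5), 2))
#' @export
barnard_test <- function(x, grid_step = 0.001) {
  x <- as.matrix(x)
  stopifnot(all(dim(x) == c(2, 2)), all(x >= 0), any(x > 0),
            all(x == round(x)))
  n1 <- sum(x[, 1])
  n2 <- sum(x[, 2])
  if (n1 == 0 || n2 == 0 || sum(x[1, ]) == 0 || sum(x[2, ]) == 0) {
    # a zero margin: the statistic carries no information
    return(tibble::tibble(statistic = 0, p_value = 1, pi_max = NA_real_,
                          degenerate = TRUE))
  }
  z <- wald_z_matrix(n1, n2)
  z_obs <- abs(z[x[1, 1] + 1, x[1, 2] + 1])
  extreme <- abs(z) >= z_obs - 1e-12
  pis <- seq(grid_step, 1 - grid_step, by = grid_step)
  p <- 0
  pi_max <- pis[1]
  for (pv in pis) {
    d1 <- stats::dbinom(0:n1, n1, pv)
    d2 <- stats::dbinom(0:n2, n2, pv)
    val <- sum((d1 %o% d2)[extreme])
    if (val > p) {
      p <- val
      pi_max <- pv
    }
  }
  tibble::tibble(statistic = z_obs, p_value = min(p, 1), pi_max = pi_max,
                 degenerate = FALSE)
}

#' Association tests between a parameter and a property
#'
#' Uniform tidy interface over the tests used in parameter-phenotype
#' screens: Barnard's unconditional exact test for two categorical
#' variables, Spearman's rank correlation, and one-tailed Wilcoxon rank-sum
#' and Student t tests for a continuous variable split by a two-level group.
#'
#' @param x,y The two variables (same length; type depends on `kind`: both
#'   categorical for `barnard`, both numeric for `spearman`, numeric +
#'   two-level group for `wilcoxon`/`ttest`).
#' @param kind Test to run.
#' @param alternative One-tailed direction for `wilcoxon`/`ttest`.
#' @param min_n Minimum number of complete pairs.
#' @return A one-row tibble: `test`, `n`, `statistic`, `p_value`.
#' @examples
#' associate(1:10, (1:10)^2, kind = "spearman")
#' @export
associate <- function(x, y,
                      kind = c("barnard", "spearman", "wilcoxon", "ttest"),
                      alternative = "greater", min_n = 3) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < min_n)
    stop("only ", n, " complete pairs; need at least ", min_n, call. = FALSE)
  res <- switch(kind,
    barnard = {
      tab <- table(factor(x), factor(y))
      if (!all(dim(tab) == c(2, 2)))
        stop("barnard needs two 2-level categorical variables", call. = FALSE)
      b <- barnard_test(unclass(tab))
      list(statistic = b$statistic, p = b$p_value)
    },
    spearman = {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      list(statistic = unname(ct$estimate), p = ct$p.value)
    },
    wilcoxon = {
      g <- split(x, y)
      if (length(g) != 2) stop("wilcoxon needs a 2-level group", call. = FALSE)
      wt <- wilcox.test(g[[1]], g[[2]], alternative = alternative,
                        exact = FALSE)
      list(statistic = unname(wt$statistic), p = wt$p.value)
    },
    ttest = {
      g <- split(x, y)
      if (length(g) != 2) stop("ttest needs a 2-level group", call. = FALSE)
      tt <- t.test(g[[1]], g[[2]], alternative = alternative)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    })
  tibble::tibble(test = kind, n = n, statistic = res$statistic,
                 p_value = res$p)
}

#' Benjamini-Hochberg discovery flags
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q Target false-discovery rate (0.25 in the parameter-property
#'   screens this package accompanies; 0.05 for strict control).
#' @return Logical vector: `TRUE` where the hypothesis is a discovery.
#' @examples
#' fdr_control(c(0.001, 0.01, 0.2, 0.9), q = 0.25)
#' @export
fdr_control <- function(pvals, q = 0.25) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE), q > 0, q < 1)
  p.adjust(pvals, method = "BH") <= q
}

#' Parameter-property association screen
#'
#' Runs [associate()] for every parameter column against every property
#' column and applies FDR control across the whole screen.
#'
#' @param params Data frame of (categorical) model parameters, e.g. from
#'   [categorize_values()].
#' @param properties Data frame of categorical properties, same row order.
#' @param q FDR level.
#' @param kind Test to apply to every pair.
#' @return A tibble with one row per pair: `parameter`, `property`, the test
#'   columns, and `discovery`.
#' @export
association_screen <- function(params, properties, q = 0.25,
                               kind = "barnard") {
  grid <- tidyr::expand_grid(parameter = names(params),
                             property = names(properties))
  res <- purrr::pmap_dfr(grid, function(parameter, property) {
    out <- tryCatch(
      associate(params[[parameter]], properties[[property]], kind = kind),
      error = function(e) tibble::tibble(test = kind, n = NA_integer_,
                                         statistic = NA_real_,
                                         p_value = NA_real_))
    dplyr::bind_cols(tibble::tibble(parameter = parameter,
                                    property = property), out)
  })
  res$discovery <- FALSE
  idx <- !is.na(res$p_value)
  res$discovery[idx] <- fdr_control(res$p_value[idx], q = q)
  res
}
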