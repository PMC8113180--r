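## Rank-based association analysis of amyloid biomarkers with clinical and
## MRI-derived covariates.

#' Spearman rank correlation with a two-sided p value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the p value
#' uses the two-sided t approximation, adequate at the cohort sizes this
#' package targets (tens to hundreds). An exact permutation p value is
#' available for very small samples.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param exact if `TRUE` (only for n <= 12), enumerate all permutations of
#'   one vector for an exact two-sided p value.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (exact) {
    if (n > 12) stop("exact permutation p value limited to n <= 12", call. = FALSE)
    rx <- rank(x); ry <- rank(y)
    perms <- asplit(permutations_of(n), 1)
    rhos <- vapply(perms, function(p) stats::cor(rx, ry[p]), numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    p <- ct$p.value
  }
  list(rho = rho, p = p)
}

# All permutations of 1..n as an (n!) x n matrix.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Significance stars for association tables
#'
#' `.` for p < 0.1, `*` < 0.05, `**` < 0.01, `***` < 0.001.
#' @param p numeric vector of p values.
#' @return Character vector of markers.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*"
    else if (pp < 0.1) "." else ""
  }, character(1))
}

#' Biomarker-by-covariate Spearman association table
#'
#' One Spearman correlation per marker x covariate pair, with the p value
#' and significance stars. Missing values are handled by pairwise deletion.
#'
#' @param table data.frame with one row per subject.
#' @param markers character vector of marker column names.
#' @param covariates character vector of covariate column names.
#' @return data.frame with columns marker, covariate, rho, p, stars.
#' @export
association_table <- function(table, markers, covariates) {
  missing <- setdiff(c(markers, covariates), names(table))
  if (length(missing)) {
    stop("unknown column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (m in markers) for (cv in covariates) {
    s <- spearman(table[[m]], table[[cv]])
    rows[[length(rows) + 1L]] <- data.frame(
      marker = m, covariate = cv, rho = s$rho, p = s$p, stars = p_stars(s$p),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Percent change in association strength
#'
#' Compares the magnitudes of two correlation coefficients:
#' `100 * (|rho_new| - |rho_ref|) / |rho_ref|`. Absolute values are used
#' because improvements are reported for positive and negative associations
#' alike.
#'
#' @param rho_new,rho_ref correlation coefficients; `rho_ref` non-zero.
#' @return Scalar percent change.
#' @export
pct_change <- function(rho_new, rho_ref) {
  if (rho_ref == 0) stop("reference correlation is zero", call. = FALSE)
  100 * (abs(rho_new) - abs(rho_ref)) / abs(rho_ref)
}
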