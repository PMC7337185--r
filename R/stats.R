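#' Pearson correlation with a t-based p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t transform with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return Tibble `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Correlation web among piRNA output and TE genomic traits
#'
#' Pairwise Pearson correlations among normalized piRNA level, normalized
#' mRNA level, copy number, median copy length, and nucleotide diversity.
#' Count-like variables (piRNA, mRNA, copy number) are `log10(x + 1)`
#' transformed by default; `pi` and `median_length` are used untransformed.
#' Pairs involving a constant column are reported with `NA` statistics.
#'
#' @param table Trait tibble with columns `pirna_level`, `mrna_level`,
#'   `copy_number`, `median_length`, `pi` (one row per family).
#' @param transform Apply the log10(x+1) transform to count-like columns
#'   (default `TRUE`).
#' @param alpha Significance level for the `significant` flag.
#' @return A `correlation_web` tibble: `var1`, `var2`, `r`, `p_value`, `n`,
#'   `significant`, `p_adj` (Benjamini-Hochberg, informational).
#' @export
correlation_web <- function(table, transform = TRUE, alpha = 0.05) {
  vars <- c("pirna_level", "mrna_level", "copy_number", "median_length", "pi")
  stopifnot(all(vars %in% names(table)))
  if (nrow(table) < 3) stop("need at least 3 families", call. = FALSE)
  d <- table[vars]
  if (transform) {
    for (v in c("pirna_level", "mrna_level", "copy_number")) {
      d[[v]] <- log10(d[[v]] + 1)
    }
  }
  pairs <- combn(vars, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    v1 <- pairs[1, k]; v2 <- pairs[2, k]
    stat <- tryCatch(pearson_cor(d[[v1]], d[[v2]]),
                     error = function(e) tibble::tibble(
                       r = NA_real_, p_value = NA_real_, n = nrow(d)))
    dplyr::mutate(stat, var1 = v1, var2 = v2, .before = 1)
  })
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  class(res) <- c("correlation_web", class(res))
  res
}

#' @export
tidy.correlation_web <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.correlation_web <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n = x$n[1])
}

#' @export
autoplot.correlation_web <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("r=%.2f%s", .data$r,
                      ifelse(.data$significant, "*", "")))) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "piRNA level vs TE genomic traits") +
    ggplot2::theme_minimal()
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration over all group assignments when both groups have at
#' most `exact_max` observations (ties handled exactly through midranks);
#' otherwise the normal approximation with tie correction (no continuity
#' correction). The exact two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for exact enumeration (default 10).
#' @return Tibble `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 10) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty", call. = FALSE)
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    sets <- combn(nx + ny, nx)
    ws <- colSums(matrix(ranks[sets], nrow = nx))
    # guard against float fuzz from midranks when comparing tails
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    mu <- nx * (n + 1) / 2
    ties <- table(ranks)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(statistic = w, p_value = p, method = method)
}

#' Compare piRNA output between copy-number classes
#'
#' Within each expression class, compares the level column between families
#' with at least `boundary` genomic copies (`ge`) and the rest (`lt`) by a
#' two-sided Wilcoxon rank-sum test. Classes with an empty group are skipped
#' with a warning.
#'
#' @param table Trait tibble with `copy_number`, the level column, and the
#'   grouping column.
#' @param level Name of the level column (default `"pirna_level"`).
#' @param by Name of the class column (default `"expression_class"`); use
#'   `NULL` for a single overall comparison.
#' @param boundary Copy-number boundary (default 20: `>= 20` vs `< 20`).
#' @return Tibble per class: group sizes, medians, `statistic`, `p_value`,
#'   `method`.
#' @export
copy_class_compare <- function(table, level = "pirna_level",
                               by = "expression_class", boundary = 20) {
  table$copy_class <- ifelse(table$copy_number >= boundary, "ge", "lt")
  groups <- if (is.null(by)) list(all = table) else
    split(table, table[[by]])
  purrr::imap_dfr(groups, function(d, cls) {
    x <- d[[level]][d$copy_class == "ge"]
    y <- d[[level]][d$copy_class == "lt"]
    if (length(x) == 0 || length(y) == 0) {
      warning("class ", cls, " skipped: empty copy-number group",
              call. = FALSE)
      return(tibble::tibble())
    }
    res <- wilcoxon_ranksum(x, y)
    tibble::tibble(class = cls, n_ge = length(x), n_lt = length(y),
                   median_ge = median(x), median_lt = median(y),
                   statistic = res$statistic, p_value = res$p_value,
                   method = res$method)
  })
}

#' Assemble the per-family trait table
#'
#' Joins the genomic family summary with normalized piRNA and mRNA levels
#' into the table consumed by [correlation_web()] and
#' [copy_class_compare()].
#'
#' @param summary Family summary from [summarize_families()].
#' @param pirna_levels Output of [normalize_and_classify()].
#' @param mrna Tibble `family_id`, `mrna_count` (raw counts; normalized
#'   upstream or used as-is).
#' @param tissue Tissue whose normalized piRNA level becomes `pirna_level`
#'   (default `"ovary"`).
#' @return Trait tibble, one row per family.
#' @export
make_trait_table <- function(summary, pirna_levels, mrna,
                             tissue = "ovary") {
  norm_col <- paste0(tissue, "_norm")
  summary |>
    dplyr::inner_join(
      dplyr::select(pirna_levels, "family_id",
                    pirna_level = dplyr::all_of(norm_col),
                    expression_class = "sex_bias_class"),
      by = "family_id") |>
    dplyr::inner_join(
      dplyr::select(mrna, "family_id", mrna_level = "mrna_count"),
      by = "family_id")
}
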