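## differential_expression module: RPM normalization, zero adjustment, log2
## fold change, Pearson chi-squared test and the two-tier significance rule.

#' Reads-per-million normalization
#'
#' @param counts Raw counts (vector).
#' @param totals Library clean-read totals (scalar or vector, > 0).
#' @return `counts / totals * 1e6`.
#' @export
#' @examples
#' normalize_rpm(37, 16109390)
normalize_rpm <- function(counts, totals) {
  stopifnot(all(totals > 0))
  counts / totals * 1e6
}

#' Zero adjustment for expression comparisons
#'
#' Expression values of exactly zero become 0.01 so fold changes stay
#' defined; small positive values are left untouched.
#'
#' @param rpm Normalized expression values (>= 0).
#' @return Adjusted values.
#' @export
adjust_zero <- function(rpm) {
  stopifnot(all(rpm >= 0))
  ifelse(rpm == 0, 0.01, rpm)
}

#' Log2 fold change between two zero-adjusted expression values
#'
#' @param rpm_t1,rpm_t2 Zero-adjusted expression in treatment 1 and 2.
#' @return `log2(rpm_t1 / rpm_t2)`.
#' @export
fold_change <- function(rpm_t1, rpm_t2) {
  log2(rpm_t1 / rpm_t2)
}

#' Pearson chi-squared test on a 2x2 count/remainder table
#'
#' Tests whether a feature's count differs between two libraries using the
#' table `[[c1, t1-c1], [c2, t2-c2]]`, without continuity correction, df = 1.
#' When both counts are zero the statistic is 0 and p = 1.
#'
#' @param count1,count2 Feature counts in the two libraries.
#' @param total1,total2 Library totals (>= counts).
#' @return Tibble with `chi2` and `p_value` (vectorized over counts).
#' @export
#' @examples
#' chi2_test(10, 1000, 40, 1000)
chi2_test <- function(count1, total1, count2, total2) {
  stopifnot(all(total1 >= count1), all(total2 >= count2),
            all(total1 > 0), all(total2 > 0))
  a <- as.numeric(count1); b <- as.numeric(total1) - a
  c <- as.numeric(count2); d <- as.numeric(total2) - c
  n <- as.numeric(total1) + as.numeric(total2)
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  chi2[a + c == 0] <- 0  # empty expected cells: not testable
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, p_value = p)
}

#' Two-tier expression significance
#'
#' `**` (extremely significant) when |fold change| >= 1 and p <= 0.01;
#' `*` (significant) when |fold change| >= 1 and 0.01 < p <= 0.05;
#' `ns` otherwise. All boundaries inclusive as stated.
#'
#' @param fold_change Log2 fold change.
#' @param p_value Chi-squared p-value.
#' @return Character vector in `c("**", "*", "ns")`.
#' @export
#' @examples
#' classify_expression(-1.23, 0.004)
classify_expression <- function(fold_change, p_value) {
  big <- abs(fold_change) >= 1
  dplyr::case_when(
    big & p_value <= 0.01 ~ "**",
    big & p_value <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

## p-value-only tier (the "statistical significance" column)
classify_stat <- function(p_value) {
  dplyr::case_when(
    p_value <= 0.01 ~ "**",
    p_value <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Pairwise differential expression over the three libraries
#'
#' For each feature and each library pair (by default drought/control,
#' salt/control, salt/drought): RPM normalization against the library
#' totals, zero adjustment, log2 fold change, Pearson chi-squared on the
#' raw counts, and both significance tiers. Features whose counts are zero
#' in both members of a pair are flagged not-testable (`testable = FALSE`,
#' fold change 0). A Benjamini-Hochberg adjusted p-value per pair is
#' emitted alongside but plays no part in the tier calls.
#'
#' @param counts Tibble with an `id` column and one `count_<library>` column
#'   per library.
#' @param totals Named numeric vector of library clean-read totals (the
#'   RPM/contingency denominator).
#' @param pairs 2-row character matrix of library pairs (treatment 1 in row
#'   1, treatment 2 in row 2); defaults to the three-treatment design.
#' @return An object of class `mirna_de`: list with `table` (long per-pair
#'   tibble), `rpm` (per-library RPM tibble) and `totals`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   id = c("miR1", "miR2"),
#'   count_control = c(100L, 5L),
#'   count_drought = c(400L, 5L),
#'   count_salt = c(100L, 0L)
#' )
#' de <- compare_expression(counts, c(control = 1e5, drought = 1e5, salt = 1e5))
#' tidy(de)
compare_expression <- function(counts, totals, pairs = NULL) {
  libs <- sub("^count_", "", grep("^count_", names(counts), value = TRUE))
  stopifnot(all(libs %in% names(totals)), "id" %in% names(counts))
  if (is.null(pairs)) {
    stopifnot(all(c("control", "drought", "salt") %in% libs))
    pairs <- rbind(c("drought", "salt", "salt"),
                   c("control", "control", "drought"))
  }
  rpm <- counts["id"]
  for (lib in libs) {
    rpm[[lib]] <- normalize_rpm(counts[[paste0("count_", lib)]], totals[[lib]])
  }
  tab <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    t1 <- pairs[1, k]; t2 <- pairs[2, k]
    c1 <- counts[[paste0("count_", t1)]]
    c2 <- counts[[paste0("count_", t2)]]
    testable <- !(c1 == 0 & c2 == 0)
    fc <- fold_change(adjust_zero(rpm[[t1]]), adjust_zero(rpm[[t2]]))
    fc[!testable] <- 0
    ct <- chi2_test(c1, totals[[t1]], c2, totals[[t2]])
    tibble::tibble(
      id = counts$id,
      treatment1 = t1, treatment2 = t2,
      pair = paste(t1, t2, sep = "/"),
      rpm_t1 = rpm[[t1]], rpm_t2 = rpm[[t2]],
      fold_change = fc,
      chi2 = ct$chi2, p_value = ct$p_value,
      p_adj = stats::p.adjust(ct$p_value, "BH"),
      testable = testable,
      stat_tier = classify_stat(ct$p_value),
      expr_tier = classify_expression(fc, ct$p_value)
    )
  })
  structure(list(table = tab, rpm = rpm, totals = totals),
            class = "mirna_de")
}

#' @export
print.mirna_de <- function(x, ...) {
  cat("<mirna_de> ", length(unique(x$table$id)), " features, ",
      length(unique(x$table$pair)), " library pairs\n", sep = "")
  sig <- table(x$table$expr_tier)
  cat("expression tiers:",
      paste(names(sig), as.integer(sig), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname compare_expression
#' @param x A `mirna_de` object.
#' @param ... Unused.
#' @method tidy mirna_de
#' @export
tidy.mirna_de <- function(x, ...) x$table

#' @rdname compare_expression
#' @method glance mirna_de
#' @export
glance.mirna_de <- function(x, ...) {
  tab <- x$table
  by_id <- dplyr::summarise(
    dplyr::group_by(tab, .data$id),
    any_p05 = any(.data$p_value <= 0.05 & .data$testable),
    any_sig = any(.data$expr_tier != "ns"),
    .groups = "drop"
  )
  tibble::tibble(
    n_features = nrow(by_id),
    n_pairs = length(unique(tab$pair)),
    n_p05 = sum(by_id$any_p05),
    frac_p05 = mean(by_id$any_p05),
    n_tier_sig = sum(by_id$any_sig),
    frac_tier_sig = mean(by_id$any_sig)
  )
}

#' @rdname compare_expression
#' @param object A `mirna_de` object (for `autoplot`).
#' @method autoplot mirna_de
#' @export
autoplot.mirna_de <- function(object, ...) {
  tab <- dplyr::filter(object$table, .data$testable)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$fold_change, y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$expr_tier
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "tier") +
    ggplot2::theme_minimal()
}

#' Presence/absence partition over the three treatments
#'
#' Presence is raw count > 0; each feature falls in exactly one of the 7
#' non-empty membership regions (features absent everywhere are labeled
#' `"none"`).
#'
#' @param counts Tibble with `id` and `count_<library>` columns.
#' @return Tibble with `id`, one logical column per library and `region`
#'   (present library names joined by `+`).
#' @export
venn_partition <- function(counts) {
  libs <- sub("^count_", "", grep("^count_", names(counts), value = TRUE))
  out <- counts["id"]
  for (lib in libs) out[[lib]] <- counts[[paste0("count_", lib)]] > 0
  pres <- as.matrix(out[libs])
  out$region <- apply(pres, 1, function(r) {
    if (!any(r)) "none" else paste(libs[r], collapse = "+")
  })
  out
}

#' Region counts of a presence/absence partition
#'
#' @param venn Result of [venn_partition()].
#' @return Tibble with `region`, `n`, `percent` (of all features, 1
#'   decimal).
#' @export
venn_counts <- function(venn) {
  out <- dplyr::count(venn, .data$region)
  dplyr::mutate(out, percent = round(100 * .data$n / sum(.data$n), 1))
}

#' Sample Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return Tibble with `r`, `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(r = r, r_squared = r^2, p_value = p, n = n)
}

#' Named summary statistics for a processed experiment
#'
#' Computes the headline numbers of a three-library run from whichever
#' pieces are supplied: total reads, per-category mean percentages over the
#' libraries (unique and redundant), mean matched percentages per reference
#' set, the shared-in-all-treatments percentage (1 decimal), and
#' differential-expression fractions (2 decimals).
#'
#' @param stats Optional [library_stats()] tibble.
#' @param categories Optional [category_table()] tibble.
#' @param matched Optional tibble with `library`, `set`, `unique_pct`,
#'   `redundant_pct` (see [matched_table()]).
#' @param venn Optional [venn_partition()] result.
#' @param de Optional [compare_expression()] result.
#' @return Named list of counts and percentages.
#' @export
summarize_experiment <- function(stats = NULL, categories = NULL,
                                 matched = NULL, venn = NULL, de = NULL) {
  out <- list()
  if (!is.null(stats)) {
    out$total_reads <- sum(stats$total_redundant)
    out$total_unique <- sum(stats$total_unique)
  }
  if (!is.null(categories)) {
    means <- dplyr::summarise(
      dplyr::group_by(categories, .data$category),
      mean_unique_pct = round(mean(.data$unique_pct), 2),
      mean_redundant_pct = round(mean(.data$redundant_pct), 2),
      .groups = "drop"
    )
    out$category_means <- means
  }
  if (!is.null(matched)) {
    mm <- dplyr::summarise(
      dplyr::group_by(matched, .data$set),
      mean_unique_pct = round(mean(.data$unique_pct), 2),
      mean_redundant_pct = round(mean(.data$redundant_pct), 2),
      .groups = "drop"
    )
    out$matched_means <- mm
  }
  if (!is.null(venn)) {
    libs <- setdiff(names(venn), c("id", "region"))
    shared <- sum(rowSums(as.matrix(venn[libs])) == length(libs))
    out$n_features <- nrow(venn)
    out$n_shared_all <- shared
    out$shared_all_pct <- round(100 * shared / nrow(venn), 1)
  }
  if (!is.null(de)) {
    g <- glance(de)
    out$n_de_p05 <- g$n_p05
    out$de_p05_pct <- round(100 * g$frac_p05, 2)
    out$n_de_tier <- g$n_tier_sig
    out$de_tier_pct <- round(100 * g$frac_tier_sig, 2)
  }
  out
}

#' Reference-match percentage table
#'
#' Per-library unique/redundant match percentages for each reference set of
#' a [match_reference()]-annotated collapsed table, plus the `any` union.
#'
#' @param matched_collapsed Collapsed tibble with `matched_*` columns.
#' @return Tibble: `library`, `set`, `unique_pct`, `redundant_pct`.
#' @export
matched_table <- function(matched_collapsed) {
  mcols <- grep("^matched_", names(matched_collapsed), value = TRUE)
  ccols <- grep("^count_", names(matched_collapsed), value = TRUE)
  purrr::map_dfr(ccols, function(cl) {
    x <- matched_collapsed[matched_collapsed[[cl]] > 0, ]
    purrr::map_dfr(mcols, function(mc) {
      tibble::tibble(
        library = sub("^count_", "", cl),
        set = sub("^matched_", "", mc),
        unique_pct = 100 * sum(x[[mc]]) / nrow(x),
        redundant_pct = 100 * sum(x[[cl]][x[[mc]]]) / sum(x[[cl]])
      )
    })
  })
}
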