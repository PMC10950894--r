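#' Tidy a Mendelian-randomization result
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return One-row tibble of estimate, SE, z, p and pleiotropy diagnostics.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate, std.error = x$se,
         statistic = x$z, p.value = x$p,
         egger_intercept = x$egger_intercept,
         egger_intercept_p = x$egger_intercept_p)
}

#' @rdname tidy.mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = x$method, n_instruments = x$n_instruments,
         significant_causal = x$significant_causal)
}

#' Tidy a mediation decomposition
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return Tibble with one row per effect (EM, MO, total, indirect, MP).
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble(term = c("B_EM", "B_MO", "B_total", "B_indirect", "MP"),
         estimate = c(x$B_EM, x$B_MO, x$B_total, x$B_indirect, x$MP),
         std.error = c(x$SE_EM, x$SE_MO, x$SE_total, x$SE_indirect,
                       x$SE_MP))
}

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble(MP = x$MP, SE_MP = x$SE_MP, p_indirect = x$p_indirect,
         all_gates_pass = all(x$gates$passes))
}

#' Tidy a fine-mapping result
#'
#' @param x A `finemap_result`.
#' @param ... Unused.
#' @return The per-gene PIP tibble.
#' @export
tidy.finemap_result <- function(x, ...) x$genes

#' @rdname tidy.finemap_result
#' @export
glance.finemap_result <- function(x, ...) {
  tibble(n_genes = nrow(x$genes), p_null = x$p_null,
         n_credible = sum(x$genes$in_credible_set),
         n_retained = sum(x$genes$retained),
         n_sigma2 = x$n_sigma2)
}

#' Tidy a GReX model set
#'
#' @param x A `grex_model_set`.
#' @param ... Unused.
#' @return Per-gene tibble of tuning choices and cross-validated
#'   performance.
#' @export
tidy.grex_model_set <- function(x, ...) {
  purrr::map_dfr(x, function(m)
    tibble(gene_id = m$gene_id, method = m$method,
           retained = isTRUE(m$retained),
           n_weights = if (is.null(m$weights)) 0L else nrow(m$weights),
           chosen_window = m$chosen_window %||% NA_character_,
           chosen_phi = m$chosen_phi %||% NA_real_,
           chosen_lambda = m$chosen_lambda %||% NA_real_,
           cv_r = m$cv_r, cv_p = m$cv_p))
}

#' @rdname tidy.grex_model_set
#' @export
glance.grex_model_set <- function(x, ...) {
  td <- tidy.grex_model_set(x)
  tibble(n_genes = nrow(td), n_retained = sum(td$retained),
         median_cv_r = median(td$cv_r[td$retained], na.rm = TRUE))
}

#' Plot PIPs from a fine-mapping result
#'
#' @param object A `finemap_result`.
#' @param ... Unused.
#' @return A ggplot: per-gene posterior inclusion probabilities, credible
#'   set members highlighted, the 0.5 retention line dashed.
#' @export
autoplot.finemap_result <- function(object, ...) {
  d <- object$genes
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$gene_id,
                                                     -.data$pip),
                                  y = .data$pip,
                                  fill = .data$in_credible_set)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "posterior inclusion probability",
                  fill = "95% credible set") +
    ggplot2::theme_minimal()
}

#' Plot cross-validated performance of a model set
#'
#' @param object A `grex_model_set`.
#' @param ... Unused.
#' @return A ggplot histogram of cv_r with the 0.1 retention threshold.
#' @export
autoplot.grex_model_set <- function(object, ...) {
  td <- tidy.grex_model_set(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$cv_r, fill = .data$retained)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "cross-validated r", y = "genes",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' Plot reciprocal-replication concordance
#'
#' @param replication Output of [reciprocal_replicate()].
#' @return A ggplot of cohort-1 vs cohort-2 z-scores, replicated hits
#'   highlighted.
#' @export
plot_replication <- function(replication) {
  ggplot2::ggplot(replication,
                  ggplot2::aes(x = .data$z_cohort1, y = .data$z_cohort2,
                               colour = .data$replicated)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "z (cohort 1)", y = "z (cohort 2)",
                  colour = "replicated") +
    ggplot2::theme_minimal()
}

#' Plot the discovery funnel of a pipeline run
#'
#' @param object An `omix_pipeline`.
#' @param ... Unused.
#' @return A ggplot bar chart of the stage counts.
#' @export
autoplot.omix_pipeline <- function(object, ...) {
  d <- object$funnel |>
    mutate(stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "genes", y = NULL) +
    ggplot2::theme_minimal()
}
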