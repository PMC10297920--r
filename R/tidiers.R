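#' Tidy a differential-expression result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return The per-gene tibble (gene_id, base_mean, log2_fold_change,
#'   lfc_se, stat, p_value, p_adjust, tested).
#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    contrast = paste(attr(x, "contrast"), collapse = " vs "),
    n_genes = nrow(x),
    n_tested = sum(x$tested),
    n_significant = length(significant_genes(x)),
    n_up = sum(x$p_adjust <= 0.05 & x$log2_fold_change > 0, na.rm = TRUE),
    n_down = sum(x$p_adjust <= 0.05 & x$log2_fold_change < 0, na.rm = TRUE)
  )
}

#' Tidy a co-expression fit
#'
#' @param x A `coexpression_fit`.
#' @param ... Unused.
#' @return Per-gene tibble: `gene_id`, `module`, `kme`, `gs`.
#' @export
tidy.coexpression_fit <- function(x, ...) x$genes

#' @rdname tidy.coexpression_fit
#' @export
glance.coexpression_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_modules = ncol(x$eigengenes),
    n_grey = sum(x$genes$module == "grey"),
    largest_module = names(x$module_sizes)[1],
    soft_power = x$config$soft_power
  )
}

#' Tidy a fuzzy c-means fit
#'
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return Long tibble: `gene_id`, `cluster`, `membership`, `hard` (TRUE on
#'   the gene's maximum-membership cluster).
#' @export
tidy.fcm_fit <- function(x, ...) {
  u <- x$membership
  ids <- rownames(u) %||% sprintf("g%04d", seq_len(nrow(u)))
  out <- tibble::as_tibble(u)
  out$gene_id <- ids
  out <- tidyr::pivot_longer(out, -"gene_id", names_to = "cluster",
                             values_to = "membership")
  out$hard <- out$cluster == paste0("C", x$cluster[match(out$gene_id, ids)])
  out
}

#' @rdname tidy.fcm_fit
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$membership),
    n_clusters = ncol(x$membership),
    fuzzifier = x$m,
    iterations = length(x$objective),
    final_objective = x$objective[length(x$objective)],
    converged = x$converged
  )
}

#' Tidy bias calls
#'
#' @param x A `bias_calls` object.
#' @param ... Unused.
#' @return The per-gene, per-stage call tibble.
#' @export
tidy.bias_calls <- function(x, ...) x$by_stage

#' @rdname tidy.bias_calls
#' @export
glance.bias_calls <- function(x, ...) {
  tab <- table(factor(x$overall$call,
                      levels = c("toward_D", "toward_H", "unbiased", "ambiguous")))
  tibble::tibble(
    n_genes = nrow(x$overall),
    n_toward_D = unname(tab["toward_D"]),
    n_toward_H = unname(tab["toward_H"]),
    n_unbiased = unname(tab["unbiased"]),
    n_ambiguous = unname(tab["ambiguous"]),
    level = x$level, mode = x$mode
  )
}

#' Tidy a morphometry summary
#'
#' @param x A `morphometry_summary`.
#' @param ... Unused.
#' @return One-row tibble: `n_accepted`, `mean_csa`, `csa_sd`, `csa_unit`,
#'   `hypertrophy_fraction`.
#' @export
tidy.morphometry_summary <- function(x, ...) {
  tibble::tibble(n_accepted = x$n_accepted, mean_csa = x$mean_csa,
                 csa_sd = x$csa_sd, csa_unit = x$csa_unit,
                 hypertrophy_fraction = x$hypertrophy_fraction)
}
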