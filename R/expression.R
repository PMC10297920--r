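#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed the median-of-ratios way:
#' reference genes are those with nonzero counts in every sample; each
#' sample's factor is the median over reference genes of the ratio of its
#' count to the gene's geometric mean across samples. Factors are rescaled
#' to geometric mean 1, so they are interpretable as relative depths.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(100, 200))
#' size_factors(m)  # depths in ratio 1:2
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  abort_if(any(counts < 0), "counts must be nonnegative")
  ref <- rowSums(counts > 0) == ncol(counts)
  abort_if(!any(ref),
           "no gene has nonzero counts in all samples; filter the matrix or merge samples")
  lg <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- exp(apply(lg - loggeo, 2, median))
  sf <- sf / geo_mean(sf)
  setNames(sf, colnames(counts))
}

# per-gene method-of-moments NB dispersion from normalized counts,
# pooled across the two groups, shrunk toward a 1/mu trend on the log scale
estimate_dispersions <- function(y, grp, sf, shrink = 0.8) {
  disp_mom <- function(sub, sfs) {
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    # Var(K/s) = mu/s + a mu^2  =>  a = (v - mu * mean(1/s)) / mu^2
    (v - m * mean(1 / sfs)) / m^2
  }
  g1 <- grp == levels(factor(grp))[1]
  a1 <- disp_mom(y[, g1, drop = FALSE], sf[g1])
  a2 <- disp_mom(y[, !g1, drop = FALSE], sf[!g1])
  w1 <- sum(g1) - 1; w2 <- sum(!g1) - 1
  a <- (w1 * a1 + w2 * a2) / (w1 + w2)
  mu <- rowMeans(y)
  ok <- is.finite(a) & a > 0 & mu > 0
  # parametric trend a = a0 + a1/mu, nonnegative coefficients
  trend <- rep(stats::quantile(a[ok], 0.5, names = FALSE), length(a))
  if (sum(ok) >= 10) {
    fit <- stats::lm(a[ok] ~ I(1 / mu[ok]))
    co <- pmax(stats::coef(fit), 0)
    if (all(is.finite(co))) trend <- co[1] + co[2] / mu
  }
  trend <- pmax(trend, 1e-6)
  raw <- pmax(a, 1e-6)
  raw[!is.finite(raw)] <- trend[!is.finite(raw)]
  exp((1 - shrink) * log(raw) + shrink * log(trend))
}

#' Negative-binomial Wald test for differential expression
#'
#' Two-group differential expression on raw counts: median-of-ratios
#' normalization, per-gene NB dispersion by method of moments with shrinkage
#' toward a fitted mean-dispersion trend, a Wald test on the log2 fold change
#' of group means (delta-method standard error, standard normal reference),
#' and Benjamini-Hochberg correction
#' across the tested genes. Genes below the minimum-count filter are excluded
#' from testing and from the BH family (their p values are NA).
#'
#' @param counts Genes x samples nonnegative integer matrix.
#' @param sheet Sample sheet tibble with a `sample_id` column and the
#'   grouping column.
#' @param contrast Length-2 character vector `c(group_a, group_b)`; the
#'   reported log2 fold change is `log2(mean_b / mean_a)`.
#' @param group Name of the sheet column holding the contrast labels
#'   (default `"breed"`); labels may also be `"breed:stage"` keys.
#' @param sf Optional precomputed size factors for the used samples.
#' @param min_total_count Genes with a smaller total raw count across the
#'   contrast samples are not tested (default 10).
#' @param dispersion_shrink Weight in `[0, 1]` pulling per-gene dispersions
#'   toward the trend (0 = raw method of moments, 1 = trend only).
#' @param pseudo_count Added to normalized group means before forming the
#'   fold change, stabilizing genes with zero means.
#' @return A tibble of class `de_result`, one row per input gene: `gene_id`,
#'   `base_mean`, `log2_fold_change`, `lfc_se`, `stat`, `p_value`,
#'   `p_adjust`, `tested`. The contrast and sample sizes are attached as
#'   attributes.
#' @export
de_test <- function(counts, sheet, contrast, group = "breed",
                    sf = NULL, min_total_count = 10,
                    dispersion_shrink = 0.8, pseudo_count = 0.5) {
  abort_if(length(contrast) != 2, "`contrast` must name two groups")
  labels <- if (group %in% names(sheet)) as.character(sheet[[group]])
            else group_key(sheet)
  if (!all(contrast %in% labels)) labels <- group_key(sheet)
  abort_if(!all(contrast %in% labels),
           "contrast group(s) %s absent from the sample sheet",
           paste(setdiff(contrast, labels), collapse = ", "))
  use <- labels %in% contrast
  sub <- counts[, sheet$sample_id[use], drop = FALSE]
  grp <- factor(labels[use], levels = contrast)
  abort_if(any(table(grp) < 2), "each contrast group needs >= 2 samples")

  sf <- sf %||% size_factors(sub)
  y <- sweep(sub, 2, sf, "/")
  tested <- rowSums(sub) >= min_total_count

  n_a <- sum(grp == contrast[1]); n_b <- sum(grp == contrast[2])
  ya <- y[, grp == contrast[1], drop = FALSE]
  yb <- y[, grp == contrast[2], drop = FALSE]
  m_a <- rowMeans(ya); m_b <- rowMeans(yb)
  base_mean <- rowMeans(y)

  disp <- rep(NA_real_, nrow(counts))
  disp[tested] <- estimate_dispersions(y[tested, , drop = FALSE],
                                       grp, sf, dispersion_shrink)

  # delta-method variance of log2 of a normalized group mean
  var_log2_mean <- function(m, sfs, a) {
    mu <- m + pseudo_count
    v <- (mu * mean(1 / sfs) + a * mu^2) / length(sfs)
    v / (mu^2 * log(2)^2)
  }
  lfc <- log2((m_b + pseudo_count) / (m_a + pseudo_count))
  se <- sqrt(var_log2_mean(m_a, sf[grp == contrast[1]], disp) +
             var_log2_mean(m_b, sf[grp == contrast[2]], disp))
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")

  out <- tibble::tibble(
    gene_id = rownames(counts) %||% sprintf("g%04d", seq_len(nrow(counts))),
    base_mean = base_mean,
    log2_fold_change = ifelse(tested, lfc, NA_real_),
    lfc_se = ifelse(tested, se, NA_real_),
    stat = ifelse(tested, stat, NA_real_),
    p_value = p,
    p_adjust = padj,
    tested = tested
  )
  structure(out, class = c("de_result", class(out)),
            contrast = contrast, n = c(n_a = n_a, n_b = n_b),
            size_factors = sf)
}

#' Significant genes from a differential-expression result
#'
#' @param de A `de_result` tibble.
#' @param alpha Adjusted-p cut (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 0, i.e.
#'   significance by adjusted p alone).
#' @return Character vector of significant gene ids.
#' @export
significant_genes <- function(de, alpha = 0.05, lfc_min = 0) {
  de$gene_id[!is.na(de$p_adjust) & de$p_adjust <= alpha &
               abs(de$log2_fold_change) >= lfc_min]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test (`P[X >= overlap]`) of a selected gene list
#' against each gene set, with BH correction across the tested sets. Sets are
#' intersected with the universe before testing; sets that become empty are
#' skipped with a note.
#'
#' @param selected Character vector of selected genes (must lie in
#'   `universe`).
#' @param gene_sets Named list of character vectors, or a GMT file path.
#' @param universe Character vector, the tested gene universe.
#' @return A tibble of class `enrichment_result`: `set_id`, `overlap_count`,
#'   `set_size`, `selected_size`, `universe_size`, `p_value`, `p_adjust`,
#'   `note`.
#' @export
#' @examples
#' u <- paste0("g", 1:10)
#' enrich_hypergeometric(u[1:4], list(s = u[1:5]), u)  # p = 5/210
enrich_hypergeometric <- function(selected, gene_sets, universe) {
  if (is.character(gene_sets) && length(gene_sets) == 1 && file.exists(gene_sets))
    gene_sets <- read_gmt(gene_sets)
  abort_if(length(universe) == 0, "empty universe")
  abort_if(length(selected) == 0, "empty selection")
  universe <- unique(universe)
  selected <- unique(selected)
  abort_if(!all(selected %in% universe), "`selected` must be a subset of `universe`")
  N <- length(universe); n <- length(selected)
  rows <- purrr::imap_dfr(gene_sets, function(set, id) {
    set <- intersect(unique(set), universe)
    K <- length(set)
    if (K == 0) {
      return(tibble::tibble(set_id = id, overlap_count = 0L, set_size = 0L,
                            selected_size = n, universe_size = N,
                            p_value = NA_real_,
                            note = "empty after universe intersection"))
    }
    k <- length(intersect(set, selected))
    tibble::tibble(set_id = id, overlap_count = k, set_size = K,
                   selected_size = n, universe_size = N,
                   p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   note = NA_character_)
  })
  rows$p_adjust <- NA_real_
  ok <- !is.na(rows$p_value)
  rows$p_adjust[ok] <- p.adjust(rows$p_value[ok], method = "BH")
  structure(dplyr::relocate(rows, "note", .after = "p_adjust"),
            class = c("enrichment_result", class(rows)))
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Stage-specific differentially expressed genes
#'
#' Given DE results for the same breed contrast at several stages, the
#' stage-specific set for a stage is the genes significant at that stage and
#' at no other stage — plain set algebra over the significance calls.
#'
#' @param de_by_stage Named list of `de_result` objects (names are stages).
#' @param alpha,lfc_min Significance rule, as in [significant_genes()].
#' @return A tibble: `stage`, `gene_id`, one row per stage-specific gene.
#' @export
stage_specific_degs <- function(de_by_stage, alpha = 0.05, lfc_min = 0) {
  abort_if(length(de_by_stage) < 2, "need DE results for >= 2 stages")
  universes <- lapply(de_by_stage, function(d) sort(d$gene_id))
  abort_if(!all(vapply(universes, identical, logical(1), universes[[1]])),
           "inconsistent gene universes across stages")
  sig <- lapply(de_by_stage, significant_genes, alpha = alpha, lfc_min = lfc_min)
  purrr::imap_dfr(sig, function(genes, stage) {
    others <- unlist(sig[setdiff(names(sig), stage)], use.names = FALSE)
    tibble::tibble(stage = stage, gene_id = sort(setdiff(genes, others)))
  })
}
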