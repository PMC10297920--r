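#' Co-expression analysis configuration
#'
#' @param soft_power Soft-threshold exponent beta applied to `|cor|`
#'   (unsigned network); must be >= 1. The value is user-set; no automatic
#'   scale-free fit is performed.
#' @param min_module_size Smallest cluster kept as a module; smaller clusters
#'   fall into the unassigned `"grey"` pool.
#' @param merge_height Eigengene-dissimilarity threshold below which modules
#'   are merged (default 0.25, i.e. eigengene correlation above 0.75).
#' @param cut_height Static cut height applied to the average-linkage
#'   dendrogram of TOM dissimilarity (default 0.95).
#' @param cv_filter Minimum coefficient of variation; genes below it are
#'   dropped before network construction (0 disables).
#' @return A list of class `coexpression_config`.
#' @export
coexpression_config <- function(soft_power = 6, min_module_size = 10,
                                merge_height = 0.25, cut_height = 0.95,
                                cv_filter = 0) {
  cfg <- list(soft_power = soft_power, min_module_size = min_module_size,
              merge_height = merge_height, cut_height = cut_height,
              cv_filter = cv_filter)
  viol <- validate_coexpression_config(cfg)
  abort_if(length(viol) > 0, paste(viol, collapse = "; "))
  structure(cfg, class = "coexpression_config")
}

validate_coexpression_config <- function(cfg) {
  v <- character()
  if (!is_scalar_number(cfg$soft_power) || cfg$soft_power < 1)
    v <- c(v, "soft_power must be >= 1")
  if (!is_scalar_number(cfg$merge_height) || cfg$merge_height <= 0 ||
      cfg$merge_height >= 1)
    v <- c(v, "merge_height must lie in (0, 1)")
  if (!is_scalar_number(cfg$min_module_size) || cfg$min_module_size < 1)
    v <- c(v, "min_module_size must be >= 1")
  if (!is_scalar_number(cfg$cut_height) || cfg$cut_height <= 0)
    v <- c(v, "cut_height must be positive")
  if (!is_scalar_number(cfg$cv_filter) || cfg$cv_filter < 0)
    v <- c(v, "cv_filter must be >= 0")
  v
}

#' Topological overlap matrix
#'
#' Unsigned TOM similarity of an adjacency matrix:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j`, and unit diagonal. Values lie
#' in `[0, 1]` and the matrix is symmetric.
#'
#' @param adjacency Symmetric gene x gene adjacency with entries in
#'   `[0, 1]` and unit diagonal.
#' @return TOM similarity matrix of the same dimension.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  k <- colSums(a)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

# WGCNA-style color labels for modules, by decreasing size
module_palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan")

module_eigengene <- function(expr_mod) {
  # expr_mod: genes x samples; eigengene = first PC over samples, unit
  # variance, sign-oriented so that the mean member correlation is positive
  x <- t(scale(t(expr_mod)))          # standardize genes
  x[!is.finite(x)] <- 0
  sv <- svd(t(x), nu = 1, nv = 0)
  me <- sv$u[, 1]
  cors <- cor(me, t(expr_mod))
  if (mean(cors, na.rm = TRUE) < 0) me <- -me
  as.numeric(scale(me))
}

#' Build co-expression modules
#'
#' A compact module-detection pipeline: optional CV filtering, unsigned
#' soft-thresholded adjacency `|cor|^beta`, topological overlap similarity,
#' average-linkage hierarchical clustering of TOM dissimilarity, a static cut
#' at `cut_height`, pruning of clusters below `min_module_size` into the
#' `"grey"` pool, module eigengenes (first principal component, unit
#' variance, sign-oriented to the members), and iterative merging of modules
#' whose eigengene correlation exceeds `1 - merge_height`. Modules are
#' labelled by the conventional color scheme in decreasing size order.
#'
#' @param expr Normalized expression matrix, genes x samples (>= 3 samples).
#' @param config A [coexpression_config()].
#' @param trait Optional per-sample trait vector (e.g. mean CSA); when given,
#'   module-trait correlations and per-gene GS are computed.
#' @return An object of class `coexpression_fit`: list with `genes` (tibble
#'   `gene_id`, `module`, `kme`, `gs`), `eigengenes` (samples x modules
#'   matrix), `module_sizes`, `trait_cor` (tibble or NULL), `config`,
#'   `tree` (the hclust object), `trait`.
#' @export
build_modules <- function(expr, config = coexpression_config(), trait = NULL) {
  expr <- as.matrix(expr)
  abort_if(ncol(expr) < 3, "co-expression needs at least 3 samples")
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
  if (config$cv_filter > 0) {
    cv <- apply(expr, 1, sd) / pmax(abs(rowMeans(expr)), .Machine$double.eps)
    expr <- expr[cv >= config$cv_filter, , drop = FALSE]
  }
  abort_if(nrow(expr) < 2, "fewer than 2 genes after filtering")
  keep <- apply(expr, 1, sd) > 0
  expr <- expr[keep, , drop = FALSE]

  a <- abs(cor(t(expr)))^config$soft_power
  diag(a) <- 1
  tom <- tom_similarity(a)
  tree <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(tree, h = min(config$cut_height, max(tree$height)))
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < config$min_module_size])
  module <- ifelse(cl %in% small, 0L, cl)

  # eigengenes + merge loop: merge the closest pair while above threshold
  repeat {
    ids <- sort(unique(module[module > 0]))
    if (length(ids) < 2) break
    me <- vapply(ids, function(k)
      module_eigengene(expr[module == k, , drop = FALSE]), numeric(ncol(expr)))
    cc <- cor(me)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - config$merge_height) break
    module[module == ids[best[2]]] <- ids[best[1]]
  }

  ids <- sort(unique(module[module > 0]))
  ord <- ids[order(-tabulate(factor(module, levels = ids)))]
  labels <- setNames(module_palette[seq_along(ord)], ord)
  mod_lab <- ifelse(module == 0, "grey", labels[as.character(module)])

  mods <- setdiff(unique(mod_lab), "grey")
  eig <- vapply(mods, function(m)
    module_eigengene(expr[mod_lab == m, , drop = FALSE]), numeric(ncol(expr)))
  eig <- matrix(eig, ncol = length(mods),
                dimnames = list(colnames(expr), mods))

  kme <- rep(NA_real_, nrow(expr))
  for (m in mods) {
    members <- mod_lab == m
    kme[members] <- as.numeric(cor(t(expr[members, , drop = FALSE]), eig[, m]))
  }
  gs <- if (!is.null(trait)) {
    abort_if(length(trait) != ncol(expr), "trait must align with samples")
    abort_if(sd(trait) == 0, "zero-variance trait")
    as.numeric(abs(cor(t(expr), trait)))
  } else rep(NA_real_, nrow(expr))

  fit <- structure(list(
    genes = tibble::tibble(gene_id = rownames(expr), module = mod_lab,
                           kme = kme, gs = gs),
    eigengenes = eig,
    module_sizes = sort(table(mod_lab), decreasing = TRUE),
    config = config, tree = tree, trait = trait,
    expr = expr
  ), class = "coexpression_fit")
  fit$trait_cor <- if (!is.null(trait)) module_trait_correlation(fit, trait)
  fit
}

#' @export
print.coexpression_fit <- function(x, ...) {
  cat(sprintf("<coexpression_fit> %d genes, %d modules (+grey)\n",
              nrow(x$genes), ncol(x$eigengenes)))
  print(x$module_sizes)
  invisible(x)
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p value) between each module eigengene
#' and a per-sample trait such as mean fiber CSA.
#'
#' @param fit A `coexpression_fit`.
#' @param trait Numeric per-sample trait vector.
#' @return A tibble: `module`, `r`, `p_value`, `n`.
#' @export
module_trait_correlation <- function(fit, trait) {
  abort_if(length(trait) != nrow(fit$eigengenes),
           "trait must have one value per sample")
  abort_if(sd(trait) == 0, "zero-variance trait")
  purrr::map_dfr(colnames(fit$eigengenes), function(m) {
    ct <- cor.test(fit$eigengenes[, m], trait)
    tibble::tibble(module = m, r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(trait))
  })
}

#' Hub-gene criteria
#'
#' @param kme_min Minimum module membership (correlation with the eigengene).
#' @param gs_min Minimum gene significance (absolute correlation with the
#'   trait).
#' @param ns_weight_min Optional network-screening-style q threshold; genes
#'   are kept when the BH q value of their gene-trait correlation test
#'   exceeds this value (the published rule's direction). `NULL` (default)
#'   disables the criterion.
#' @return A list of class `hub_criteria`.
#' @export
hub_criteria <- function(kme_min = 0.6, gs_min = 0.8, ns_weight_min = NULL) {
  abort_if(!is_scalar_number(kme_min) || !is_scalar_number(gs_min),
           "thresholds must be single numbers")
  structure(list(kme_min = kme_min, gs_min = gs_min,
                 ns_weight_min = ns_weight_min), class = "hub_criteria")
}

#' Hub genes of a module
#'
#' Hub genes are module members whose module membership (kME, the correlation
#' of the gene with the module eigengene) and gene significance (GS, the
#' absolute gene-trait correlation) both exceed their thresholds; an optional
#' network-screening-style q criterion can be enabled through
#' [hub_criteria()].
#'
#' @param fit A `coexpression_fit` built with a trait.
#' @param module Module label (e.g. `"turquoise"`).
#' @param criteria A [hub_criteria()].
#' @return Tibble of hub genes: `gene_id`, `module`, `kme`, `gs`
#'   (plus `q_gs` when the screening criterion is enabled).
#' @export
hub_genes <- function(fit, module, criteria = hub_criteria()) {
  abort_if(!module %in% fit$genes$module, "unknown module '%s'", module)
  members <- dplyr::filter(fit$genes, .data$module == !!module)
  abort_if(all(is.na(members$gs)),
           "fit has no trait; rebuild with `trait` to compute GS")
  sel <- members$kme > criteria$kme_min & members$gs > criteria$gs_min
  if (!is.null(criteria$ns_weight_min)) {
    n <- nrow(fit$eigengenes)
    tstat <- members$gs * sqrt((n - 2) / pmax(1 - members$gs^2, 1e-12))
    pv <- 2 * pt(-abs(tstat), df = n - 2)
    members$q_gs <- p.adjust(pv, "BH")
    sel <- sel & members$q_gs > criteria$ns_weight_min
  }
  members[sel & !is.na(sel), , drop = FALSE]
}

#' Row-wise score-trait correlation
#'
#' Correlates each row of a score matrix (e.g. per-pathway enrichment scores)
#' with a per-sample trait, by Spearman rank or Pearson correlation. Constant
#' rows are reported as missing with a note instead of failing.
#'
#' @param scores Numeric matrix, rows x samples.
#' @param trait Numeric vector, one value per sample (column).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble: `row_id`, `rho`, `p_value`, `note`.
#' @export
score_trait_correlation <- function(scores, trait,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  abort_if(ncol(scores) != length(trait), "trait must align with score columns")
  ids <- rownames(scores) %||% sprintf("row%04d", seq_len(nrow(scores)))
  purrr::map_dfr(seq_len(nrow(scores)), function(i) {
    x <- scores[i, ]
    if (sd(x) == 0) {
      return(tibble::tibble(row_id = ids[i], rho = NA_real_,
                            p_value = NA_real_, note = "constant row"))
    }
    ct <- suppressWarnings(cor.test(x, trait, method = method, exact = FALSE))
    tibble::tibble(row_id = ids[i], rho = unname(ct$estimate),
                   p_value = ct$p.value, note = NA_character_)
  })
}
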