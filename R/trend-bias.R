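#' Correct count-scale expression toward normality
#'
#' Quantile normalization across samples to a common reference distribution
#' (tied ranks averaged), optionally followed by per-gene standardization.
#' This is the usual "NB to normal" correction applied before trend
#' clustering and confidence-interval work on count-derived expression.
#'
#' @param expr Nonnegative expression matrix, genes x samples (>= 2 samples).
#' @param standardize Also z-score each gene across samples (default TRUE);
#'   genes constant after quantile normalization are set to 0.
#' @return Corrected matrix with the input's dimnames.
#' @export
normalize_to_normal <- function(expr, standardize = TRUE) {
  expr <- as.matrix(expr)
  abort_if(ncol(expr) < 2, "quantile normalization needs >= 2 samples")
  abort_if(any(expr < 0), "expression values must be nonnegative")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  if (standardize) {
    mu <- rowMeans(out)
    s <- apply(out, 1, sd)
    out <- (out - mu) / ifelse(s > 0, s, 1)
    out[s == 0, ] <- 0
  }
  dimnames(out) <- dimnames(expr)
  out
}

#' Fuzzy c-means clustering of expression trends
#'
#' Standard fuzzy c-means: minimizes
#' `sum_ij u_ij^m * ||x_i - c_j||^2` subject to each gene's memberships
#' summing to 1, with the usual update equations and the singularity rule
#' (a gene exactly on a center gets membership 1 there). Centers are seeded
#' by a k-means++-style farthest-point scheme from the given seed, so results
#' are deterministic.
#'
#' @param x Matrix, genes x timepoints (rows are usually standardized
#'   stage profiles).
#' @param c Number of clusters (>= 2, <= number of genes).
#' @param m Fuzzifier, > 1 (default 2).
#' @param seed Integer seed for center initialization.
#' @param tol Convergence tolerance on `max |U_new - U_old|`.
#' @param max_iter Iteration cap.
#' @return An object of class `fcm_fit`: list with `membership` (genes x
#'   clusters, rows sum to 1), `centers` (clusters x timepoints), `cluster`
#'   (hard assignment), `objective` (per-iteration trace), `m`, `converged`.
#' @export
fcm_cluster <- function(x, c = 6, m = 2, seed = 1, tol = 1e-6, max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  check_count(c, "c")
  abort_if(c < 2, "`c` must be >= 2")
  abort_if(c > n, "more clusters than genes")
  abort_if(!is_scalar_number(m) || m <= 1, "fuzzifier `m` must be > 1")

  centers <- withr::with_seed(seed, {
    # k-means++-style: first center at random, then rows far from chosen set
    ctr <- x[sample(n, 1), , drop = FALSE]
    while (nrow(ctr) < c) {
      d2 <- apply(x, 1, function(r) min(colSums((t(ctr) - r)^2)))
      probs <- d2 / sum(d2)
      ctr <- rbind(ctr, x[sample(n, 1, prob = probs), ])
    }
    ctr
  })

  u <- matrix(0, n, c)
  obj <- numeric(0)
  converged <- FALSE
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(c), function(j)
      rowSums(sweep(x, 2, centers[j, ])^2), numeric(n))
    d2 <- matrix(d2, n, c)
    zero <- d2 < .Machine$double.eps
    u_new <- 1 / (d2^(expo / 2) * rowSums((1 / d2)^(expo / 2)))
    if (any(zero)) {     # singularity rule: all mass on coincident centers
      zr <- which(rowSums(zero) > 0)
      u_new[zr, ] <- 0
      u_new[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    }
    obj <- c(obj, sum(u_new^m * d2))
    um <- u_new^m
    centers <- (t(um) %*% x) / colSums(um)
    if (max(abs(u_new - u)) < tol) { u <- u_new; converged <- TRUE; break }
    u <- u_new
  }
  dimnames(u) <- list(rownames(x), paste0("C", seq_len(c)))
  dimnames(centers) <- list(paste0("C", seq_len(c)), colnames(x))
  structure(list(membership = u, centers = centers,
                 cluster = max.col(u), objective = obj, m = m,
                 converged = converged),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> %d genes, %d clusters, m = %g, %s after %d iterations\n",
              nrow(x$membership), ncol(x$membership), x$m,
              if (x$converged) "converged" else "NOT converged",
              length(x$objective)))
  invisible(x)
}

#' Classify stage-trend patterns per breed and flag discordance
#'
#' For each breed, genes' stage-ordered profiles (standardized per gene) are
#' clustered into `c` fuzzy c-means trend patterns; each cluster gets the
#' sign of the Pearson correlation of its center with the breed's trait
#' trajectory (e.g. mean CSA per stage), and each gene inherits its cluster's
#' sign. A gene is flagged discordant when its sign in the reference breed
#' (the first list element, typically H) differs from its sign in any other
#' breed.
#'
#' @param trends_by_breed Named list of genes x stages matrices, identical
#'   gene sets and stage grids across breeds.
#' @param trait_by_breed Named list of per-stage trait vectors, same names
#'   and stage grid.
#' @param c,m,seed Clustering parameters, see [fcm_cluster()].
#' @return A tibble: `gene_id`, then per breed `cluster_<breed>` and
#'   `sign_<breed>`, plus a logical `discordant` column.
#' @export
classify_trend_patterns <- function(trends_by_breed, trait_by_breed,
                                    c = 6, m = 2, seed = 1) {
  breeds <- names(trends_by_breed)
  abort_if(is.null(breeds) || !setequal(breeds, names(trait_by_breed)),
           "trend and trait lists must share breed names")
  dims <- lapply(trends_by_breed, dim)
  abort_if(!all(vapply(dims, identical, logical(1), dims[[1]])),
           "breeds must share the same gene set and stage grid")
  stages <- ncol(trends_by_breed[[1]])
  abort_if(any(vapply(trait_by_breed, length, 1L) != stages),
           "trait trajectories must have one value per stage")

  res <- purrr::imap(trends_by_breed, function(mat, b) {
    z <- t(scale(t(mat)))
    z[!is.finite(z)] <- 0
    fit <- fcm_cluster(z, c = c, m = m, seed = seed)
    center_sign <- sign(as.numeric(cor(t(fit$centers), trait_by_breed[[b]])))
    list(cluster = fit$cluster, sign = center_sign[fit$cluster])
  })
  gene_ids <- rownames(trends_by_breed[[1]]) %||%
    sprintf("g%04d", seq_len(nrow(trends_by_breed[[1]])))
  out <- tibble::tibble(gene_id = gene_ids)
  for (b in breeds) {
    out[[paste0("cluster_", b)]] <- res[[b]]$cluster
    out[[paste0("sign_", b)]] <- res[[b]]$sign
  }
  ref <- res[[1]]$sign
  disc <- rep(FALSE, length(ref))
  for (b in breeds[-1]) disc <- disc | (res[[b]]$sign != ref)
  out$discordant <- disc
  out
}

#' Student-t confidence interval for a mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * s / sqrt(n)` — the classic one-sample
#' t interval. A constant sample gives a width-0 interval.
#'
#' @param values Numeric vector, n >= 2.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list of class `confidence_interval`: `mean`, `lower`, `upper`,
#'   `level`, `n`.
#' @export
#' @examples
#' confidence_interval(c(0, 2))  # half-width 12.706 (t quantile, 1 df)
confidence_interval <- function(values, level = 0.95) {
  abort_if(length(values) < 2, "confidence interval needs n >= 2")
  abort_if(!is_scalar_number(level) || level <= 0 || level >= 1,
           "`level` must lie in (0, 1)")
  n <- length(values)
  mu <- mean(values)
  half <- qt((1 + level) / 2, df = n - 1) * sd(values) / sqrt(n)
  structure(list(mean = mu, lower = mu - half, upper = mu + half,
                 level = level, n = n),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("%.0f%% CI: %.4g [%.4g, %.4g] (n = %d)\n",
              100 * x$level, x$mean, x$lower, x$upper, x$n))
  invisible(x)
}

ci_contains <- function(ci, x) x >= ci$lower && x <= ci$upper

#' Classify crossbred expression bias at one stage
#'
#' Compares the crossbred (HD) corrected expression against the parental
#' breeds' confidence intervals. In the default `"two_ci"` mode one t
#' interval is built per parental breed: HD inside only the D interval is
#' `toward_D`, inside only the H interval is `toward_H`, inside both is
#' `unbiased`, and outside both is assigned to the breed with the nearer
#' mean (`ambiguous` on a distance tie). In `"pooled_ci"` mode a single
#' interval from the pooled H+D values is used: inside is `unbiased`,
#' outside is biased toward the nearer breed mean.
#'
#' @param values_H,values_D Parental expression values at the stage
#'   (each n >= 2).
#' @param value_HD The HD value: the HD group mean, or a vector of HD
#'   animals, which is averaged (mean mode) or majority-voted per animal
#'   (see `per_animal`).
#' @param level Confidence level.
#' @param mode `"two_ci"` (default) or `"pooled_ci"`.
#' @param per_animal When `value_HD` is a vector: `FALSE` (default) compares
#'   the HD mean; `TRUE` classifies each HD animal and takes the majority
#'   call (ties -> `ambiguous`).
#' @param tol Relative tolerance for distance ties.
#' @return A list of class `bias_call`: `call` (one of `toward_D`,
#'   `toward_H`, `unbiased`, `ambiguous`), `hd_value`, `ci_H`, `ci_D`
#'   (`ci_pooled` in pooled mode), `mode`, `level`.
#' @export
call_bias <- function(values_H, values_D, value_HD, level = 0.95,
                      mode = c("two_ci", "pooled_ci"), per_animal = FALSE,
                      tol = 1e-8) {
  mode <- match.arg(mode)
  abort_if(length(values_H) < 2, "group H needs >= 2 values")
  abort_if(length(values_D) < 2, "group D needs >= 2 values")
  abort_if(length(value_HD) < 1, "missing HD value")

  if (per_animal && length(value_HD) > 1) {
    calls <- vapply(value_HD, function(v)
      call_bias(values_H, values_D, v, level, mode, FALSE, tol)$call,
      character(1))
    return(structure(list(call = majority_call(calls), hd_value = mean(value_HD),
                          per_animal_calls = calls, mode = mode, level = level),
                     class = "bias_call"))
  }
  hd <- mean(value_HD)
  mean_H <- mean(values_H); mean_D <- mean(values_D)
  nearer <- function() {
    dH <- abs(hd - mean_H); dD <- abs(hd - mean_D)
    scale <- max(abs(c(dH, dD, 1)))
    if (abs(dH - dD) <= tol * scale) "ambiguous"
    else if (dD < dH) "toward_D" else "toward_H"
  }
  if (mode == "two_ci") {
    ci_H <- confidence_interval(values_H, level)
    ci_D <- confidence_interval(values_D, level)
    inH <- ci_contains(ci_H, hd); inD <- ci_contains(ci_D, hd)
    call <- if (inH && inD) "unbiased"
            else if (inD) "toward_D"
            else if (inH) "toward_H"
            else nearer()
    structure(list(call = call, hd_value = hd, ci_H = ci_H, ci_D = ci_D,
                   mode = mode, level = level), class = "bias_call")
  } else {
    ci_p <- confidence_interval(c(values_H, values_D), level)
    call <- if (ci_contains(ci_p, hd)) "unbiased" else nearer()
    structure(list(call = call, hd_value = hd, ci_pooled = ci_p,
                   mode = mode, level = level), class = "bias_call")
  }
}

majority_call <- function(calls) {
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
}

#' @export
print.bias_call <- function(x, ...) {
  cat(sprintf("<bias_call> %s (HD = %.4g, mode %s, level %.2f)\n",
              x$call, x$hd_value, x$mode, x$level))
  invisible(x)
}

#' Bias calls for every gene and stage
#'
#' Applies [call_bias()] gene by gene and stage by stage to a corrected
#' expression matrix, then aggregates each gene's per-stage calls into an
#' overall call by majority (ties, including all-stage disagreement,
#' give `ambiguous`; stages called `ambiguous` are counted like any other
#' category).
#'
#' @param corrected Corrected expression matrix (genes x samples), e.g. from
#'   [normalize_to_normal()].
#' @param sheet Sample sheet aligned with the matrix columns.
#' @param genes Genes to call (default all rows).
#' @param level,mode,per_animal See [call_bias()].
#' @return A list of class `bias_calls`: `by_stage` (tibble `gene_id`,
#'   `stage`, `call`, `hd_value`, `ci_H_lower`, `ci_H_upper`, `ci_D_lower`,
#'   `ci_D_upper`) and `overall` (tibble `gene_id`, `call`).
#' @export
call_bias_table <- function(corrected, sheet, genes = rownames(corrected),
                            level = 0.95, mode = "two_ci",
                            per_animal = FALSE) {
  abort_if(!all(c("H", "D", "HD") %in% sheet$breed),
           "sheet must contain breeds H, D and HD")
  stages <- levels(sheet$stage) %||% unique(as.character(sheet$stage))
  genes <- intersect(genes, rownames(corrected))
  abort_if(length(genes) == 0, "no requested genes found in the matrix")
  by_stage <- purrr::map_dfr(stages, function(st) {
    sH <- sheet$sample_id[sheet$breed == "H" & sheet$stage == st]
    sD <- sheet$sample_id[sheet$breed == "D" & sheet$stage == st]
    sHD <- sheet$sample_id[sheet$breed == "HD" & sheet$stage == st]
    abort_if(length(sH) < 2, "breed H needs >= 2 replicates at stage %s", st)
    abort_if(length(sD) < 2, "breed D needs >= 2 replicates at stage %s", st)
    abort_if(length(sHD) < 1, "breed HD missing at stage %s", st)
    purrr::map_dfr(genes, function(g) {
      bc <- call_bias(corrected[g, sH], corrected[g, sD], corrected[g, sHD],
                      level = level, mode = mode, per_animal = per_animal)
      tibble::tibble(
        gene_id = g, stage = st, call = bc$call, hd_value = bc$hd_value,
        ci_H_lower = bc$ci_H$lower %||% NA_real_,
        ci_H_upper = bc$ci_H$upper %||% NA_real_,
        ci_D_lower = bc$ci_D$lower %||% NA_real_,
        ci_D_upper = bc$ci_D$upper %||% NA_real_)
    })
  })
  overall <- dplyr::summarise(dplyr::group_by(by_stage, .data$gene_id),
                              call = majority_call(.data$call), .groups = "drop")
  structure(list(by_stage = by_stage, overall = overall,
                 level = level, mode = mode),
            class = "bias_calls")
}

#' @export
print.bias_calls <- function(x, ...) {
  cat(sprintf("<bias_calls> %d genes x %d stages (mode %s, level %.2f)\n",
              length(unique(x$by_stage$gene_id)),
              length(unique(x$by_stage$stage)), x$mode, x$level))
  print(table(x$overall$call))
  invisible(x)
}

#' Candidate hypertrophy genes by set intersection
#'
#' Intersects a DEG list (or union of several DEG lists) with the gene set of
#' a chosen co-expression module — or with that module's hub genes — exactly
#' the screening step used to nominate hypertrophy candidates. The output is
#' sorted, hence order-stable.
#'
#' @param degs Character vector of DEG ids, or a list of vectors whose union
#'   is used.
#' @param fit A `coexpression_fit`.
#' @param module Module label whose genes are intersected.
#' @param hubs_only Restrict the module side to hub genes under `criteria`.
#' @param criteria A [hub_criteria()], used when `hubs_only = TRUE`.
#' @return Sorted character vector of candidate gene ids.
#' @export
hypertrophy_gene_screen <- function(degs, fit, module, hubs_only = FALSE,
                                    criteria = hub_criteria()) {
  if (is.list(degs)) degs <- unique(unlist(degs, use.names = FALSE))
  abort_if(!module %in% fit$genes$module, "unknown module '%s'", module)
  pool <- if (hubs_only) hub_genes(fit, module, criteria)$gene_id
          else fit$genes$gene_id[fit$genes$module == module]
  sort(intersect(degs, pool))
}
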