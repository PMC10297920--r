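#' Sample sheet for the three-breed, four-stage design
#'
#' Builds the default experimental layout used throughout the package: Hu
#' sheep (H), Dorper (D) and their binary cross (HD, Hu dam x Dorper sire)
#' sampled at 3 days (D3) and 3, 6 and 12 months (M3, M6, M12). The default
#' replicate numbers match a typical small-flock design (H: 6, HD: 5, D: 3
#' animals per stage).
#'
#' @param n_H,n_HD,n_D Replicates per stage for each breed.
#' @param stages Ordered character vector of developmental stages.
#' @return A tibble with columns `sample_id`, `breed`, `stage`, `replicate`.
#' @export
#' @examples
#' sheep_sample_sheet(n_H = 2, n_HD = 2, n_D = 2, stages = c("D3", "M3"))
sheep_sample_sheet <- function(n_H = 6, n_HD = 5, n_D = 3,
                               stages = c("D3", "M3", "M6", "M12")) {
  breeds <- c(H = n_H, HD = n_HD, D = n_D)
  out <- tidyr::expand_grid(
    stage = factor(stages, levels = stages),
    breed = names(breeds)
  )
  out <- tidyr::uncount(out, weights = breeds[out$breed])
  out <- dplyr::group_by(out, .data$stage, .data$breed)
  out <- dplyr::mutate(out, replicate = dplyr::row_number())
  out <- dplyr::ungroup(out)
  dplyr::transmute(out,
    sample_id = paste(.data$breed, .data$replicate, .data$stage, sep = "_"),
    breed = .data$breed, stage = .data$stage, replicate = .data$replicate)
}

group_key <- function(sheet) paste(sheet$breed, sheet$stage, sep = ":")

# samples matched by a planted "group" label: breed, stage, or breed:stage
match_group <- function(sheet, group) {
  key <- group_key(sheet)
  hit <- key == group | sheet$breed == group | as.character(sheet$stage) == group
  abort_if(!any(hit), "planted group '%s' matches no samples in the sheet", group)
  hit
}

# k mutually orthogonal, centered, unit-sd latent profiles over n samples
# (Gram-Schmidt; centering is preserved because all vectors have mean 0)
orthogonal_profiles <- function(k, n) {
  abort_if(k >= n, "need more samples than planted modules for distinct profiles")
  z <- matrix(rnorm(k * n), k, n)
  z <- z - rowMeans(z)
  for (i in seq_len(k)) {
    if (i > 1) for (j in seq_len(i - 1))
      z[i, ] <- z[i, ] - sum(z[i, ] * z[j, ]) / sum(z[j, ]^2) * z[j, ]
    z[i, ] <- z[i, ] / sd(z[i, ])
  }
  z
}

# six canonical stage-trend shapes (rows), standardized scale, for 4 stages
trend_shapes <- function(stages) {
  n <- length(stages)
  abort_if(n < 3, "trend shapes need at least 3 stages")
  t <- seq(-1, 1, length.out = n)
  shapes <- rbind(
    up        = t,
    down      = -t,
    mid_peak  = 1 - 2 * t^2,
    mid_dip   = 2 * t^2 - 1,
    early_peak = -sin(pi * (t + 1) / 2) * sign(t) - 0.5 * t,
    late_peak  = sin(pi * (t + 1) / 2) * sign(t) + 0.5 * t
  )
  shapes <- shapes / apply(abs(shapes), 1, max)
  colnames(shapes) <- stages
  shapes
}

#' Simulate a negative-binomial count matrix with planted structure
#'
#' Generates raw RNA-seq-like counts for a gene x sample design with known
#' ground truth for every downstream analysis: per-sample depth factors,
#' planted differential expression, planted co-expression modules (genes
#' sharing a latent per-sample profile), planted stage-trend patterns, and
#' planted crossbred-bias scenarios in which the HD group mean tracks the D
#' mean (`toward_D`), the H mean (`toward_H`), sits between them
#' (`intermediate`), or carries no breed effect at all (`unbiased`).
#'
#' Counts are NB(mu, dispersion) with `Var = mu + dispersion * mu^2` and
#' `mu = depth_factor(sample) * baseline(gene) * 2^(planted log2 effects)`.
#'
#' @param n_genes Number of genes.
#' @param sheet Sample sheet, as from [sheep_sample_sheet()].
#' @param baseline Optional per-gene baseline means; defaults to log-normal
#'   draws (median 100).
#' @param depth_factors Optional per-sample positive depth factors
#'   (default all 1).
#' @param nb_dispersion NB dispersion; 0 gives Poisson counts.
#' @param planted_de Tibble `gene`, `group`, `log2fc`: gene `gene` gets its
#'   mean multiplied by `2^log2fc` in the samples of `group` (a breed, a
#'   stage, or `"breed:stage"`).
#' @param planted_modules List of module descriptors
#'   `list(genes =, amplitude =)`; each module draws one latent N(0,1)
#'   profile over samples, added (times `amplitude`) to members' log2 means.
#' @param planted_trends Tibble `gene`, `pattern` (1-6), `amplitude`: adds
#'   one of six canonical stage-trend shapes to the gene's log2 mean.
#' @param planted_bias Tibble `gene`, `scenario` in
#'   `c("toward_D", "toward_H", "intermediate", "unbiased")`; `bias_lfc` is
#'   the H-to-D log2 separation used for the biased scenarios.
#' @param bias_lfc Log2 separation between the parental breeds for planted
#'   bias genes.
#' @param seed Integer seed; output is deterministic given the spec and seed.
#'
#' @return A list of class `sim_counts`: `counts` (integer matrix, genes x
#'   samples, dimnames set), `sheet`, and `truth` (list of tibbles
#'   `de`, `modules`, `trends`, `bias`, plus `baseline`, `depth_factors`,
#'   `module_profiles`, `trend_shapes`, and the full log2 `effects` matrix).
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 50, sheet = sheep_sample_sheet(2, 2, 2),
#'                        seed = 1)
#' dim(sim$counts)
simulate_counts <- function(n_genes = 2000,
                            sheet = sheep_sample_sheet(),
                            baseline = NULL,
                            depth_factors = NULL,
                            nb_dispersion = 0.05,
                            planted_de = NULL,
                            planted_modules = NULL,
                            planted_trends = NULL,
                            planted_bias = NULL,
                            bias_lfc = 2,
                            seed = 1) {
  check_count(n_genes, "n_genes")
  abort_if(!is_scalar_number(nb_dispersion) || nb_dispersion < 0,
           "`nb_dispersion` must be >= 0")
  n_s <- nrow(sheet)
  depth_factors <- depth_factors %||% rep(1, n_s)
  abort_if(length(depth_factors) != n_s || any(depth_factors <= 0),
           "`depth_factors` must be one positive value per sample")
  check_planted_genes <- function(g, what) {
    abort_if(any(g < 1 | g > n_genes | g != round(g)),
             "%s refers to gene indices outside 1..%d", what, n_genes)
  }
  if (!is.null(planted_bias)) {
    reps <- table(sheet$breed, sheet$stage)
    abort_if(any(reps < 2),
             "planted_bias needs >= 2 replicates in every breed x stage group (confidence intervals need n >= 2)")
  }

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  stages <- levels(sheet$stage) %||% unique(as.character(sheet$stage))

  withr::with_seed(seed, {
    baseline <- baseline %||% rlnorm(n_genes, meanlog = log(100), sdlog = 1.2)
    abort_if(length(baseline) != n_genes || any(baseline <= 0),
             "`baseline` must be one positive mean per gene")
    eff <- matrix(0, n_genes, n_s)  # log2 effects

    if (!is.null(planted_de)) {
      check_planted_genes(planted_de$gene, "planted_de")
      for (i in seq_len(nrow(planted_de))) {
        hit <- match_group(sheet, planted_de$group[i])
        eff[planted_de$gene[i], hit] <- eff[planted_de$gene[i], hit] +
          planted_de$log2fc[i]
      }
    }

    module_profiles <- NULL
    modules_truth <- NULL
    if (!is.null(planted_modules)) {
      all_genes <- unlist(lapply(planted_modules, `[[`, "genes"))
      check_planted_genes(all_genes, "planted_modules")
      abort_if(anyDuplicated(all_genes) > 0,
               "planted modules must be disjoint gene sets")
      modules_truth <- purrr::imap_dfr(planted_modules, function(m, k) {
        tibble::tibble(gene = m$genes, module = k)
      })
      module_profiles <- orthogonal_profiles(length(planted_modules), n_s)
      for (k in seq_along(planted_modules)) {
        z <- module_profiles[k, ]
        amp <- planted_modules[[k]]$amplitude %||% 1
        g <- planted_modules[[k]]$genes
        eff[g, ] <- eff[g, , drop = FALSE] + amp * matrix(z, length(g), n_s, byrow = TRUE)
      }
    }

    shp <- if (length(stages) >= 3) trend_shapes(stages)
    if (!is.null(planted_trends)) {
      abort_if(is.null(shp), "planted trends need at least 3 stages")
      check_planted_genes(planted_trends$gene, "planted_trends")
      abort_if(any(!planted_trends$pattern %in% seq_len(nrow(shp))),
               "trend `pattern` must be in 1..%d", nrow(shp))
      stage_idx <- match(as.character(sheet$stage), stages)
      amp <- planted_trends$amplitude %||% rep(1, nrow(planted_trends))
      for (i in seq_len(nrow(planted_trends))) {
        eff[planted_trends$gene[i], ] <-
          eff[planted_trends$gene[i], ] + amp[i] * shp[planted_trends$pattern[i], stage_idx]
      }
    }

    if (!is.null(planted_bias)) {
      check_planted_genes(planted_bias$gene, "planted_bias")
      hd_off <- c(toward_D = bias_lfc, toward_H = 0,
                  intermediate = bias_lfc / 2, unbiased = 0)
      abort_if(any(!planted_bias$scenario %in% names(hd_off)),
               "unknown bias scenario")
      for (i in seq_len(nrow(planted_bias))) {
        g <- planted_bias$gene[i]; sc <- planted_bias$scenario[i]
        if (sc == "unbiased") next  # no breed effect at all
        eff[g, sheet$breed == "D"] <- eff[g, sheet$breed == "D"] + bias_lfc
        eff[g, sheet$breed == "HD"] <- eff[g, sheet$breed == "HD"] + hd_off[[sc]]
      }
    }

    mu <- baseline * 2^eff * rep(depth_factors, each = n_genes)
    counts <- if (nb_dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), n_genes, n_s)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion), n_genes, n_s)
    }
  })

  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sheet$sample_id)
  truth <- list(
    baseline = setNames(baseline, gene_ids),
    depth_factors = setNames(depth_factors, sheet$sample_id),
    de = if (!is.null(planted_de))
      dplyr::mutate(planted_de, gene_id = gene_ids[.data$gene]),
    modules = if (!is.null(modules_truth))
      dplyr::mutate(modules_truth, gene_id = gene_ids[.data$gene]),
    module_profiles = module_profiles,
    trends = if (!is.null(planted_trends))
      dplyr::mutate(planted_trends, gene_id = gene_ids[.data$gene]),
    trend_shapes = shp,
    bias = if (!is.null(planted_bias))
      dplyr::mutate(planted_bias, gene_id = gene_ids[.data$gene]),
    effects = eff
  )
  structure(list(counts = counts, sheet = sheet, truth = truth,
                 params = list(n_genes = n_genes, nb_dispersion = nb_dispersion,
                               bias_lfc = bias_lfc, seed = seed)),
            class = "sim_counts")
}

#' Simulate a Gaussian expression matrix with planted co-expression modules
#'
#' A light generator for testing the co-expression machinery directly:
#' each planted module shares one latent per-sample profile; member genes are
#' the profile plus independent Gaussian noise, background genes are pure
#' noise. Returned values are already on the normalized (log-like) scale.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module.
#' @param n_background Pure-noise genes.
#' @param n_samples Number of samples.
#' @param noise_sd Within-module residual standard deviation (the latent
#'   profile has unit variance).
#' @param seed Integer seed.
#' @return List: `expr` (genes x samples), `truth` (tibble `gene_id`,
#'   `module`; background genes have module `"none"`), `profiles`
#'   (modules x samples latent matrix).
#' @export
simulate_module_expression <- function(n_modules = 3, module_size = 50,
                                       n_background = 50, n_samples = 12,
                                       noise_sd = 0.3, seed = 1) {
  n_genes <- n_modules * module_size + n_background
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    profiles <- orthogonal_profiles(n_modules, n_samples)
    expr <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes, n_samples)
    module <- rep("none", n_genes)
    for (k in seq_len(n_modules)) {
      g <- (k - 1) * module_size + seq_len(module_size)
      expr[g, ] <- expr[g, ] + matrix(profiles[k, ], module_size, n_samples, byrow = TRUE)
      module[g] <- paste0("M", k)
    }
    bg <- module == "none"
    expr[bg, ] <- expr[bg, ] * (1 / noise_sd)  # unit-variance background noise
  })
  dimnames(expr) <- list(gene_ids, sprintf("s%02d", seq_len(n_samples)))
  list(expr = expr,
       truth = tibble::tibble(gene_id = gene_ids, module = module),
       profiles = profiles)
}

#' Write simulated counts to disk
#'
#' Writes the count matrix (genes in rows, tab-separated, header of sample
#' ids) and the sample sheet as TSV files.
#'
#' @param sim A `sim_counts` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_counts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "counts.tsv")
  spath <- file.path(dir, "sample_sheet.tsv")
  write.table(data.frame(gene_id = rownames(sim$counts), sim$counts,
                         check.names = FALSE),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$sheet, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cpath, sheet = spath))
}

#' Read a count matrix and sample sheet from TSV
#'
#' @param counts_path TSV with a `gene_id` first column and one column per
#'   sample.
#' @param sheet_path TSV with columns `sample_id`, `breed`, `stage`,
#'   `replicate`.
#' @param stages Stage ordering applied to the sheet's `stage` column.
#' @return List with `counts` (integer matrix) and `sheet` (tibble).
#' @export
read_counts <- function(counts_path, sheet_path,
                        stages = c("D3", "M3", "M6", "M12")) {
  df <- read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  sheet <- tibble::as_tibble(read.delim(sheet_path))
  sheet$stage <- factor(sheet$stage, levels = intersect(stages, sheet$stage))
  abort_if(!setequal(colnames(counts), sheet$sample_id) ||
             anyDuplicated(sheet$sample_id) > 0,
           "sample sheet ids must match count matrix columns exactly")
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  list(counts = counts, sheet = sheet)
}
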