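# Pretreatment of feature-by-sample abundance tables and two-group
# differential analysis. Tables are tibbles whose first column(s) identify
# the feature and whose remaining columns are samples; `NA` marks a
# missing value.

# Split an abundance tibble into id columns and a numeric feature x sample
# matrix. Id columns are every non-numeric leading column (at least the
# first column).
abundance_parts <- function(table) {
  table <- tibble::as_tibble(table)
  if (ncol(table) < 2) stop_input("abundance table needs sample columns")
  is_id <- !vapply(table, is.numeric, logical(1))
  is_id[1] <- TRUE
  # id columns must be a leading block
  first_num <- match(FALSE, is_id, nomatch = ncol(table) + 1)
  is_id[seq_along(is_id) >= first_num] <- FALSE
  ids <- table[, is_id, drop = FALSE]
  mat <- as.matrix(table[, !is_id, drop = FALSE])
  if (!is.numeric(mat)) stop_input("sample columns must be numeric")
  fid <- as.character(ids[[1]])
  if (anyDuplicated(fid)) stop_input("duplicate feature ids")
  if (anyDuplicated(colnames(mat))) stop_input("duplicate sample ids")
  rownames(mat) <- fid
  if (any(is.finite(mat) & mat < 0))
    stop_input("abundance values must be non-negative")
  list(ids = ids, mat = mat)
}

abundance_rebuild <- function(ids, mat) {
  dplyr::bind_cols(ids, tibble::as_tibble(mat))
}

#' Impute missing values in an abundance table
#'
#' Four imputation strategies for left-censored metabolomics intensities:
#'
#' * `min`: replace each feature's missing cells with the feature's
#'   observed minimum (or half of it with `half_min = TRUE`) — the
#'   assumption being that values are missing because they fell below the
#'   detection limit.
#' * `knn`: feature-wise k-nearest-neighbour imputation; neighbours are
#'   features, distance is Euclidean over the samples observed in both
#'   features (scaled to a per-sample average), and a missing cell is the
#'   mean of the k nearest features observed in that sample.
#' * `rf`: iterative random-forest imputation ([ranger::ranger()]),
#'   initialized with the minimum rule and refined for `iterations`
#'   rounds; seeded and deterministic.
#' * `qrilc`: quantile-regression imputation of left-censored data — the
#'   observed values of each feature are treated as the upper tail of a
#'   normal distribution, mean and sd are recovered by regressing observed
#'   order statistics on standard-normal quantiles, and the missing cells
#'   receive the fitted sub-detection quantile values (randomly assigned
#'   to cells, seeded).
#'
#' Observed values are never altered. Features with no observed value at
#' all are dropped with a warning.
#'
#' @param table abundance tibble (first column feature id, then samples).
#' @param method one of `"min"`, `"knn"`, `"rf"`, `"qrilc"`.
#' @param seed integer seed for the stochastic methods.
#' @param k number of neighbour features for `knn`.
#' @param half_min for `min`: impute half the observed minimum.
#' @param iterations refinement rounds for `rf`.
#' @return the table with no missing values (dropped features removed).
#' @export
impute_missing <- function(table, method = c("min", "knn", "rf", "qrilc"),
                           seed = 1L, k = 5L, half_min = FALSE,
                           iterations = 2L) {
  method <- match.arg(method)
  parts <- abundance_parts(table)
  mat <- parts$mat
  all_missing <- rowSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " feature(s) with no observed values", call. = FALSE)
    mat <- mat[!all_missing, , drop = FALSE]
    parts$ids <- parts$ids[!all_missing, , drop = FALSE]
  }
  if (!anyNA(mat)) return(abundance_rebuild(parts$ids, mat))
  imputed <- switch(method,
                    min = impute_min(mat, half_min),
                    knn = impute_knn(mat, k),
                    rf = with_seed(seed, impute_rf(mat, seed, iterations)),
                    qrilc = with_seed(seed, impute_qrilc(mat)))
  stopifnot(!anyNA(imputed))
  abundance_rebuild(parts$ids, imputed)
}

impute_min <- function(mat, half_min) {
  mins <- apply(mat, 1, min, na.rm = TRUE)
  if (half_min) mins <- mins / 2
  idx <- which(is.na(mat), arr.ind = TRUE)
  mat[idx] <- mins[idx[, 1]]
  mat
}

impute_knn <- function(mat, k) {
  out <- mat
  n_feat <- nrow(mat)
  for (f in which(rowSums(is.na(mat)) > 0)) {
    target <- mat[f, ]
    d <- vapply(seq_len(n_feat), function(g) {
      if (g == f) return(Inf)
      shared <- !is.na(target) & !is.na(mat[g, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((target[shared] - mat[g, shared])^2))
    }, numeric(1))
    ord <- order(d, seq_len(n_feat))          # deterministic tie-break
    for (s in which(is.na(target))) {
      donors <- ord[!is.na(mat[ord, s]) & is.finite(d[ord])]
      donors <- donors[seq_len(min(k, length(donors)))]
      out[f, s] <- if (length(donors) > 0) mean(mat[donors, s])
      else min(target, na.rm = TRUE)          # isolated feature fallback
    }
  }
  out
}

impute_rf <- function(mat, seed, iterations) {
  out <- impute_min(mat, half_min = FALSE)
  miss <- is.na(mat)
  # predictors are the other features; cases are samples
  for (it in seq_len(iterations)) {
    for (f in which(rowSums(miss) > 0)) {
      df <- as.data.frame(t(out))
      names(df) <- paste0("f", seq_len(nrow(out)))
      obs <- !miss[f, ]
      fit <- ranger::ranger(
        x = df[obs, -f, drop = FALSE], y = out[f, obs],
        num.trees = 100, seed = seed + it, num.threads = 1)
      pred <- stats::predict(fit, df[!obs, -f, drop = FALSE],
                             num.threads = 1)$predictions
      out[f, !obs] <- pmax(pred, 0)
    }
  }
  out
}

impute_qrilc <- function(mat) {
  out <- mat
  n <- ncol(mat)
  for (f in which(rowSums(is.na(mat)) > 0)) {
    obs <- sort(mat[f, !is.na(mat[f, ])])
    n_miss <- sum(is.na(mat[f, ]))
    # observed values occupy the upper ranks of the censored normal
    p_obs <- (n_miss + seq_along(obs) - 0.5) / n
    q_obs <- stats::qnorm(p_obs)
    if (length(obs) >= 2 && stats::sd(obs) > 0) {
      fit <- stats::lm(obs ~ q_obs)
      mu <- stats::coef(fit)[1]
      sigma <- max(stats::coef(fit)[2], 0)
    } else {
      mu <- obs[1]
      sigma <- 0
    }
    p_miss <- (seq_len(n_miss) - 0.5) / n
    draws <- pmax(mu + sigma * stats::qnorm(p_miss), 0)
    cells <- which(is.na(mat[f, ]))
    out[f, cells] <- draws[sample.int(n_miss)]
  }
  out
}

#' Normalize an abundance table
#'
#' * `log`: elementwise `log10(x + pseudo_count)`. The default
#'   pseudo-count is half the smallest non-zero value in the table when
#'   zeros are present, 0 otherwise.
#' * `percentage`: per-sample total-sum scaling; each sample column is
#'   rescaled to sum to 100, turning abundances into relative percentages.
#'
#' @param table abundance tibble with no missing values
#'   (run [impute_missing()] first).
#' @param method `"log"` or `"percentage"`.
#' @param pseudo_count pseudo-count for `log`; `NULL` for the default rule.
#' @return the normalized table.
#' @export
normalize_abundance <- function(table, method = c("log", "percentage"),
                                pseudo_count = NULL) {
  method <- match.arg(method)
  parts <- abundance_parts(table)
  mat <- parts$mat
  if (anyNA(mat)) stop_input("normalize requires a complete table; impute first")
  if (method == "log") {
    if (is.null(pseudo_count)) {
      pseudo_count <- if (any(mat == 0)) min(mat[mat > 0]) / 2 else 0
    }
    if (any(mat + pseudo_count <= 0))
      stop_input("log normalization needs a positive pseudo-count for zeros")
    mat <- log10(mat + pseudo_count)
  } else {
    sums <- colSums(mat)
    if (any(sums == 0))
      stop_input("all-zero sample column(s): ",
                 paste(colnames(mat)[sums == 0], collapse = ", "))
    mat <- sweep(mat, 2, sums, "/") * 100
  }
  abundance_rebuild(parts$ids, mat)
}

#' Read an abundance table or sample-information table
#'
#' @param path TSV or CSV file; the delimiter is inferred from the
#'   extension (`.csv` vs anything else). Empty cells and `"NA"` are
#'   missing values.
#' @param n_id_cols number of leading identifier columns to keep as
#'   character (1 for taxa tables, 3 for metabolite tables with
#'   name/kegg_id/hmdb_id).
#' @return a tibble.
#' @export
read_abundance <- function(path, n_id_cols = 1) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::read_csv else readr::read_tsv
  tbl <- reader(path, col_types = readr::cols(), progress = FALSE,
                show_col_types = FALSE)
  for (i in seq_len(n_id_cols)) tbl[[i]] <- as.character(tbl[[i]])
  tbl
}

#' @rdname read_abundance
#' @export
read_sample_info <- function(path) {
  tbl <- read_abundance(path, n_id_cols = 1)
  names(tbl)[1:2] <- c("sample_id", "group")
  tbl$group <- as.character(tbl$group)
  tbl
}

check_sample_info <- function(mat, sample_info) {
  sample_info <- tibble::as_tibble(sample_info)
  if (!all(c("sample_id", "group") %in% names(sample_info)))
    stop_input("sample_info needs columns sample_id and group")
  missing_s <- setdiff(colnames(mat), sample_info$sample_id)
  if (length(missing_s) > 0)
    stop_input("samples without group labels: ",
               paste(missing_s, collapse = ", "))
  sample_info <- sample_info[sample_info$sample_id %in% colnames(mat), ]
  groups <- unique(sample_info$group)
  if (length(groups) != 2)
    stop_input("differential analysis needs exactly two groups, got ",
               length(groups))
  sizes <- table(sample_info$group)
  if (any(sizes < 2))
    stop_input("each group needs at least 2 samples")
  list(info = sample_info, groups = groups)
}

#' Two-group differential analysis
#'
#' Tests every feature for a location difference between the two groups in
#' `sample_info`. The default test is the two-sided Mann-Whitney U
#' (Wilcoxon rank-sum, normal approximation), which is robust for both
#' metabolite intensities and relative abundances; Welch's t-test is
#' available. The effect size is the log2 fold change of group means
#' (group2, the "case", over group1, the "control", in the order groups
#' first appear in `sample_info`); direction follows its sign, with ties
#' reported as `"up"` by convention. Features constant across all samples
#' are degenerate: p = 1, effect = 0, never significant.
#'
#' @param table complete abundance tibble.
#' @param sample_info tibble `sample_id`, `group` (exactly two groups,
#'   each with >= 2 samples).
#' @param test `"mannwhitney"` or `"ttest"`.
#' @param alpha significance level applied to `p_value`
#'   (or to `p_adj` when `adjust = "BH"`).
#' @param adjust `"none"` (raw p thresholding, the default) or `"BH"`.
#' @return tibble of class `differential_result`: `feature_id`, `p_value`,
#'   `p_adj`, `effect`, `direction`, `significant`, `degenerate`. The
#'   group order used is attached as attribute `"groups"`.
#' @export
differential_analysis <- function(table, sample_info,
                                  test = c("mannwhitney", "ttest"),
                                  alpha = 0.05,
                                  adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  parts <- abundance_parts(table)
  mat <- parts$mat
  if (anyNA(mat)) stop_input("differential analysis requires a complete table")
  chk <- check_sample_info(mat, sample_info)
  g1 <- chk$info$sample_id[chk$info$group == chk$groups[1]]
  g2 <- chk$info$sample_id[chk$info$group == chk$groups[2]]
  res <- purrr::map(seq_len(nrow(mat)), function(f) {
    x1 <- mat[f, g1]
    x2 <- mat[f, g2]
    if (stats::sd(c(x1, x2)) == 0)
      return(list(p = 1, effect = 0, degenerate = TRUE))
    p <- if (test == "mannwhitney") {
      suppressWarnings(stats::wilcox.test(x2, x1, exact = FALSE)$p.value)
    } else {
      tryCatch(stats::t.test(x2, x1)$p.value, error = function(e) 1)
    }
    m1 <- mean(x1)
    m2 <- mean(x2)
    effect <- if (m1 == m2) 0
    else if (m1 == 0) Inf
    else if (m2 == 0) -Inf
    else log2(m2 / m1)
    list(p = p, effect = effect, degenerate = FALSE)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  effect <- vapply(res, `[[`, numeric(1), "effect")
  out <- tibble::tibble(
    feature_id = rownames(mat),
    p_value = p,
    p_adj = p_adj,
    effect = effect,
    direction = ifelse(effect < 0, "down", "up"),
    significant = p_adj <= alpha &
      !vapply(res, `[[`, logical(1), "degenerate"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"))
  attr(out, "groups") <- chk$groups
  attr(out, "test") <- test
  attr(out, "alpha") <- alpha
  class(out) <- c("differential_result", class(out))
  out
}
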