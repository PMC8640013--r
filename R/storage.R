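# Multivariate analysis of factorial storage-quality experiments:
# standardization, Ward/Euclidean hierarchical clustering of treatment
# profiles, per-cluster Pearson correlations, and compact letter displays
# from one-way ANOVA + Tukey's HSD.

STORAGE_FACTORS <- c("harvest_moisture_pct", "drying_temp", "storage_temp_C",
                     "package", "time_months")
STORAGE_VARIABLES <- c("moisture_pct", "ec", "oil_pct", "acidity_ml",
                       "protein_pct")

#' Treatment-mean matrix from storage records
#'
#' Averages the quality variables over replicates for every factor
#' combination (treatment), producing the treatments x variables matrix
#' that feeds standardization and clustering.
#'
#' @param records storage records: a data frame with the factor columns
#'   `harvest_moisture_pct`, `drying_temp`, `storage_temp_C`, `package`,
#'   `time_months`, a `replicate` column, and the quality variables.
#' @param variables quality variables to keep (default: moisture, EC,
#'   oil, acidity, protein).
#' @return A numeric matrix with one row per treatment; row names encode
#'   the factor levels, and the factor combinations are attached as
#'   attribute `treatments`.
#' @export
treatment_matrix <- function(records, variables = STORAGE_VARIABLES) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(c(STORAGE_FACTORS, variables), names(records))
  if (length(miss)) {
    stop_contract("records are missing column(s): ", paste(miss, collapse = ", "))
  }
  agg <- stats::aggregate(records[variables],
                          by = records[STORAGE_FACTORS], FUN = mean)
  m <- as.matrix(agg[variables])
  rownames(m) <- do.call(paste, c(agg[STORAGE_FACTORS], list(sep = "/")))
  attr(m, "treatments") <- agg[STORAGE_FACTORS]
  m
}

#' Standardize a treatments x variables matrix
#'
#' Centers each column to mean 0 and scales to sample standard deviation
#' 1 - the usual preparation before Euclidean-distance clustering of
#' variables on different measurement scales.
#'
#' @param m numeric matrix with at least 2 rows and no constant column.
#' @return The standardized matrix.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop_contract("need at least 2 rows to standardize")
  sds <- apply(m, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    stop_contract("constant column(s): ",
                  paste(colnames(m)[bad] %||% bad, collapse = ", "))
  }
  scale(m)[, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ward hierarchical clustering of treatments
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean
#' distances between standardized treatment profiles, with labels from
#' cutting the tree into `k` groups. The Ward dialect is the
#' squared-Euclidean minimum-variance update (`hclust` method
#' `"ward.D2"`, which takes plain Euclidean distances); dialects differ
#' between implementations, so this one is fixed and documented.
#'
#' @param z standardized matrix from [standardize()].
#' @param k number of clusters, `1 <= k <= nrow(z)`.
#' @return An object of class `cluster_result`: list with
#'   `treatment_ids`, `labels` (1..k), `merge_heights` (non-decreasing),
#'   `k`, and the underlying `hclust` object.
#' @export
ward_cluster <- function(z, k) {
  z <- as.matrix(z)
  stopifnot(is.numeric(k), length(k) == 1)
  if (k < 1 || k > nrow(z)) {
    stop_contract("k must lie between 1 and the number of rows (", nrow(z), ")")
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(treatment_ids = rownames(z) %||% as.character(seq_len(nrow(z))),
                 labels = unname(labels), merge_heights = hc$height,
                 k = as.integer(k), hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d treatments in %d groups (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Per-cluster Pearson correlation matrices
#'
#' Pairwise Pearson correlations between the (raw, unstandardized)
#' quality variables within each cluster. Clusters with fewer than 3
#' members, and variable pairs involving a within-cluster constant
#' variable, yield `NA` entries rather than fabricated zeros.
#'
#' @param m raw treatments x variables matrix (same row order as the
#'   clustering input).
#' @param labels cluster assignment per row.
#' @return Named list (one element per cluster, `"1"`, `"2"`, ...) of
#'   correlation matrices with unit diagonal.
#' @export
cluster_correlations <- function(m, labels) {
  m <- as.matrix(m)
  if (length(labels) != nrow(m)) {
    stop_contract("`labels` length must match the number of rows")
  }
  out <- list()
  for (g in sort(unique(labels))) {
    sub <- m[labels == g, , drop = FALSE]
    if (nrow(sub) < 3) {
      cm <- matrix(NA_real_, ncol(m), ncol(m),
                   dimnames = list(colnames(m), colnames(m)))
      diag(cm) <- 1
    } else {
      cm <- suppressWarnings(stats::cor(sub, method = "pearson"))
      diag(cm) <- 1
    }
    out[[as.character(g)]] <- cm
  }
  out
}

# compact letter display by insert-and-absorb over a logical
# "significantly different" pair matrix
.letters_insert_absorb <- function(levels_ordered, diff_pairs) {
  sets <- list(levels_ordered)
  for (pr in diff_pairs) {
    i <- pr[1]; j <- pr[2]
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], i)
        b <- setdiff(sets[[s]], j)
        sets[[s]] <- a
        sets[[length(sets) + 1]] <- b
      }
    }
    # absorb: drop sets contained in another
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) {
      for (t in seq_along(sets)) {
        if (s != t && keep[t] &&
            all(sets[[s]] %in% sets[[t]]) &&
            (length(sets[[s]]) < length(sets[[t]]) || s > t)) {
          keep[s] <- FALSE
          break
        }
      }
    }
    sets <- sets[keep]
  }
  # order letter sets by the best-ranked member so 'a' goes to the top group
  first_member <- vapply(sets, function(s) min(match(s, levels_ordered)), numeric(1))
  sets <- sets[order(first_member)]
  vapply(levels_ordered, function(lv) {
    paste(letters[which(vapply(sets, function(s) lv %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Compact letter display from one-way ANOVA and Tukey's HSD
#'
#' Runs a one-way ANOVA of `response` on `factor`, applies Tukey's
#' honestly-significant-difference test at level `alpha`, and assigns
#' compact letters: levels sharing a letter do not differ significantly.
#' Letters are assigned in order of decreasing group mean ('a' for the
#' highest mean).
#'
#' @param data data frame holding the response and factor columns.
#' @param response name of the (numeric) response column.
#' @param factor name of the grouping column (>= 2 levels, each with
#'   >= 2 replicates).
#' @param alpha significance level (0.05 or 0.01 in the usual reporting).
#' @return Data frame with columns `level`, `n`, `mean`, `letters`,
#'   ordered by decreasing mean.
#' @export
tukey_letters <- function(data, response, factor, alpha = 0.05) {
  stopifnot(is.data.frame(data), response %in% names(data),
            factor %in% names(data), alpha > 0, alpha < 1)
  y <- data[[response]]
  f <- as.factor(data[[factor]])
  check_numeric(y, response)
  counts <- table(f)
  if (length(counts) < 2) stop_contract("need at least 2 factor levels")
  if (any(counts < 2)) {
    stop_contract("every level needs at least 2 replicates (violated by: ",
                  paste(names(counts)[counts < 2], collapse = ", "), ")")
  }
  means <- tapply(y, f, mean)
  lv <- names(sort(means, decreasing = TRUE))
  if (stats::var(y) == 0) {
    lets <- stats::setNames(rep("a", length(lv)), lv)
  } else {
    # recode levels so TukeyHSD pair labels split unambiguously
    code <- stats::setNames(paste0("L", seq_along(levels(f))), levels(f))
    fc <- factor(unname(code[as.character(f)]), levels = unname(code))
    fit <- stats::aov(y ~ fc)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$fc
    padj <- tk[, "p adj"]
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    decode <- stats::setNames(names(code), code)
    sig <- which(!is.na(padj) & padj < alpha)
    diff_pairs <- lapply(sig, function(i) unname(decode[pairs[[i]]]))
    lets <- .letters_insert_absorb(lv, diff_pairs)
  }
  out <- data.frame(level = lv, n = as.integer(counts[lv]),
                    mean = as.numeric(means[lv]),
                    letters = unname(lets[lv]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
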