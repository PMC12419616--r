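#' Hierarchical patient stratification with automatic cluster count
#'
#' Agglomerative clustering (Ward criterion, Euclidean distance) of
#' per-patient vectors -- attribution vectors one day before death in the
#' primary arm, standardized raw day-1 laboratory values in the
#' comparison arm. The number of subtypes is chosen as the silhouette
#' argmax over `k_range`; the elbow curve (within-cluster sum of squares
#' per k) is reported alongside for inspection, and a fixed `k` override
#' reproduces any manual choice.
#'
#' @param x a `shap_panel` (day-1 correct positives) or a numeric matrix
#'   with one row per patient (rownames = patient ids).
#' @param k_range candidate cluster counts (default 2:10).
#' @param k optional fixed cluster count, bypassing selection.
#' @param standardize standardize columns first (default FALSE; the
#'   raw-value arm passes TRUE so analytes on large scales do not
#'   dominate the distance).
#' @param space label recorded on the result (`"attribution"` or
#'   `"raw-value"`).
#' @return A `subtype_result`: list with `tree` (hclust), `k`, `labels`
#'   (named by patient), `selection` (data.frame `k`, `silhouette`,
#'   `wss`), `space`.
#' @export
cluster_and_select_k <- function(x, k_range = 2:10, k = NULL,
                                 standardize = FALSE,
                                 space = "attribution") {
  if (inherits(x, "shap_panel")) {
    X <- x$phi
    rownames(X) <- x$patient_id
  } else {
    X <- as.matrix(x)
  }
  if (anyNA(X)) stop("clustering input must have no missing cells")
  if (anyDuplicated(rownames(X)))
    stop("one row per patient is required")
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(X) < 2 * min(k_range))
    stop("too few patients to cluster over the requested k range")
  k_range <- k_range[k_range < nrow(X)]
  if (standardize) {
    sds <- apply(X, 2, sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  d <- dist(X)
  tree <- hclust(d, method = "ward.D2")
  sel <- data.frame(k = k_range, silhouette = NA_real_, wss = NA_real_)
  lab_k <- list()
  for (i in seq_along(k_range)) {
    kk <- k_range[i]
    lab <- cutree(tree, kk)
    lab_k[[i]] <- lab
    sil <- cluster::silhouette(lab, d)
    sel$silhouette[i] <- mean(sil[, "sil_width"])
    sel$wss[i] <- sum(vapply(split(seq_len(nrow(X)), lab), function(ix) {
      xc <- X[ix, , drop = FALSE]
      sum(sweep(xc, 2, colMeans(xc))^2)
    }, numeric(1)))
  }
  if (is.null(k)) {
    k <- k_range[which.max(sel$silhouette)]
    labels <- lab_k[[which.max(sel$silhouette)]]
  } else {
    labels <- cutree(tree, k)
  }
  names(labels) <- rownames(X)
  structure(list(tree = tree, k = as.integer(k), labels = labels,
                 selection = sel, space = space),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("<subtype_result> %s space, k = %d, sizes: %s\n", x$space, x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Per-subtype laboratory summaries and hypothesis tests
#'
#' For each laboratory parameter, reports median and IQR per subtype, an
#' omnibus Kruskal-Wallis test across subtypes and -- where the corrected
#' omnibus is significant -- pairwise Mann-Whitney follow-ups localizing
#' the difference. Categorical attributes (sex, age group, disease
#' category, ...) are tested by chi-square, or Fisher's exact test when
#' any expected count falls below 5. Omnibus p-values (labs and
#' categoricals together) are Holm-corrected as one family and pairwise
#' p-values Holm-corrected within each variable; the gatekeeping keeps
#' the family-wise error at `alpha` under the global null. Rank-based
#' tests match the skewed, median/IQR-style reporting of terminal lab
#' values.
#'
#' @param labels named subtype labels (from [cluster_and_select_k()]).
#' @param labs data.frame of per-patient laboratory values: `patient_id`
#'   plus one numeric column per parameter (missing values allowed,
#'   dropped per test).
#' @param attributes optional data.frame: `patient_id` plus categorical
#'   columns.
#' @param alpha significance level after correction (default 0.01).
#' @return A `subtype_summary`: list with `counts`, `lab_summary`
#'   (subtype x lab median/IQR), `tests` (omnibus), `pairwise`, `alpha`,
#'   `skipped` (subtypes with n < 3, excluded from testing).
#' @export
subtype_summary_and_tests <- function(labels, labs, attributes = NULL,
                                      alpha = 0.01) {
  stopifnot(!is.null(names(labels)), "patient_id" %in% names(labs))
  ids <- intersect(names(labels), labs$patient_id)
  z <- labels[ids]
  labvals <- labs[match(ids, labs$patient_id), setdiff(names(labs), "patient_id"),
                  drop = FALSE]
  counts <- table(subtype = z)
  small <- names(counts)[counts < 3]
  test_ok <- !(as.character(z) %in% small)
  if (length(unique(z[test_ok])) < 2) {
    warning("fewer than two testable subtypes; tests skipped")
    test_ok[] <- FALSE
  }

  summ <- do.call(rbind, lapply(sort(unique(z)), function(g) {
    do.call(rbind, lapply(names(labvals), function(v) {
      vals <- labvals[z == g, v]
      vals <- vals[!is.na(vals)]
      q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(subtype = g, parameter = v, n = length(vals),
                 median = q[2], q25 = q[1], q75 = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL

  tests <- NULL; pairwise <- NULL
  if (any(test_ok)) {
    zt <- factor(z[test_ok])
    omni <- list()
    for (v in names(labvals)) {
      vals <- labvals[test_ok, v]
      ok <- !is.na(vals)
      kt <- kruskal.test(vals[ok], zt[ok])
      omni[[v]] <- data.frame(variable = v, type = "lab",
                              test = "kruskal-wallis",
                              statistic = unname(kt$statistic),
                              p = kt$p.value, stringsAsFactors = FALSE)
    }
    if (!is.null(attributes)) {
      aids <- match(ids[test_ok], attributes$patient_id)
      for (v in setdiff(names(attributes), "patient_id")) {
        av <- attributes[aids, v]
        ok <- !is.na(av)
        tab <- table(zt[ok], av[ok])
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (any(dim(tab) < 2)) next
        expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expd < 5)) {
          ft <- fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                            B = 10000)
          omni[[v]] <- data.frame(variable = v, type = "categorical",
                                  test = "fisher", statistic = NA_real_,
                                  p = ft$p.value, stringsAsFactors = FALSE)
        } else {
          ct <- suppressWarnings(chisq.test(tab))
          omni[[v]] <- data.frame(variable = v, type = "categorical",
                                  test = "chi-square",
                                  statistic = unname(ct$statistic),
                                  p = ct$p.value, stringsAsFactors = FALSE)
        }
      }
    }
    tests <- do.call(rbind, omni)
    rownames(tests) <- NULL
    tests$p_adj <- p.adjust(tests$p, method = "holm")
    tests$significant <- tests$p_adj < alpha

    sig_labs <- tests$variable[tests$significant & tests$type == "lab"]
    pw <- list()
    groups <- levels(zt)
    for (v in sig_labs) {
      vals <- labvals[test_ok, v]
      prs <- utils::combn(groups, 2, simplify = FALSE)
      rows <- do.call(rbind, lapply(prs, function(pr) {
        a <- vals[zt == pr[1]]; b <- vals[zt == pr[2]]
        wt <- suppressWarnings(wilcox.test(a[!is.na(a)], b[!is.na(b)]))
        data.frame(variable = v, group1 = pr[1], group2 = pr[2],
                   statistic = unname(wt$statistic), p = wt$p.value,
                   stringsAsFactors = FALSE)
      }))
      rows$p_adj <- p.adjust(rows$p, method = "holm")
      rows$significant <- rows$p_adj < alpha
      pw[[v]] <- rows
    }
    if (length(pw)) {
      pairwise <- do.call(rbind, pw)
      rownames(pairwise) <- NULL
    }
  }

  structure(list(counts = counts, lab_summary = summ, tests = tests,
                 pairwise = pairwise, alpha = alpha, skipped = small),
            class = "subtype_summary")
}

#' Behavior matrices recomputed per subtype
#'
#' Restricts each horizon's panel to the patients of one subtype and
#' reassembles the behavior matrix, per subtype. A subtype with no
#' retained row at some horizon gets an unavailable (`NA`) column there.
#'
#' @param labels named subtype labels.
#' @param panels per-horizon `shap_panel`s (correct positives).
#' @return named list of `shap_behavior_matrix`, one per subtype.
#' @export
subtype_behaviors <- function(labels, panels) {
  stopifnot(!is.null(names(labels)))
  out <- list()
  for (g in sort(unique(labels))) {
    ids <- names(labels)[labels == g]
    sub <- lapply(panels, function(p) panel_subset(p, which(p$patient_id %in% ids)))
    out[[as.character(g)]] <- behavior_matrix(sub)
  }
  out
}
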