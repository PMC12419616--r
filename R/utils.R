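#' Area under the ROC curve
#'
#' Thin wrapper around [pROC::roc()] with the orientation fixed so that
#' scores larger for positives give AUROC > 0.5.
#'
#' @param y binary labels (0/1).
#' @param score numeric scores, higher = more positive.
#' @return AUROC as a single number.
#' @export
auroc <- function(y, score) {
  stopifnot(length(y) == length(score))
  r <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Derive a reproducible child seed
#'
#' Maps a master seed and a stage label to a deterministic child seed, so
#' every stage of a run draws from its own stream while the whole run
#' stays reproducible from one integer. Always below 2^31 - 1, hence a
#' valid R integer seed.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483629)
}

# Spearman correlation that tolerates constant inputs (returns 0).
spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y, method = "spearman")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}
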