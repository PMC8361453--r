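#' Dice similarity coefficient
#'
#' \deqn{DSC(T, P) = 2 |T \cap P| / (|T| + |P|);} two empty masks count
#' as perfect agreement (DSC = 1).
#'
#' @param truth_mask,pred_mask logical (or 0/1) arrays of the same shape.
#' @return value in [0, 1].
#' @export
dsc <- function(truth_mask, pred_mask) {
  check_masks(truth_mask, pred_mask)
  t_n <- sum(truth_mask); p_n <- sum(pred_mask)
  if (t_n + p_n == 0) return(1)
  2 * sum(truth_mask & pred_mask) / (t_n + p_n)
}

#' Jaccard index
#'
#' \deqn{J(T, P) = |T \cap P| / |T \cup P|;} two empty masks count as 1.
#' Related to Dice by \eqn{DSC = 2J / (1 + J)}.
#'
#' @inheritParams dsc
#' @return value in [0, 1].
#' @export
jaccard <- function(truth_mask, pred_mask) {
  check_masks(truth_mask, pred_mask)
  uni <- sum(truth_mask | pred_mask)
  if (uni == 0) return(1)
  sum(truth_mask & pred_mask) / uni
}

check_masks <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop_input("masks must have identical shapes")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop_input("masks must be binary")
  invisible(TRUE)
}

#' Partition coefficient
#'
#' \deqn{V_{pc} = (1/n) \sum_j \sum_i u_{ij}^2,} ranging from 1/c (uniform
#' memberships) to 1 (hard partition); crisper partitions score higher.
#'
#' @param U c x n membership matrix with unit column sums.
#' @return value in [1/c, 1].
#' @export
v_pc <- function(U) sum(U^2) / ncol(U)

#' Partition entropy
#'
#' The Bezdek partition entropy
#' \deqn{V_{pe} = -(1/n) \sum_j \sum_i u_{ij} \ln u_{ij}} (natural log,
#' with 0 ln 0 = 0), ranging from 0 (hard partition) to ln c (uniform).
#' \code{literal = TRUE} instead evaluates the unsigned
#' \eqn{(1/n) \sum u^2 \ln u} variant for comparison.
#'
#' @param U c x n membership matrix.
#' @param literal evaluate the unsigned squared-membership variant.
#' @return entropy value; in [0, ln c] for the default form.
#' @export
v_pe <- function(U, literal = FALSE) {
  lg <- ifelse(U > 0, log(U), 0)
  if (literal) sum(U^2 * lg) / ncol(U) else -sum(U * lg) / ncol(U)
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}(max\_value^2 / MSE)} in decibels; identical
#' images return \code{Inf}.
#'
#' @param reference,test numeric arrays of the same shape.
#' @param max_value peak intensity of the representation (1 for unit-range
#'   floats, 255 for 8-bit).
#' @return decibels (possibly \code{Inf}).
#' @export
psnr <- function(reference, test, max_value = 1) {
  if (!identical(dim(reference), dim(test)))
    stop_input("images must have identical shapes")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Match predicted cluster labels to ground-truth classes
#'
#' Cluster indices are arbitrary, so before per-class overlap can be
#' scored the prediction is relabeled by the one-to-one assignment that
#' maximizes total pixel overlap with the truth (exhaustive over
#' permutations; intended for c <= 6).
#'
#' @param pred integer label map (0-based), possibly with fewer classes
#'   than the truth.
#' @param truth integer label map of the same shape.
#' @return list with \code{mapping} (index i+1 gives the truth label
#'   assigned to predicted label i) and \code{relabeled} (the remapped
#'   prediction).
#' @export
match_labels <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop_input("label maps must have identical shapes")
  p_lab <- sort(unique(as.vector(pred)))
  t_lab <- sort(unique(as.vector(truth)))
  n_t <- max(length(t_lab), length(p_lab))
  conf <- matrix(0, n_t, length(p_lab))  # truth x pred overlap counts
  for (i in seq_along(t_lab))
    for (k in seq_along(p_lab))
      conf[i, k] <- sum(truth == t_lab[i] & pred == p_lab[k])
  best <- NULL; best_score <- -1
  for (perm in all_perms(n_t)) {
    score <- sum(conf[cbind(perm[seq_along(p_lab)], seq_along(p_lab))])
    if (score > best_score) { best_score <- score; best <- perm }
  }
  t_ext <- c(t_lab, max(t_lab) + seq_len(n_t - length(t_lab)))
  mapping <- t_ext[best[seq_along(p_lab)]]
  relabeled <- pred
  for (k in seq_along(p_lab)) relabeled[pred == p_lab[k]] <- mapping[k]
  list(mapping = mapping, relabeled = relabeled)
}

#' Bundle segmentation-quality metrics into a validity report
#'
#' Computes the fuzzy validity indices from the membership matrix and,
#' when a ground truth is supplied, per-class Dice and Jaccard after
#' label matching; when a clean reference and a test image are supplied,
#' their PSNR.
#'
#' @param U membership matrix (or NULL).
#' @param pred hard label map (or NULL; derived from U if absent).
#' @param truth ground-truth label map (optional).
#' @param clean,test clean reference and degraded/denoised image for PSNR
#'   (optional).
#' @param max_value PSNR peak value (default 1, unit-range floats).
#' @param shape image shape when pred must be derived from U.
#' @return An object of class \code{validity_report}: fields \code{v_pc},
#'   \code{v_pe}, \code{dsc_per_class}, \code{jaccard_per_class},
#'   \code{psnr_db}, \code{label_mapping}, \code{psnr_max_value}.
#' @export
validity_report <- function(U = NULL, pred = NULL, truth = NULL,
                            clean = NULL, test = NULL, max_value = 1,
                            shape = NULL) {
  rep <- list(v_pc = NA_real_, v_pe = NA_real_,
              dsc_per_class = NULL, jaccard_per_class = NULL,
              psnr_db = NA_real_, psnr_max_value = max_value,
              label_mapping = NULL)
  if (!is.null(U)) {
    rep$v_pc <- v_pc(U)
    rep$v_pe <- v_pe(U)
    if (is.null(pred)) pred <- defuzzify(U, shape)
  }
  if (!is.null(truth) && !is.null(pred)) {
    m <- match_labels(pred, truth)
    rep$label_mapping <- m$mapping
    classes <- sort(unique(as.vector(truth)))
    rep$dsc_per_class <- vapply(classes, function(k)
      dsc(truth == k, m$relabeled == k), numeric(1))
    rep$jaccard_per_class <- vapply(classes, function(k)
      jaccard(truth == k, m$relabeled == k), numeric(1))
    names(rep$dsc_per_class) <- names(rep$jaccard_per_class) <-
      paste0("class", classes)
  }
  if (!is.null(clean) && !is.null(test))
    rep$psnr_db <- psnr(clean, test, max_value)
  structure(rep, class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  cat(sprintf("  V_pc = %.4f, V_pe = %.4f\n", x$v_pc, x$v_pe))
  if (!is.null(x$dsc_per_class)) {
    cat("  DSC per class:    ", paste(sprintf("%.4f", x$dsc_per_class), collapse = " "), "\n")
    cat("  Jaccard per class:", paste(sprintf("%.4f", x$jaccard_per_class), collapse = " "), "\n")
  }
  if (is.finite(x$psnr_db)) cat(sprintf("  PSNR = %.2f dB (max %g)\n", x$psnr_db, x$psnr_max_value))
  invisible(x)
}
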