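# Overlap and lesion-wise detection metrics.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`: 0 is no overlap, 1 full overlap. Both
#' masks empty is defined as perfect agreement (1).
#'
#' @param a,b 3D logical arrays (or anything coercible; non-zero =
#'   foreground) of identical shape.
#' @return Scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch in dice")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Lesion-wise detection metrics
#'
#' Works on 26-connected components rather than voxels: a true lesion
#' counts as detected if at least one of its voxels overlaps any predicted
#' component. TPR is the fraction of true lesions detected; FPR is the
#' fraction of predicted components with no true-lesion overlap (false
#' discovery fraction — conventions differ between challenges, so this
#' definition is stated explicitly); the F-score combines precision
#' `P = 1 - FPR` and recall `R = TPR` as `2PR / (P + R)`.
#'
#' Empty-set conventions: both masks empty gives TPR 1, FPR 0, F 1;
#' empty prediction with non-empty truth gives TPR 0, FPR 0, F 0; non-empty
#' prediction with empty truth gives TPR 1, FPR 1, F 0.
#'
#' @param pred,truth 3D logical arrays of identical shape.
#' @return List with `tpr`, `fpr`, `f_score`, and `counts` (true lesions,
#'   detected, predicted components, false-positive components).
#' @export
lesion_detection_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch in lesion metrics")
  pred <- pred != 0; truth <- truth != 0
  cct <- label_components(truth)
  ccp <- label_components(pred)
  nt <- max(cct); np <- max(ccp)
  detected <- if (nt > 0) length(unique(cct[cct != 0L & pred])) else 0L
  fp_comps <- if (np > 0) np - length(unique(ccp[ccp != 0L & truth])) else 0L
  tpr <- if (nt > 0) detected / nt else 1
  fpr <- if (np > 0) fp_comps / np else 0
  p <- 1 - fpr
  r <- tpr
  f <- if (nt == 0 && np == 0) 1 else if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(tpr = tpr, fpr = fpr, f_score = f,
       counts = c(truth_lesions = nt, detected = detected,
                  predicted_components = np, false_positive_components = fp_comps))
}

#' Evaluate a segmentation against ground truth
#'
#' Structures mode: per-class Dice for classes 1..K-1 and their mean.
#' Lesions mode: Dice of the lesion mask plus lesion-wise detection metrics.
#'
#' @param result A `segmentation_result` or `label_map` with the predicted
#'   labels.
#' @param truth The ground-truth `label_map`.
#' @param mode `"structures"` or `"lesions"`; defaults to the result's mode.
#' @return An object of class `metric_report`: `per_class` (named Dice
#'   vector, structures), `mean_dsc`, and (lesions) `tpr`, `fpr`,
#'   `f_score`; `row` holds a one-row data frame for tabulation.
#' @export
evaluate_case <- function(result, truth, mode = NULL) {
  pred <- if (inherits(result, "segmentation_result")) result$labels else result
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (!identical(dim(pred$data), dim(truth$data))) {
    stop("evaluation error: prediction and truth shapes differ")
  }
  if (is.null(mode)) {
    mode <- if (inherits(result, "segmentation_result")) result$mode
    else if (truth$class_count > 2L) "structures" else "lesions"
  }
  if (mode == "structures") {
    K <- truth$class_count
    if (pred$class_count > K) {
      stop("evaluation error: prediction has more classes than the truth")
    }
    classes <- seq_len(K - 1L)
    dscs <- vapply(classes, function(k) dice(pred$data == k, truth$data == k),
                   numeric(1))
    names(dscs) <- paste0("class", classes)
    rep <- list(mode = mode, per_class = dscs, mean_dsc = mean(dscs),
                row = data.frame(t(c(dscs, mean_dsc = mean(dscs)))))
  } else {
    pm <- pred$data != 0L; tm <- truth$data != 0L
    det <- lesion_detection_metrics(pm, tm)
    d <- dice(pm, tm)
    rep <- list(mode = mode, mean_dsc = d, dsc = d, tpr = det$tpr,
                fpr = det$fpr, f_score = det$f_score, counts = det$counts,
                row = data.frame(dsc = d, tpr = det$tpr, fpr = det$fpr,
                                 f_score = det$f_score))
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> ", x$mode, " mode\n", sep = "")
  if (x$mode == "structures") {
    print(round(x$per_class, 4))
    cat("  mean DSC: ", round(x$mean_dsc, 4), "\n", sep = "")
  } else {
    cat("  DSC ", round(x$dsc, 4), "  TPR ", round(x$tpr, 4),
        "  FPR ", round(x$fpr, 4), "  F ", round(x$f_score, 4), "\n", sep = "")
  }
  invisible(x)
}
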