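# Evaluation of predicted T stages against gold labels: substage accuracy,
# collapsed stage accuracy, size-only accuracy, per-class one-vs-rest
# precision/recall/F1 and the full confusion matrix.

#' Collapse a T-substage label to its stage
#'
#' `T1a/T1b/T1c -> T1`; `T2/T2a/T2b -> T2`; `T3`, `T4` and `Tx` unchanged.
#'
#' @param label character vector of T labels.
#' @return Character vector of collapsed labels.
#' @export
collapse_stage <- function(label) {
  out <- label
  out[label %in% c("T1a", "T1b", "T1c")] <- "T1"
  out[label %in% c("T2a", "T2b")] <- "T2"
  out
}

#' Score predictions against gold labels
#'
#' Computes the three accuracy views — substage accuracy, stage accuracy
#' after collapsing substages, and size-only accuracy where the prediction
#' is rebuilt from the size component alone (absent size scored as Tx) —
#' plus per-class one-vs-rest precision/recall/F1 with supports, and the
#' confusion matrix over all nine labels. A class never predicted has
#' undefined precision, reported as `NA` (serialized as `null`), not 0.
#'
#' @param predictions named character vector of predicted labels, or a
#'   named list of `tstage_result` objects (required for the size-only
#'   view).
#' @param gold named character vector of gold labels; names must match the
#'   prediction ids exactly.
#' @return A list of class `eval_report`.
#' @export
evaluate_staging <- function(predictions, gold) {
  if (is.list(predictions) && length(predictions) &&
      inherits(predictions[[1]], "tstage_result")) {
    size_labels <- vapply(predictions, function(r)
      if (is.na(r$size_component)) "Tx" else r$size_component, "")
    predictions <- vapply(predictions, `[[`, "", "label")
    names(size_labels) <- names(predictions)
  } else {
    predictions <- unlist(predictions)
    size_labels <- NULL
  }
  if (is.null(names(predictions)) || is.null(names(gold)))
    stop("input error: predictions and gold must be named by report id")
  only_pred <- setdiff(names(predictions), names(gold))
  only_gold <- setdiff(names(gold), names(predictions))
  if (length(only_pred) || length(only_gold))
    stop("input error: id mismatch; only in predictions: {",
         paste(only_pred, collapse = ", "), "}; only in gold: {",
         paste(only_gold, collapse = ", "), "}")
  n <- length(gold)
  if (n < 1L) stop("input error: need at least one case")
  pred <- predictions[names(gold)]
  bad <- setdiff(unique(c(pred, gold)), T_LEVELS)
  if (length(bad)) stop("input error: unknown label(s) ", paste(bad, collapse = ", "))

  acc_sub <- mean(pred == gold)
  acc_stage <- mean(collapse_stage(pred) == collapse_stage(gold))
  acc_size <- if (is.null(size_labels)) NA_real_
              else mean(size_labels[names(gold)] == gold)

  lv <- T_LEVELS
  confusion <- table(factor(gold, levels = lv), factor(pred, levels = lv))
  dimnames(confusion) <- list(true = lv, predicted = lv)
  per_class <- lapply(lv, function(cl) {
    tp <- sum(pred == cl & gold == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(pred != cl & gold == cl)
    support <- tp + fn
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (support == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_
          else 2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1, support = support)
  })
  names(per_class) <- lv
  structure(list(accuracy_substage = acc_sub, accuracy_stage = acc_stage,
                 accuracy_size_only = acc_size, per_class = per_class,
                 confusion = confusion, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over n = %d reports\n", x$n))
  cat(sprintf("  accuracy (T-substage):  %.3f\n", x$accuracy_substage))
  cat(sprintf("  accuracy (T-stage):     %.3f\n", x$accuracy_stage))
  if (!is.na(x$accuracy_size_only))
    cat(sprintf("  accuracy (size-only):   %.3f\n", x$accuracy_size_only))
  cat("  per class (precision/recall/F1/support):\n")
  for (cl in names(x$per_class)) {
    m <- x$per_class[[cl]]
    if (m$support == 0 && is.na(m$precision)) next
    fmt <- function(v) if (is.na(v)) "  NA" else sprintf("%.2f", v)
    cat(sprintf("    %-4s %s / %s / %s / %d\n", cl, fmt(m$precision),
                fmt(m$recall), fmt(m$f1), m$support))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
eval_report_json <- function(report, path = NULL) {
  obj <- list(n = report$n,
              accuracy_substage = report$accuracy_substage,
              accuracy_stage = report$accuracy_stage,
              accuracy_size_only = report$accuracy_size_only,
              per_class = report$per_class,
              confusion = list(labels = rownames(report$confusion),
                               matrix = unclass(unname(apply(report$confusion, 1,
                                                             as.integer,
                                                             simplify = FALSE)))))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", digits = NA)
  if (!is.null(path)) { writeLines(json, path, useBytes = TRUE); return(invisible(as.character(json))) }
  as.character(json)
}

#' Diff predicted findings against a gold record
#'
#' Lists mismatched components (primary size, involvement structures,
#' presence kinds) of one document against its planted gold findings, to
#' support error triage.
#'
#' @param doc an annotated `annotation_document`.
#' @param gold_record a gold record from [generate_report()].
#' @return Data frame with columns `component`, `expected`, `observed`;
#'   zero rows on exact match.
#' @export
diff_findings <- function(doc, gold_record) {
  get_parts <- function(findings) {
    size <- NA_real_; inv <- character(0); pres <- character(0)
    for (f in findings) {
      if (f$role == "primary") size <- f$size_mm
      inv <- c(inv, f$involvement$structure)
      pres <- c(pres, f$presence$kind)
    }
    list(size = size, inv = sort(unique(inv)), pres = sort(unique(pres)))
  }
  p <- get_parts(doc$findings)
  g <- get_parts(gold_record$planted)
  rows <- list()
  add <- function(component, expected, observed)
    rows[[length(rows) + 1L]] <<- data.frame(component = component,
                                             expected = expected,
                                             observed = observed,
                                             stringsAsFactors = FALSE)
  if (!identical(is.na(p$size), is.na(g$size)) ||
      (!is.na(p$size) && p$size != g$size))
    add("size", paste(g$size, "mm"), paste(p$size, "mm"))
  if (!identical(p$inv, g$inv))
    add("involvement", paste(g$inv, collapse = "+"), paste(p$inv, collapse = "+"))
  if (!identical(p$pres, g$pres))
    add("presence", paste(g$pres, collapse = "+"), paste(p$pres, collapse = "+"))
  if (!length(rows))
    return(data.frame(component = character(0), expected = character(0),
                      observed = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
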